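# Small built-in ontologies: byte-stable named fixtures exercising every
# semantic function, plus seeded random DAGs for property tests.  The named
# fixtures are the minimal graphs consistent with the behaviour each
# function is documented to show; they stand in for real ontologies (GO,
# human anatomy, insect anatomy) at desk scale.

fixture_names <- c("fig2", "fig3", "fig4", "tribolium")

#' Built-in fixture ontologies and random DAGs
#'
#' `"fig2"`: a regulation-of-binding slice of a process ontology, pure
#' `is_a`, rooted at "thing" (level 1), with classes down to level 8; the
#' marked input set for clustering examples is attached as attribute
#' `marked`.  `"fig3"`: an abstract anatomy slice with organs under an
#' `organ` anchor and cells/tissues tied in by `isPartOf`, `isCellOf`,
#' `isPartOfOrgan` and a `differentiatesInto` edge that rollup must
#' ignore.  `"fig4"`: a partonomy/hierarchy slice (kidney, digestive
#' organs) for set-restricted search; the predefined list is attached as
#' attribute `member_set`.  `"tribolium"`: a staged insect-anatomy slice
#' with developmental stages, generic structures and stage-concrete
#' classes.  `"random"`: a seeded random rooted DAG with optional
#' `isPartOf` edges (acyclic by construction).
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4"`, `"tribolium"`,
#'   `"random"`.
#' @param seed Integer seed (random fixtures only).
#' @param size Node count including the root (random only, >= 2).
#' @param max_parents Maximum `is_a` parents per node (random only).
#' @param p_relation Probability that a node also gets one `isPartOf` edge
#'   to a random earlier node (random only).
#' @return A rooted `ontology_graph`.
#' @export
make_fixture <- function(name, seed = 1L, size = 30L, max_parents = 2L,
                         p_relation = 0) {
  switch(name,
         fig2 = fixture_fig2(),
         fig3 = fixture_fig3(),
         fig4 = fixture_fig4(),
         tribolium = fixture_tribolium(),
         random = fixture_random(seed, size, max_parents, p_relation),
         stop_not_found(paste0("unknown fixture '", name, "'")))
}

cls_list <- function(ids) lapply(ids, function(i)
  ontology_class(i, label = gsub("_", " ", i)))

fixture_fig2 <- function() {
  is_a <- list(
    biological_process = "thing",
    biological_regulation = "biological_process",
    regulation_of_biological_process = "biological_regulation",
    regulation_of_molecular_function = "biological_regulation",
    regulation_of_signaling = "regulation_of_biological_process",
    regulation_of_binding = "regulation_of_molecular_function",
    negative_regulation_of_molecular_function = "regulation_of_molecular_function",
    regulation_of_protein_binding = "regulation_of_binding",
    negative_regulation_of_binding = c("regulation_of_binding",
                                       "negative_regulation_of_molecular_function"),
    negative_regulation_of_protein_binding = "regulation_of_protein_binding",
    positive_regulation_of_protein_binding = "regulation_of_protein_binding",
    regulation_of_cytokine_activity = "positive_regulation_of_protein_binding")
  ids <- unique(c("thing", names(is_a), unlist(is_a, use.names = FALSE)))
  g <- ontology_graph("fig2", cls_list(ids), is_a, root_id = "thing")
  attr(g, "marked") <- c("regulation_of_signaling",
                         "negative_regulation_of_protein_binding",
                         "regulation_of_cytokine_activity")
  g
}

fixture_fig3 <- function() {
  is_a <- list(Organ_1 = "organ", Organ_2 = "organ", Organ_3 = "organ")
  rel <- data.frame(
    source   = c("Cell_1", "Structure_A", "Cell_2", "Cell_2", "Tissue_1",
                 "Cell_2"),
    target   = c("Structure_A", "Organ_3", "Organ_1", "Tissue_1", "Organ_2",
                 "Cell_1"),
    relation = c("isCellOf", "isPartOf", "isCellOf", "isPartOf",
                 "isPartOfOrgan", "differentiatesInto"),
    stringsAsFactors = FALSE)
  ids <- unique(c("organ", names(is_a), rel$source, rel$target))
  g <- ontology_graph("fig3", cls_list(ids), is_a, rel)
  add_virtual_root(g)
}

fixture_fig4 <- function() {
  is_a <- list(liver = "digestive_organ", pancreas = "digestive_organ",
               stomach = "digestive_organ")
  rel <- data.frame(source = "nephron", target = "kidney",
                    relation = "isPartOf", stringsAsFactors = FALSE)
  ids <- unique(c("digestive_organ", "kidney", names(is_a),
                  rel$source, rel$target))
  g <- ontology_graph("fig4", cls_list(ids), is_a, rel)
  g <- add_virtual_root(g)
  attr(g, "member_set") <- c("kidney", "liver", "pancreas")
  g
}

fixture_tribolium <- function() {
  is_a <- list(larva = "developmental_stage", pupa = "developmental_stage",
               larval_head = "head", larval_antenna = "antenna",
               larval_flagellum = "flagellum", pupal_antenna = "antenna")
  rel <- data.frame(
    source   = c("larval_head", "larval_antenna", "larval_flagellum",
                 "pupal_antenna"),
    target   = c("larva", "larval_head", "larval_antenna", "pupa"),
    relation = "isPartOf", stringsAsFactors = FALSE)
  ids <- unique(c("developmental_stage", "head", "antenna", "flagellum",
                  names(is_a), rel$source, rel$target))
  classes <- cls_list(ids)
  g <- ontology_graph("tribolium", classes, is_a, rel)
  add_virtual_root(g)
}

fixture_random <- function(seed, size, max_parents, p_relation) {
  stopifnot(size >= 2, max_parents >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- c("thing", sprintf("n%02d", seq_len(size - 1L)))
  is_a <- list()
  for (k in seq.int(2L, size)) {
    np <- sample.int(min(max_parents, k - 1L), 1L)
    is_a[[ids[k]]] <- ids[sample.int(k - 1L, np)]  # earlier nodes only: DAG
  }
  rel <- empty_relations()
  if (p_relation > 0) {
    for (k in seq.int(2L, size)) {
      if (stats::runif(1) < p_relation) {
        rel <- rbind(rel, data.frame(
          source = ids[k], target = ids[sample.int(k - 1L, 1L)],
          relation = "isPartOf", stringsAsFactors = FALSE))
      }
    }
  }
  g <- ontology_graph(paste0("random", seed), cls_list(ids), is_a, rel)
  add_virtual_root(g)
}
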