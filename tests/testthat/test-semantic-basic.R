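test_that("search matches labels case-insensitively by substring", {
  fig2 <- make_fixture("fig2")
  expect_equal(
    search_cls(fig2, pattern = "binding"),
    c("negative_regulation_of_binding",
      "negative_regulation_of_protein_binding",
      "positive_regulation_of_protein_binding",
      "regulation_of_binding",
      "regulation_of_protein_binding"))
  expect_equal(search_cls(fig2, pattern = "BINDING"),
               search_cls(fig2, pattern = "binding"))
  expect_equal(search_cls(fig2, pattern = "zzz"), character())
  expect_error(search_cls(fig2, pattern = "  "),
               class = "obokit_argument_error")
})

test_that("search covers indexed annotation fields and honours restriction", {
  mk <- function(id, ...) ontology_class(id, annotations = list(...))
  g <- ontology_graph("anno", list(
    mk("pontocerebellar_cistern",
       definitionEnglish = "a cistern of the brain"),
    mk("basilar_artery",
       definitionEnglish = "artery near the pontocerebellar cistern"),
    mk("cistern_free", comment = "mentions cistern only in a comment")))
  cfg <- ontology_config("anno", indexed_fields = "definitionEnglish")

  # unrestricted: label or any indexed field
  expect_equal(search_cls(g, cfg, "cistern"),
               c("basilar_artery", "cistern_free",
                 "pontocerebellar_cistern"))
  # restricted to one field: label and other fields excluded
  expect_equal(search_cls(g, cfg, "cistern",
                          restrict_fields = "definitionEnglish"),
               c("basilar_artery", "pontocerebellar_cistern"))
  # unindexed fields are invisible even unrestricted
  expect_equal(search_cls(g, cfg, "mentions"), character())
  expect_error(search_cls(g, cfg, "x", restrict_fields = "comment"),
               class = "obokit_argument_error")
})

test_that("reduce_to_level maps a class to all ancestors at the level", {
  fig2 <- make_fixture("fig2")
  expect_equal(
    reduce_to_level(fig2, "negative_regulation_of_binding", 5),
    list(negative_regulation_of_binding =
           c("negative_regulation_of_molecular_function",
             "regulation_of_binding")))
  expect_equal(reduce_to_level(fig2, "thing", 1), list(thing = "thing"))
  # a class at exactly the level maps to itself
  expect_equal(
    reduce_to_level(fig2, "regulation_of_signaling", 5)[[1]],
    "regulation_of_signaling")
  # all root paths shorter than the level: class copied unchanged
  expect_equal(reduce_to_level(fig2, "biological_process", 7)[[1]],
               "biological_process")
  expect_error(reduce_to_level(fig2, "thing", 0),
               class = "obokit_argument_error")
  expect_error(reduce_to_level(fig2, "nope", 2),
               class = "obokit_not_found")
})

test_that("reduce_to_level equals root-path enumeration on random DAGs", {
  for (g in random_graph_cases(30, base_seed = 300L)) {
    ids <- class_ids(g)
    depth <- max(levels_of(g))
    res <- lapply(seq_len(depth), function(l) reduce_to_level(g, ids, l))
    for (id in ids) {
      maxlev <- oracle_level(g, id)
      for (l in seq_len(depth)) {
        want <- if (maxlev < l) id else oracle_level_ancestors(g, id, l)
        expect_equal(res[[l]][[id]], want,
                     info = sprintf("%s id=%s level=%d", g$name, id, l))
      }
    }
  }
})

test_that("cluster reduction follows the farthest-first trace", {
  fig2 <- make_fixture("fig2")
  marked <- attr(fig2, "marked")
  cls <- reduce_to_cluster_size(fig2, marked, 2)
  reps <- vapply(cls, `[[`, "", "representative")
  expect_equal(reps, c("regulation_of_protein_binding",
                       "regulation_of_signaling"))
  expect_equal(cls[[1]]$members,
               c("negative_regulation_of_protein_binding",
                 "regulation_of_cytokine_activity"))
  expect_equal(cls[[2]]$members, "regulation_of_signaling")
  # the two representatives sit at root distances 6 and 5
  expect_equal(sort(unname(vapply(reps, level_of, integer(1),
                                  graph = fig2))),
               c(5L, 6L))
})

test_that("cluster reduction trivial and boundary behaviour", {
  fig2 <- make_fixture("fig2")
  marked <- attr(fig2, "marked")
  # input already small enough: identity clusters
  cls <- reduce_to_cluster_size(fig2, marked, 3)
  expect_equal(vapply(cls, `[[`, "", "representative"),
               sort(marked, method = "radix"))
  for (cl in cls) expect_equal(cl$members, cl$representative)
  # max 1: single cluster whose representative covers every input
  cls1 <- reduce_to_cluster_size(fig2, marked, 1)
  expect_length(cls1, 1)
  expect_setequal(cls1[[1]]$members, marked)
  rep_id <- cls1[[1]]$representative
  for (m in marked)
    expect_true(rep_id %in% ancestors(fig2, m))
  expect_error(reduce_to_cluster_size(fig2, character(), 2),
               class = "obokit_argument_error")
})

test_that("cluster reduction invariants hold on random inputs", {
  for (g in random_graph_cases(15, base_seed = 900L)) {
    ids <- class_ids(g)
    set.seed(42)
    input <- sample(ids, min(8L, length(ids)))
    lvl <- levels_of(g)
    prev_min_level <- NULL
    for (k in c(1L, 2L, 4L, 8L)) {
      cls <- reduce_to_cluster_size(g, input, k)
      expect_lte(length(cls), k)
      got <- unique(unlist(lapply(cls, `[[`, "members")))
      expect_setequal(got, input)   # members cover the input set
      for (cl in cls)
        for (m in cl$members)
          expect_true(cl$representative %in% ancestors(g, m),
                      info = sprintf("%s k=%d rep=%s member=%s",
                                     g$name, k, cl$representative, m))
      # raising the bound never drives representatives closer to the root
      min_level <- min(lvl[vapply(cls, `[[`, "", "representative")])
      if (!is.null(prev_min_level)) expect_gte(min_level, prev_min_level)
      prev_min_level <- min_level
    }
  }
})
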