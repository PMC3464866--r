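# Staged-anatomy semantic functions, in the style of an insect ontology
# that carries one class per structure per developmental stage (a "larval
# antenna" and a "pupal antenna" both subclassing a stage-free "antenna").
# Structures are tied to their stage by partonomy links, possibly through a
# chain of is_a and isPartOf steps.

#' Stage-partition configuration
#'
#' @param stage_anchor_id Class id whose `is_a` descendants are the
#'   developmental stages (e.g. `"developmental_stage"`).
#' @param link_relations Relation names that tie a structure to its stage
#'   (mixed freely with `is_a` on the path); default `"isPartOf"`.
#' @param part_relation Relation inverted on the fly for downstream
#'   expansion (the `hasPart` view); default `"isPartOf"`.
#' @return An object of class `stage_config`.
#' @export
stage_config <- function(stage_anchor_id = "developmental_stage",
                         link_relations = "isPartOf",
                         part_relation = "isPartOf") {
  structure(list(stage_anchor_id = stage_anchor_id,
                 link_relations = as.character(link_relations),
                 part_relation = part_relation),
            class = "stage_config")
}

#' Load the stage plugin for an ontology
#'
#' Scans the ontology once and caches the three class partitions:
#' developmental stages (`is_a` descendants of the stage anchor), concrete
#' classes (structures from which some stage is reachable through any
#' mixture of `is_a`-upward and `link_relations` steps) and generic
#' classes (everything else except the root and the stage subtree).
#' Reload the plugin after the ontology changes.
#'
#' @param graph A rooted `ontology_graph`.
#' @param cfg A [stage_config()].
#' @return An object of class `stage_plugin` with cached partitions.
#' @export
stage_plugin <- function(graph, cfg = stage_config()) {
  stopifnot(inherits(cfg, "stage_config"))
  if (!cfg$stage_anchor_id %in% names(graph$classes))
    stop_config(paste0("ontology '", graph$name, "' has no stage anchor '",
                       cfg$stage_anchor_id, "'"))
  stages <- descendants(graph, cfg$stage_anchor_id, include_self = FALSE)
  if (!length(stages))
    stop_config(paste0("stage anchor '", cfg$stage_anchor_id,
                       "' has no descendants"))
  subtree <- c(cfg$stage_anchor_id, stages)
  concrete <- scan_concrete(graph, cfg, stages, subtree)
  root <- if (is.na(graph$root_id)) character() else graph$root_id
  generic <- setdiff(class_ids(graph), c(subtree, concrete, root))
  structure(list(graph_name = graph$name, config = cfg,
                 stages = sort_ids(stages), stage_subtree = sort_ids(subtree),
                 concrete = sort_ids(concrete), generic = sort_ids(generic)),
            class = "stage_plugin")
}

# classes (outside the stage subtree) from which `target_stages` is
# reachable via is_a-upward and link_relations steps
scan_concrete <- function(graph, cfg, target_stages, subtree) {
  pol <- traversal_policy("upstream",
                          intersect(cfg$link_relations,
                                    relation_names(graph)))
  # reverse reachability: walk downstream from the stages instead of
  # upstream from every class (one BFS instead of n)
  rev_pol <- traversal_policy("downstream", pol$relations)
  reached <- character()
  frontier <- target_stages
  seen <- target_stages
  while (length(frontier)) {
    frontier <- setdiff(policy_neighbours(graph, frontier, rev_pol), seen)
    seen <- c(seen, frontier)
    reached <- c(reached, frontier)
  }
  setdiff(reached, subtree)
}

#' Concrete classes: structures linked to a developmental stage
#'
#' The path to the stage may be a chain of `is_a` and partonomy links; the
#' stage classes themselves are not part of the result.
#'
#' @param graph A rooted `ontology_graph`.
#' @param cfg A [stage_config()].
#' @param plugin Optional preloaded [stage_plugin()] (avoids rescanning).
#' @return Sorted character vector of class ids.
#' @export
concrete_classes <- function(graph, cfg = stage_config(),
                             plugin = stage_plugin(graph, cfg)) {
  plugin$concrete
}

#' Generic classes: structures not related to any developmental stage
#'
#' The complement of the concrete classes within the ontology, excluding
#' the virtual root and the stage subtree; used e.g. to feed auto-complete
#' suggestions with stage-free structure names.
#'
#' @inheritParams concrete_classes
#' @export
generic_classes <- function(graph, cfg = stage_config(),
                            plugin = stage_plugin(graph, cfg)) {
  plugin$generic
}

#' Search the generic classes by label or synonym
#'
#' Case-insensitive substring search over labels and `synonym` annotation
#' values, restricted to the generic (stage-free) classes.
#'
#' @inheritParams concrete_classes
#' @param pattern Search string.
#' @return Sorted character vector of matching generic class ids.
#' @export
find_in_generic <- function(graph, cfg = stage_config(), pattern,
                            plugin = stage_plugin(graph, cfg)) {
  hits <- search_cls(graph,
                     ontology_config(graph$name, indexed_fields = "synonym"),
                     pattern)
  sort_ids(intersect(hits, plugin$generic))
}

#' Concrete classes downstream of a generic class for one stage
#'
#' Expands the generic class downstream through `is_a` children and the
#' on-the-fly inverse of the partonomy relation (`hasPart`), then keeps
#' the classes that are concrete for the *given* stage, i.e. from which
#' that particular stage is reachable via `is_a`-upward / partonomy links.
#' Classes tied only to other stages are excluded.
#'
#' @inheritParams concrete_classes
#' @param generic_id A generic (stage-free) class id.
#' @param stage_id A developmental-stage class id.
#' @return Sorted character vector of concrete class ids (possibly empty).
#' @export
concrete_for_dev_stage <- function(graph, cfg = stage_config(), generic_id,
                                   stage_id,
                                   plugin = stage_plugin(graph, cfg)) {
  assert_class_exists(graph, generic_id)
  if (!stage_id %in% plugin$stages)
    stop_argument(paste0("'", stage_id, "' is not a developmental stage"))
  if (!generic_id %in% plugin$generic)
    stop_argument(paste0("'", generic_id, "' is not a generic class"))

  down_pol <- traversal_policy(
    "downstream",
    intersect(cfg$part_relation, relation_names(graph)))
  closure <- generic_id
  frontier <- generic_id
  while (length(frontier)) {
    frontier <- setdiff(policy_neighbours(graph, frontier, down_pol), closure)
    closure <- c(closure, frontier)
  }

  # stage reachability restricted to this stage id
  stage_concrete <- scan_concrete(graph, cfg, stage_id, plugin$stage_subtree)
  sort_ids(intersect(closure, stage_concrete))
}
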