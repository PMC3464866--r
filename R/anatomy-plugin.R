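# Anatomy-ontology semantic functions: rollup of an arbitrary anatomical
# entity to key classes (organs, physiological systems) along a restricted
# relation set, and level-synchronous BFS against a stored class set.

#' Key-class rollup policy
#'
#' Defines a rollup target: the key classes are the `is_a` descendants of a
#' configured anchor class (e.g. every subclass of `organ`), and the
#' traversal policy says which relations may be crossed on the way there.
#' The default relation set is the partonomy of anatomy ontologies:
#' `isPartOf`, `isPartOfOrgan`, `isCellOf`; developmental relations such as
#' `differentiatesInto` are deliberately not listed and therefore never
#' traversed.
#'
#' @param anchor_id Class id whose `is_a` descendants form the key set; the
#'   anchor itself is not a key class.
#' @param relations Relation names the traversal may follow (upstream).
#' @param use_hierarchy Follow `is_a` toward parents as well?
#' @param expand_key_classes If `FALSE` (default) a reached key class is
#'   reported and not expanded further, so the most specific key classes
#'   are returned; set `TRUE` to also collect key classes lying behind
#'   other key classes.
#' @return An object of class `key_class_policy`.
#' @export
key_class_policy <- function(anchor_id,
                             relations = c("isPartOf", "isPartOfOrgan",
                                           "isCellOf"),
                             use_hierarchy = TRUE,
                             expand_key_classes = FALSE) {
  structure(list(anchor_id = anchor_id,
                 traversal = traversal_policy("upstream", relations,
                                              use_hierarchy),
                 expand_key_classes = isTRUE(expand_key_classes)),
            class = "key_class_policy")
}

#' Roll an ontology class up to its key classes
#'
#' Breadth-first traversal from `start_id` following only the policy's
#' relations (and `is_a` toward parents): every reached key class -- an
#' `is_a` descendant of the policy's anchor -- is added to the result and,
#' by default, not expanded further; non-key classes are expanded.  A start
#' class that is itself a key class is returned alone.
#'
#' @param graph An `ontology_graph`.
#' @param start_id Start class id.
#' @param policy A [key_class_policy()].
#' @return Sorted character vector of key-class ids (possibly empty).
#' @export
rollup_to_key_classes <- function(graph, start_id, policy) {
  stopifnot(inherits(policy, "key_class_policy"))
  assert_class_exists(graph, start_id)
  assert_class_exists(graph, policy$anchor_id, "anchor class")
  key_set <- descendants(graph, policy$anchor_id, include_self = FALSE)

  found <- character()
  visited <- start_id
  frontier <- start_id
  while (length(frontier)) {
    hits <- intersect(frontier, key_set)
    found <- c(found, hits)
    expand <- if (policy$expand_key_classes) frontier
              else setdiff(frontier, key_set)
    frontier <- setdiff(policy_neighbours(graph, expand, policy$traversal),
                        visited)
    visited <- c(visited, frontier)
  }
  sort_ids(found)
}

#' Anatomy plugin: organ and physiological-system rollup
#'
#' Binds the key-class rollup to a concrete anatomy ontology.  At load time
#' the anchor classes (default `"organ"` and `"physiological_system"`) are
#' checked to exist; a graph lacking an anchor refuses to load the plugin.
#'
#' @param graph An `ontology_graph`.
#' @param organ_anchor,system_anchor Anchor class ids whose descendants are
#'   the organs / physiological systems.
#' @param relations Relations followed during rollup.
#' @return An object of class `anatomy_plugin` with precomputed key sets.
#' @export
anatomy_plugin <- function(graph, organ_anchor = "organ",
                           system_anchor = "physiological_system",
                           relations = c("isPartOf", "isPartOfOrgan",
                                         "isCellOf")) {
  anchors <- c(organ = organ_anchor, system = system_anchor)
  present <- anchors[anchors %in% names(graph$classes)]
  if (!length(present))
    stop_config(paste0("ontology '", graph$name, "' has neither anchor ",
                       "class '", organ_anchor, "' nor '", system_anchor,
                       "'; anatomy plugin not loaded"))
  policies <- lapply(present, key_class_policy, relations = relations)
  structure(list(graph_name = graph$name, policies = policies),
            class = "anatomy_plugin")
}

#' Organs of an anatomical entity
#'
#' Rollup of an arbitrary anatomical class to the organs it belongs to,
#' searched along the class hierarchy and the relations `isPartOf`,
#' `isPartOfOrgan` and `isCellOf`; developmental relations are ignored.
#'
#' @param graph An `ontology_graph` holding an `organ` anchor class.
#' @param start_id Start class id.
#' @param plugin Optional preloaded [anatomy_plugin()].
#' @return Sorted character vector of organ ids.
#' @export
organs_of <- function(graph, start_id, plugin = anatomy_plugin(graph)) {
  pol <- plugin$policies[["organ"]]
  if (is.null(pol))
    stop_config(paste0("ontology '", graph$name, "' has no organ anchor"))
  rollup_to_key_classes(graph, start_id, pol)
}

#' Physiological systems of an anatomical entity
#' @inheritParams organs_of
#' @return Sorted character vector of physiological-system ids.
#' @export
physiological_systems_of <- function(graph, start_id,
                                     plugin = anatomy_plugin(graph)) {
  pol <- plugin$policies[["system"]]
  if (is.null(pol))
    stop_config(paste0("ontology '", graph$name,
                       "' has no physiological_system anchor"))
  rollup_to_key_classes(graph, start_id, pol)
}

#' Find the nearest members of a class set up- or downstream
#'
#' Level-synchronous breadth-first search from `start_id` under a
#' [traversal_policy()]: upstream follows `is_a` parents and the policy's
#' relations source-to-target, downstream follows `is_a` children and the
#' on-the-fly inverse relations.  The search stops in the iteration step
#' with the first match and returns all members of `member_ids` found at
#' that depth; path length is otherwise unbounded, and a path may mix the
#' allowed relations.  The start class itself (depth 0) counts as a match.
#'
#' @param graph An `ontology_graph`.
#' @param start_id Start class id.
#' @param member_ids Non-empty character vector: the predefined class set.
#' @param policy A [traversal_policy()]; its relation names must exist in
#'   the graph.
#' @return Sorted character vector of set members at the first matching
#'   depth; empty when no member is reachable.
#' @export
find_in_set <- function(graph, start_id, member_ids, policy) {
  assert_class_exists(graph, start_id)
  if (!length(member_ids)) stop_argument("member set is empty")
  validate_policy(graph, policy)
  member_ids <- unique(as.character(member_ids))

  visited <- start_id
  frontier <- start_id
  while (length(frontier)) {
    hits <- intersect(frontier, member_ids)
    if (length(hits)) return(sort_ids(hits))
    frontier <- setdiff(policy_neighbours(graph, frontier, policy), visited)
    visited <- c(visited, frontier)
  }
  character()
}

#' Upstream / downstream search against a stored set
#'
#' Convenience wrappers over [find_in_set()] with the anatomy partonomy
#' relations (`isPartOf`, `isPartOfOrgan`, `isCellOf`) restricted to those
#' present in the graph.
#'
#' @inheritParams find_in_set
#' @param relations Relation names to follow (intersected with the graph's).
#' @export
find_upstream_in_set <- function(graph, start_id, member_ids,
                                 relations = c("isPartOf", "isPartOfOrgan",
                                               "isCellOf")) {
  pol <- traversal_policy("upstream",
                          intersect(relations, relation_names(graph)))
  find_in_set(graph, start_id, member_ids, pol)
}

#' @rdname find_upstream_in_set
#' @export
find_downstream_in_set <- function(graph, start_id, member_ids,
                                   relations = c("isPartOf", "isPartOfOrgan",
                                                 "isCellOf")) {
  pol <- traversal_policy("downstream",
                          intersect(relations, relation_names(graph)))
  find_in_set(graph, start_id, member_ids, pol)
}
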