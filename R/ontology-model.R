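# Locale-independent ordering used for every neighbour/result list so that
# output is byte-stable across platforms.
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

#' Create an ontology class record
#'
#' An ontology class is a named concept (term): an opaque string identifier,
#' a display label, a set of annotation fields (each holding one or more
#' string values, e.g. `def` or `synonym`) and an obsolete flag.  Obsolete
#' classes are kept in the graph but excluded from all traversal.
#'
#' @param id Non-empty string identifier, unique within a graph.
#' @param label Display name; defaults to the id.
#' @param annotations Named list mapping annotation field names to character
#'   vectors of values.
#' @param obsolete Logical; obsolete classes carry no edges after loading.
#' @return A list of class `ontology_class`.
#' @export
ontology_class <- function(id, label = id, annotations = list(),
                           obsolete = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("class id must be a non-empty string", call. = FALSE)
  stopifnot(is.list(annotations))
  if (length(annotations) && is.null(names(annotations)))
    stop("annotations must be a named list", call. = FALSE)
  structure(list(id = id, label = as.character(label),
                 annotations = lapply(annotations, as.character),
                 obsolete = isTRUE(obsolete)),
            class = "ontology_class")
}

#' Build an ontology graph
#'
#' The graph holds the class records, the `is_a` subsumption hierarchy as a
#' child-to-parents adjacency (multiple parents allowed), and all other
#' typed relations (e.g. `isPartOf`, `isCellOf`) as a separate edge table --
#' `is_a` is never stored as a relation edge.  The hierarchy must be
#' acyclic; a cycle aborts construction naming one of its members.
#'
#' @param name Ontology name (the segment it is served under).
#' @param classes List of [ontology_class()] records.
#' @param is_a Named list: child id -> character vector of parent ids.
#' @param relations Data frame with columns `source`, `target`, `relation`.
#' @param root_id Id of the (possibly virtual) root, or `NA` if not rooted.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(name, classes = list(), is_a = list(),
                           relations = empty_relations(), root_id = NA_character_) {
  ids <- vapply(classes, function(cl) cl$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate class id: ", ids[duplicated(ids)][1], call. = FALSE)
  names(classes) <- ids
  obsolete <- vapply(classes, function(cl) cl$obsolete, logical(1))

  # normalise hierarchy: drop edges touching unknown or obsolete classes
  is_a <- is_a[names(is_a) %in% ids[!obsolete]]
  is_a <- lapply(is_a, function(p) {
    p <- unique(as.character(p))
    p[p %in% ids & !obsolete[p]]
  })
  is_a <- is_a[lengths(is_a) > 0]

  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "relation") %in% names(relations)))
  keep <- relations$source %in% ids & relations$target %in% ids &
    !obsolete[relations$source] & !obsolete[relations$target] &
    nzchar(relations$relation)
  if (any(relations$relation == "is_a"))
    stop("'is_a' must live in the hierarchy, not in the relation table",
         call. = FALSE)
  relations <- unique(relations[keep, c("source", "target", "relation")])
  rownames(relations) <- NULL

  g <- structure(list(name = name, classes = classes, is_a = is_a,
                      relations = relations, root_id = root_id),
                 class = "ontology_graph")
  cyc <- find_isa_cycle(g)
  if (!is.null(cyc))
    stop("is_a hierarchy contains a cycle through class '", cyc, "'",
         call. = FALSE)
  g$children_index <- build_children_index(is_a)
  g
}

empty_relations <- function() {
  data.frame(source = character(), target = character(),
             relation = character(), stringsAsFactors = FALSE)
}

build_children_index <- function(is_a) {
  if (!length(is_a)) return(list())
  child <- rep(names(is_a), lengths(is_a))
  parent <- unlist(is_a, use.names = FALSE)
  split(child, parent)
}

# Returns the id of a class on an is_a cycle, or NULL when acyclic
# (iterative colouring; recursion would overflow on deep ontologies).
find_isa_cycle <- function(g) {
  colour <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  for (start in names(g$is_a)) {
    if (!is.null(colour[[start]])) next
    stack <- list(list(id = start, i = 0L))
    colour[[start]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- g$is_a[[top$id]]
      if (top$i < length(ps)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- ps[[top$i + 1L]]
        st <- colour[[nxt]]
        if (is.null(st)) {
          colour[[nxt]] <- 1L
          stack[[length(stack) + 1L]] <- list(id = nxt, i = 0L)
        } else if (st == 1L) {
          return(nxt)
        }
      } else {
        colour[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph '%s': %d classes, %d is_a edges, %d relation edges%s>\n",
              x$name, length(x$classes), sum(lengths(x$is_a)),
              nrow(x$relations),
              if (!is.na(x$root_id)) paste0(", root '", x$root_id, "'") else ""))
  invisible(x)
}

#' @export
format.ontology_class <- function(x, ...) {
  sprintf("<ontology_class '%s' (%s)%s>", x$id, x$label,
          if (x$obsolete) " [obsolete]" else "")
}

#' @export
print.ontology_class <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Ids of all classes in a graph
#' @param graph An `ontology_graph`.
#' @param include_obsolete Include obsolete classes?
#' @return Character vector of ids, radix-sorted.
#' @export
class_ids <- function(graph, include_obsolete = FALSE) {
  ids <- names(graph$classes)
  if (!include_obsolete) {
    obs <- vapply(graph$classes, function(cl) cl$obsolete, logical(1))
    ids <- ids[!obs]
  }
  sort_ids(ids)
}

assert_class_exists <- function(graph, cls_id, what = "class") {
  if (!is.character(cls_id) || length(cls_id) != 1L ||
      !cls_id %in% names(graph$classes))
    stop_not_found(sprintf("unknown %s '%s' in ontology '%s'",
                           what, paste(cls_id, collapse = ","), graph$name))
  invisible(cls_id)
}

#' Direct is_a parents / children of a class
#'
#' @param graph An `ontology_graph`.
#' @param cls_id A class id present in the graph.
#' @return Character vector of class ids in deterministic (radix) order.
#' @export
parents <- function(graph, cls_id) {
  assert_class_exists(graph, cls_id)
  sort_ids(graph$is_a[[cls_id]] %||% character())
}

#' @rdname parents
#' @export
children <- function(graph, cls_id) {
  assert_class_exists(graph, cls_id)
  sort_ids(graph$children_index[[cls_id]] %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classes linked to a class by a named relation
#'
#' With `direction = "upstream"` the stored edges are followed from source
#' to target; with `"downstream"` the inverse relation is generated on the
#' fly (edge targets yield their sources), so e.g. a `hasPart` view of
#' `isPartOf` needs no materialised inverse edges.
#'
#' @inheritParams parents
#' @param relation_name Relation type, e.g. `"isPartOf"`.
#' @param direction `"upstream"` (source to target) or `"downstream"`.
#' @return Character vector of class ids in deterministic order.
#' @export
relation_targets <- function(graph, cls_id, relation_name,
                             direction = c("upstream", "downstream")) {
  assert_class_exists(graph, cls_id)
  direction <- match.arg(direction)
  rel <- graph$relations[graph$relations$relation == relation_name, ]
  out <- if (direction == "upstream") rel$target[rel$source == cls_id]
         else rel$source[rel$target == cls_id]
  sort_ids(out)
}

#' Relation type names present in a graph
#' @inheritParams parents
#' @export
relation_names <- function(graph) sort_ids(graph$relations$relation)

#' Add a virtual root class
#'
#' Inserts a single top class (conventionally "thing") at level 1 and links
#' every formerly parentless non-obsolete class below it by `is_a`, so that
#' every class has at least one path to a unique root.  Idempotent: if the
#' graph already has a sole parentless class with the requested label it is
#' returned unchanged.
#'
#' @param graph An `ontology_graph`.
#' @param root_label Label (and id) of the virtual root, default `"thing"`.
#' @return The rooted graph, with `root_id` set.
#' @export
add_virtual_root <- function(graph, root_label = "thing") {
  orphan <- parentless_classes(graph)
  if (length(orphan) == 1L && orphan == root_label) {
    graph$root_id <- root_label
    return(graph)
  }
  if (root_label %in% names(graph$classes))
    stop("class '", root_label, "' exists but is not the sole root",
         call. = FALSE)
  classes <- c(graph$classes, stats::setNames(
    list(ontology_class(root_label)), root_label))
  is_a <- graph$is_a
  for (id in orphan) is_a[[id]] <- root_label
  g <- ontology_graph(graph$name, classes, is_a, graph$relations,
                      root_id = root_label)
  g
}

parentless_classes <- function(graph) {
  ids <- class_ids(graph)
  sort_ids(ids[!ids %in% names(graph$is_a)])
}

#' Level of every class (longest is_a path from the root)
#'
#' The root is at level 1; each other class sits at one plus the maximum
#' level of its is_a parents, i.e. its greatest distance to the root over
#' all hierarchy paths.
#'
#' @param graph A rooted `ontology_graph` (see [add_virtual_root()]).
#' @return Named integer vector over all non-obsolete classes.
#' @export
levels_of <- function(graph) {
  root <- require_root(graph)
  memo <- new.env(parent = emptyenv())
  assign(root, 1L, envir = memo)
  lvl1 <- function(id) {
    got <- memo[[id]]
    if (!is.null(got)) return(got)
    ps <- graph$is_a[[id]]
    v <- if (is.null(ps)) 1L else 1L + max(vapply(ps, lvl1, integer(1)))
    assign(id, v, envir = memo)
    v
  }
  ids <- class_ids(graph)
  stats::setNames(vapply(ids, lvl1, integer(1)), ids)
}

#' Level of one class
#' @inheritParams parents
#' @return Positive integer: 1 for the root, else the longest-path distance.
#' @export
level_of <- function(graph, cls_id) {
  assert_class_exists(graph, cls_id)
  unname(levels_of(graph)[cls_id])
}

require_root <- function(graph) {
  if (is.na(graph$root_id) || !graph$root_id %in% names(graph$classes))
    stop("graph has no virtual root; call add_virtual_root() first",
         call. = FALSE)
  graph$root_id
}

#' Path positions of a class over all root paths
#'
#' Considers every `is_a` path between the root and the class and returns
#' the set of positions (root = 1) at which the class occurs.  A class with
#' multiple parents typically occurs at several depths.
#'
#' @inheritParams parents
#' @return Sorted integer vector (a set) of path positions.
#' @export
path_levels <- function(graph, cls_id) {
  assert_class_exists(graph, cls_id)
  unname(all_path_levels(graph)[[cls_id]])
}

# set of root-path lengths for every class, by DP over the hierarchy
all_path_levels <- function(graph) {
  root <- require_root(graph)
  memo <- new.env(parent = emptyenv())
  assign(root, 1L, envir = memo)
  lv <- function(id) {
    got <- memo[[id]]
    if (!is.null(got)) return(got)
    ps <- graph$is_a[[id]]
    v <- if (is.null(ps)) 1L
         else sort(unique(unlist(lapply(ps, lv), use.names = FALSE)) + 1L)
    assign(id, v, envir = memo)
    v
  }
  ids <- class_ids(graph)
  stats::setNames(lapply(ids, lv), ids)
}

#' Is_a ancestors (transitive parents) of a class
#' @inheritParams parents
#' @param include_self Count the class itself as an ancestor?
#' @export
ancestors <- function(graph, cls_id, include_self = TRUE) {
  assert_class_exists(graph, cls_id)
  seen <- character()
  frontier <- cls_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph$is_a[frontier], use.names = FALSE)), seen)
  }
  if (!include_self) seen <- setdiff(seen, cls_id)
  sort_ids(seen)
}

#' Is_a descendants (transitive children) of a class
#' @inheritParams ancestors
#' @export
descendants <- function(graph, cls_id, include_self = FALSE) {
  assert_class_exists(graph, cls_id)
  seen <- character()
  frontier <- cls_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph$children_index[frontier], use.names = FALSE)), seen)
  }
  if (!include_self) seen <- setdiff(seen, cls_id)
  sort_ids(seen)
}

#' Traversal policy: which edges a semantic function may follow
#'
#' The contract of every rollup and set-restricted search: a direction, the
#' set of relation names that may be crossed, and whether the `is_a`
#' hierarchy is followed in that direction as well.  A path may mix
#' hierarchy steps and any of the allowed relations.
#'
#' @param direction `"upstream"` (toward parents / relation targets) or
#'   `"downstream"` (toward children / on-the-fly inverse relations).
#' @param relations Character vector of relation names; may be empty.
#' @param use_hierarchy Follow `is_a` in the chosen direction?
#' @return An object of class `traversal_policy`.
#' @export
traversal_policy <- function(direction = c("upstream", "downstream"),
                             relations = character(),
                             use_hierarchy = TRUE) {
  direction <- match.arg(direction)
  structure(list(direction = direction,
                 relations = sort_ids(relations),
                 use_hierarchy = isTRUE(use_hierarchy)),
            class = "traversal_policy")
}

validate_policy <- function(graph, policy) {
  stopifnot(inherits(policy, "traversal_policy"))
  unknown <- setdiff(policy$relations, relation_names(graph))
  if (length(unknown))
    stop_argument(sprintf("policy names relation(s) absent from '%s': %s",
                          graph$name, paste(unknown, collapse = ", ")))
  invisible(policy)
}

# one BFS step under a policy: all neighbours of `ids` (obsolete-free by
# construction since edges to obsolete classes are dropped at load)
policy_neighbours <- function(graph, ids, policy) {
  out <- character()
  if (policy$use_hierarchy) {
    out <- if (policy$direction == "upstream")
      unlist(graph$is_a[ids], use.names = FALSE)
    else unlist(graph$children_index[ids], use.names = FALSE)
    out <- out %||% character()
  }
  if (length(policy$relations)) {
    rel <- graph$relations[graph$relations$relation %in% policy$relations, ]
    more <- if (policy$direction == "upstream")
      rel$target[rel$source %in% ids]
    else rel$source[rel$target %in% ids]
    out <- c(out, more)
  }
  sort_ids(out)
}

# Error signalling -----------------------------------------------------------

stop_not_found <- function(msg) {
  stop(structure(class = c("obokit_not_found", "obokit_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_argument <- function(msg) {
  stop(structure(class = c("obokit_argument_error", "obokit_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_conflict <- function(msg) {
  stop(structure(class = c("obokit_conflict", "obokit_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_config <- function(msg) {
  stop(structure(class = c("obokit_config_error", "obokit_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}
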