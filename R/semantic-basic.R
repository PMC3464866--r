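# Built-in semantic functions available for every loaded ontology:
# searchCls, reduceToLevel, reduceToClusterSize.

#' Search ontology classes by pattern
#'
#' Case-insensitive substring search over the class labels and the values
#' of the annotation fields listed in the config's search index.  With
#' `restrict_fields` the match is limited to those fields only (the label
#' is then excluded), the field-restriction filter of the service's
#' `searchCls;field=...` URL form.
#'
#' @param graph An `ontology_graph`.
#' @param config An `ontology_config` whose `indexed_fields` define which
#'   annotation fields are searchable; `NULL` means label-only search.
#' @param pattern Search string (non-empty after trimming).
#' @param restrict_fields Optional character vector of annotation field
#'   names; each must be in `config$indexed_fields`.
#' @return Character vector of matching class ids, sorted, no duplicates.
#'   Obsolete classes never match.
#' @export
search_cls <- function(graph, config = NULL, pattern,
                       restrict_fields = NULL) {
  pattern <- trimws(pattern)
  if (!nzchar(pattern)) stop_argument("search pattern is empty")
  indexed <- if (is.null(config)) character() else config$indexed_fields
  if (!is.null(restrict_fields)) {
    unknown <- setdiff(restrict_fields, indexed)
    if (length(unknown))
      stop_argument(paste0("field(s) not in the search index: ",
                           paste(unknown, collapse = ", ")))
    fields <- restrict_fields
    use_label <- FALSE
  } else {
    fields <- indexed
    use_label <- TRUE
  }
  needle <- tolower(pattern)
  hit <- vapply(graph$classes, function(cl) {
    if (cl$obsolete) return(FALSE)
    if (use_label && grepl(needle, tolower(cl$label), fixed = TRUE))
      return(TRUE)
    for (f in fields) {
      v <- cl$annotations[[f]]
      if (!is.null(v) && any(grepl(needle, tolower(v), fixed = TRUE)))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  sort_ids(names(graph$classes)[hit])
}

#' Map classes to all ancestors at a fixed level
#'
#' Each input class is mapped to every class occurring at position `level`
#' (root = position 1) on at least one `is_a` path between the root and the
#' input class.  Because classes can have several parents there may be
#' several such paths and hence several ancestors.  A class sitting at
#' exactly the requested level on some path maps to itself; a class all of
#' whose root paths are shorter than `level` is copied to the result
#' unchanged.
#'
#' @param graph A rooted `ontology_graph`.
#' @param class_ids Character vector of input class ids.
#' @param level Target level, a positive integer (1 = root).
#' @return Named list: input id -> sorted character vector of ancestors.
#' @export
reduce_to_level <- function(graph, class_ids, level) {
  require_root(graph)
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level != as.integer(level))
    stop_argument("level must be a positive integer")
  level <- as.integer(level)
  for (id in class_ids) assert_class_exists(graph, id)
  plv <- all_path_levels(graph)
  res <- lapply(class_ids, function(id) {
    if (max(plv[[id]]) < level) return(id)   # every path shorter: copy
    anc <- ancestors(graph, id, include_self = TRUE)
    sort_ids(anc[vapply(anc, function(a) level %in% plv[[a]], logical(1))])
  })
  stats::setNames(res, class_ids)
}

#' Reduce a class list to at most a given number of clusters
#'
#' Successively maps classes to their `is_a` parents: in each iteration
#' only the representatives with the greatest distance to the root (the
#' deepest, by longest path) are replaced by all of their parents, while
#' shallower representatives are just copied; representatives arriving at
#' the same class pool their members.  The process stops as soon as the
#' number of representatives is not larger than `max_clusters` (checked
#' after each full iteration).  Because a maximum count is specified
#' instead of a level, the returned representatives may sit at different
#' root distances.
#'
#' @param graph A rooted `ontology_graph`.
#' @param class_ids Non-empty character vector of input class ids.
#' @param max_clusters Positive integer bound on the cluster count.
#' @return List of `cluster_assignment` objects (fields `representative`,
#'   `members`), sorted by representative id.  Members may appear in more
#'   than one cluster when a representative has multiple parents.
#' @export
reduce_to_cluster_size <- function(graph, class_ids, max_clusters) {
  require_root(graph)
  if (!length(class_ids)) stop_argument("input class list is empty")
  if (!is.numeric(max_clusters) || max_clusters < 1)
    stop_argument("max_clusters must be >= 1")
  for (id in class_ids) assert_class_exists(graph, id)
  lvl <- levels_of(graph)

  # representative -> member set
  members <- stats::setNames(as.list(unique(class_ids)), unique(class_ids))
  while (length(members) > max_clusters) {
    deepest <- max(lvl[names(members)])
    if (deepest == 1L) break                      # everything at the root
    nxt <- list()
    for (rep_id in names(members)) {
      targets <- if (lvl[[rep_id]] == deepest) parents(graph, rep_id)
                 else rep_id                       # shallower: just copied
      for (t in targets)
        nxt[[t]] <- sort_ids(c(nxt[[t]] %||% character(),
                               members[[rep_id]]))
    }
    members <- nxt
  }
  reps <- sort_ids(names(members))
  lapply(reps, function(r)
    structure(list(representative = r, members = members[[r]]),
              class = "cluster_assignment"))
}

#' @export
format.cluster_assignment <- function(x, ...) {
  sprintf("%s <- {%s}", x$representative, paste(x$members, collapse = ", "))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
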