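# Brute-force oracles, independent of the package's traversal code: they
# read the graph's raw adjacency and enumerate paths explicitly (or hand
# the edge list to igraph), never calling the functions under test.

# all root->cls is_a paths as a list of id vectors (root first)
oracle_root_paths <- function(graph, cls) {
  root <- graph$root_id
  recurse <- function(id) {
    if (id == root) return(list(root))
    ps <- graph$is_a[[id]]
    if (is.null(ps)) return(list())   # unreachable from root
    out <- list()
    for (p in ps)
      for (path in recurse(p))
        out[[length(out) + 1L]] <- c(path, id)
    out
  }
  recurse(cls)
}

oracle_level <- function(graph, cls) {
  max(vapply(oracle_root_paths(graph, cls), length, integer(1)))
}

oracle_path_levels <- function(graph, cls) {
  sort(unique(vapply(oracle_root_paths(graph, cls), length, integer(1))))
}

# classes at position `level` on at least one root->cls path
oracle_level_ancestors <- function(graph, cls, level) {
  paths <- oracle_root_paths(graph, cls)
  hits <- unlist(lapply(paths, function(p)
    if (length(p) >= level) p[level] else NULL))
  sort(unique(hits), method = "radix")
}

# directed edge list of one traversal step under a policy, straight from
# the stored adjacency (used to hand the search space to igraph)
oracle_policy_edges <- function(graph, policy) {
  from <- character(); to <- character()
  if (policy$use_hierarchy) {
    child <- rep(names(graph$is_a), lengths(graph$is_a))
    parent <- unlist(graph$is_a, use.names = FALSE)
    if (policy$direction == "upstream") { from <- child; to <- parent }
    else { from <- parent; to <- child }
  }
  rel <- graph$relations[graph$relations$relation %in% policy$relations, ]
  if (nrow(rel)) {
    if (policy$direction == "upstream") {
      from <- c(from, rel$source); to <- c(to, rel$target)
    } else {
      from <- c(from, rel$target); to <- c(to, rel$source)
    }
  }
  cbind(from, to)
}

# shortest BFS depth from start to every member, via igraph::distances
oracle_min_depth_members <- function(graph, start, members, policy) {
  ids <- sort(names(graph$classes), method = "radix")
  el <- oracle_policy_edges(graph, policy)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = TRUE, vertices = ids)
  d <- igraph::distances(ig, v = start, to = members, mode = "out")[1, ]
  if (!any(is.finite(d))) return(character())
  sort(names(d)[d == min(d)], method = "radix")
}

# tiny graph builder for hand-rolled cases
g_build <- function(is_a = list(), rel = NULL, name = "test",
                    extra_ids = character(), root = TRUE) {
  ids <- unique(c(names(is_a), unlist(is_a, use.names = FALSE),
                  if (!is.null(rel)) c(rel$source, rel$target), extra_ids))
  g <- ontology_graph(name, lapply(ids, ontology_class), is_a,
                      if (is.null(rel)) data.frame(source = character(),
                                                   target = character(),
                                                   relation = character())
                      else rel)
  if (root) add_virtual_root(g) else g
}

random_graph_cases <- function(n, base_seed, size_range = c(5L, 40L),
                               p_relation = 0) {
  lapply(seq_len(n), function(i) {
    sz <- size_range[1] + ((base_seed + 7L * i) %% (size_range[2] -
                                                    size_range[1] + 1L))
    make_fixture("random", seed = base_seed + i, size = sz,
                 p_relation = p_relation)
  })
}
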