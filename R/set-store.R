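# Named storage partitions holding reusable lists of class ids.  A
# partition is only reachable through its assigned name (basic access
# control); each partition is one JSON document on disk, so stored lists
# survive process restarts.

#' Open (or create) a flat-file set store
#'
#' @param dir Directory holding one `<partition>.json` file per partition;
#'   created if missing.
#' @return An object of class `set_store`.
#' @export
set_store <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = normalizePath(dir)), class = "set_store")
}

partition_path <- function(store, name) {
  if (!grepl("^[A-Za-z0-9._-]+$", name))
    stop_argument(paste0("invalid partition name: '", name, "'"))
  file.path(store$dir, paste0(name, ".json"))
}

read_partition <- function(store, name) {
  p <- partition_path(store, name)
  if (!file.exists(p))
    stop_not_found(paste0("unknown partition '", name, "'"))
  jsonlite::read_json(p, simplifyVector = FALSE)
}

write_partition <- function(store, name, part) {
  jsonlite::write_json(part, partition_path(store, name),
                       auto_unbox = TRUE, null = "null")
  invisible(NULL)
}

#' Create a storage partition
#'
#' @param store A [set_store()].
#' @param name Partition name (letters, digits, `._-`); must not exist yet.
#' @return The partition name, invisibly.
#' @export
create_partition <- function(store, name) {
  p <- partition_path(store, name)
  if (file.exists(p))
    stop_conflict(paste0("partition '", name, "' already exists"))
  write_partition(store, name,
                  list(partition_name = name,
                       created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                       lists = stats::setNames(list(), character())))
  invisible(name)
}

#' List partition names / list names in a partition
#' @param store A [set_store()].
#' @export
partitions <- function(store) {
  sort_ids(sub("\\.json$", "", list.files(store$dir, pattern = "\\.json$")))
}

#' @rdname partitions
#' @param partition_name Name of an existing partition.
#' @export
list_names <- function(store, partition_name) {
  sort_ids(names(read_partition(store, partition_name)$lists))
}

#' Store, fetch or delete a named id list
#'
#' `put_list()` stores `ids` (order and duplicates preserved) under
#' `list_name`, overwriting any previous content; `get_list()` returns the
#' ids in stored order; `delete_list()` removes the list.  Ids are not
#' validated against any ontology at storage time -- validation happens
#' when a semantic function consumes the list.
#'
#' @param store A [set_store()].
#' @param partition_name Name of an existing partition.
#' @param list_name Name of the list inside the partition.
#' @param ids Character vector of class ids.
#' @export
put_list <- function(store, partition_name, list_name, ids) {
  part <- read_partition(store, partition_name)
  part$lists[[list_name]] <- as.list(as.character(ids))
  write_partition(store, partition_name, part)
  invisible(list_name)
}

#' @rdname put_list
#' @export
get_list <- function(store, partition_name, list_name) {
  part <- read_partition(store, partition_name)
  lst <- part$lists[[list_name]]
  if (is.null(lst))
    stop_not_found(paste0("unknown list '", list_name, "' in partition '",
                          partition_name, "'"))
  as.character(unlist(lst))
}

#' @rdname put_list
#' @export
delete_list <- function(store, partition_name, list_name) {
  part <- read_partition(store, partition_name)
  if (is.null(part$lists[[list_name]]))
    stop_not_found(paste0("unknown list '", list_name, "' in partition '",
                          partition_name, "'"))
  part$lists[[list_name]] <- NULL
  write_partition(store, partition_name, part)
  invisible(list_name)
}

#' Resolve a "partition/list" reference to its stored ids
#'
#' Semantic functions accepting a set parameter may reference a stored
#' list as `"partition/list"` instead of passing inline ids.
#'
#' @param store A [set_store()].
#' @param ref Either a character vector of ids (length != 1 or containing
#'   no `/`) or a single `"partition/list"` reference.
#' @export
resolve_set <- function(store, ref) {
  if (length(ref) == 1L && grepl("/", ref, fixed = TRUE)) {
    parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop_argument(paste0("bad set reference: '", ref, "'"))
    get_list(store, parts[1], parts[2])
  } else {
    as.character(ref)
  }
}
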