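# OBO 1.2 flat-file reader/writer and per-ontology config files.
#
# Only the tags the semantic functions need get structure (id, name, is_a,
# relationship, is_obsolete); every other tag line passes through verbatim
# into the class annotations, keyed by tag, so field-restricted search can
# cover arbitrary annotation fields.

#' Read an ontology from an OBO 1.2 flat file
#'
#' Each `[Term]` stanza becomes one class: `name` is the label, `is_a`
#' lines feed the hierarchy, `relationship: <rel> <id>` lines become typed
#' relation edges, `is_obsolete: true` marks the class obsolete, and all
#' remaining tag lines (def, synonym, xref, ...) are stored as annotation
#' values under their tag name.  Trailing `!`-comments and OBO escapes are
#' stripped from values.  Edges whose target is never declared are dropped
#' with a warning.  No virtual root is added; see [add_virtual_root()].
#'
#' @param path Path to an OBO file (UTF-8).
#' @param name Ontology name; defaults to the file's base name.
#' @return An `ontology_graph`.
#' @export
read_obo <- function(path, name = NULL) {
  if (!file.exists(path)) stop_not_found(paste0("no such file: ", path))
  if (is.null(name)) name <- sub("\\.obo$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  # stanza boundaries
  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1] - 1L, length(lines))
  names(ends) <- starts

  classes <- list()
  is_a <- list()
  rel_src <- character(); rel_tgt <- character(); rel_name <- character()

  for (s in term_starts) {
    block <- lines[seq.int(s + 1L, ends[[as.character(s)]])]
    block <- block[nzchar(trimws(block))]
    tags <- sub("^([^:]+):.*$", "\\1", block)
    vals <- trimws(sub("^[^:]+:", "", block))
    vals <- strip_obo_comment(vals)

    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id))
      stop("OBO parse error: [Term] stanza near line ", s, " has no id",
           call. = FALSE)
    label <- vals[tags == "name"][1]
    if (is.na(label)) label <- id
    obsolete <- any(tags == "is_obsolete" & tolower(vals) == "true")

    pa <- sub("\\s.*$", "", vals[tags == "is_a"])
    if (length(pa)) is_a[[id]] <- pa

    rl <- vals[tags == "relationship"]
    if (length(rl)) {
      parts <- strsplit(rl, "\\s+")
      ok <- lengths(parts) >= 2
      rel_src <- c(rel_src, rep(id, sum(ok)))
      rel_name <- c(rel_name, vapply(parts[ok], `[`, "", 1L))
      rel_tgt <- c(rel_tgt, vapply(parts[ok], `[`, "", 2L))
    }

    keep <- !tags %in% c("id", "name", "is_a", "relationship", "is_obsolete")
    ann <- split(unescape_obo(vals[keep]), tags[keep])
    classes[[id]] <- ontology_class(id, label, ann, obsolete)
  }

  ids <- names(classes)
  dangling <- unique(c(
    setdiff(unlist(is_a, use.names = FALSE), ids),
    setdiff(rel_tgt, ids)))
  if (length(dangling))
    warning("dropping edges to undeclared class(es): ",
            paste(dangling, collapse = ", "), call. = FALSE)

  ontology_graph(name, classes, is_a,
                 data.frame(source = rel_src, target = rel_tgt,
                            relation = rel_name, stringsAsFactors = FALSE))
}

strip_obo_comment <- function(x) {
  # an unescaped " ! " starts a trailing comment
  trimws(sub("(^|[^\\\\])\\s!\\s.*$", "\\1", x))
}

unescape_obo <- function(x) gsub("\\\\(.)", "\\1", x)

escape_obo <- function(x) gsub("(!|\\\\)", "\\\\\\1", x)

#' Write an ontology to an OBO 1.2 flat file
#'
#' Terms are written sorted by id so that output is byte-stable; annotations
#' are emitted under their field names.  `read_obo(write_obo(g))` returns a
#' graph equal to `g` up to that canonical ordering.
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("ontology: ", graph$name)), con)
  for (id in sort_ids(names(graph$classes))) {
    cl <- graph$classes[[id]]
    out <- c("", "[Term]", paste0("id: ", id), paste0("name: ", cl$label))
    for (p in sort_ids(graph$is_a[[id]] %||% character()))
      out <- c(out, paste0("is_a: ", p))
    rel <- graph$relations[graph$relations$source == id, ]
    if (nrow(rel)) {
      rel <- rel[order(rel$relation, rel$target, method = "radix"), ]
      out <- c(out, paste0("relationship: ", rel$relation, " ", rel$target))
    }
    for (field in sort_ids(names(cl$annotations)))
      out <- c(out, paste0(field, ": ", escape_obo(cl$annotations[[field]])))
    if (cl$obsolete) out <- c(out, "is_obsolete: true")
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a per-ontology config ("property") file
#'
#' A plain `key=value` text file stating under which name an ontology is
#' served and which annotation fields the search index covers:
#' \preformatted{name=cytomer
#' file=cytomer.obo
#' indexed_fields=definitionEnglish,synonym}
#'
#' @param path Path to the config file.
#' @return An object of class `ontology_config` with fields
#'   `ontology_name`, `file_path`, `indexed_fields`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_not_found(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop_config(paste0("config line is not key=value: '", lines[bad][1], "'"))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  get1 <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  name <- get1("name")
  if (is.null(name) || !nzchar(name))
    stop_config("config is missing mandatory key 'name'")
  if (grepl("/", name, fixed = TRUE))
    stop_config("ontology name must not contain '/'")
  fields <- get1("indexed_fields")
  fields <- if (is.null(fields) || !nzchar(fields)) character()
            else trimws(strsplit(fields, ",", fixed = TRUE)[[1]])
  ontology_config(name, indexed_fields = fields,
                  file_path = get1("file") %||% NA_character_)
}

#' Construct an ontology config in code
#' @param ontology_name Name the ontology is served under (no slashes).
#' @param indexed_fields Annotation fields covered by the search index.
#' @param file_path Optional path of the backing OBO file.
#' @export
ontology_config <- function(ontology_name, indexed_fields = character(),
                            file_path = NA_character_) {
  if (!nzchar(ontology_name) || grepl("/", ontology_name, fixed = TRUE))
    stop_config("ontology name must be non-empty without '/'")
  structure(list(ontology_name = ontology_name,
                 indexed_fields = as.character(indexed_fields),
                 file_path = file_path),
            class = "ontology_config")
}
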