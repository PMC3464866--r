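# Client side: connectors encapsulate the transport (in-process routing or
# HTTP), and class proxies load their neighbours through the connector upon
# first access only, so traversing the object graph never fetches the whole
# ontology.  Every connector counts its requests, which the tests use to
# verify memoization.

#' Connectors: transport handles for the client
#'
#' `local_connector()` drives an [ontology_service()] in-process (no
#' network); `http_connector()` speaks to a running [obo_serve()] endpoint
#' via curl.  Both count the requests they issue (`request_count()`), and
#' both raise a `obokit_not_found` condition on 404 and a transport error
#' (`obokit_transport_error`) on connection failure, keeping the two cases
#' distinct.
#'
#' @param app An [ontology_service()].
#' @return A connector object.
#' @export
local_connector <- function(app) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  structure(list(app = app, state = env),
            class = c("local_connector", "obo_connector"))
}

#' @rdname local_connector
#' @param base_url Server base URL, e.g. `"http://127.0.0.1:8765"`.
#' @export
http_connector <- function(base_url) {
  if (!requireNamespace("curl", quietly = TRUE))
    stop("http_connector() needs the 'curl' package", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  structure(list(base_url = sub("/+$", "", base_url), state = env),
            class = c("http_connector", "obo_connector"))
}

#' Number of requests a connector has issued
#' @param conn A connector.
#' @export
request_count <- function(conn) conn$state$count

connector_get <- function(conn, path, accept = "application/json") {
  UseMethod("connector_get")
}

#' @export
connector_get.local_connector <- function(conn, path,
                                          accept = "application/json") {
  conn$state$count <- conn$state$count + 1L
  res <- route(conn$app, path, accept = accept)
  if (res$status == 404L) stop_not_found(res$body)
  if (res$status >= 400L) stop_argument(res$body)
  res$body
}

#' @export
connector_get.http_connector <- function(conn, path,
                                         accept = "application/json") {
  conn$state$count <- conn$state$count + 1L
  h <- curl::new_handle()
  curl::handle_setheaders(h, Accept = accept)
  res <- tryCatch(
    curl::curl_fetch_memory(paste0(conn$base_url, path), handle = h),
    error = function(e)
      stop(structure(class = c("obokit_transport_error", "obokit_error",
                               "error", "condition"),
                     list(message = conditionMessage(e), call = NULL))))
  body <- rawToChar(res$content)
  if (res$status_code == 404L) stop_not_found(body)
  if (res$status_code >= 400L) stop_argument(body)
  body
}

parse_id_lines <- function(body) {
  ids <- strsplit(body, "\n", fixed = TRUE)[[1]]
  ids[nzchar(ids)]
}

#' Fetch an ontology class as a lazy proxy
#'
#' The proxy knows its id and carries the connector; the label and
#' annotations are fetched on first field access, and each neighbour
#' subresource (parents, children, relations) is fetched at most once and
#' then served from the proxy's cache.  Two proxies are equal when they
#' denote the same id in the same ontology.
#'
#' @param conn A connector.
#' @param ontology Ontology name on the service.
#' @param id Class id.
#' @param fetch Fetch the class body eagerly to validate existence?
#' @return An object of class `class_proxy`.
#' @export
get_class <- function(conn, ontology, id, fetch = TRUE) {
  cache <- new.env(parent = emptyenv())
  p <- structure(list(conn = conn, ontology = ontology, id = id,
                      cache = cache),
                 class = "class_proxy")
  if (fetch) proxy_entity(p)
  p
}

proxy_entity <- function(proxy) {
  got <- proxy$cache$entity
  if (is.null(got)) {
    body <- connector_get(proxy$conn,
                          paste0("/", proxy$ontology, "/cls/", proxy$id))
    got <- jsonlite::fromJSON(body, simplifyVector = FALSE)
    proxy$cache$entity <- got
  }
  got
}

#' Proxy field access and neighbour traversal
#'
#' `proxy_label()` and `proxy_annotations()` read the cached entity body;
#' `proxy_parents()` / `proxy_children()` return lists of proxies for the
#' neighbouring classes, fetching each subresource at most once;
#' `proxy_relation()` lists the classes linked by one relation type in the
#' requested direction.
#'
#' @param proxy A `class_proxy`.
#' @export
proxy_label <- function(proxy) proxy_entity(proxy)$label

#' @rdname proxy_label
#' @export
proxy_annotations <- function(proxy) proxy_entity(proxy)$annotations

proxy_neighbour_ids <- function(proxy, sub) {
  key <- paste0("sub_", sub)
  got <- proxy$cache[[key]]
  if (is.null(got)) {
    body <- connector_get(
      proxy$conn, paste0("/", proxy$ontology, "/cls/", proxy$id, "/", sub),
      accept = "text/plain")
    got <- parse_id_lines(body)
    proxy$cache[[key]] <- got
  }
  got
}

#' @rdname proxy_label
#' @export
proxy_parents <- function(proxy) {
  lapply(proxy_neighbour_ids(proxy, "parents"),
         function(i) get_class(proxy$conn, proxy$ontology, i, fetch = FALSE))
}

#' @rdname proxy_label
#' @export
proxy_children <- function(proxy) {
  lapply(proxy_neighbour_ids(proxy, "children"),
         function(i) get_class(proxy$conn, proxy$ontology, i, fetch = FALSE))
}

#' @rdname proxy_label
#' @param relation_name Relation type to follow.
#' @param direction `"upstream"` or `"downstream"`.
#' @export
proxy_relation <- function(proxy, relation_name,
                           direction = c("upstream", "downstream")) {
  direction <- match.arg(direction)
  key <- "sub_relations"
  got <- proxy$cache[[key]]
  if (is.null(got)) {
    body <- connector_get(
      proxy$conn,
      paste0("/", proxy$ontology, "/cls/", proxy$id, "/relations"))
    got <- jsonlite::fromJSON(body, simplifyVector = TRUE)
    proxy$cache[[key]] <- got
  }
  if (!NROW(got)) return(list())
  ids <- if (direction == "upstream")
    got$target[got$relation == relation_name & got$source == proxy$id]
  else got$source[got$relation == relation_name & got$target == proxy$id]
  lapply(sort_ids(ids),
         function(i) get_class(proxy$conn, proxy$ontology, i, fetch = FALSE))
}

#' @export
format.class_proxy <- function(x, ...)
  sprintf("<class_proxy %s/%s>", x$ontology, x$id)

#' @export
print.class_proxy <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
`==.class_proxy` <- function(e1, e2) {
  inherits(e1, "class_proxy") && inherits(e2, "class_proxy") &&
    e1$ontology == e2$ontology && e1$id == e2$id
}

#' Call a semantic function through a connector
#'
#' Client-side mirror of the `/{ontology}/functions/{plugin}/{fn}` resource:
#' builds the URL (matrix parameters included), issues one request and
#' returns the resulting ids.
#'
#' @param conn A connector.
#' @param ontology Ontology name.
#' @param plugin Plugin name (`"basic"`, `"anatomy"`, `"stage"`, ...).
#' @param fn Function name as served (e.g. `"reduceToLevel"`).
#' @param argument Path argument (single id or comma-joined ids), or `NA`.
#' @param params Named list of matrix parameters.
#' @return Character vector of class ids.
#' @export
call_function <- function(conn, ontology, plugin, fn, argument = NA,
                          params = list()) {
  seg <- fn
  if (length(params))
    seg <- paste0(seg, paste0(";", names(params), "=",
                              vapply(params, as.character, character(1)),
                              collapse = ""))
  path <- paste0("/", ontology, "/functions/", plugin, "/", seg)
  if (!(length(argument) == 1L && is.na(argument)))
    path <- paste0(path, "/", paste(argument, collapse = ","))
  parse_id_lines(connector_get(conn, path, accept = "text/plain"))
}
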