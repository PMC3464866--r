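# REST-style facade.  The router is pure in-process code: it maps a URL
# path plus Accept header to a response, so it can be exercised directly,
# mounted on httpuv by obo_serve(), or driven through a connector by the
# lazy-loading client.  URL scheme:
#
#   /{ontology}/cls/{id}                     one class
#   /{ontology}/cls/{id}/parents|children|relations
#   /{ontology}/functions/{plugin}/{fn};k=v/{arg}
#   /storage/{partition}/{list}              (GET/PUT/DELETE)
#
# Content types: application/json (structured), text/plain (one id per
# line), text/html (minimal anchor list).

#' Assemble an ontology service
#'
#' Bundles named ontologies (each with its search config) into a routable
#' application.  The built-in plugin (`basic`: searchCls, reduceToLevel,
#' reduceToClusterSize) is always available; the anatomy plugin
#' (`anatomy`: organsOf, physiologicalSystemsOf, findUpstreamInSet,
#' findDownstreamInSet) and the stage plugin (`stage`: concreteClasses,
#' genericClasses, findInGeneric, concreteForDevStage) attach per ontology
#' when their anchor classes exist.
#'
#' @param graphs List of `ontology_graph` objects (rooted).
#' @param configs Optional named list of [ontology_config()]s keyed by
#'   ontology name.
#' @param store Optional [set_store()] backing `/storage` and stored-set
#'   references.
#' @return An object of class `ontology_service`.
#' @export
ontology_service <- function(graphs, configs = list(), store = NULL) {
  if (inherits(graphs, "ontology_graph")) graphs <- list(graphs)
  names(graphs) <- vapply(graphs, function(g) g$name, character(1))
  plugins <- lapply(graphs, function(g) {
    p <- list(basic = TRUE)
    p$anatomy <- tryCatch(anatomy_plugin(g), obokit_config_error = function(e) NULL)
    p$stage <- tryCatch(stage_plugin(g), obokit_config_error = function(e) NULL)
    p
  })
  structure(list(graphs = graphs, configs = configs, plugins = plugins,
                 store = store),
            class = "ontology_service")
}

service_graph <- function(app, ont) {
  g <- app$graphs[[ont]]
  if (is.null(g)) stop_not_found(paste0("unknown ontology '", ont, "'"))
  g
}

# ---------------------------------------------------------------------------
# address parsing

#' Parse a resource path into its address components
#'
#' Splits `/{ontology}/{kind}/...` and extracts matrix parameters
#' (`;name=value` modifiers inside the function path segment).
#'
#' @param path URL path, e.g.
#'   `"/cytomer/functions/basic/searchCls;field=definitionEnglish/cistern"`.
#' @return A list with components `ontology`, `kind`, `plugin`, `fn`,
#'   `matrix_params`, `argument`.
#' @export
parse_resource_address <- function(path) {
  segs <- strsplit(sub("^/+", "", path), "/", fixed = TRUE)[[1]]
  segs <- vapply(segs, utils::URLdecode, character(1), USE.NAMES = FALSE)
  if (length(segs) < 2L) stop_argument(paste0("bad resource path: ", path))
  if (segs[1] == "storage") {
    return(list(ontology = NA_character_, kind = "storage",
                partition = segs[2],
                list = if (length(segs) >= 3L) segs[3] else NA_character_))
  }
  kind <- segs[2]
  if (kind == "cls") {
    if (length(segs) < 3L) stop_argument("cls address needs a class id")
    list(ontology = segs[1], kind = "cls", id = segs[3],
         sub = if (length(segs) >= 4L) segs[4] else NA_character_)
  } else if (kind == "functions") {
    if (length(segs) < 4L)
      stop_argument("functions address needs /{plugin}/{fn}")
    fnseg <- strsplit(segs[4], ";", fixed = TRUE)[[1]]
    mp <- list()
    for (kv in fnseg[-1]) {
      eq <- regmatches(kv, regexpr("=", kv, fixed = TRUE), invert = TRUE)[[1]]
      if (length(eq) != 2L)
        stop_argument(paste0("bad matrix parameter: '", kv, "'"))
      mp[[eq[1]]] <- eq[2]
    }
    list(ontology = segs[1], kind = "functions", plugin = segs[3],
         fn = fnseg[1], matrix_params = mp,
         argument = if (length(segs) >= 5L)
           paste(segs[5:length(segs)], collapse = "/") else NA_character_)
  } else {
    stop_not_found(paste0("unknown resource kind '", kind, "'"))
  }
}

# ---------------------------------------------------------------------------
# representations

entity_json <- function(graph, id) {
  cl <- graph$classes[[id]]
  base <- paste0("/", graph$name, "/cls/", id)
  list(id = cl$id, label = cl$label, obsolete = cl$obsolete,
       annotations = cl$annotations,
       links = list(self = base, parents = paste0(base, "/parents"),
                    children = paste0(base, "/children"),
                    relations = paste0(base, "/relations")))
}

render_ids <- function(app, ont, ids, accept) {
  if (accept == "text/plain") {
    body <- paste0(paste(ids, collapse = "\n"), if (length(ids)) "\n" else "")
  } else if (accept == "text/html") {
    body <- paste0(
      "<html><body><ul>",
      paste0("<li><a href=\"/", ont, "/cls/", ids, "\">", ids,
             "</a></li>", collapse = ""),
      "</ul></body></html>")
  } else {
    accept <- "application/json"
    g <- service_graph(app, ont)
    body <- jsonlite::toJSON(lapply(ids, entity_json, graph = g),
                             auto_unbox = TRUE)
  }
  list(status = 200L, content_type = accept, body = as.character(body))
}

response_error <- function(e) {
  status <- if (inherits(e, "obokit_not_found")) 404L
            else if (inherits(e, "obokit_conflict")) 409L
            else 400L
  list(status = status, content_type = "text/plain",
       body = paste0(conditionMessage(e), "\n"))
}

# ---------------------------------------------------------------------------
# routing

#' Route a request against the service
#'
#' @param app An [ontology_service()].
#' @param path Resource path (see the URL scheme in the package docs).
#' @param accept One of `"application/json"`, `"text/plain"`,
#'   `"text/html"`.
#' @param method `"GET"`, `"PUT"` or `"DELETE"` (the latter two for
#'   `/storage` only).
#' @param body Request body for PUT: newline-separated ids.
#' @return List with `status`, `content_type`, `body` (a string).
#' @export
route <- function(app, path, accept = "application/json", method = "GET",
                  body = NULL) {
  tryCatch({
    addr <- parse_resource_address(path)
    if (addr$kind == "storage")
      return(route_storage(app, addr, accept, method, body))
    if (method != "GET") stop_argument("only GET is supported here")
    if (addr$kind == "cls") route_cls(app, addr, accept)
    else route_function(app, addr, accept)
  }, obokit_error = response_error)
}

route_cls <- function(app, addr, accept) {
  g <- service_graph(app, addr$ontology)
  assert_class_exists(g, addr$id)
  if (is.na(addr$sub)) {
    if (accept == "text/plain")
      return(list(status = 200L, content_type = accept,
                  body = paste0(addr$id, "\n")))
    return(list(status = 200L, content_type = "application/json",
                body = as.character(jsonlite::toJSON(
                  entity_json(g, addr$id), auto_unbox = TRUE))))
  }
  ids <- switch(addr$sub,
                parents = parents(g, addr$id),
                children = children(g, addr$id),
                relations = NULL,
                stop_not_found(paste0("unknown subresource '", addr$sub, "'")))
  if (is.null(ids)) {   # relation table of the class, both directions
    rel <- g$relations[g$relations$source == addr$id |
                       g$relations$target == addr$id, ]
    rel <- rel[order(rel$relation, rel$source, rel$target, method = "radix"), ]
    if (accept == "text/plain") {
      body <- paste0(paste(rel$relation, rel$source, rel$target,
                           collapse = "\n"),
                     if (nrow(rel)) "\n" else "")
      return(list(status = 200L, content_type = accept,
                  body = if (nrow(rel)) body else ""))
    }
    return(list(status = 200L, content_type = "application/json",
                body = as.character(jsonlite::toJSON(rel, dataframe = "rows"))))
  }
  render_ids(app, addr$ontology, ids, accept)
}

route_function <- function(app, addr, accept) {
  g <- service_graph(app, addr$ontology)
  plug <- app$plugins[[addr$ontology]]
  cfg <- app$configs[[addr$ontology]]
  mp <- addr$matrix_params
  arg <- addr$argument
  arg_ids <- if (!is.na(arg)) strsplit(arg, ",", fixed = TRUE)[[1]]

  set_arg <- function() {
    if (!is.null(mp$set)) resolve_set_param(app, mp$set)
    else if (!is.na(arg)) arg_ids
    else stop_argument("missing class-set argument")
  }
  need_arg <- function() {
    if (is.na(arg)) stop_argument("missing path argument")
    arg
  }
  int_param <- function(name) {
    v <- mp[[name]]
    if (is.null(v)) stop_argument(paste0("missing parameter '", name, "'"))
    n <- suppressWarnings(as.integer(v))
    if (is.na(n)) stop_argument(paste0("parameter '", name,
                                       "' must be an integer"))
    n
  }

  dispatch_basic <- function() {
    switch(addr$fn,
      searchCls = search_cls(g, cfg, need_arg(),
                             restrict_fields = mp$field),
      reduceToLevel = sort_ids(unlist(
        reduce_to_level(g, set_arg(), int_param("level")),
        use.names = FALSE)),
      reduceToClusterSize = vapply(
        reduce_to_cluster_size(g, set_arg(), int_param("max")),
        function(cl) cl$representative, character(1)),
      stop_not_found(paste0("unknown function '", addr$fn, "'")))
  }
  need_anatomy <- function() {
    if (is.null(plug$anatomy))
      stop_not_found(paste0("plugin '", addr$plugin,
                            "' not loaded for this ontology"))
    plug$anatomy
  }
  dispatch_anatomy <- function() {
    switch(addr$fn,
      organsOf = organs_of(g, need_arg(), need_anatomy()),
      physiologicalSystemsOf =
        physiological_systems_of(g, need_arg(), need_anatomy()),
      findUpstreamInSet = find_upstream_in_set(
        g, need_arg(), resolve_set_param(app, mp$set)),
      findDownstreamInSet = find_downstream_in_set(
        g, need_arg(), resolve_set_param(app, mp$set)),
      stop_not_found(paste0("unknown function '", addr$fn, "'")))
  }
  dispatch_stage <- function() {
    if (is.null(plug$stage))
      stop_not_found(paste0("plugin '", addr$plugin,
                            "' not loaded for this ontology"))
    sp <- plug$stage
    switch(addr$fn,
      concreteClasses = sp$concrete,
      genericClasses = sp$generic,
      findInGeneric = find_in_generic(g, sp$config, need_arg(), plugin = sp),
      concreteForDevStage = concrete_for_dev_stage(
        g, sp$config, need_arg(),
        mp$stage %||% stop_argument("missing ';stage=' parameter"),
        plugin = sp),
      stop_not_found(paste0("unknown function '", addr$fn, "'")))
  }

  ids <- switch(addr$plugin,
                basic = dispatch_basic(),
                anatomy = , cytomer = dispatch_anatomy(),
                stage = , tribolium = dispatch_stage(),
                stop_not_found(paste0("unknown plugin '", addr$plugin, "'")))
  render_ids(app, addr$ontology, ids, accept)
}

# a ';set=' matrix parameter is either a stored-set reference
# 'partition:list' (':' because '/' would split the path segment; an
# encoded '%2F' works too) or a comma-separated inline id list
resolve_set_param <- function(app, v) {
  if (is.null(v)) stop_argument("missing ';set=' parameter")
  v <- sub(":", "/", v, fixed = TRUE)
  if (grepl("/", v, fixed = TRUE)) {
    if (is.null(app$store)) stop_argument("service has no set store")
    resolve_set(app$store, v)
  } else {
    strsplit(v, ",", fixed = TRUE)[[1]]
  }
}

route_storage <- function(app, addr, accept, method, body) {
  if (is.null(app$store)) stop_argument("service has no set store")
  st <- app$store
  if (is.na(addr$list)) {
    if (method == "PUT") {
      create_partition(st, addr$partition)
      return(list(status = 201L, content_type = "text/plain",
                  body = paste0(addr$partition, "\n")))
    }
    if (method == "GET") {
      nm <- list_names(st, addr$partition)
      return(list(status = 200L, content_type = "text/plain",
                  body = paste0(paste(nm, collapse = "\n"),
                                if (length(nm)) "\n" else "")))
    }
    stop_argument("unsupported storage method")
  }
  if (method == "PUT") {
    ids <- strsplit(body %||% "", "\n", fixed = TRUE)[[1]]
    ids <- trimws(ids)
    put_list(st, addr$partition, addr$list, ids[nzchar(ids)])
    return(list(status = 201L, content_type = "text/plain",
                body = paste0(addr$list, "\n")))
  }
  if (method == "DELETE") {
    delete_list(st, addr$partition, addr$list)
    return(list(status = 200L, content_type = "text/plain", body = ""))
  }
  ids <- get_list(st, addr$partition, addr$list)
  if (accept == "application/json")
    return(list(status = 200L, content_type = accept,
                body = as.character(jsonlite::toJSON(ids))))
  list(status = 200L, content_type = "text/plain",
       body = paste0(paste(ids, collapse = "\n"),
                     if (length(ids)) "\n" else ""))
}

# ---------------------------------------------------------------------------
# HTTP server (httpuv)

#' Serve an ontology service over HTTP
#'
#' Thin httpuv binding around [route()].  Runs until interrupted when
#' `blocking = TRUE`; otherwise returns the server handle (stop it with
#' `httpuv::stopServer()`).
#'
#' @param app An [ontology_service()].
#' @param port TCP port.
#' @param host Bind address.
#' @param blocking Serve in a blocking loop?
#' @export
obo_serve <- function(app, port = 8765L, host = "127.0.0.1",
                      blocking = TRUE) {
  if (!requireNamespace("httpuv", quietly = TRUE))
    stop("obo_serve() needs the 'httpuv' package", call. = FALSE)
  handler <- function(req) {
    accept <- req$HTTP_ACCEPT %||% "application/json"
    accept <- pick_content_type(accept)
    body <- NULL
    if (!is.null(req$rook.input)) {
      raw <- req$rook.input$read()
      if (length(raw)) body <- rawToChar(raw)
    }
    res <- route(app, req$PATH_INFO, accept = accept,
                 method = req$REQUEST_METHOD, body = body)
    list(status = res$status,
         headers = list("Content-Type" = paste0(res$content_type,
                                                "; charset=utf-8")),
         body = res$body)
  }
  srv <- httpuv::startServer(host, port, list(call = handler))
  if (!blocking) return(invisible(srv))
  on.exit(httpuv::stopServer(srv))
  message("serving on http://", host, ":", port)
  httpuv::service(Inf)
}

pick_content_type <- function(accept) {
  for (ct in c("text/plain", "text/html", "application/json"))
    if (grepl(ct, accept, fixed = TRUE)) return(ct)
  "application/json"
}
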