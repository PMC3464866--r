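make_app <- function(store_dir = tempfile()) {
  st <- set_store(store_dir)
  create_partition(st, "anatomydb")
  put_list(st, "anatomydb", "anatomy", c("kidney", "liver", "pancreas"))
  ontology_service(lapply(c("fig2", "fig3", "fig4", "tribolium"),
                          make_fixture),
                   configs = list(fig2 = ontology_config("fig2")),
                   store = st)
}

app <- make_app()

test_that("class resources return entities with navigable links", {
  r <- route(app, "/fig2/cls/regulation_of_binding")
  expect_equal(r$status, 200L)
  expect_equal(r$content_type, "application/json")
  e <- jsonlite::fromJSON(r$body)
  expect_equal(e$id, "regulation_of_binding")
  expect_equal(e$label, "regulation of binding")
  expect_equal(e$links$parents, "/fig2/cls/regulation_of_binding/parents")

  r <- route(app, "/fig2/cls/negative_regulation_of_binding/parents",
             accept = "text/plain")
  expect_equal(strsplit(r$body, "\n")[[1]],
               c("negative_regulation_of_molecular_function",
                 "regulation_of_binding"))

  r <- route(app, "/fig3/cls/Cell_2/relations")
  rel <- jsonlite::fromJSON(r$body)
  expect_setequal(rel$relation,
                  c("differentiatesInto", "isCellOf", "isPartOf"))
})

test_that("unknown resources map to 404-style responses, bad params to 400", {
  expect_equal(route(app, "/nope/cls/x")$status, 404L)
  expect_equal(route(app, "/fig2/cls/nope")$status, 404L)
  expect_equal(route(app, "/fig2/functions/nope/f/x")$status, 404L)
  expect_equal(route(app, "/fig2/functions/basic/nope/x")$status, 404L)
  expect_equal(route(app, "/fig2/weird/x")$status, 404L)
  # level missing / malformed -> argument error
  expect_equal(route(app, "/fig2/functions/basic/reduceToLevel/thing")$status,
               400L)
  expect_equal(
    route(app, "/fig2/functions/basic/reduceToLevel;level=x/thing")$status,
    400L)
  # anatomy plugin not loadable for fig2 (no anchors)
  expect_equal(route(app, "/fig2/functions/anatomy/organsOf/thing")$status,
               404L)
})

test_that("function resources dispatch with matrix parameters", {
  r <- route(app,
             "/fig2/functions/basic/reduceToLevel;level=5/negative_regulation_of_binding",
             accept = "text/plain")
  expect_equal(strsplit(r$body, "\n")[[1]],
               c("negative_regulation_of_molecular_function",
                 "regulation_of_binding"))
  r <- route(app, "/fig2/functions/basic/searchCls/zzz",
             accept = "text/plain")
  expect_equal(r$status, 200L)   # empty result is still a success
  expect_equal(r$body, "")
  r <- route(app, "/fig3/functions/anatomy/organsOf/Cell_2",
             accept = "text/plain")
  expect_equal(strsplit(r$body, "\n")[[1]], c("Organ_1", "Organ_2"))
  r <- route(app,
             "/fig4/functions/anatomy/findUpstreamInSet;set=anatomydb:anatomy/nephron",
             accept = "text/plain")
  expect_equal(strsplit(r$body, "\n")[[1]], "kidney")
  r <- route(app,
             "/tribolium/functions/stage/concreteForDevStage;stage=larva/antenna",
             accept = "text/plain")
  expect_equal(strsplit(r$body, "\n")[[1]],
               c("larval_antenna", "larval_flagellum"))
})

test_that("content negotiation serves json, plain text and html", {
  path <- "/fig2/functions/basic/searchCls/protein"
  js <- route(app, path, accept = "application/json")
  tx <- route(app, path, accept = "text/plain")
  ht <- route(app, path, accept = "text/html")
  ids <- vapply(jsonlite::fromJSON(js$body, simplifyVector = FALSE),
                `[[`, "", "id")
  expect_equal(ids, strsplit(tx$body, "\n")[[1]])
  expect_match(ht$body, "<a href=\"/fig2/cls/regulation_of_protein_binding\"")
  expect_equal(ht$content_type, "text/html")
})

test_that("storage resources support put/get/delete over the router", {
  app2 <- make_app()
  expect_equal(route(app2, "/storage/p1", method = "PUT")$status, 201L)
  expect_equal(route(app2, "/storage/p1", method = "PUT")$status, 409L)
  r <- route(app2, "/storage/p1/genes", method = "PUT",
             body = "tll\nmlpt\n")
  expect_equal(r$status, 201L)
  r <- route(app2, "/storage/p1/genes", accept = "text/plain")
  expect_equal(strsplit(r$body, "\n")[[1]], c("tll", "mlpt"))
  r <- route(app2, "/storage/p1/genes", accept = "application/json")
  expect_equal(jsonlite::fromJSON(r$body), c("tll", "mlpt"))
  expect_equal(route(app2, "/storage/p1/genes", method = "DELETE")$status,
               200L)
  expect_equal(route(app2, "/storage/p1/genes")$status, 404L)
  expect_equal(route(app2, "/storage/missing/x")$status, 404L)
})

test_that("matrix-parameter parsing matches the URL shape", {
  a <- parse_resource_address(
    "/cytomer/functions/basic/searchCls;field=definitionEnglish/cistern")
  expect_equal(a$ontology, "cytomer")
  expect_equal(a$plugin, "basic")
  expect_equal(a$fn, "searchCls")
  expect_equal(a$matrix_params, list(field = "definitionEnglish"))
  expect_equal(a$argument, "cistern")
  expect_error(parse_resource_address("/x"),
               class = "obokit_argument_error")
  expect_error(parse_resource_address("/ont/functions/p"),
               class = "obokit_argument_error")
})

test_that("every fixture function gives identical results via REST and library", {
  conn <- local_connector(app)
  fig2 <- make_fixture("fig2")
  marked <- attr(fig2, "marked")
  tr <- make_fixture("tribolium")
  plug <- stage_plugin(tr)

  cases <- list(
    list(call_function(conn, "fig2", "basic", "searchCls", "binding"),
         search_cls(fig2, pattern = "binding")),
    list(call_function(conn, "fig2", "basic", "reduceToLevel",
                       "negative_regulation_of_binding",
                       params = list(level = 5)),
         reduce_to_level(fig2, "negative_regulation_of_binding", 5)[[1]]),
    list(call_function(conn, "fig2", "basic", "reduceToClusterSize",
                       marked, params = list(max = 2)),
         vapply(reduce_to_cluster_size(fig2, marked, 2), `[[`, "",
                "representative")),
    list(call_function(conn, "fig3", "anatomy", "organsOf", "Cell_2"),
         organs_of(make_fixture("fig3"), "Cell_2")),
    list(call_function(conn, "fig4", "anatomy", "findUpstreamInSet",
                       "nephron", params = list(set = "anatomydb:anatomy")),
         find_upstream_in_set(make_fixture("fig4"), "nephron",
                              c("kidney", "liver", "pancreas"))),
    list(call_function(conn, "fig4", "anatomy", "findDownstreamInSet",
                       "digestive_organ",
                       params = list(set = "anatomydb:anatomy")),
         find_downstream_in_set(make_fixture("fig4"), "digestive_organ",
                                c("kidney", "liver", "pancreas"))),
    list(call_function(conn, "tribolium", "stage", "concreteClasses"),
         plug$concrete),
    list(call_function(conn, "tribolium", "stage", "genericClasses"),
         plug$generic),
    list(call_function(conn, "tribolium", "stage", "findInGeneric",
                       "antenna"),
         find_in_generic(tr, plug$config, "antenna", plugin = plug)),
    list(call_function(conn, "tribolium", "stage", "concreteForDevStage",
                       "antenna", params = list(stage = "larva")),
         concrete_for_dev_stage(tr, plug$config, "antenna", "larva",
                                plugin = plug)))
  for (i in seq_along(cases))
    expect_equal(cases[[i]][[1]], cases[[i]][[2]], info = paste("case", i))
})
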