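write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(lines, f)
  f
}

test_that("minimal stanzas parse into classes, hierarchy and relations", {
  f <- write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: A", "name: alpha", "is_a: B ! beta",
    "relationship: isPartOf X", "",
    "[Term]", "id: B", "name: beta", "",
    "[Term]", "id: X", "name: chi"))
  g <- read_obo(f)
  expect_setequal(names(g$classes), c("A", "B", "X"))
  expect_equal(g$classes$A$label, "alpha")
  expect_equal(g$is_a, list(A = "B"))
  expect_equal(g$relations$source, "A")
  expect_equal(g$relations$target, "X")
  expect_equal(g$relations$relation, "isPartOf")
})

test_that("unknown tags land in annotations verbatim; obsolete flag honoured", {
  f <- write_lines_tmp(c(
    "[Term]", "id: A", "name: alpha",
    "def: \"a fine class\" [src:1]",
    "synonym: \"first letter\" EXACT []",
    "custom_field: some value",
    "custom_field: another value", "",
    "[Term]", "id: OLD", "name: gone", "is_obsolete: true", "is_a: A"))
  g <- read_obo(f)
  ann <- g$classes$A$annotations
  expect_equal(ann$custom_field, c("some value", "another value"))
  expect_match(ann$def, "a fine class")
  expect_match(ann$synonym, "first letter")
  expect_true(g$classes$OLD$obsolete)
  expect_length(g$is_a, 0)   # obsolete classes carry no edges
})

test_that("a stanza without an id is a parse error with a position", {
  f <- write_lines_tmp(c("[Term]", "name: anonymous"))
  expect_error(read_obo(f), "id")
})

test_that("dangling edge targets are dropped with a warning", {
  f <- write_lines_tmp(c(
    "[Term]", "id: A", "is_a: GHOST",
    "relationship: isPartOf PHANTOM"))
  expect_warning(g <- read_obo(f), "GHOST|PHANTOM")
  expect_length(g$is_a, 0)
  expect_equal(nrow(g$relations), 0)
})

test_that("write/read round trip is the identity on every named fixture", {
  for (nm in c("fig2", "fig3", "fig4", "tribolium")) {
    g <- make_fixture(nm)
    f <- tempfile(fileext = ".obo")
    write_obo(g, f)
    g2 <- read_obo(f, name = g$name)
    expect_equal(sort(names(g2$classes)), sort(names(g$classes)), info = nm)
    expect_equal(g2$is_a[order(names(g2$is_a))],
                 lapply(g$is_a, sort)[order(names(g$is_a))], info = nm)
    rel_key <- function(r) sort(paste(r$source, r$relation, r$target))
    expect_equal(rel_key(g2$relations), rel_key(g$relations), info = nm)
    labs <- vapply(g$classes, `[[`, "", "label")
    labs2 <- vapply(g2$classes, `[[`, "", "label")
    expect_equal(labs2[sort(names(labs2))], labs[sort(names(labs))],
                 info = nm)
    # second round trip reproduces the file byte for byte
    f2 <- tempfile(fileext = ".obo")
    write_obo(g2, f2)
    expect_identical(readLines(f2), readLines(f), info = nm)
  }
})

test_that("round trip preserves annotations including escaped characters", {
  cl <- ontology_class("A", "alpha",
                       annotations = list(def = "uses ! and \\ freely",
                                          synonym = c("s one", "s two")))
  g <- ontology_graph("t", list(cl, ontology_class("B")), list(A = "B"))
  f <- tempfile(fileext = ".obo")
  write_obo(g, f)
  g2 <- read_obo(f, name = "t")
  expect_equal(g2$classes$A$annotations$def, "uses ! and \\ freely")
  expect_equal(g2$classes$A$annotations$synonym, c("s one", "s two"))
})

test_that("an independent OBO parser reads the emitted files the same way", {
  # cross-check the writer against the Python 'obonet' reader on one fixture
  py <- Sys.which("python")
  f <- tempfile(fileext = ".obo")
  write_obo(make_fixture("fig2"), f)
  out <- suppressWarnings(system2(
    py, c("-c", shQuote(paste0(
      "import obonet; g = obonet.read_obo('", f, "'); ",
      "print(g.number_of_nodes(), g.number_of_edges())"))),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    fail(paste("obonet cross-check did not run:", paste(out, collapse = " ")))
  nums <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  g <- make_fixture("fig2")
  expect_equal(nums[1], length(g$classes))
  expect_equal(nums[2], sum(lengths(g$is_a)))
})

test_that("config files parse name, file and indexed fields", {
  f <- tempfile()
  writeLines(c("name=cytomer", "file=cytomer.obo",
               "indexed_fields=definitionEnglish,synonym"), f)
  cfg <- read_config(f)
  expect_equal(cfg$ontology_name, "cytomer")
  expect_equal(cfg$indexed_fields, c("definitionEnglish", "synonym"))
  expect_equal(cfg$file_path, "cytomer.obo")

  writeLines(c("name=x", "indexed_fields="), f)
  expect_equal(read_config(f)$indexed_fields, character())

  writeLines("file=only.obo", f)
  expect_error(read_config(f), class = "obokit_config_error")
  expect_error(read_config(f), "name")

  writeLines("name=a/b", f)
  expect_error(read_config(f), class = "obokit_config_error")
})
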