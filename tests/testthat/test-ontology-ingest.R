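# Ingestion: NATIVE_TSV and Turtle dialects, validation reporting.

test_that("NATIVE_TSV round trip is lossless up to row order", {
  onto <- demo_ontology()
  dir <- withr::local_tempdir()
  write_ontology_tsv(onto, dir)
  onto2 <- read_ontology_tsv(dir)
  for (nm in c("concepts", "is_a", "parts", "sites", "morphs")) {
    expect_equal(as.data.frame(onto[[nm]]), as.data.frame(onto2[[nm]]),
                 info = nm)
  }
})

test_that("the two dialects yield identical ontologies", {
  onto <- demo_ontology()
  ttl <- withr::local_tempfile(fileext = ".ttl")
  write_ontology_ttl(onto, ttl)
  onto2 <- load_source_ontology(ttl, dialect = "TURTLE_OWL_SUBSET")
  for (nm in c("concepts", "is_a", "parts", "sites", "morphs")) {
    expect_equal(as.data.frame(onto[[nm]]), as.data.frame(onto2[[nm]]),
                 info = nm)
  }
})

test_that("empty input files produce an empty ontology", {
  dir <- withr::local_tempdir()
  writeLines("id\tlabel\taxis", file.path(dir, "concepts.tsv"))
  writeLines("child\tparent", file.path(dir, "is_a.tsv"))
  writeLines("child\tparent\trole", file.path(dir, "part_edges.tsv"))
  writeLines("concept\trole\tvalue", file.path(dir, "role_assertions.tsv"))
  onto <- read_ontology_tsv(dir)
  expect_equal(nrow(onto$concepts), 0)
  expect_equal(nrow(onto$is_a), 0)
})

test_that("validation reports cycles, dangling edges and off-axis fillers", {
  expect_true(ontology_valid(validate_ontology(demo_ontology())))

  concepts <- tibble::tibble(id = c("a", "b", "n1"),
                             label = c("a", "b", "n1"),
                             axis = c("ANATOMY", "ANATOMY", "NEOPLASM"))
  cyc <- ontology(concepts,
                  is_a = tibble::tibble(child = c("a", "b"), parent = c("b", "a")),
                  validate = FALSE)
  rep <- validate_ontology(cyc)
  expect_gt(nrow(rep$cycles), 0)
  expect_error(ontology(concepts,
                        is_a = tibble::tibble(child = c("a", "b"), parent = c("b", "a"))),
               class = "oncolattice_invalid_ontology")

  dangle <- ontology(concepts,
                     sites = tibble::tibble(concept = "n1", site = "missing"),
                     validate = FALSE)
  expect_gt(nrow(validate_ontology(dangle)$dangling), 0)

  # a site filler pointing at a neoplasm concept is flagged, mirroring
  # crosswalk rows that map topography codes to disease concepts
  off <- ontology(concepts,
                  sites = tibble::tibble(concept = "n1", site = "n1"),
                  validate = FALSE)
  rep <- validate_ontology(off)
  expect_equal(nrow(rep$off_axis_sites), 1)
  expect_equal(rep$off_axis_sites$filler, "n1")
})

test_that("neoplasm extraction keeps annotations and empty sets", {
  onto <- demo_ontology()
  neo <- extract_neoplasm_graph(onto)
  expect_setequal(neo$sites$site[neo$sites$concept == "NCIT:C9329"],
                  c("NCIT:A_GIS", "NCIT:A_CEC", "NCIT:A_COL",
                    "NCIT:A_INT", "NCIT:A_CRR"))
  expect_true("NCIT:C3262" %in% neo$concepts$id)
  expect_equal(sum(neo$morphs$concept == "NCIT:C3262"), 0)
  # no anatomy concepts leak into the neoplasm graph
  expect_false(any(neo$concepts$axis == "ANATOMY"))
})

test_that("axis tags partition the extracted subgraphs", {
  onto <- demo_ontology()
  anat <- extract_anatomy_graph(onto)$nodes
  neo <- extract_neoplasm_graph(onto)$concepts$id
  expect_length(intersect(anat, neo), 0)
  expect_setequal(c(anat, neo), onto$concepts$id)
})

test_that("anatomy cycles through part edges are fatal", {
  concepts <- tibble::tibble(id = c("a", "b"), label = c("a", "b"),
                             axis = "ANATOMY")
  onto <- ontology(concepts,
                   parts = tibble::tibble(child = c("a", "b"), parent = c("b", "a"),
                                          role = "PART_PHYSICAL"),
                   validate = FALSE)
  expect_error(extract_anatomy_graph(onto), class = "oncolattice_cycle")
})
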