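# Morphology parsing, behavior classification, axis construction and the
# refined (ancestor-closed) concept index.

test_that("morphology codes parse into histology and behavior digit", {
  p <- parse_morphology_code(c("8140/3", "8500/3", "0001/0"))
  expect_equal(p$histology, c("8140", "8500", "0001"))
  expect_equal(p$behavior_digit, c("3", "3", "0"))
  expect_error(parse_morphology_code("814/3"), class = "oncolattice_format")
  expect_error(parse_morphology_code("8140-3"), class = "oncolattice_format")
})

test_that("behavior digits map onto the six behavior classes", {
  expect_equal(behavior_class_of(c(0, 1, 2, 3, 6, 9)),
               c("BENIGN", "UNKNOWN_BENIGN_MALIGNANT", "IN_SITU",
                 "MALIGNANT_PRIMARY", "MALIGNANT_METASTATIC",
                 "UNKNOWN_PRIMARY_METASTATIC"))
  expect_error(behavior_class_of(4), class = "oncolattice_format")
})

test_that("the axis holds one class per code under its behavior root", {
  axis <- get_model()$axis
  nodes <- axis$nodes
  expect_equal(sum(nodes$kind == "behavior"), 6)
  expect_equal(nodes$behavior[nodes$id == "8140/3"], "MALIGNANT_PRIMARY")
  expect_equal(nodes$behavior[nodes$id == "9121/0"], "BENIGN")
  expect_equal(nodes$behavior[nodes$id == "9120/0"], "BENIGN")
  # every specific node has exactly one behavior parent
  spec <- nodes[nodes$kind == "specific", ]
  expect_true(all(spec$parent %in% BEHAVIOR_CLASSES))

  # empty graph still carries root plus the six roots
  empty_neo <- structure(list(
    concepts = tibble::tibble(id = character(), label = character(), axis = character()),
    is_a = tibble::tibble(child = character(), parent = character()),
    sites = tibble::tibble(concept = character(), site = character()),
    morphs = tibble::tibble(concept = character(), code = character())
  ), class = "neoplasm_graph")
  expect_equal(nrow(build_morphology_axis(empty_neo)$nodes), 7)
})

test_that("axis size is six roots plus the distinct annotated codes", {
  for (s in 1:5) {
    onto <- random_ontology(n_anatomy = 10, n_neoplasm = 12, n_morph = 6, seed = s)
    axis <- build_morphology_axis(extract_neoplasm_graph(onto))
    expect_equal(nrow(axis$nodes), 7 + dplyr::n_distinct(onto$morphs$code))
  }
})

test_that("refined index closes annotations over is_a ancestors", {
  m <- get_model()
  # the hemangioma chain inherits both the specific and the NOS code
  expect_setequal(m$refined$morphs$code[m$refined$morphs$concept == "NCIT:D_CCHEM"],
                  c("9121/0", "9120/0"))
  # stage-0 disease inherits an in situ and an invasive code: the clash the
  # audit must surface later
  stage0 <- m$refined$morphs$code[m$refined$morphs$concept == "NCIT:C3641"]
  axis <- m$axis
  beh <- setNames(axis$nodes$behavior, axis$nodes$id)
  expect_true("IN_SITU" %in% beh[stage0])
  expect_true("MALIGNANT_PRIMARY" %in% beh[stage0])
  # a root concept with no ancestors keeps only its own assertions
  expect_length(m$refined$morphs$code[m$refined$morphs$concept == "NCIT:C3262"], 0)
  expect_setequal(m$refined$sites$site[m$refined$sites$concept == "NCIT:C9329"],
                  c("NCIT:A_GIS", "NCIT:A_CEC", "NCIT:A_COL",
                    "NCIT:A_INT", "NCIT:A_CRR"))
})

test_that("inheritance is monotone along is_a (oracle check)", {
  for (s in 1:3) {
    onto <- random_ontology(n_anatomy = 8, n_neoplasm = 15, n_morph = 6, seed = s)
    orc <- brute_force_oracle(onto)
    neo <- extract_neoplasm_graph(onto)
    axis <- build_morphology_axis(neo)
    refined <- compute_refined_index(neo, axis)
    for (c0 in refined$concepts) {
      eng_m <- sort(refined$morphs$code[refined$morphs$concept == c0])
      eng_s <- sort(refined$sites$site[refined$sites$concept == c0])
      expect_identical(eng_m, orc$refined_morphs[[c0]])
      expect_identical(eng_s, orc$refined_sites[[c0]])
    }
    for (i in seq_len(nrow(neo$is_a))) {
      child <- neo$is_a$child[[i]]
      parent <- neo$is_a$parent[[i]]
      expect_true(all(orc$refined_morphs[[parent]] %in% orc$refined_morphs[[child]]))
      expect_true(all(orc$refined_sites[[parent]] %in% orc$refined_sites[[child]]))
    }
  }
})
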