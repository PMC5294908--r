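# Structural order engine: anatomy reachability, morphology and diagnosis
# subsumption, transitive reduction, minimal antichains.

test_that("anatomy reachability follows is_a and both part roles, reflexively", {
  idx <- get_model()$index
  # part-whole chain: cecum lies within the large intestine
  expect_true(anat_reachable(idx, "NCIT:A_CEC", "NCIT:A_LI"))
  # no link between colon and colorectal region in the source
  expect_false(anat_reachable(idx, "NCIT:A_COL", "NCIT:A_CRR"))
  expect_false(anat_reachable(idx, "NCIT:A_CRR", "NCIT:A_COL"))
  # cell-part chain propagates all the way up to the organ
  expect_true(anat_reachable(idx, "NCIT:A_BG", "NCIT:A_SKN"))
  # reflexivity for every node
  expect_true(all(anat_reachable(idx, idx$nodes, idx$nodes)))
  expect_error(anat_reachable(idx, "NCIT:NOPE", "NCIT:A_LI"),
               class = "oncolattice_unknown_id")
})

test_that("morphology subsumption is flat below the behavior roots", {
  axis <- get_model()$axis
  expect_true(morph_subsumes(axis, "8140/3", "MALIGNANT_PRIMARY"))
  expect_true(morph_subsumes(axis, "8140/3", "8140/3"))
  expect_true(morph_subsumes(axis, "8140/3", "MORPHOLOGY"))
  expect_false(morph_subsumes(axis, "8140/3", "BENIGN"))
  # no histology hierarchy: cavernous hemangioma and hemangioma NOS are
  # incomparable specific classes
  expect_false(morph_subsumes(axis, "9121/0", "9120/0"))
  expect_false(morph_subsumes(axis, "9120/0", "9121/0"))
  expect_error(morph_subsumes(axis, "0000/0", "BENIGN"),
               class = "oncolattice_unknown_id")
})

test_that("diagnosis subsumption combines both component orders", {
  m <- get_model()
  d_spec <- "DX:8140/3@NCIT:A_LOQ"
  d_gen <- "DX:MALIGNANT_PRIMARY@NCIT:A_LOQ"
  expect_true(dx_subsumes(m$axis, m$index, d_spec, d_gen))
  expect_false(dx_subsumes(m$axis, m$index, d_gen, d_spec))
  expect_true(dx_subsumes(m$axis, m$index, d_spec, d_spec))
  # cecum does not reach the colorectal region, so neither does the diagnosis
  expect_false(dx_subsumes(m$axis, m$index,
                           "DX:MALIGNANT_PRIMARY@NCIT:A_CEC",
                           "DX:MALIGNANT_PRIMARY@NCIT:A_CRR"))
  # but it reaches the large intestine
  expect_true(dx_subsumes(m$axis, m$index,
                          "DX:MALIGNANT_PRIMARY@NCIT:A_CEC",
                          "DX:MALIGNANT_PRIMARY@NCIT:A_LI"))
})

test_that("transitive reduction returns the Hasse diagram", {
  # chain with a shortcut reduces to the two covering edges
  up <- list(a = c("a", "b", "c"), b = c("b", "c"), c = "c")
  red <- transitive_reduction(up)
  expect_equal(red, tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  # an antichain has no edges
  expect_equal(nrow(transitive_reduction(list(x = "x", y = "y", z = "z"))), 0)
  # antisymmetry violations are cycle errors
  expect_error(transitive_reduction(list(a = c("a", "b"), b = c("a", "b"))),
               class = "oncolattice_cycle")
})

test_that("closure of the reduction equals the input order on random DAGs", {
  for (s in 1:5) {
    ord <- random_order(25, p = 0.15, seed = s)
    red <- transitive_reduction(up_sets_from_matrix(ord$closure))
    expect_equal(naive_closure(ord$nodes, red), ord$closure)
  }
})

test_that("minimal_elements returns exactly the antichain of minima", {
  m <- get_model()
  leq <- function(x, y) dx_subsumes(m$axis, m$index, x, y)
  cands <- paste0("DX:MALIGNANT_PRIMARY@", c("NCIT:A_CEC", "NCIT:A_COL",
                                             "NCIT:A_CRR", "NCIT:A_INT",
                                             "NCIT:A_GIS"))
  out <- minimal_elements(cands, leq)
  expect_equal(out, sort(paste0("DX:MALIGNANT_PRIMARY@",
                                c("NCIT:A_CEC", "NCIT:A_COL", "NCIT:A_CRR"))))
  # result is an antichain
  for (x in out) for (y in setdiff(out, x)) expect_false(leq(x, y))
  expect_equal(minimal_elements("DX:8140/3@NCIT:C12971", leq),
               "DX:8140/3@NCIT:C12971")
  # a full chain reduces to its bottom element
  chain <- paste0("DX:MALIGNANT_PRIMARY@", c("NCIT:A_CEC", "NCIT:A_LI",
                                             "NCIT:A_INT", "NCIT:A_GIS"))
  expect_equal(minimal_elements(chain, leq), "DX:MALIGNANT_PRIMARY@NCIT:A_CEC")
  expect_equal(minimal_elements(character(), leq), character())
})
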