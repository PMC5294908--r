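# Candidate generation, retention, lattice construction, direct types.

test_that("candidate stream emits the exact cross product", {
  m <- get_model()
  # 3 morphologies x 4 reflexive parts -> 12 pairs
  axis3 <- m$axis
  axis3$nodes <- dplyr::filter(axis3$nodes, .data$kind %in% c("root", "behavior") |
                                 .data$id %in% c("8140/3", "9120/0", "9121/0"))
  rp4 <- build_rp_lattice(c("NCIT:A_CEC", "NCIT:A_COL", "NCIT:A_LI", "NCIT:C12971"),
                          m$index)
  pairs <- generate_candidates(axis3, rp4)
  expect_equal(nrow(pairs), (3 + 6) * 4)
  expect_equal(attr(pairs, "n_candidates"), 36)
  expect_false(any(duplicated(pairs)))

  # streaming visits the same pairs in chunks without materializing them
  seen <- list()
  n <- generate_candidates(axis3, rp4, callback = function(ch) {
    seen[[length(seen) + 1]] <<- ch
  }, chunk_size = 7)
  expect_equal(n, 36)
  streamed <- dplyr::bind_rows(seen)
  materialized <- pairs[, c("morph", "base")]
  attr(materialized, "n_candidates") <- NULL
  expect_equal(as.data.frame(streamed), as.data.frame(materialized))

  # empty axis streams zero pairs
  empty_axis <- axis3
  empty_axis$nodes <- empty_axis$nodes[0, ]
  expect_equal(nrow(generate_candidates(empty_axis, rp4)), 0)
})

test_that("satisfaction uses inherited morphologies and sites", {
  m <- get_model()
  expect_true(concept_satisfies("NCIT:D_BADC", "8140/3", "NCIT:C12971",
                                m$refined, m$axis, m$index))
  # inherited behavior-level satisfaction
  expect_true(concept_satisfies("NCIT:D_BADC", "MALIGNANT_PRIMARY", "NCIT:C12971",
                                m$refined, m$axis, m$index))
  # concepts without any inherited morphology satisfy nothing, even when
  # their sites reach the candidate base (C9329 asserts the colorectal region)
  expect_false(concept_satisfies("NCIT:C9329", "MALIGNANT_PRIMARY", "NCIT:A_CRR",
                                 m$refined, m$axis, m$index))
  expect_error(concept_satisfies("NCIT:NOPE", "8140/3", "NCIT:C12971",
                                 m$refined, m$axis, m$index),
               class = "oncolattice_unknown_id")
})

test_that("retention equals the brute-force scan and prunes the rest", {
  m <- get_model()
  ret_ids <- paste(m$retained$morph, m$retained$base)
  expect_true("MALIGNANT_PRIMARY NCIT:A_CEC" %in% ret_ids)
  # no benign hemangioma of the breast: nothing supports it
  expect_false("9121/0 NCIT:C12971" %in% ret_ids)

  orc <- brute_force_oracle(demo_ontology())
  expect_identical(sort(ret_ids), sort(paste(orc$retained$morph, orc$retained$base)))
  # support sets agree row by row
  orc_support <- setNames(orc$retained$support,
                          paste(orc$retained$morph, orc$retained$base))
  for (i in seq_len(nrow(m$retained))) {
    expect_identical(m$retained$support[[i]], orc_support[[ret_ids[[i]]]])
  }
})

test_that("retention on an ontology without neoplasm concepts is empty", {
  onto <- ontology(tibble::tibble(id = "a", label = "a", axis = "ANATOMY"))
  model <- build_derivative_model(onto)
  expect_equal(nrow(model$retained), 0)
  expect_null(model$lattice)
})

test_that("lattice edges close to the pairwise diagnosis order", {
  m <- get_model()
  lat <- m$lattice
  ids <- lat$classes$id
  clo <- naive_closure(ids, lat$edges)
  for (x in ids) {
    expect_setequal(colnames(clo)[clo[x, ]],
                    ids[dx_subsumes(m$axis, m$index, x, ids)])
  }
  # incomparable hemangioma nodes coexist
  expect_true(all(c("DX:9121/0@NCIT:A_COL", "DX:9120/0@NCIT:A_COL") %in% ids))
  expect_false(clo["DX:9121/0@NCIT:A_COL", "DX:9120/0@NCIT:A_COL"])

  one <- build_dx_lattice(m$retained[1, ], m$axis, m$index)
  expect_equal(nrow(one$classes), 1)
  expect_equal(nrow(one$edges), 0)
})

test_that("direct diagnosis superclasses form the printed antichains", {
  m <- get_model()
  got <- direct_dx_superclasses("NCIT:D_CCHEM", m$lattice, m$refined, m$axis, m$index)
  expect_equal(got, sort(c("DX:9121/0@NCIT:A_CRR", "DX:9121/0@NCIT:A_COL",
                           "DX:9120/0@NCIT:A_CRR", "DX:9120/0@NCIT:A_COL")))
  # antichain property
  for (x in got) for (y in setdiff(got, x)) {
    expect_false(dx_subsumes(m$axis, m$index, x, y))
  }
  # a concept with no inherited morphology satisfies nothing... except through
  # the lattice it still has none (C3262 root)
  expect_length(direct_dx_superclasses("NCIT:C3262", m$lattice, m$refined,
                                       m$axis, m$index), 0)
})

test_that("support is upward-closed along the lattice", {
  m <- get_model()
  lat <- m$lattice
  support <- setNames(lat$classes$support, lat$classes$id)
  for (i in seq_len(nrow(lat$edges))) {
    lower <- lat$edges$from[[i]]
    upper <- lat$edges$to[[i]]
    expect_true(all(support[[lower]] %in% support[[upper]]),
                info = paste(lower, "->", upper))
  }
})
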