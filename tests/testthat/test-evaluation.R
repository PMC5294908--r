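# Gold-standard reading, branch sharing, edge distance, mapping rebuild.

test_that("SEER-style reader applies the behavior scope filter and strata", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "gold.tsv")
  writeLines(c("topography\tmorphology\ticd10",
               "C18.9\t8140/3\tC18.9",
               "C18.9\t8140/6\tC18.9",
               "C42.1\t9732/3\tC90.0"), p)
  gold <- read_seer_conversion(p)
  expect_equal(nrow(gold), 2)
  expect_equal(attr(gold, "n_dropped"), 1)
  expect_equal(gold$stratum[gold$morphology == "8140/3"], "SOLID")
  # myeloma: both the C90 block and the 9732 histology are hematopoietic
  expect_equal(gold$stratum[gold$morphology == "9732/3"], "HEMATOPOIETIC")

  empty <- file.path(dir, "empty.tsv")
  writeLines("topography\tmorphology\ticd10", empty)
  expect_equal(nrow(read_seer_conversion(empty)), 0)
})

test_that("shared branches recover the large-intestine link", {
  demo <- get_demo()
  m <- demo$model
  sat <- satisfied_dx_of_combination(binding_of(demo, "ICDO3_T", "C18.9"),
                                     binding_of(demo, "ICDO3_M", "8140/3"), m)
  shared <- shared_branches(binding_of(demo, "ICD10", "C19.9"), sat, m)
  # the SEER file has no such conversion row, yet the model links them
  expect_equal(shared, "DX:MALIGNANT_PRIMARY@NCIT:A_LI")
  # result is an antichain for a multi-branch pairing
  shared2 <- shared_branches(binding_of(demo, "ICD10", "C18.0"), sat, m)
  for (x in shared2) for (y in setdiff(shared2, x)) {
    expect_false(dx_subsumes(m$axis, m$index, x, y))
  }
  # disjoint satisfied sets share nothing
  sat_breast <- satisfied_dx_of_combination(binding_of(demo, "ICDO3_T", "C50.5"),
                                            binding_of(demo, "ICDO3_M", "9120/0"), m)
  expect_length(shared_branches(binding_of(demo, "ICD10", "C19.9"), sat_breast, m), 0)
  # unbound ICD-10 side is not evaluable, not an error
  expect_null(shared_branches(binding_of(demo, "ICD10", "C00.1"), sat, m))
})

test_that("edge distance is zero on the diagonal, one across a Hasse edge", {
  demo <- get_demo()
  lat <- demo$model$lattice
  expect_equal(dx_edge_distance(lat, lat$classes$id[[1]], lat$classes$id[[1]]), 0)
  e <- lat$edges[1, ]
  expect_equal(dx_edge_distance(lat, e$from, e$to), 1)
  expect_error(dx_edge_distance(lat, "DX:none@none", e$from),
               class = "oncolattice_unknown_id")
})

test_that("edge distance equals exhaustive common-ancestor search and is symmetric", {
  demo <- get_demo()
  lat <- demo$model$lattice
  ids <- lat$classes$id
  clo <- naive_closure(ids, lat$edges)
  g_up <- setNames(lapply(ids, function(i) lat$edges$to[lat$edges$from == i]), ids)
  brute_dist <- function(a, b) {
    # BFS levels upward from each node, then min total steps to a common node
    levels <- function(x) {
      d <- c(stats::setNames(0, x))
      frontier <- x
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(g_up[frontier])), names(d))
        if (!length(nxt)) break
        d <- c(d, stats::setNames(rep(max(d) + 1, length(nxt)), nxt))
        frontier <- nxt
      }
      d
    }
    # levels() assigns BFS depth, which on a DAG is the minimum step count
    da <- levels(a)
    db <- levels(b)
    common <- intersect(names(da), names(db))
    if (!length(common)) Inf else min(da[common] + db[common])
  }
  set.seed(42)
  pick <- sample(ids, 8)
  for (a in pick) for (b in pick) {
    expect_equal(dx_edge_distance(lat, a, b), unname(brute_dist(a, b)),
                 info = paste(a, b))
    expect_equal(dx_edge_distance(lat, a, b), dx_edge_distance(lat, b, a))
  }
})

test_that("rebuild keeps ties and leaves unconnected combos unpredicted", {
  demo <- get_demo()
  m <- demo$model
  combos <- tibble::tibble(
    topography = "C18.9", morphology = "8140/3",
    combo_minimal = list("DX:8140/3@NCIT:A_COL")
  )
  pred <- rebuild_mappings(demo$bindings, combos, m)
  # C18.9 and C18.0 are both one Hasse step away: the tie is preserved
  expect_setequal(pred$predicted[[1]], c("C18.0", "C18.9"))
  expect_equal(pred$n_predicted, 2L)
  expect_equal(pred$distance, 1)
})

test_that("evaluation counts are conserved across strata", {
  demo <- get_demo()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "gold.tsv")
  readr::write_tsv(demo$gold, p)
  gold <- read_seer_conversion(p)
  ev <- evaluate_against_gold(gold, demo$bindings, demo$model)
  s <- ev$summary
  for (col in c("n_evaluable", "n_related", "n_multibranch", "n_rebuilt", "n_nonunique")) {
    expect_equal(s[[col]][s$stratum == "ALL"],
                 s[[col]][s$stratum == "HEMATOPOIETIC"] + s[[col]][s$stratum == "SOLID"])
  }
  expect_true(all(s$n_related <= s$n_evaluable))
  expect_true(all(s$n_rebuilt <= s$n_evaluable))
  expect_true(all(s$n_multibranch <= pmax(s$n_related, 0)))
  # rebuilt mappings always share a branch
  expect_true(all(!ev$rows$rebuilt | ev$rows$related))
  # empty gold standard: all zeros
  ev0 <- evaluate_against_gold(gold[0, ], demo$bindings, demo$model)
  expect_true(all(ev0$summary$n_evaluable == 0))
})

test_that("planted gold standards are fully recovered; decoys break uniqueness", {
  b <- random_bundle(seed = 11)
  b <- plant_gold_standard(b, n = 12, seed = 11)
  ev <- evaluate_against_gold(b$gold, b$bindings, b$model)
  all_row <- dplyr::filter(ev$summary, stratum == "ALL")
  expect_equal(all_row$n_evaluable, nrow(b$gold))
  expect_equal(all_row$n_related, all_row$n_evaluable)
  expect_equal(all_row$n_rebuilt, all_row$n_evaluable)
  expect_equal(all_row$n_nonunique, 0)

  # duplicate one planted code's classes under a decoy: exactly the combos
  # predicted by that code flip to non-unique
  victim <- b$gold$icd10[[1]]
  bindings2 <- add_decoy_code(b$bindings, victim)
  ev2 <- evaluate_against_gold(b$gold, bindings2, b$model)
  affected <- sum(b$gold$icd10 == victim)
  expect_equal(dplyr::filter(ev2$summary, stratum == "ALL")$n_nonunique, affected)
  expect_equal(dplyr::filter(ev2$summary, stratum == "ALL")$n_rebuilt,
               all_row$n_rebuilt)
})
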