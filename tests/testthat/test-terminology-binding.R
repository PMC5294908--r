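# Terminology ingestion, CUI crosswalks, and code instantiation.

test_that("terminology readers populate behavior per system", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.csv")
  writeLines(c("code,label", "8140/3,Adenocarcinoma NOS", "9120/0,Hemangioma NOS"), p)
  m <- read_terminology(p, "ICDO3_M")
  expect_equal(m$behavior[m$code == "8140/3"], "MALIGNANT_PRIMARY")
  expect_equal(m$behavior[m$code == "9120/0"], "BENIGN")

  p2 <- file.path(dir, "i.csv")
  writeLines(c("code,label", "C50.9,Breast unspecified", "D05,Carcinoma in situ of breast"), p2)
  i <- read_terminology(p2, "ICD10")
  expect_equal(i$behavior[i$code == "C50.9"], "MALIGNANT_PRIMARY")
  expect_equal(i$behavior[i$code == "D05"], "IN_SITU")

  p3 <- file.path(dir, "e.csv")
  writeLines("code,label", p3)
  expect_equal(nrow(read_terminology(p3, "ICDO3_T")), 0)

  p4 <- file.path(dir, "d.csv")
  writeLines(c("code,label", "C50.9,a", "C50.9,b"), p4)
  expect_warning(read_terminology(p4, "ICD10"), "duplicate")
})

test_that("ICD-10 behavior ranges follow the configured blocks", {
  beh <- derive_icd10_behavior(c("C50.9", "C76.8", "C77.0", "C80", "D05",
                                 "D10", "D36.9", "D40", "D48", "Z99", "bogus"))
  expect_equal(beh$behavior,
               c("MALIGNANT_PRIMARY", "MALIGNANT_PRIMARY", "EXCLUDED",
                 "EXCLUDED", "IN_SITU", "BENIGN", "BENIGN", "EXCLUDED",
                 "EXCLUDED", "EXCLUDED", "EXCLUDED"))
  expect_match(beh$reason[beh$code == "C77.0"], "secondary")
  expect_match(beh$reason[beh$code == "D40"], "uncertain")
  expect_match(beh$reason[beh$code == "bogus"], "not an ICD-10 code")
})

test_that("RRF and TSV crosswalk dialects read identically", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "map.tsv")
  writeLines(c("cui\tsab\tcode",
               "CUI0001\tICD10\tC50.9",
               "CUI0001\tNCI\tNCIT:C9335"), tsv)
  rrf <- file.path(dir, "map.rrf")
  row <- function(cui, sab, code) {
    f <- rep("", 18)
    f[1] <- cui; f[12] <- sab; f[14] <- code
    paste(f, collapse = "|")
  }
  writeLines(c(row("CUI0001", "ICD10", "C50.9"),
               row("CUI0001", "NCI", "NCIT:C9335")), rrf)
  expect_equal(read_cui_map(tsv, "TSV"), read_cui_map(rrf, "RRF_PIPE"))
  empty <- file.path(dir, "empty.rrf")
  writeLines(character(), empty)
  expect_equal(nrow(read_cui_map(empty, "RRF_PIPE")), 0)
  bad <- file.path(dir, "bad.rrf")
  writeLines("only|three|fields", bad)
  expect_error(read_cui_map(bad, "RRF_PIPE"), "malformed")
})

test_that("topography binding lands on the minimal reflexive parts", {
  demo <- get_demo()
  b <- binding_of(demo, "ICDO3_T", "C50.5")
  expect_equal(b$status, "BOUND")
  expect_equal(b$direct[[1]], "RP:NCIT:A_LOQ")
  # erroneous crosswalk: only a disease concept shares the CUI
  expect_equal(binding_of(demo, "ICDO3_T", "C05.1")$status, "NON_ANATOMY_ONLY")
  expect_equal(binding_of(demo, "ICDO3_T", "C76.0")$status, "UNMAPPED")
})

test_that("morphology binding is code-identity against the axis", {
  demo <- get_demo()
  expect_equal(binding_of(demo, "ICDO3_M", "8140/3")$direct[[1]], "8140/3")
  expect_equal(binding_of(demo, "ICDO3_M", "8720/3")$status, "UNMAPPED")
  bound <- dplyr::filter(demo$bindings, system == "ICDO3_M", status == "BOUND")
  expect_equal(nrow(bound), 5)
})

test_that("ICD-10 binding reproduces the worked examples", {
  demo <- get_demo()
  expect_equal(binding_of(demo, "ICD10", "C50.9")$direct[[1]],
               "DX:MALIGNANT_PRIMARY@NCIT:C12971")
  expect_equal(binding_of(demo, "ICD10", "C18.0")$direct[[1]],
               sort(c("DX:MALIGNANT_PRIMARY@NCIT:A_CEC",
                      "DX:MALIGNANT_PRIMARY@NCIT:A_COL",
                      "DX:MALIGNANT_PRIMARY@NCIT:A_CRR")))
  # in situ code keeps both conflicting inherited morphologies
  expect_equal(binding_of(demo, "ICD10", "D05")$direct[[1]],
               sort(c("DX:8010/2@NCIT:C12971", "DX:8011/3@NCIT:C12971")))
  expect_equal(binding_of(demo, "ICD10", "D40")$status, "EXCLUDED_SCOPE")
  expect_equal(binding_of(demo, "ICD10", "C00.1")$status, "UNMAPPED")
})

test_that("a mapped concept without sites yields NO_SITE", {
  concepts <- tibble::tibble(
    id = c("a1", "n1", "n2"), label = c("a1", "n1", "n2"),
    axis = c("ANATOMY", "NEOPLASM", "NEOPLASM")
  )
  onto <- ontology(concepts,
                   sites = tibble::tibble(concept = "n2", site = "a1"),
                   morphs = tibble::tibble(concept = "n2", code = "8000/3"))
  model <- build_derivative_model(onto)
  cuimap <- tibble::tibble(cui = c("X1", "X1"), sab = c("ICD10", "NCI"),
                           code = c("C10.1", "n1"))
  out <- bind_icd10("C10.1", "test", cuimap, model)
  expect_equal(out$status, "NO_SITE")
})

test_that("binding is total and statuses are conserved", {
  demo <- get_demo()
  b <- demo$bindings
  expect_equal(nrow(b), nrow(demo$terminologies))
  expect_true(all(table(b$status) >= 0))
  counts <- dplyr::count(b, .data$system, .data$status)
  for (sys in unique(b$system)) {
    expect_equal(sum(counts$n[counts$system == sys]),
                 sum(demo$terminologies$system == sys))
  }
  # every BOUND direct set is a nonempty antichain
  bound <- dplyr::filter(b, status == "BOUND")
  m <- demo$model
  for (i in seq_len(nrow(bound))) {
    d <- bound$direct[[i]]
    expect_gt(length(d), 0)
    if (bound$system[[i]] == "ICD10" && length(d) > 1) {
      for (x in d) for (y in setdiff(d, x)) {
        expect_false(dx_subsumes(m$axis, m$index, x, y))
      }
    }
  }
})

test_that("combination satisfaction is upward-closed and needs bound inputs", {
  demo <- get_demo()
  m <- demo$model
  topo <- binding_of(demo, "ICDO3_T", "C18.9")
  morph <- binding_of(demo, "ICDO3_M", "8140/3")
  sat <- satisfied_dx_of_combination(topo, morph, m)
  expect_true("DX:MALIGNANT_PRIMARY@NCIT:A_LI" %in% sat)
  # upward closure within the lattice
  ids <- m$lattice$classes$id
  for (x in sat) {
    above <- ids[dx_subsumes(m$axis, m$index, x, ids)]
    expect_true(all(above %in% sat), info = x)
  }
  unbound <- binding_of(demo, "ICDO3_T", "C76.0")
  expect_error(satisfied_dx_of_combination(unbound, morph, m),
               class = "oncolattice_unbound")
})
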