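# Deterministic demo fixture (NCIt-style fragments), randomized ontology
# generator, synthetic code bundles and planted gold standards.

demo_anatomy <- function() {
  tibble::tribble(
    ~id, ~label,
    "NCIT:C12971", "Breast",
    "NCIT:A_LOQ", "Lower Outer Quadrant of the Breast",
    "NCIT:A_GIS", "Gastrointestinal System",
    "NCIT:A_INT", "Intestine",
    "NCIT:A_LI", "Large Intestine",
    "NCIT:A_CEC", "Cecum",
    "NCIT:A_COL", "Colon",
    "NCIT:A_CRR", "Colorectal Region",
    "NCIT:A_RSJ", "Rectosigmoid Junction",
    "NCIT:A_SP", "Soft Palate",
    "NCIT:A_SKN", "Skin",
    "NCIT:A_EPI", "Epidermis",
    "NCIT:A_LC", "Langerhans Cell",
    "NCIT:A_BG", "Birbeck Granule"
  ) |> mutate(axis = "ANATOMY")
}

demo_neoplasms <- function() {
  tibble::tribble(
    ~id, ~label,
    "NCIT:C3262", "Neoplasm",
    "NCIT:C9305", "Malignant Neoplasm",
    "NCIT:D_BEN", "Benign Neoplasm",
    "NCIT:D_CA", "Carcinoma",
    "NCIT:D_CIS", "Carcinoma In Situ",
    "NCIT:C3641", "Stage 0 Breast Cancer",
    "NCIT:C9335", "Malignant Breast Neoplasm",
    "NCIT:D_MLOQ", "Malignant Neoplasm of Lower Outer Quadrant of Breast",
    "NCIT:C9329", "Malignant Cecum Neoplasm",
    "NCIT:D_MCOL", "Malignant Colon Neoplasm",
    "NCIT:D_MRSJ", "Malignant Rectosigmoid Neoplasm",
    "NCIT:D_ADC", "Adenocarcinoma",
    "NCIT:D_BADC", "Breast Adenocarcinoma",
    "NCIT:D_CADC", "Cecum Adenocarcinoma",
    "NCIT:D_COLADC", "Colon Adenocarcinoma",
    "NCIT:D_CRADC", "Colorectal Adenocarcinoma",
    "NCIT:D_HEM", "Hemangioma",
    "NCIT:D_CHEM", "Cavernous Hemangioma",
    "NCIT:D_CCHEM", "Colon Cavernous Hemangioma",
    "NCIT:D_MSPN", "Malignant Soft Palate Neoplasm"
  ) |> mutate(axis = "NEOPLASM")
}

#' Deterministic demo source ontology
#'
#' A small NCIt-style fragment assembled from well-known problem cases in
#' oncology terminology integration: the breast-quadrant partonomy, a
#' gastrointestinal partonomy in which Colon, Cecum and Colorectal Region are
#' mutually unrelated below Large Intestine, a malignant cecum neoplasm
#' asserting five primary sites, the carcinoma-in-situ / invasive-carcinoma
#' annotation clash, the cavernous/NOS hemangioma pair, a soft-palate code
#' crosswalked only to a non-anatomy concept, and the Birbeck Granule
#' cell-part chain below Skin.
#'
#' @return A validated `src_ontology`.
#' @export
demo_ontology <- function() {
  concepts <- bind_rows(demo_anatomy(), demo_neoplasms())
  parts <- tibble::tribble(
    ~child, ~parent, ~role,
    "NCIT:A_LOQ", "NCIT:C12971", "PART_PHYSICAL",
    "NCIT:A_INT", "NCIT:A_GIS", "PART_PHYSICAL",
    "NCIT:A_LI", "NCIT:A_INT", "PART_PHYSICAL",
    "NCIT:A_CEC", "NCIT:A_LI", "PART_PHYSICAL",
    "NCIT:A_COL", "NCIT:A_LI", "PART_PHYSICAL",
    "NCIT:A_CRR", "NCIT:A_LI", "PART_LOCATION",
    "NCIT:A_RSJ", "NCIT:A_CRR", "PART_PHYSICAL",
    "NCIT:A_BG", "NCIT:A_LC", "PART_PHYSICAL",
    "NCIT:A_LC", "NCIT:A_EPI", "PART_PHYSICAL",
    "NCIT:A_EPI", "NCIT:A_SKN", "PART_PHYSICAL"
  )
  is_a <- tibble::tribble(
    ~child, ~parent,
    "NCIT:C9305", "NCIT:C3262",
    "NCIT:D_BEN", "NCIT:C3262",
    "NCIT:D_CA", "NCIT:C9305",
    "NCIT:D_CIS", "NCIT:D_CA",
    "NCIT:C3641", "NCIT:D_CIS",
    "NCIT:C9335", "NCIT:C9305",
    "NCIT:D_MLOQ", "NCIT:C9335",
    "NCIT:C9329", "NCIT:C9305",
    "NCIT:D_MCOL", "NCIT:C9305",
    "NCIT:D_MRSJ", "NCIT:C9305",
    "NCIT:D_ADC", "NCIT:D_CA",
    "NCIT:D_BADC", "NCIT:D_ADC",
    "NCIT:D_CADC", "NCIT:D_ADC",
    "NCIT:D_COLADC", "NCIT:D_ADC",
    "NCIT:D_CRADC", "NCIT:D_ADC",
    "NCIT:D_HEM", "NCIT:D_BEN",
    "NCIT:D_CHEM", "NCIT:D_HEM",
    "NCIT:D_CCHEM", "NCIT:D_CHEM",
    "NCIT:D_MSPN", "NCIT:C9305"
  )
  sites <- tibble::tribble(
    ~concept, ~site,
    "NCIT:C3641", "NCIT:C12971",
    "NCIT:C9335", "NCIT:C12971",
    "NCIT:D_MLOQ", "NCIT:A_LOQ",
    "NCIT:C9329", "NCIT:A_GIS",
    "NCIT:C9329", "NCIT:A_CEC",
    "NCIT:C9329", "NCIT:A_COL",
    "NCIT:C9329", "NCIT:A_INT",
    "NCIT:C9329", "NCIT:A_CRR",
    "NCIT:D_MCOL", "NCIT:A_COL",
    "NCIT:D_MRSJ", "NCIT:A_RSJ",
    "NCIT:D_BADC", "NCIT:C12971",
    "NCIT:D_CADC", "NCIT:A_CEC",
    "NCIT:D_COLADC", "NCIT:A_COL",
    "NCIT:D_CRADC", "NCIT:A_CRR",
    "NCIT:D_CCHEM", "NCIT:A_COL",
    "NCIT:D_CCHEM", "NCIT:A_CRR",
    "NCIT:D_MSPN", "NCIT:A_SP"
  )
  morphs <- tibble::tribble(
    ~concept, ~code,
    "NCIT:D_CA", "8011/3",   # Epithelioma, NOS (invasive)
    "NCIT:D_CIS", "8010/2",  # Intraepithelial carcinoma, NOS (in situ)
    "NCIT:D_ADC", "8140/3",  # Adenocarcinoma, NOS
    "NCIT:D_HEM", "9120/0",  # Hemangioma, NOS
    "NCIT:D_CHEM", "9121/0"  # Cavernous hemangioma
  )
  ontology(concepts, is_a = is_a, parts = parts, sites = sites, morphs = morphs)
}

demo_terminologies <- function() {
  bind_rows(
    tibble(system = "ICD10", code = c("C18.0", "C18.9", "C19.9", "C50.9",
                                      "D05", "D40", "C77.0", "C00.1"),
           label = c("Malignant neoplasm: caecum",
                     "Malignant neoplasm: colon, unspecified",
                     "Malignant neoplasm of rectosigmoid junction",
                     "Malignant neoplasm of breast, unspecified",
                     "Carcinoma in situ of breast",
                     "Neoplasm of uncertain behaviour of male genital organs",
                     "Secondary malignant neoplasm of lymph nodes of head",
                     "Malignant neoplasm: external lower lip")),
    tibble(system = "ICDO3_T", code = c("C50.5", "C18.9", "C05.1", "C76.0"),
           label = c("Lower-outer quadrant of breast", "Colon, NOS",
                     "Soft palate, NOS", "Head, face or neck, NOS")),
    tibble(system = "ICDO3_M", code = c("8140/3", "8010/2", "8011/3",
                                        "9120/0", "9121/0", "8720/3", "8140/6"),
           label = c("Adenocarcinoma, NOS", "Intraepithelial carcinoma, NOS",
                     "Epithelioma, NOS", "Hemangioma, NOS",
                     "Cavernous hemangioma", "Malignant melanoma, NOS",
                     "Adenocarcinoma, metastatic, NOS"))
  )
}

demo_cuimap <- function() {
  tibble::tribble(
    ~cui, ~sab, ~code,
    "CUI0001", "ICD10", "C50.9",
    "CUI0001", "NCI", "NCIT:C9335",
    "CUI0002", "ICD10", "C18.0",
    "CUI0002", "NCI", "NCIT:C9329",
    "CUI0003", "ICD10", "D05",
    "CUI0003", "NCI", "NCIT:C3641",
    "CUI0004", "ICD10", "C19.9",
    "CUI0004", "NCI", "NCIT:D_MRSJ",
    "CUI0005", "ICD10", "C18.9",
    "CUI0005", "NCI", "NCIT:D_MCOL",
    "CUI0006", "ICDO3", "C50.5",
    "CUI0006", "NCI", "NCIT:A_LOQ",
    "CUI0007", "ICDO3", "C18.9",
    "CUI0007", "NCI", "NCIT:A_COL",
    "CUI0008", "ICDO3", "C05.1",
    "CUI0008", "NCI", "NCIT:D_MSPN"
  )
}

demo_gold <- function() {
  tibble::tribble(
    ~topography, ~morphology, ~icd10,
    "C18.9", "8140/3", "C18.9",
    "C50.5", "8140/3", "C50.9",
    "C18.9", "8140/6", "C18.9", # out of scope: metastatic behavior
    "C50.5", "9590/3", "C81.9"  # evaluable only if 9590/3 ever binds
  )
}

# Frozen expectations for the demo bundle, cross-checked against the
# saturation oracle at build time.
demo_truth <- function() {
  list(
    bindings = tibble::tribble(
      ~system, ~code, ~status, ~direct,
      "ICD10", "C18.0", "BOUND", list(c("DX:MALIGNANT_PRIMARY@NCIT:A_CEC",
                                        "DX:MALIGNANT_PRIMARY@NCIT:A_COL",
                                        "DX:MALIGNANT_PRIMARY@NCIT:A_CRR")),
      "ICD10", "C50.9", "BOUND", list("DX:MALIGNANT_PRIMARY@NCIT:C12971"),
      "ICD10", "D05", "BOUND", list(c("DX:8010/2@NCIT:C12971",
                                      "DX:8011/3@NCIT:C12971")),
      "ICD10", "C19.9", "BOUND", list("DX:MALIGNANT_PRIMARY@NCIT:A_CRR"),
      "ICD10", "C18.9", "BOUND", list("DX:MALIGNANT_PRIMARY@NCIT:A_COL"),
      "ICD10", "D40", "EXCLUDED_SCOPE", list(character()),
      "ICD10", "C77.0", "EXCLUDED_SCOPE", list(character()),
      "ICD10", "C00.1", "UNMAPPED", list(character()),
      "ICDO3_T", "C50.5", "BOUND", list("RP:NCIT:A_LOQ"),
      "ICDO3_T", "C18.9", "BOUND", list("RP:NCIT:A_COL"),
      "ICDO3_T", "C05.1", "NON_ANATOMY_ONLY", list(character()),
      "ICDO3_T", "C76.0", "UNMAPPED", list(character()),
      "ICDO3_M", "8140/3", "BOUND", list("8140/3"),
      "ICDO3_M", "8720/3", "UNMAPPED", list(character()),
      "ICDO3_M", "8140/6", "UNMAPPED", list(character())
    ) |> mutate(direct = map(.data$direct, 1L)),
    direct_types = list(
      "NCIT:D_CCHEM" = c("DX:9120/0@NCIT:A_COL", "DX:9120/0@NCIT:A_CRR",
                         "DX:9121/0@NCIT:A_COL", "DX:9121/0@NCIT:A_CRR")
    ),
    conflict_codes = "D05",
    c18_0_incomparable = c("NCIT:A_CEC", "NCIT:A_COL", "NCIT:A_CRR")
  )
}

#' Deterministic demo fixture bundle
#'
#' The demo ontology together with matching terminology lists, a CUI
#' crosswalk, a small SEER-style gold table, the built derivative model, the
#' code bindings, and frozen truth tables. With `verify = TRUE` (default) the
#' truth tables are replayed against the independent saturation oracle and
#' the build aborts on any disagreement.
#'
#' @param verify Cross-check truth tables against [brute_force_oracle()].
#' @return List of class `fixture_bundle`.
#' @export
demo_bundle <- function(verify = TRUE) {
  onto <- demo_ontology()
  model <- build_derivative_model(onto)
  terms <- demo_terminologies()
  terms$behavior <- NA_character_
  cuimap <- demo_cuimap()
  bindings <- bind_codes(terms, cuimap, model)
  truth <- demo_truth()
  bundle <- structure(
    list(
      ontology = onto, model = model, terminologies = terms,
      cuimap = cuimap, gold = demo_gold(), bindings = bindings, truth = truth
    ),
    class = "fixture_bundle"
  )
  if (verify) verify_bundle(bundle)
  bundle
}

# Oracle replay of the bundle truth tables (direct types + retained support),
# plus engine-vs-truth binding equality.
verify_bundle <- function(bundle) {
  oracle <- brute_force_oracle(bundle$ontology)
  for (concept in names(bundle$truth$direct_types)) {
    want <- sort(bundle$truth$direct_types[[concept]])
    got <- oracle$direct_types[[concept]]
    if (!identical(got, want)) {
      abort(sprintf("fixture truth mismatch (oracle direct types of %s):\n  want %s\n  got %s",
                    concept, paste(want, collapse = ", "),
                    paste(got, collapse = ", ")))
    }
  }
  eng <- bundle$model$retained |> mutate(id = dx_id(.data$morph, .data$base))
  orc <- oracle$retained |> mutate(id = dx_id(.data$morph, .data$base))
  if (!identical(sort(eng$id), sort(orc$id))) {
    abort("fixture truth mismatch: engine and oracle disagree on retained classes")
  }
  tr <- bundle$truth$bindings
  for (i in seq_len(nrow(tr))) {
    row <- filter(bundle$bindings, .data$system == tr$system[[i]],
                  .data$code == tr$code[[i]])
    if (nrow(row) != 1L || row$status[[1]] != tr$status[[i]] ||
        !identical(row$direct[[1]], sort_ids(tr$direct[[i]]))) {
      abort(sprintf("fixture truth mismatch for %s %s", tr$system[[i]], tr$code[[i]]))
    }
  }
  invisible(bundle)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d concepts, %d codes, %d gold rows\n",
              nrow(x$ontology$concepts), nrow(x$terminologies), nrow(x$gold)))
  invisible(x)
}

#' Write a fixture bundle's input files to disk
#'
#' Emits the NATIVE_TSV ontology, the three terminology CSVs, the crosswalk
#' TSV and the SEER-style gold TSV under `dir` — the exact formats the
#' ingestion functions read.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ontology_tsv(bundle$ontology, file.path(dir, "ontology"))
  for (sys in unique(bundle$terminologies$system)) {
    readr::write_csv(
      bundle$terminologies |> filter(.data$system == sys) |> select("code", "label"),
      file.path(dir, paste0(tolower(sys), ".csv")), progress = FALSE
    )
  }
  readr::write_tsv(bundle$cuimap, file.path(dir, "cuimap.tsv"), progress = FALSE)
  readr::write_tsv(bundle$gold, file.path(dir, "gold.tsv"), progress = FALSE)
  invisible(dir)
}

#' Generate a random source ontology
#'
#' Anatomy and neoplasm concepts are laid out on a topological ranking, so
#' is_a and part-whole edges (drawn independently with the given densities,
#' always pointing toward lower ranks) can never form cycles. Neoplasm
#' concepts receive random primary-site fillers and ICD-O-3 morphology
#' annotations. Identical parameters and seed reproduce the ontology exactly.
#'
#' @param n_anatomy,n_neoplasm,n_morph Component counts.
#' @param p_edge Probability of an edge to each eligible lower-ranked node.
#' @param p_site,p_morph Per-concept probability of carrying a site filler /
#'   morphology annotation (one or two are drawn when present).
#' @param seed Integer seed.
#' @return A validated `src_ontology`.
#' @export
random_ontology <- function(n_anatomy = 20, n_neoplasm = 15, n_morph = 8,
                            p_edge = 0.15, p_site = 0.8, p_morph = 0.6,
                            seed = 1L) {
  stopifnot(n_anatomy >= 0, n_neoplasm >= 0, n_morph >= 0)
  set.seed(seed)
  pad <- function(prefix, n) {
    if (n == 0) character() else sprintf("%s%03d", prefix, seq_len(n))
  }
  a_ids <- pad("A", n_anatomy)
  n_ids <- pad("N", n_neoplasm)
  concepts <- bind_rows(
    tibble(id = a_ids, label = paste("Anatomy", a_ids), axis = "ANATOMY"),
    tibble(id = n_ids, label = paste("Neoplasm", n_ids), axis = "NEOPLASM")
  )
  rank_edges <- function(ids, p) {
    out <- list()
    for (i in seq_along(ids)) {
      if (i == 1L) next
      to <- ids[seq_len(i - 1L)][runif(i - 1L) < p]
      if (length(to)) out[[length(out) + 1L]] <- tibble(child = ids[[i]], parent = to)
    }
    bind_rows(out)
  }
  a_isa <- rank_edges(a_ids, p_edge / 2)
  a_part <- rank_edges(a_ids, p_edge)
  if (nrow(a_part %||% tibble())) {
    a_part$role <- sample(c("PART_PHYSICAL", "PART_LOCATION"), nrow(a_part),
                          replace = TRUE)
  }
  n_isa <- rank_edges(n_ids, p_edge)
  codes <- character()
  if (n_morph > 0) {
    hist <- sample(8000:9989, n_morph)
    beh <- sample(c("0", "1", "2", "3", "6", "9"), n_morph, replace = TRUE)
    codes <- sprintf("%04d/%s", hist, beh)
  }
  sites <- list()
  morphs <- list()
  for (cid in n_ids) {
    if (length(a_ids) && runif(1) < p_site) {
      k <- sample(1:2, 1)
      sites[[length(sites) + 1L]] <-
        tibble(concept = cid, site = sample(a_ids, min(k, length(a_ids))))
    }
    if (length(codes) && runif(1) < p_morph) {
      k <- sample(1:2, 1)
      morphs[[length(morphs) + 1L]] <-
        tibble(concept = cid, code = sample(codes, min(k, length(codes))))
    }
  }
  ontology(
    concepts,
    is_a = bind_rows(a_isa, n_isa),
    parts = if (is.null(a_part) || nrow(a_part) == 0) NULL else a_part,
    sites = bind_rows(sites),
    morphs = bind_rows(morphs)
  )
}

#' Generate a large synthetic ontology for scale smoke runs
#'
#' A shallow anatomy forest of `n_topo` concepts (every one of which ends up
#' a topography), `n_morph` distinct annotated morphology codes, and
#' `n_concepts` neoplasm concepts carrying the annotations and site fillers.
#' No truth tables: this generator exists to exercise streaming candidate
#' generation and indexed retention at scale.
#'
#' @param n_topo Number of anatomy concepts.
#' @param n_morph Number of distinct specific morphology codes.
#' @param n_concepts Number of neoplasm concepts.
#' @param seed Integer seed.
#' @return A validated `src_ontology`.
#' @export
scale_ontology <- function(n_topo = 5000, n_morph = 994, n_concepts = 300,
                           seed = 1L) {
  set.seed(seed)
  a_ids <- sprintf("A%05d", seq_len(n_topo))
  n_ids <- sprintf("N%05d", seq_len(n_concepts))
  concepts <- bind_rows(
    tibble(id = a_ids, label = a_ids, axis = "ANATOMY"),
    tibble(id = n_ids, label = n_ids, axis = "NEOPLASM")
  )
  # shallow partonomy: parent drawn from the first tenth of earlier nodes
  parent_idx <- vapply(seq_len(n_topo), function(i) {
    if (i == 1L) NA_integer_ else sample.int(max(1L, i %/% 10L), 1L)
  }, integer(1))
  parts <- tibble(
    child = a_ids[!is.na(parent_idx)],
    parent = a_ids[parent_idx[!is.na(parent_idx)]],
    role = "PART_PHYSICAL"
  )
  hist4 <- sample(1000:9989, n_morph)
  codes <- sprintf("%04d/%s", hist4,
                   sample(c("0", "1", "2", "3", "6", "9"), n_morph, replace = TRUE))
  morphs <- tibble(
    concept = n_ids[(seq_len(n_morph) - 1L) %% n_concepts + 1L],
    code = codes
  )
  sites <- tibble(
    concept = n_ids[(seq_len(n_topo) - 1L) %% n_concepts + 1L],
    site = a_ids
  )
  ontology(concepts, parts = parts, sites = sites, morphs = morphs)
}

#' Generate a random fixture bundle with synthetic terminologies
#'
#' Builds a random ontology, derives a synthetic ICD-10 list (codes drawn in
#' the C00-C76 malignant-primary block, each crosswalked to one neoplasm
#' concept), a topography list (one code per sampled anatomy concept) and the
#' morphology list of all annotated codes, then binds everything.
#'
#' @param seed Integer seed.
#' @param ... Passed to [random_ontology()].
#' @return A `fixture_bundle` (without gold or truth tables; see
#'   [plant_gold_standard()]).
#' @export
random_bundle <- function(seed = 1L, ...) {
  onto <- random_ontology(seed = seed, ...)
  model <- build_derivative_model(onto)
  set.seed(seed + 1000L)
  neo <- onto$concepts$id[onto$concepts$axis == "NEOPLASM"]
  anat <- onto$concepts$id[onto$concepts$axis == "ANATOMY"]
  icd10_codes <- sprintf("C%02d.%d", sample(0:76, length(neo), replace = TRUE),
                         seq_along(neo) %% 10)
  icd10_codes <- make.unique(icd10_codes, sep = "")
  topo_codes <- sprintf("C%02d.%d", sample(0:76, length(anat), replace = TRUE),
                        seq_along(anat) %% 10)
  topo_codes <- paste0("T", make.unique(topo_codes, sep = ""))
  morph_codes <- sort_ids(onto$morphs$code)
  terms <- bind_rows(
    tibble(system = "ICD10", code = sort(icd10_codes), label = neo),
    tibble(system = "ICDO3_T", code = sort(topo_codes), label = anat),
    tibble(system = "ICDO3_M", code = morph_codes, label = morph_codes)
  )
  cuimap <- bind_rows(
    tibble(cui = sprintf("CUI1%04d", seq_along(neo)), sab = "ICD10",
           code = sort(icd10_codes)),
    tibble(cui = sprintf("CUI1%04d", seq_along(neo)), sab = "NCI", code = neo),
    tibble(cui = sprintf("CUI2%04d", seq_along(anat)), sab = "ICDO3",
           code = sort(topo_codes)),
    tibble(cui = sprintf("CUI2%04d", seq_along(anat)), sab = "NCI", code = anat)
  )
  config <- default_binding_config()
  bindings <- bind_codes(terms, cuimap, model, config)
  structure(
    list(ontology = onto, model = model, terminologies = terms,
         cuimap = cuimap, bindings = bindings, gold = NULL, truth = NULL),
    class = "fixture_bundle"
  )
}

#' Plant a recoverable gold standard in a bundle
#'
#' For each bound topography-morphology combination, computes the edge
#' distance to every bound ICD-10 code and keeps combinations with a strict
#' unique argmin; the gold mapping is that nearest code, so
#' [evaluate_against_gold()] must rebuild 100% of the planted rows with zero
#' non-unique mappings. Combinations without a unique nearest code are
#' skipped.
#'
#' @param bundle A `fixture_bundle` with bindings.
#' @param n Maximum number of gold rows to plant.
#' @param seed Sampling seed.
#' @return The bundle with `gold` (tibble `topography`, `morphology`,
#'   `icd10`) and `truth$planted` filled in.
#' @export
plant_gold_standard <- function(bundle, n = 20L, seed = 1L) {
  model <- bundle$model
  b <- bundle$bindings
  topo <- filter(b, .data$system == "ICDO3_T", .data$status == "BOUND")
  morph <- filter(b, .data$system == "ICDO3_M", .data$status == "BOUND")
  if (nrow(topo) == 0 || nrow(morph) == 0) {
    abort("bundle has no bound topography/morphology codes to combine")
  }
  combos <- tidyr::expand_grid(topography = topo$code, morphology = morph$code)
  combos$combo_minimal <- map(seq_len(nrow(combos)), function(i) {
    sat <- satisfied_dx_of_combination(
      filter(topo, .data$code == combos$topography[[i]]),
      filter(morph, .data$code == combos$morphology[[i]]),
      model
    )
    minimal_dx(sat, model$axis, model$index)
  })
  combos <- filter(combos, lengths(.data$combo_minimal) > 0)
  if (nrow(combos) == 0) abort("no satisfiable combinations; cannot plant gold")
  pred <- rebuild_mappings(b, combos, model)
  unique_hit <- filter(pred, .data$n_predicted == 1L)
  if (nrow(unique_hit) == 0) {
    abort("no combination has a unique nearest ICD-10 code; cannot plant gold")
  }
  set.seed(seed)
  take <- unique_hit[sample(nrow(unique_hit), min(n, nrow(unique_hit))), ]
  gold <- tibble(
    topography = take$topography,
    morphology = take$morphology,
    icd10 = map_chr(take$predicted, 1L)
  ) |>
    mutate(stratum = stratum_of(.data$icd10, .data$morphology)) |>
    arrange(.data$topography, .data$morphology)
  bundle$gold <- gold
  bundle$truth <- c(bundle$truth, list(planted = take))
  bundle
}

#' Add an equidistant decoy ICD-10 code to a bundle's bindings
#'
#' Duplicates the direct and satisfied classes of an existing bound ICD-10
#' code under a fresh code, making every combination whose unique nearest
#' code was the original now tie with the decoy (non-unique).
#'
#' @param bindings Bindings tibble.
#' @param copy_of Code whose classes the decoy copies.
#' @param decoy_code New code name (defaults to `<copy_of>X`).
#' @return Bindings tibble with the decoy row appended.
#' @export
add_decoy_code <- function(bindings, copy_of, decoy_code = paste0(copy_of, "X")) {
  src <- filter(bindings, .data$system == "ICD10", .data$code == copy_of)
  if (nrow(src) != 1L || src$status[[1]] != "BOUND") {
    abort(paste0("no bound ICD-10 code ", copy_of, " to copy"))
  }
  decoy <- mutate(src, code = decoy_code)
  bind_rows(bindings, decoy) |> arrange(.data$system, .data$code)
}
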