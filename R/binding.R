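# Terminology ingestion (ICD-10, ICD-O-3), CUI crosswalks, and instantiation
# of the derivative model's classes with codes.

#' Default binding configuration
#'
#' ICD-10 block-to-behavior ranges (C00-C76 malignant primary; C77-C79
#' excluded as secondary malignancies; D00-D09 in situ; D10-D36 benign;
#' D37-D48 excluded as uncertain behavior; anything else excluded as
#' unclassifiable), source-vocabulary tags used in the CUI crosswalk, the
#' positional columns of MRCONSO-style RRF files, and the hematopoietic
#' stratum ranges used in evaluation.
#'
#' @return A named list; override elements and pass to the binding functions.
#' @export
default_binding_config <- function() {
  list(
    icd10_ranges = tibble(
      letter = c("C", "C", "D", "D", "D"),
      lo = c(0L, 77L, 0L, 10L, 37L),
      hi = c(76L, 79L, 9L, 36L, 48L),
      behavior = c("MALIGNANT_PRIMARY", "EXCLUDED", "IN_SITU", "BENIGN", "EXCLUDED"),
      reason = c(NA, "secondary malignancy (C77-C79)", NA, NA,
                 "uncertain or unknown behavior (D37-D48)")
    ),
    sab = c(ICD10 = "ICD10", ICDO3_T = "ICDO3", NCIT = "NCI"),
    rrf_cols = c(cui = 1L, sab = 12L, code = 14L),
    hematopoietic_icd10 = c(81L, 96L),
    hematopoietic_morph = c(9590L, 9993L)
  )
}

#' Read a terminology code list
#'
#' CSV or TSV with a `code,label` header (delimiter sniffed from the header
#' line). Codes are deduplicated; behavior is populated from the fifth digit
#' for ICD-O-3 morphologies and from the configured block ranges for ICD-10
#' (topographies carry none).
#'
#' @param path File path.
#' @param system One of `"ICD10"`, `"ICDO3_T"`, `"ICDO3_M"`.
#' @param config See [default_binding_config()].
#' @return Tibble with columns `code`, `system`, `label`, `behavior`,
#'   `behavior_reason`.
#' @export
read_terminology <- function(path, system = c("ICD10", "ICDO3_T", "ICDO3_M"),
                             config = default_binding_config()) {
  system <- match.arg(system)
  if (!file.exists(path)) abort(paste0("missing terminology file: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) df <- tibble(code = character(), label = character())
  missing <- setdiff(c("code", "label"), names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$code)) {
    warn(sprintf("%s: %d duplicate code(s) dropped", path,
                 sum(duplicated(df$code))))
    df <- df[!duplicated(df$code), , drop = FALSE]
  }
  out <- tibble(code = df$code, system = system, label = df$label)
  if (system == "ICDO3_M") {
    parsed <- if (nrow(out)) parse_morphology_code(out$code) else NULL
    out$behavior <- if (is.null(parsed)) character() else behavior_class_of(parsed$behavior_digit)
    out$behavior_reason <- NA_character_
  } else if (system == "ICD10") {
    beh <- derive_icd10_behavior(out$code, config)
    out$behavior <- beh$behavior
    out$behavior_reason <- beh$reason
  } else {
    out$behavior <- NA_character_
    out$behavior_reason <- NA_character_
  }
  arrange(out, .data$code)
}

#' Derive the behavior class of ICD-10 neoplasm codes
#'
#' Block-range lookup on the category part of the code (letter plus two
#' digits; any subcategory suffix is ignored). Codes in the secondary-
#' malignancy or uncertain-behavior ranges, and codes outside every
#' configured range, come back `EXCLUDED` with a reason.
#'
#' @param code Character vector of ICD-10 codes.
#' @param config See [default_binding_config()].
#' @return Tibble with columns `code`, `behavior`, `reason`.
#' @export
derive_icd10_behavior <- function(code, config = default_binding_config()) {
  ranges <- config$icd10_ranges
  ok <- stringr::str_detect(code, "^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,2})?$")
  letter <- substr(code, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(code, 2L, 3L)))
  behavior <- rep("EXCLUDED", length(code))
  reason <- rep("outside configured neoplasm ranges", length(code))
  reason[!ok] <- "not an ICD-10 code"
  for (i in seq_len(nrow(ranges))) {
    hit <- ok & letter == ranges$letter[[i]] & !is.na(num) &
      num >= ranges$lo[[i]] & num <= ranges$hi[[i]]
    behavior[hit] <- ranges$behavior[[i]]
    reason[hit] <- ranges$reason[[i]]
  }
  tibble(code = code, behavior = behavior, reason = reason)
}

#' Read a CUI crosswalk
#'
#' Either an MRCONSO-style pipe-delimited file (no header; CUI, source
#' vocabulary and code taken from the configured positional columns) or a
#' three-column TSV with header `cui`, `sab`, `code`. Other columns are
#' ignored; `(cui, sab, code)` triples are deduplicated.
#'
#' @param path File path.
#' @param dialect `"RRF_PIPE"` or `"TSV"`.
#' @param config See [default_binding_config()].
#' @return Tibble with columns `cui`, `sab`, `code`.
#' @export
read_cui_map <- function(path, dialect = c("RRF_PIPE", "TSV"),
                         config = default_binding_config()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("missing crosswalk file: ", path))
  if (dialect == "TSV") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
    if (nrow(df) == 0 && ncol(df) == 0) {
      df <- tibble(cui = character(), sab = character(), code = character())
    }
    missing <- setdiff(c("cui", "sab", "code"), names(df))
    if (length(missing)) {
      abort(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
    }
    out <- select(df, "cui", "sab", "code")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    cols <- config$rrf_cols
    if (length(lines) == 0) {
      out <- tibble(cui = character(), sab = character(), code = character())
    } else {
      fields <- strsplit(lines, "|", fixed = TRUE)
      need <- max(cols)
      bad <- lengths(fields) < need
      if (any(bad)) {
        abort(sprintf("%s: %d malformed row(s) with fewer than %d fields (first at line %d)",
                      path, sum(bad), need, which(bad)[[1]]))
      }
      out <- tibble(
        cui = map_chr(fields, cols[["cui"]]),
        sab = map_chr(fields, cols[["sab"]]),
        code = map_chr(fields, cols[["code"]])
      )
    }
  }
  out |> distinct() |> arrange(.data$cui, .data$sab, .data$code)
}

# NCIt concept ids sharing a CUI with `code` under source vocabulary `sab_in`.
cui_targets <- function(code, sab_in, cuimap, config) {
  cuis <- cuimap$cui[cuimap$sab == sab_in & cuimap$code == code]
  if (length(cuis) == 0) return(character())
  sort_ids(cuimap$code[cuimap$sab == config$sab[["NCIT"]] & cuimap$cui %in% cuis])
}

binding_row <- function(code, system, label, behavior, status,
                        direct = character(), satisfied = character(),
                        bound_anatomy = character(), mapped = character(),
                        reason = NA_character_) {
  tibble(
    code = code, system = system, label = label,
    behavior = behavior %||% NA_character_,
    status = status,
    direct = list(sort_ids(direct)),
    satisfied = list(sort_ids(satisfied)),
    bound_anatomy = list(sort_ids(bound_anatomy)),
    mapped_concepts = list(sort_ids(mapped)),
    reason = reason
  )
}

#' Bind an ICD-O-3 topography code to reflexive-part classes
#'
#' Looks up the NCIt concepts sharing a CUI with the code, keeps anatomy-axis
#' targets, and instantiates the minimal reflexive-part classes reachable
#' above each target. Codes whose targets are all outside the anatomy axis
#' are excluded as `NON_ANATOMY_ONLY` (erroneous crosswalk rows).
#'
#' @param code Topography code (e.g. `"C50.5"`).
#' @param label Code label (carried through).
#' @param cuimap Crosswalk tibble from [read_cui_map()].
#' @param model A `derivative_model`.
#' @param config See [default_binding_config()].
#' @return One-row bindings tibble.
#' @export
bind_topography <- function(code, label = NA_character_, cuimap, model,
                            config = default_binding_config()) {
  targets <- cui_targets(code, config$sab[["ICDO3_T"]], cuimap, config)
  targets <- intersect(targets, model$ontology$concepts$id)
  if (length(targets) == 0) {
    return(binding_row(code, "ICDO3_T", label, NA, "UNMAPPED",
                       reason = "no NCIt concept shares a CUI with this code"))
  }
  ax <- axis_of(model$ontology)
  anat <- targets[ax[targets] == "ANATOMY"]
  if (length(anat) == 0) {
    return(binding_row(code, "ICDO3_T", label, NA, "NON_ANATOMY_ONLY",
                       mapped = targets,
                       reason = "all CUI targets lie outside the anatomy axis"))
  }
  topos <- rp_bases(model$rp)
  per_target <- lapply(anat, function(a) {
    reach <- intersect(model$index$anc[[a]], topos)
    minimal_elements(reach, function(x, y) anat_reachable(model$index, x, y))
  })
  bases <- sort_ids(unlist(per_target, use.names = FALSE))
  bases <- minimal_elements(bases, function(x, y) anat_reachable(model$index, x, y))
  if (length(bases) == 0) {
    return(binding_row(code, "ICDO3_T", label, NA, "NO_SITE",
                       mapped = targets, bound_anatomy = anat,
                       reason = "no reflexive-part class reachable from the mapped anatomy"))
  }
  binding_row(code, "ICDO3_T", label, NA, "BOUND",
              direct = rp_id(bases), bound_anatomy = anat, mapped = targets)
}

#' Bind an ICD-O-3 morphology code to its morphology class
#'
#' @param code Morphology code `"HHHH/B"`.
#' @param label Code label.
#' @param model A `derivative_model`.
#' @return One-row bindings tibble (`BOUND` to the class with the same code,
#'   else `UNMAPPED`).
#' @export
bind_morphology <- function(code, label = NA_character_, model) {
  parsed <- parse_morphology_code(code)
  behavior <- behavior_class_of(parsed$behavior_digit)
  if (code %in% morphology_ids(model$axis)) {
    binding_row(code, "ICDO3_M", label, behavior, "BOUND", direct = code)
  } else {
    binding_row(code, "ICDO3_M", label, behavior, "UNMAPPED",
                reason = "no morphology class carries this code")
  }
}

#' Bind an ICD-10 code to diagnosis classes
#'
#' Builds, for every NCIt concept sharing a CUI with the code, the set of
#' retained diagnoses satisfied by the concept's inherited morphologies
#' *plus* the behavior class derived from the ICD-10 block (inherited
#' morphologies are never filtered by that behavior: conflicts survive to the
#' audit stage). Direct classes are the minimal elements of the union.
#'
#' @param code ICD-10 code.
#' @param label Code label.
#' @param cuimap Crosswalk tibble.
#' @param model A `derivative_model`.
#' @param config See [default_binding_config()].
#' @return One-row bindings tibble.
#' @export
bind_icd10 <- function(code, label = NA_character_, cuimap, model,
                       config = default_binding_config()) {
  beh <- derive_icd10_behavior(code, config)
  if (beh$behavior[[1]] == "EXCLUDED") {
    return(binding_row(code, "ICD10", label, "EXCLUDED", "EXCLUDED_SCOPE",
                       reason = beh$reason[[1]]))
  }
  behavior <- beh$behavior[[1]]
  targets <- cui_targets(code, config$sab[["ICD10"]], cuimap, config)
  mapped <- intersect(targets, model$refined$concepts)
  if (length(mapped) == 0) {
    return(binding_row(code, "ICD10", label, behavior, "UNMAPPED",
                       mapped = targets,
                       reason = "no neoplasm concept shares a CUI with this code"))
  }
  sat <- character()
  any_site <- FALSE
  for (C in mapped) {
    sites <- refined_sites_of(model$refined, C)
    if (length(sites) == 0) next
    any_site <- TRUE
    morphs <- c(refined_morphs_of(model$refined, C), behavior)
    sat <- c(sat, satisfied_classes(model$lattice, morphs, sites,
                                    model$axis, model$index))
  }
  sat <- sort_ids(sat)
  if (!any_site) {
    return(binding_row(code, "ICD10", label, behavior, "NO_SITE", mapped = mapped,
                       reason = "every mapped concept lacks a primary-site assertion"))
  }
  if (length(sat) == 0) {
    return(binding_row(code, "ICD10", label, behavior, "NO_SITE", mapped = mapped,
                       reason = "no retained diagnosis matches the mapped concepts"))
  }
  binding_row(code, "ICD10", label, behavior, "BOUND",
              direct = minimal_dx(sat, model$axis, model$index),
              satisfied = sat, mapped = mapped)
}

#' Bind a table of terminology codes to the model
#'
#' Dispatches each row of a terminology tibble (see [read_terminology()]) to
#' the system-specific binder. Binding is total: every code receives exactly
#' one status.
#'
#' @param codes Tibble with columns `code`, `system`, `label` (ICD-10 rows may
#'   carry `behavior`, recomputed anyway).
#' @param cuimap Crosswalk tibble.
#' @param model A `derivative_model`.
#' @param config See [default_binding_config()].
#' @return Bindings tibble, one row per input code.
#' @export
bind_codes <- function(codes, cuimap, model, config = default_binding_config()) {
  rows <- map(seq_len(nrow(codes)), function(i) {
    code <- codes$code[[i]]
    label <- codes$label[[i]] %||% NA_character_
    switch(codes$system[[i]],
      ICD10 = bind_icd10(code, label, cuimap, model, config),
      ICDO3_T = bind_topography(code, label, cuimap, model, config),
      ICDO3_M = bind_morphology(code, label, model),
      abort(paste0("unknown terminology system: ", codes$system[[i]]))
    )
  })
  bind_rows(rows) |> arrange(.data$system, .data$code)
}

#' Diagnoses satisfied by an ICD-O-3 topography-morphology combination
#'
#' All retained diagnosis classes (not just direct ones) satisfied by the
#' combination: the morphology class must be subsumed by the candidate
#' morphology and some anatomy concept the topography is bound to must reach
#' the candidate base. The bound anatomy concepts (not their reflexive
#' parts) enter the satisfaction check, mirroring instantiation of the
#' corresponding source concepts.
#'
#' @param topo_binding One-row bindings tibble of a `BOUND` topography.
#' @param morph_binding One-row bindings tibble of a `BOUND` morphology.
#' @param model A `derivative_model`.
#' @return Character vector of diagnosis class ids (upward-closed within the
#'   lattice).
#' @export
satisfied_dx_of_combination <- function(topo_binding, morph_binding, model) {
  if (topo_binding$status[[1]] != "BOUND" || morph_binding$status[[1]] != "BOUND") {
    abort("both the topography and the morphology must be BOUND",
          class = "oncolattice_unbound")
  }
  satisfied_classes(
    model$lattice,
    morph_binding$code[[1]],
    topo_binding$bound_anatomy[[1]],
    model$axis, model$index
  )
}
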