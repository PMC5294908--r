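# Shared vocabulary: role kinds, behavior classes, axis tags, id helpers.

#' Role kinds recognised in the source ontology
#'
#' `PART_PHYSICAL` and `PART_LOCATION` are the two part-whole roles used to
#' build reflexive-part topography classes; `PRIMARY_SITE` links a neoplasm
#' concept to its primary anatomic site; `HAS_FINDING` carries the morphology
#' restriction in diagnosis definitions. `IS_A` is ordinary subsumption.
#'
#' @format Character vector of length 5.
#' @export
ROLE_KINDS <- c("IS_A", "PART_PHYSICAL", "PART_LOCATION", "PRIMARY_SITE", "HAS_FINDING")

#' The six tumour behavior classes
#'
#' Matches the ICD-O-3 behavior axis: benign; uncertain whether benign or
#' malignant; in situ; malignant, primary site; malignant, metastatic;
#' uncertain whether primary or metastatic.
#'
#' @format Character vector of length 6.
#' @export
BEHAVIOR_CLASSES <- c(
  "BENIGN",
  "UNKNOWN_BENIGN_MALIGNANT",
  "IN_SITU",
  "MALIGNANT_PRIMARY",
  "MALIGNANT_METASTATIC",
  "UNKNOWN_PRIMARY_METASTATIC"
)

# ICD-O-3 fifth-digit -> behavior class. /4 and /5 are not assigned in ICD-O-3.
BEHAVIOR_DIGIT_TABLE <- c(
  "0" = "BENIGN",
  "1" = "UNKNOWN_BENIGN_MALIGNANT",
  "2" = "IN_SITU",
  "3" = "MALIGNANT_PRIMARY",
  "6" = "MALIGNANT_METASTATIC",
  "9" = "UNKNOWN_PRIMARY_METASTATIC"
)

AXIS_TAGS <- c("ANATOMY", "NEOPLASM", "OTHER")

MORPH_ROOT_ID <- "MORPHOLOGY"

DEFAULT_NS <- "http://purl.example.org/oncolattice#"

# Identifier scheme for generated classes. Anatomy/morphology components keep
# their source ids; '/' in ICD-O-3 codes is preserved internally and mangled
# only in IRIs.
rp_id <- function(base) {
  if (length(base) == 0) return(character())
  paste0("RP:", base)
}

dx_id <- function(morph, base) {
  if (length(morph) == 0 && length(base) == 0) return(character())
  paste0("DX:", morph, "@", base)
}

rp_base <- function(id) sub("^RP:", "", id)

dx_parts <- function(id) {
  body <- sub("^DX:", "", id)
  at <- regexpr("@", body, fixed = TRUE)
  list(
    morph = substr(body, 1L, at - 1L),
    base = substr(body, at + 1L, nchar(body))
  )
}

iri_safe <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

rp_iri <- function(base, ns = DEFAULT_NS) paste0(ns, "RP_", iri_safe(base))

dx_iri <- function(morph, base, ns = DEFAULT_NS) {
  paste0(ns, "DX_", iri_safe(morph), "_", iri_safe(base))
}

morph_iri <- function(id, ns = DEFAULT_NS) paste0(ns, "M_", iri_safe(id))

is_behavior <- function(x) x %in% BEHAVIOR_CLASSES

stop_unknown_id <- function(ids, where) {
  abort(
    sprintf("unknown id%s in %s: %s", if (length(ids) > 1L) "s" else "", where,
            paste(sort(unique(ids)), collapse = ", ")),
    class = "oncolattice_unknown_id"
  )
}

# Deterministic ordering used for every set-valued result.
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")
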