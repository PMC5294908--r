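# Behavior-stratified morphology axis and "refined" concept index.
#
# Specific morphologies sit flat under six behavior roots (no histology
# hierarchy): the source ontology's own diagnosis lattice is what carries
# histological specialization, and it is consumed through the refined index.

#' Parse an ICD-O-3 morphology code
#'
#' Splits `"HHHH/B"` into a four-digit histology and one-digit behavior,
#' preserving leading zeros.
#'
#' @param text Character vector of codes.
#' @return Tibble with columns `code`, `histology`, `behavior_digit`.
#' @export
parse_morphology_code <- function(text) {
  text <- stringr::str_trim(text)
  ok <- stringr::str_detect(text, "^[0-9]{4}/[0-9]$")
  if (any(!ok)) {
    abort(paste0("malformed ICD-O-3 morphology code(s): ",
                 paste(unique(text[!ok]), collapse = ", ")),
          class = "oncolattice_format")
  }
  tibble(
    code = text,
    histology = substr(text, 1L, 4L),
    behavior_digit = substr(text, 6L, 6L)
  )
}

#' Behavior class of an ICD-O-3 behavior digit
#'
#' `/0` benign, `/1` unknown whether benign or malignant, `/2` in situ,
#' `/3` malignant primary, `/6` malignant metastatic, `/9` unknown whether
#' primary or metastatic.
#'
#' @param digit Character or integer vector of fifth digits.
#' @return Character vector of behavior class names.
#' @export
behavior_class_of <- function(digit) {
  digit <- as.character(digit)
  bad <- setdiff(unique(digit), names(BEHAVIOR_DIGIT_TABLE))
  if (length(bad)) {
    abort(paste0("invalid ICD-O-3 behavior digit(s): ", paste(bad, collapse = ", "),
                 " (valid: ", paste(names(BEHAVIOR_DIGIT_TABLE), collapse = ", "), ")"),
          class = "oncolattice_format")
  }
  unname(BEHAVIOR_DIGIT_TABLE[digit])
}

#' Build the morphology axis from a neoplasm graph
#'
#' One specific morphology class per distinct annotated ICD-O-3 code, each
#' with exactly one parent: its behavior root. The root and the six behavior
#' roots are always present, even when no code falls under them.
#'
#' @param neo A `neoplasm_graph` (see [extract_neoplasm_graph()]).
#' @param ns IRI namespace for generated classes.
#' @return Object of class `morphology_axis` with a `nodes` tibble
#'   (`id`, `kind`, `behavior`, `parent`, `iri`).
#' @export
build_morphology_axis <- function(neo, ns = DEFAULT_NS) {
  codes <- sort_ids(neo$morphs$code)
  parsed <- if (length(codes)) parse_morphology_code(codes) else NULL
  roots <- tibble(
    id = c(MORPH_ROOT_ID, BEHAVIOR_CLASSES),
    kind = c("root", rep("behavior", 6L)),
    behavior = c(NA_character_, BEHAVIOR_CLASSES),
    parent = c(NA_character_, rep(MORPH_ROOT_ID, 6L))
  )
  specific <- if (is.null(parsed)) {
    tibble(id = character(), kind = character(), behavior = character(),
           parent = character())
  } else {
    tibble(
      id = parsed$code,
      kind = "specific",
      behavior = behavior_class_of(parsed$behavior_digit),
      parent = behavior_class_of(parsed$behavior_digit)
    )
  }
  nodes <- bind_rows(roots, specific) |>
    mutate(iri = morph_iri(.data$id, ns))
  structure(list(nodes = nodes, ns = ns), class = "morphology_axis")
}

#' @export
print.morphology_axis <- function(x, ...) {
  cat(sprintf("<morphology_axis> %d specific morphologies under %d behavior roots\n",
              sum(x$nodes$kind == "specific"), sum(x$nodes$kind == "behavior")))
  invisible(x)
}

#' Specific morphology ids of an axis
#' @param axis A `morphology_axis`.
#' @param include_behaviors Also include the six behavior roots (the candidate
#'   morphology set of the diagnosis lattice).
#' @return Character vector of class ids.
#' @export
morphology_ids <- function(axis, include_behaviors = FALSE) {
  keep <- axis$nodes$kind == "specific" |
    (include_behaviors & axis$nodes$kind == "behavior")
  sort_ids(axis$nodes$id[keep])
}

#' Compute the refined-concept index
#'
#' For every neoplasm concept, the inherited morphology codes and inherited
#' primary-site fillers: the union of its own annotations and those of all its
#' is_a ancestors (inclusive). These are the "refined" concept definitions
#' through which satisfaction of diagnosis classes is decided.
#'
#' @param neo A `neoplasm_graph`.
#' @param axis A `morphology_axis` (codes are checked against it).
#' @return Object of class `refined_index` with long tibbles `morphs`
#'   (`concept`, `code`) and `sites` (`concept`, `site`), ancestor-closed.
#' @export
compute_refined_index <- function(neo, axis) {
  anc <- ancestor_sets(sort_ids(neo$concepts$id),
                       select(neo$is_a, "child", "parent"))
  anc_tbl <- tibble(
    concept = as.character(rep(names(anc), lengths(anc))),
    ancestor = as.character(unlist(anc, use.names = FALSE))
  )
  unknown <- setdiff(unique(neo$morphs$code), axis$nodes$id)
  if (length(unknown)) stop_unknown_id(unknown, "morphology axis")
  morphs <- anc_tbl |>
    inner_join(neo$morphs, by = c(ancestor = "concept"),
               relationship = "many-to-many") |>
    distinct(.data$concept, .data$code) |>
    arrange(.data$concept, .data$code)
  sites <- anc_tbl |>
    inner_join(neo$sites, by = c(ancestor = "concept"),
               relationship = "many-to-many") |>
    distinct(.data$concept, .data$site) |>
    arrange(.data$concept, .data$site)
  structure(
    list(concepts = sort_ids(neo$concepts$id), morphs = morphs, sites = sites),
    class = "refined_index"
  )
}

#' @export
print.refined_index <- function(x, ...) {
  cat(sprintf("<refined_index> %d concepts; %d inherited morphology rows, %d inherited site rows\n",
              length(x$concepts), nrow(x$morphs), nrow(x$sites)))
  invisible(x)
}

refined_morphs_of <- function(refined, concept) {
  refined$morphs$code[refined$morphs$concept == concept]
}

refined_sites_of <- function(refined, concept) {
  refined$sites$site[refined$sites$concept == concept]
}
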