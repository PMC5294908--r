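# Evaluation against SEER-style conversion gold standards: branch sharing,
# minimum hierarchical edge distance, and mapping reconstruction.

#' Read a SEER-style conversion table
#'
#' TSV with header columns `topography`, `morphology`, `icd10`. Rows whose
#' morphology behavior falls outside scope (metastatic `/6`, uncertain `/1`
#' and `/9` by default) are dropped with counts; each kept row is assigned a
#' stratum (`HEMATOPOIETIC` when the ICD-10 category or the morphology
#' histology falls in the configured ranges, else `SOLID`).
#'
#' @param path File path.
#' @param config See [default_binding_config()].
#' @param excluded_behaviors Behavior digits dropped from scope.
#' @return Tibble with columns `topography`, `morphology`, `icd10`, `stratum`;
#'   attribute `"n_dropped"` counts out-of-scope rows.
#' @export
read_seer_conversion <- function(path, config = default_binding_config(),
                                 excluded_behaviors = c("1", "6", "9")) {
  if (!file.exists(path)) abort(paste0("missing conversion file: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- tibble(topography = character(), morphology = character(), icd10 = character())
  }
  missing <- setdiff(c("topography", "morphology", "icd10"), names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    out <- tibble(topography = character(), morphology = character(),
                  icd10 = character(), stratum = character())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  parsed <- parse_morphology_code(df$morphology)
  in_scope <- !(parsed$behavior_digit %in% excluded_behaviors)
  out <- tibble(
    topography = df$topography[in_scope],
    morphology = df$morphology[in_scope],
    icd10 = df$icd10[in_scope],
    stratum = stratum_of(df$icd10[in_scope], df$morphology[in_scope], config)
  ) |> distinct()
  attr(out, "n_dropped") <- sum(!in_scope)
  out
}

#' Tumor-type stratum of gold mappings
#'
#' `HEMATOPOIETIC` when the ICD-10 category or the morphology histology falls
#' in the configured ranges, else `SOLID`. Vectorized.
#'
#' @param icd10,morphology Code vectors.
#' @param config See [default_binding_config()].
#' @return Character vector.
#' @export
stratum_of <- function(icd10, morphology, config = default_binding_config()) {
  parsed <- parse_morphology_code(morphology)
  icd10_num <- suppressWarnings(as.integer(substr(icd10, 2L, 3L)))
  hema <- (substr(icd10, 1L, 1L) == "C" & !is.na(icd10_num) &
             icd10_num >= config$hematopoietic_icd10[[1]] &
             icd10_num <= config$hematopoietic_icd10[[2]]) |
    (as.integer(parsed$histology) >= config$hematopoietic_morph[[1]] &
       as.integer(parsed$histology) <= config$hematopoietic_morph[[2]])
  ifelse(hema, "HEMATOPOIETIC", "SOLID")
}

#' Shared branches between an ICD-10 code and a combination
#'
#' The minimal elements of the intersection of the diagnosis classes
#' satisfied by the ICD-10 code and by the topography-morphology combination:
#' each minimal shared class is one branch of the diagnosis lattice
#' instantiated by both sides. Unbound inputs yield `NULL` (not evaluable),
#' not an error.
#'
#' @param icd10_binding One-row bindings tibble for the ICD-10 code.
#' @param combo_satisfied Character vector from
#'   [satisfied_dx_of_combination()].
#' @param model A `derivative_model`.
#' @return Character vector of diagnosis class ids (an antichain), or `NULL`
#'   when the ICD-10 side is not bound.
#' @export
shared_branches <- function(icd10_binding, combo_satisfied, model) {
  if (icd10_binding$status[[1]] != "BOUND") return(NULL)
  shared <- intersect(icd10_binding$satisfied[[1]], combo_satisfied)
  minimal_dx(shared, model$axis, model$index)
}

#' Minimum hierarchical edge distance between two diagnosis classes
#'
#' The minimum, over common ancestors `z` in the Hasse diagram of the
#' lattice, of the number of upward steps from each class to `z`. `Inf` when
#' the classes share no ancestor. Symmetric, zero on the diagonal; not
#' necessarily a metric.
#'
#' @param lattice A `dx_lattice`.
#' @param d1,d2 Diagnosis class ids.
#' @return Non-negative number or `Inf`.
#' @export
dx_edge_distance <- function(lattice, d1, d2) {
  ids <- lattice$classes$id
  missing <- setdiff(c(d1, d2), ids)
  if (length(missing)) stop_unknown_id(missing, "diagnosis lattice")
  if (d1 == d2) return(0)
  dmat <- igraph::distances(lattice$graph, v = c(d1, d2), mode = "out")
  tot <- dmat[1L, ] + dmat[2L, ]
  if (all(!is.finite(tot))) Inf else min(tot)
}

# Pairwise up-step distance matrix from a set of classes to all classes.
dx_updist <- function(lattice, from) {
  igraph::distances(lattice$graph, v = from, mode = "out")
}

#' Rebuild code mappings by minimum edge distance
#'
#' For every bound topography-morphology combination, the distance to each
#' bound ICD-10 code is the minimum edge distance over (direct class of the
#' code) x (minimal satisfied class of the combination) pairs; every argmin
#' code is predicted (ties are preserved, flagged as non-unique). Combinations
#' at infinite distance from every code stay unpredicted.
#'
#' @param icd10_bindings Bindings tibble restricted to ICD-10 rows (unbound
#'   rows are ignored).
#' @param combos Tibble with columns `topography`, `morphology`,
#'   `combo_minimal` (list of minimal satisfied class ids).
#' @param model A `derivative_model`.
#' @return Tibble with columns `topography`, `morphology`, `predicted`
#'   (list of codes), `distance`, `n_predicted`.
#' @export
rebuild_mappings <- function(icd10_bindings, combos, model) {
  lattice <- model$lattice
  icd10 <- filter(icd10_bindings, .data$status == "BOUND", .data$system == "ICD10")
  code_classes <- setNames(icd10$direct, icd10$code)
  all_from <- sort_ids(c(unlist(code_classes), unlist(combos$combo_minimal)))
  updist <- if (length(all_from)) dx_updist(lattice, all_from) else NULL
  pair_dist <- function(a, b) {
    # min over common ancestors of up-steps from a plus up-steps from b
    if (length(a) == 0 || length(b) == 0) return(Inf)
    best <- Inf
    for (x in a) {
      for (y in b) {
        if (x == y) {
          best <- min(best, 0)
        } else {
          tot <- updist[x, ] + updist[y, ]
          fin <- tot[is.finite(tot)]
          if (length(fin)) best <- min(best, min(fin))
        }
      }
    }
    best
  }
  rows <- map(seq_len(nrow(combos)), function(i) {
    cm <- combos$combo_minimal[[i]]
    dists <- map_dbl_named(code_classes, function(cc) pair_dist(cc, cm))
    finite <- dists[is.finite(dists)]
    if (length(finite) == 0) {
      return(tibble(
        topography = combos$topography[[i]], morphology = combos$morphology[[i]],
        predicted = list(character()), distance = Inf, n_predicted = 0L
      ))
    }
    dmin <- min(finite)
    preds <- sort_ids(names(finite)[finite == dmin])
    tibble(
      topography = combos$topography[[i]], morphology = combos$morphology[[i]],
      predicted = list(preds), distance = dmin, n_predicted = length(preds)
    )
  })
  bind_rows(rows)
}

map_dbl_named <- function(x, f) {
  out <- vapply(x, f, numeric(1))
  setNames(out, names(x))
}

#' Evaluate model links against a gold standard
#'
#' Restricts the gold mappings to the evaluable subset (topography, morphology
#' and ICD-10 code all bound), then counts, overall and per stratum: rows
#' related through at least one shared branch; rows sharing more than one
#' branch; rows whose gold ICD-10 code is among the codes rebuilt for the
#' combination; and rebuilt rows whose combination predicted more than one
#' code.
#'
#' @param gold Tibble from [read_seer_conversion()].
#' @param bindings Bindings tibble covering all three systems.
#' @param model A `derivative_model`.
#' @return Object of class `eval_report`: `summary` tibble (per stratum and
#'   overall), `rows` tibble with per-mapping outcomes, and `n_excluded`
#'   (gold rows with an unbound code).
#' @export
evaluate_against_gold <- function(gold, bindings, model) {
  key <- function(sys, code) paste(sys, code)
  bmap <- setNames(split(bindings, seq_len(nrow(bindings))),
                   key(bindings$system, bindings$code))
  get_binding <- function(sys, code) bmap[[key(sys, code)]]
  is_bound <- function(sys, code) {
    b <- get_binding(sys, code)
    !is.null(b) && b$status[[1]] == "BOUND"
  }
  evaluable <- map_lgl(seq_len(nrow(gold)), function(i) {
    is_bound("ICDO3_T", gold$topography[[i]]) &&
      is_bound("ICDO3_M", gold$morphology[[i]]) &&
      is_bound("ICD10", gold$icd10[[i]])
  })
  ev <- gold[evaluable, , drop = FALSE]
  if (nrow(ev) == 0) {
    empty <- tibble(stratum = c("ALL", "HEMATOPOIETIC", "SOLID"),
                    n_evaluable = 0L, n_related = 0L, n_multibranch = 0L,
                    n_rebuilt = 0L, n_nonunique = 0L)
    return(structure(list(summary = empty,
                          rows = tibble(), n_excluded = sum(!evaluable)),
                     class = "eval_report"))
  }
  combos <- distinct(ev, .data$topography, .data$morphology)
  combos$combo_satisfied <- map(seq_len(nrow(combos)), function(i) {
    satisfied_dx_of_combination(
      get_binding("ICDO3_T", combos$topography[[i]]),
      get_binding("ICDO3_M", combos$morphology[[i]]),
      model
    )
  })
  combos$combo_minimal <- map(combos$combo_satisfied,
                              function(s) minimal_dx(s, model$axis, model$index))
  pred <- rebuild_mappings(bindings, combos, model)
  combos <- left_join(combos, pred, by = c("topography", "morphology"))

  rows <- ev |>
    left_join(combos, by = c("topography", "morphology")) |>
    mutate(
      shared = map2(.data$icd10, .data$combo_satisfied, function(code, sat) {
        shared_branches(get_binding("ICD10", code), sat, model)
      }),
      related = lengths(.data$shared) > 0L,
      multibranch = lengths(.data$shared) > 1L,
      rebuilt = map2_lgl_(.data$icd10, .data$predicted,
                          function(code, p) code %in% p),
      nonunique = .data$rebuilt & .data$n_predicted > 1L
    )

  summarise_stratum <- function(sub, name) {
    tibble(
      stratum = name,
      n_evaluable = nrow(sub),
      n_related = sum(sub$related),
      n_multibranch = sum(sub$multibranch),
      n_rebuilt = sum(sub$rebuilt),
      n_nonunique = sum(sub$nonunique)
    )
  }
  summary <- bind_rows(
    summarise_stratum(rows, "ALL"),
    summarise_stratum(filter(rows, .data$stratum == "HEMATOPOIETIC"), "HEMATOPOIETIC"),
    summarise_stratum(filter(rows, .data$stratum == "SOLID"), "SOLID")
  )
  structure(
    list(summary = summary,
         rows = select(rows, "topography", "morphology", "icd10", "stratum",
                       "shared", "related", "multibranch", "predicted",
                       "distance", "n_predicted", "rebuilt", "nonunique"),
         n_excluded = sum(!evaluable)),
    class = "eval_report"
  )
}

map2_lgl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), logical(1))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summary)
  cat(sprintf("(%d gold rows not evaluable: a code did not bind)\n", x$n_excluded))
  invisible(x)
}
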