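# Auditing: multi-class instantiation, behavior conflicts, and candidate
# source-ontology inconsistencies (is_a overloading, missing part_of links).

direct_bases_of <- function(binding_row) {
  d <- binding_row$direct[[1]]
  if (binding_row$system[[1]] == "ICDO3_T") {
    rp_base(d)
  } else if (binding_row$system[[1]] == "ICD10") {
    map_chr(d, function(x) dx_parts(x)$base)
  } else {
    character()
  }
}

#' Multi-instantiation audit report
#'
#' Counts, per category (all ICD-10 plus its behavior strata, ICD-O-3
#' topographies, ICD-O-3 morphologies), how many bound codes instantiate more
#' than one direct class, with per-code detail rows.
#'
#' @param bindings Bindings tibble from [bind_codes()].
#' @return Object of class `audit_report` with tibbles `summary`
#'   (`category`, `n_bound`, `n_multi`, `pct_multi`) and `detail`
#'   (`code`, `system`, `n_direct`, `classes`).
#' @export
multi_instantiation_report <- function(bindings) {
  bound <- filter(bindings, .data$status == "BOUND") |>
    mutate(n_direct = lengths(.data$direct))
  strata <- list(
    `ICD-10` = quote(system == "ICD10"),
    `ICD-10 Benign` = quote(system == "ICD10" & behavior == "BENIGN"),
    `ICD-10 In situ` = quote(system == "ICD10" & behavior == "IN_SITU"),
    `ICD-10 Malignant` = quote(system == "ICD10" & behavior == "MALIGNANT_PRIMARY"),
    `ICD-O-3 Topographies` = quote(system == "ICDO3_T"),
    `ICD-O-3 Morphologies` = quote(system == "ICDO3_M")
  )
  summary <- bind_rows(imap(strata, function(cond, name) {
    sub <- filter(bound, !!cond)
    tibble(
      category = name,
      n_bound = nrow(sub),
      n_multi = sum(sub$n_direct > 1L),
      pct_multi = if (nrow(sub)) 100 * sum(sub$n_direct > 1L) / nrow(sub) else NA_real_
    )
  }))
  detail <- bound |>
    arrange(.data$system, .data$code) |>
    mutate(classes = map_chr(.data$direct, function(d) paste(d, collapse = ";"))) |>
    select("code", "system", "n_direct", "classes")
  structure(list(summary = summary, detail = detail), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  print(x$summary)
  invisible(x)
}

#' Behavior conflicts among a code's direct classes
#'
#' Flags every bound ICD-10 code whose direct diagnosis classes carry at
#' least two distinct behavior ancestries (the behavior of a diagnosis class
#' is the behavior of its morphology): a tumour cannot, e.g., be invasive and
#' in situ at once, so such codes expose inconsistent source annotations.
#'
#' @param bindings Bindings tibble.
#' @param lattice A `dx_lattice`.
#' @return Tibble with columns `code`, `kind` (`"BEHAVIOR_CONFLICT"`),
#'   `behaviors`, `evidence` (one pair of class ids with distinct behaviors).
#' @export
behavior_conflicts <- function(bindings, lattice) {
  beh <- setNames(lattice$classes$behavior, lattice$classes$id)
  rows <- bindings |>
    filter(.data$status == "BOUND", .data$system == "ICD10")
  out <- map(seq_len(nrow(rows)), function(i) {
    d <- rows$direct[[i]]
    bs <- sort_ids(beh[d])
    if (length(bs) < 2L) return(NULL)
    a <- d[match(bs[[1]], beh[d])]
    b <- d[match(bs[[2]], beh[d])]
    tibble(
      code = rows$code[[i]],
      kind = "BEHAVIOR_CONFLICT",
      behaviors = paste(bs, collapse = ";"),
      evidence = paste(c(a, b), collapse = ";")
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(code = character(), kind = character(),
                  behaviors = character(), evidence = character()))
  }
  arrange(out, .data$code)
}

#' Hypotheses about source-ontology inconsistencies
#'
#' For every multi-instantiated code whose direct classes sit on mutually
#' incomparable topography bases, emits the incomparable base pairs as
#' candidate missing part-whole links or is_a-overloading evidence.
#'
#' @param bindings Bindings tibble.
#' @param index An `anatomy_index`.
#' @return Tibble with columns `code`, `system`, `kind`
#'   (`"INCOMPARABLE_SITES"`), `base_a`, `base_b`.
#' @export
inconsistency_hypotheses <- function(bindings, index) {
  rows <- filter(bindings, .data$status == "BOUND",
                 .data$system %in% c("ICD10", "ICDO3_T"))
  out <- map(seq_len(nrow(rows)), function(i) {
    bases <- sort_ids(direct_bases_of(rows[i, ]))
    if (length(bases) < 2L) return(NULL)
    pairs <- utils::combn(bases, 2L)
    keep <- map_lgl(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]
      b <- pairs[2L, j]
      !anat_reachable(index, a, b) && !anat_reachable(index, b, a)
    })
    if (!any(keep)) return(NULL)
    tibble(
      code = rows$code[[i]],
      system = rows$system[[i]],
      kind = "INCOMPARABLE_SITES",
      base_a = pairs[1L, keep],
      base_b = pairs[2L, keep]
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(code = character(), system = character(), kind = character(),
                  base_a = character(), base_b = character()))
  }
  arrange(out, .data$code, .data$base_a, .data$base_b)
}

#' Run the full audit
#'
#' @param bindings Bindings tibble.
#' @param model A `derivative_model`.
#' @return `audit_report` with additional elements `conflicts` and
#'   `hypotheses`.
#' @export
audit_bindings <- function(bindings, model) {
  rep <- multi_instantiation_report(bindings)
  rep$conflicts <- behavior_conflicts(bindings, model$lattice)
  rep$hypotheses <- inconsistency_hypotheses(bindings, model$index)
  rep
}
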