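# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @describeIn tidy_oncolattice concept table of a source ontology
#' @export
tidy.src_ontology <- function(x, ...) as_tibble(x$concepts)

#' Tidy and glance methods
#'
#' `tidy()` returns the principal per-item table of each object; `glance()`
#' returns a one-row summary.
#'
#' @param x An oncolattice result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_oncolattice
NULL

#' @describeIn tidy_oncolattice reflexive-part classes
#' @export
tidy.rp_lattice <- function(x, ...) as_tibble(x$classes)

#' @describeIn tidy_oncolattice morphology axis nodes
#' @export
tidy.morphology_axis <- function(x, ...) as_tibble(x$nodes)

#' @describeIn tidy_oncolattice diagnosis classes with support sizes
#' @export
tidy.dx_lattice <- function(x, ...) {
  x$classes |>
    mutate(n_support = lengths(.data$support)) |>
    select("id", "morph", "base", "behavior", "n_support", "iri")
}

#' @describeIn tidy_oncolattice component sizes of a derivative model
#' @export
glance.derivative_model <- function(x, ...) {
  tibble(
    n_concepts = nrow(x$ontology$concepts),
    n_topographies = length(x$topos),
    n_morphologies = length(morphology_ids(x$axis)),
    n_candidates = (length(morphology_ids(x$axis)) + 6) * length(x$topos),
    n_retained = nrow(x$retained),
    retention_pct = if (length(x$topos))
      100 * nrow(x$retained) / ((length(morphology_ids(x$axis)) + 6) * length(x$topos))
    else NA_real_
  )
}

#' @describeIn tidy_oncolattice per-category multi-instantiation counts
#' @export
tidy.audit_report <- function(x, ...) as_tibble(x$summary)

#' @describeIn tidy_oncolattice one-row audit totals
#' @export
glance.audit_report <- function(x, ...) {
  tibble(
    n_bound = sum(x$summary$n_bound[x$summary$category %in%
                                      c("ICD-10", "ICD-O-3 Topographies",
                                        "ICD-O-3 Morphologies")]),
    n_multi = sum(x$summary$n_multi[x$summary$category %in%
                                      c("ICD-10", "ICD-O-3 Topographies",
                                        "ICD-O-3 Morphologies")]),
    n_conflicts = if (is.null(x$conflicts)) NA_integer_ else nrow(x$conflicts),
    n_hypotheses = if (is.null(x$hypotheses)) NA_integer_ else nrow(x$hypotheses)
  )
}

#' @describeIn tidy_oncolattice per-stratum evaluation counts
#' @export
tidy.eval_report <- function(x, ...) as_tibble(x$summary)

#' @describeIn tidy_oncolattice overall evaluation rates
#' @export
glance.eval_report <- function(x, ...) {
  all_row <- filter(x$summary, .data$stratum == "ALL")
  tibble(
    n_evaluable = all_row$n_evaluable,
    related_pct = if (all_row$n_evaluable) 100 * all_row$n_related / all_row$n_evaluable else NA_real_,
    multibranch_pct = if (all_row$n_related) 100 * all_row$n_multibranch / all_row$n_related else NA_real_,
    rebuilt_pct = if (all_row$n_evaluable) 100 * all_row$n_rebuilt / all_row$n_evaluable else NA_real_,
    nonunique_pct = if (all_row$n_rebuilt) 100 * all_row$n_nonunique / all_row$n_rebuilt else NA_real_,
    n_excluded = x$n_excluded
  )
}

#' Plot multi-instantiation rates per category
#'
#' @param object An `audit_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.audit_report <- function(object, ...) {
  df <- filter(object$summary, .data$n_bound > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, .data$pct_multi),
    y = .data$pct_multi
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of bound codes instantiating multiple classes",
                  title = "Multi-instantiation audit") +
    ggplot2::theme_minimal()
}

#' Plot evaluation rates per stratum
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$summary |>
    filter(.data$n_evaluable > 0) |>
    mutate(
      `related` = 100 * .data$n_related / .data$n_evaluable,
      `rebuilt` = 100 * .data$n_rebuilt / .data$n_evaluable
    ) |>
    tidyr::pivot_longer(c("related", "rebuilt"),
                        names_to = "measure", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$pct,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of evaluable gold mappings",
                  title = "Gold-standard comparison") +
    ggplot2::theme_minimal()
}

#' Plot the diagnosis lattice Hasse diagram
#'
#' Classes are laid out in layers by their longest upward path; direct edges
#' are drawn as segments. Intended for desk-scale lattices.
#'
#' @param object A `dx_lattice`.
#' @param max_nodes Refuse to draw lattices larger than this.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dx_lattice <- function(object, max_nodes = 200, ...) {
  if (nrow(object$classes) > max_nodes) {
    abort(sprintf("lattice has %d classes; raise max_nodes to plot anyway",
                  nrow(object$classes)))
  }
  ids <- object$classes$id
  depth <- setNames(rep(0L, length(ids)), ids)
  # longest path to a maximal element, computed bottom-up over the Hasse DAG
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(object$edges))) {
      f <- object$edges$from[[i]]
      t <- object$edges$to[[i]]
      if (depth[[f]] < depth[[t]] + 1L) {
        depth[[f]] <- depth[[t]] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  nodes <- tibble(id = ids, depth = unname(depth[ids])) |>
    group_by(.data$depth) |>
    mutate(x = row_number() - (n() + 1) / 2) |>
    ungroup() |>
    mutate(label = sub("^DX:", "", .data$id))
  seg <- object$edges |>
    left_join(nodes, by = c(from = "id")) |>
    rename(x0 = "x", d0 = "depth") |>
    left_join(nodes, by = c(to = "id")) |>
    rename(x1 = "x", d1 = "depth")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = -.data$d0,
                                       xend = .data$x1, yend = -.data$d1),
                          color = "grey60") +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = -.data$depth,
                                     label = .data$label), size = 2.6) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Diagnosis lattice (Hasse diagram)")
}
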