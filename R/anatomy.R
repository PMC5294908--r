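# Topography collection and the reflexive-part (S-node) lattice.

#' Collect the topographies involved in diagnosis definitions
#'
#' The union of all primary-site fillers of all neoplasm concepts, optionally
#' completed with every anatomy concept reachable above them (`<=A`
#' ancestors). Ancestor completion is on by default so that coarse classes
#' (e.g. a Large Intestine reflexive part) exist even when never directly
#' asserted as a filler. Fillers missing from the anatomy index are excluded
#' with a warning (they surface in [validate_ontology()]).
#'
#' @param neo A `neoplasm_graph`.
#' @param index An `anatomy_index`.
#' @param ancestor_completion Include all `<=A` ancestors of the fillers.
#' @return Character vector of anatomy concept ids.
#' @export
collect_topographies <- function(neo, index, ancestor_completion = TRUE) {
  fillers <- sort_ids(neo$sites$site)
  off <- setdiff(fillers, index$nodes)
  if (length(off)) {
    warn(paste0("excluding site filler(s) outside the anatomy index: ",
                paste(off, collapse = ", ")))
    fillers <- setdiff(fillers, off)
  }
  if (!ancestor_completion || length(fillers) == 0) return(fillers)
  sort_ids(unlist(index$anc[fillers], use.names = FALSE))
}

#' Build the reflexive-part topography lattice
#'
#' One reflexive-part class `RP(t)` per collected topography `t`, ordered by
#' `RP(s)` below `RP(t)` iff `s <=A t`; direct edges are the transitive
#' reduction (Hasse diagram) of that order restricted to the collected set.
#' At serialization time each class expands to the S-node definition
#' `t OR (part_of SOME t)`.
#'
#' @param topos Character vector of anatomy concept ids.
#' @param index An `anatomy_index`.
#' @param ns IRI namespace for generated classes.
#' @return Object of class `rp_lattice`: `classes` tibble (`id`, `base`,
#'   `iri`), `edges` tibble (`from`, `to`, child below parent), and the
#'   restricted up-sets.
#' @export
build_rp_lattice <- function(topos, index, ns = DEFAULT_NS) {
  topos <- sort_ids(topos)
  missing <- setdiff(topos, index$nodes)
  if (length(missing)) stop_unknown_id(missing, "anatomy index")
  up <- lapply(setNames(topos, topos), function(t) {
    intersect(index$anc[[t]], topos)
  })
  edges <- transitive_reduction(up)
  classes <- tibble(
    id = rp_id(topos),
    base = topos,
    iri = rp_iri(topos, ns)
  )
  structure(
    list(
      classes = classes,
      edges = tibble(from = rp_id(edges$from), to = rp_id(edges$to)),
      up = up,
      ns = ns
    ),
    class = "rp_lattice"
  )
}

#' @export
print.rp_lattice <- function(x, ...) {
  cat(sprintf("<rp_lattice> %d reflexive-part classes, %d direct edges\n",
              nrow(x$classes), nrow(x$edges)))
  invisible(x)
}

#' Topography bases of a reflexive-part lattice
#' @param rp An `rp_lattice`.
#' @return Character vector of anatomy concept ids.
#' @export
rp_bases <- function(rp) rp$classes$base
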