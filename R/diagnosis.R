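# Candidate diagnosis generation, retention and the diagnosis Hasse lattice.
#
# A candidate is a (morphology, reflexive-part topography) pair; the candidate
# morphology set is the specific codes plus the six behavior roots. A
# candidate is retained iff at least one source concept satisfies it through
# its inherited (ancestor-closed) morphology and site sets.

#' Stream the candidate diagnosis cross product
#'
#' Emits exactly `|morphologies incl. behavior roots| x |reflexive parts|`
#' pairs in deterministic lexicographic order. With a `callback` the pairs are
#' produced chunk-by-chunk and never materialized at once (constant memory per
#' chunk); without one, a single tibble is returned (desk-scale use).
#'
#' @param axis A `morphology_axis`.
#' @param rp An `rp_lattice`.
#' @param callback Optional `function(chunk)` receiving a tibble with columns
#'   `morph`, `base`; its return value is discarded.
#' @param chunk_size Rows per emitted chunk when streaming.
#' @return The total number of pairs (invisibly when streaming; as an
#'   attribute `"n_candidates"` of the tibble otherwise).
#' @export
generate_candidates <- function(axis, rp, callback = NULL, chunk_size = 100000L) {
  morphs <- morphology_ids(axis, include_behaviors = TRUE)
  bases <- sort_ids(rp_bases(rp))
  n_m <- length(morphs)
  n_b <- length(bases)
  total <- as.numeric(n_m) * n_b
  if (is.null(callback)) {
    if (total == 0) {
      out <- tibble(morph = character(), base = character())
    } else {
      out <- tibble(
        morph = rep(morphs, each = n_b),
        base = rep(bases, times = n_m)
      )
    }
    attr(out, "n_candidates") <- total
    return(out)
  }
  if (total > 0) {
    per_morph <- max(1L, as.integer(chunk_size %/% max(1L, n_b)))
    i <- 1L
    while (i <= n_m) {
      j <- min(n_m, i + per_morph - 1L)
      block <- morphs[i:j]
      callback(tibble(
        morph = rep(block, each = n_b),
        base = rep(bases, times = length(block))
      ))
      i <- j + 1L
    }
  }
  invisible(total)
}

# Up-closure of a morphology set within the candidate morphology universe:
# a specific code contributes itself and its behavior root; a behavior root
# contributes itself.
morph_up_tbl <- function(axis) {
  nodes <- filter(axis$nodes, .data$kind != "root")
  bind_rows(
    tibble(morph = nodes$id, up = nodes$id),
    tibble(morph = nodes$id[nodes$kind == "specific"],
           up = nodes$behavior[nodes$kind == "specific"])
  ) |> distinct()
}

# Site up-closure pairs restricted to a topography set.
site_up_tbl <- function(index, topos) {
  anc <- index$anc
  tibble(
    site = as.character(rep(names(anc), lengths(anc))),
    up = as.character(unlist(anc, use.names = FALSE))
  ) |> filter(.data$up %in% topos)
}

#' Does a concept satisfy a candidate diagnosis?
#'
#' True iff some inherited morphology of the concept is subsumed by the
#' candidate morphology and some inherited site reaches the candidate base
#' under the anatomy order.
#'
#' @param concept Concept id.
#' @param morph Candidate morphology id (code or behavior root).
#' @param base Candidate topography base (anatomy id).
#' @param refined A `refined_index`.
#' @param axis A `morphology_axis`.
#' @param index An `anatomy_index`.
#' @return Logical scalar.
#' @export
concept_satisfies <- function(concept, morph, base, refined, axis, index) {
  if (!concept %in% refined$concepts) stop_unknown_id(concept, "refined index")
  mcs <- refined_morphs_of(refined, concept)
  if (length(mcs) == 0 || !any(morph_subsumes(axis, mcs, morph))) return(FALSE)
  ss <- refined_sites_of(refined, concept)
  ss <- intersect(ss, index$nodes)
  length(ss) > 0 && any(anat_reachable(index, ss, base))
}

#' Retain the candidate diagnoses satisfied by at least one concept
#'
#' Indexed retention: for every concept the up-sets of its inherited
#' morphologies and sites are expanded and their cross product accumulated, so
#' pruned candidates never occupy storage. Equivalent to scanning all
#' candidates against all concepts (the brute-force oracle used in tests).
#'
#' @param refined A `refined_index`.
#' @param axis A `morphology_axis`.
#' @param rp An `rp_lattice`.
#' @param index An `anatomy_index`.
#' @return Tibble with columns `morph`, `base`, `support` (list of concept
#'   ids), sorted lexicographically.
#' @export
retain_diagnoses <- function(refined, axis, rp, index) {
  topos <- rp_bases(rp)
  m_up <- inner_join(refined$morphs, morph_up_tbl(axis),
                     by = c(code = "morph"), relationship = "many-to-many") |>
    distinct(.data$concept, morph = .data$up)
  s_up <- inner_join(refined$sites, site_up_tbl(index, topos),
                     by = "site", relationship = "many-to-many") |>
    distinct(.data$concept, base = .data$up)
  hits <- inner_join(m_up, s_up, by = "concept", relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(morph = character(), base = character(), support = list()))
  }
  hits |>
    group_by(.data$morph, .data$base) |>
    summarise(support = list(sort_ids(.data$concept)), .groups = "drop") |>
    arrange(.data$morph, .data$base)
}

#' Build the diagnosis Hasse lattice from retained candidates
#'
#' Direct edges are the transitive reduction of the diagnosis order (morph
#' subsumption x anatomy reachability) restricted to the retained classes.
#'
#' @param retained Tibble from [retain_diagnoses()].
#' @param axis A `morphology_axis`.
#' @param index An `anatomy_index`.
#' @param ns IRI namespace.
#' @return Object of class `dx_lattice`: `classes` tibble (`id`, `morph`,
#'   `base`, `behavior`, `iri`, `support`), `edges` tibble, and an igraph of
#'   the Hasse diagram (edges pointing upward).
#' @export
build_dx_lattice <- function(retained, axis, index, ns = DEFAULT_NS) {
  if (nrow(retained) == 0) {
    abort("no retained diagnosis classes; cannot build an empty lattice")
  }
  beh <- setNames(axis$nodes$behavior, axis$nodes$id)
  classes <- retained |>
    mutate(
      id = dx_id(.data$morph, .data$base),
      behavior = unname(beh[.data$morph]),
      iri = dx_iri(.data$morph, .data$base, ns)
    ) |>
    select("id", "morph", "base", "behavior", "iri", "support") |>
    arrange(.data$id)

  # up-sets within the lattice via joined closures
  mu <- morph_up_tbl(axis)
  key <- setNames(classes$id, paste(classes$morph, classes$base))
  up <- vector("list", nrow(classes))
  names(up) <- classes$id
  su_all <- index$anc
  present <- split(classes$base, classes$morph)
  for (i in seq_len(nrow(classes))) {
    m <- classes$morph[[i]]
    b <- classes$base[[i]]
    ms <- mu$up[mu$morph == m]
    bs <- su_all[[b]]
    hits <- unlist(lapply(ms, function(mm) {
      bb <- intersect(bs, present[[mm]])
      if (length(bb)) paste(mm, bb) else character()
    }), use.names = FALSE)
    up[[i]] <- unname(key[hits])
  }
  edges <- transitive_reduction(up)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$from, to = edges$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = classes$id, stringsAsFactors = FALSE)
  )
  structure(
    list(classes = classes, edges = edges, up = up, graph = g, ns = ns),
    class = "dx_lattice"
  )
}

#' @export
print.dx_lattice <- function(x, ...) {
  cat(sprintf("<dx_lattice> %d diagnosis classes, %d direct edges\n",
              nrow(x$classes), nrow(x$edges)))
  invisible(x)
}

# Lattice classes satisfied by a morphology set and an (already up-closed or
# raw) site set. morph_set may mix codes and behavior roots.
satisfied_classes <- function(lattice, morph_set, site_set, axis, index) {
  if (length(morph_set) == 0 || length(site_set) == 0) return(character())
  mu <- morph_up_tbl(axis)
  m_ok <- sort_ids(mu$up[mu$morph %in% morph_set])
  site_set <- intersect(site_set, index$nodes)
  b_ok <- sort_ids(unlist(index$anc[site_set], use.names = FALSE))
  lattice$classes$id[lattice$classes$morph %in% m_ok &
                       lattice$classes$base %in% b_ok]
}

#' Direct diagnosis superclasses of a source concept
#'
#' The minimal elements (an antichain) of the retained classes the concept
#' satisfies — its direct types in the derivative model.
#'
#' @param concept Concept id.
#' @param lattice A `dx_lattice`.
#' @param refined A `refined_index`.
#' @param axis A `morphology_axis`.
#' @param index An `anatomy_index`.
#' @return Character vector of diagnosis class ids.
#' @export
direct_dx_superclasses <- function(concept, lattice, refined, axis, index) {
  if (!concept %in% refined$concepts) stop_unknown_id(concept, "refined index")
  sat <- satisfied_classes(
    lattice,
    refined_morphs_of(refined, concept),
    refined_sites_of(refined, concept),
    axis, index
  )
  minimal_dx(sat, axis, index)
}

#' Build the full derivative model from a source ontology
#'
#' Runs extraction, topography collection, reflexive-part lattice, morphology
#' axis, refined index, retention and the diagnosis lattice in order.
#'
#' @param onto A validated `src_ontology`.
#' @param ancestor_completion Passed to [collect_topographies()].
#' @param ns IRI namespace for generated classes.
#' @return Object of class `derivative_model` bundling all components.
#' @export
build_derivative_model <- function(onto, ancestor_completion = TRUE, ns = DEFAULT_NS) {
  index <- extract_anatomy_graph(onto)
  neo <- extract_neoplasm_graph(onto)
  axis <- build_morphology_axis(neo, ns = ns)
  topos <- collect_topographies(neo, index, ancestor_completion = ancestor_completion)
  rp <- build_rp_lattice(topos, index, ns = ns)
  refined <- compute_refined_index(neo, axis)
  retained <- retain_diagnoses(refined, axis, rp, index)
  lattice <- if (nrow(retained)) build_dx_lattice(retained, axis, index, ns = ns) else NULL
  structure(
    list(
      ontology = onto, index = index, neoplasm = neo, axis = axis,
      topos = topos, rp = rp, refined = refined, retained = retained,
      lattice = lattice, ns = ns
    ),
    class = "derivative_model"
  )
}

#' @export
print.derivative_model <- function(x, ...) {
  cat(sprintf(
    "<derivative_model> %d topographies, %d morphologies (+6 behavior roots), %d retained diagnoses\n",
    length(x$topos), length(morphology_ids(x$axis)), nrow(x$retained)
  ))
  invisible(x)
}
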