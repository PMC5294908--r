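# Structural order engine: anatomy reachability, morphology subsumption,
# diagnosis subsumption, transitive reduction and minimal antichains.
#
# The anatomy order <=A is plain directed reachability over the union of is_a
# and both part-whole roles, all treated as transitive and freely composable
# (reproducing NCIt-style propagation down to cell parts).

#' Build the anatomy reachability index
#'
#' Extracts the ANATOMY-tagged subgraph (is_a plus both part-whole roles) and
#' precomputes its reflexive-transitive closure: `s <=A t` holds whenever `t`
#' is reachable from `s` along any mixture of `is_a`, `PART_PHYSICAL` and
#' `PART_LOCATION` edges.
#'
#' @param onto A `src_ontology`.
#' @return An object of class `anatomy_index`: node set, direct edge tibble,
#'   and per-node ancestor sets (each including the node itself).
#' @export
extract_anatomy_graph <- function(onto) {
  anat <- onto$concepts$id[onto$concepts$axis == "ANATOMY"]
  is_a <- filter(onto$is_a, .data$child %in% anat & .data$parent %in% anat)
  parts <- filter(onto$parts, .data$child %in% anat & .data$parent %in% anat)
  edges <- bind_rows(
    tibble(child = is_a$child, parent = is_a$parent, role = "IS_A"),
    select(parts, "child", "parent", "role")
  ) |> distinct() |> arrange(.data$child, .data$parent, .data$role)
  cyc <- find_cycle(edges)
  if (!is.null(cyc)) {
    abort(paste0("anatomy graph is cyclic: ", paste(cyc, collapse = " -> ")),
          class = "oncolattice_cycle")
  }
  structure(
    list(
      nodes = sort_ids(anat),
      edges = edges,
      anc = ancestor_sets(sort_ids(anat), edges)
    ),
    class = "anatomy_index"
  )
}

#' @export
print.anatomy_index <- function(x, ...) {
  cat(sprintf("<anatomy_index> %d concepts, %d direct edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Reflexive-transitive ancestor sets of a DAG given (child, parent) edges.
# igraph BFS over the edge union; names are concept ids.
ancestor_sets <- function(nodes, edges) {
  if (length(nodes) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    d = unique(data.frame(from = edges$child, to = edges$parent,
                          stringsAsFactors = FALSE)),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  reach <- igraph::ego(g, order = length(nodes), mode = "out", mindist = 0)
  out <- lapply(reach, function(vs) sort_ids(names(vs)))
  names(out) <- igraph::V(g)$name
  out[nodes]
}

#' Anatomy reachability
#'
#' Is `to` reachable from `from` under the reflexive-transitive anatomy order
#' (is_a and both part roles)? Vectorized over `from`/`to`.
#'
#' @param index An `anatomy_index`.
#' @param from,to Anatomy concept ids (recycled to common length).
#' @return Logical vector.
#' @export
anat_reachable <- function(index, from, to) {
  n <- max(length(from), length(to))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  missing <- setdiff(unique(c(from, to)), index$nodes)
  if (length(missing)) stop_unknown_id(missing, "anatomy index")
  map_lgl(seq_len(n), function(i) to[[i]] %in% index$anc[[from[[i]]]])
}

#' Morphology subsumption
#'
#' A specific morphology class is subsumed by itself, by its behavior root and
#' by the morphology root; the axis is flat below the six behavior roots.
#' Vectorized over `a`/`b`.
#'
#' @param axis A `morphology_axis` (see [build_morphology_axis()]).
#' @param a,b Morphology class ids (`"HHHH/B"` codes, behavior class names, or
#'   the root).
#' @return Logical vector: `a` is subsumed by `b`.
#' @export
morph_subsumes <- function(axis, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  known <- axis$nodes$id
  missing <- setdiff(unique(c(a, b)), known)
  if (length(missing)) stop_unknown_id(missing, "morphology axis")
  beh <- setNames(axis$nodes$behavior, axis$nodes$id)
  a == b | b == MORPH_ROOT_ID | (b %in% BEHAVIOR_CLASSES & !is.na(beh[a]) & beh[a] == b)
}

#' Diagnosis subsumption
#'
#' `D(m1, t1)` is subsumed by `D(m2, t2)` iff `m1` is subsumed by `m2` on the
#' morphology axis and `base(t1) <=A base(t2)` in the anatomy order.
#'
#' @param axis A `morphology_axis`.
#' @param index An `anatomy_index`.
#' @param d1,d2 Diagnosis class ids (`"DX:<morph>@<anatomy>"`), vectorized.
#' @return Logical vector.
#' @export
dx_subsumes <- function(axis, index, d1, d2) {
  n <- max(length(d1), length(d2))
  d1 <- rep_len(d1, n)
  d2 <- rep_len(d2, n)
  p1 <- dx_parts(d1)
  p2 <- dx_parts(d2)
  morph_subsumes(axis, p1$morph, p2$morph) & anat_reachable(index, p1$base, p2$base)
}

#' Transitive reduction (Hasse diagram) of a partial order
#'
#' Given per-node up-sets (all order-ancestors, each set containing the node
#' itself), returns the unique minimal direct-edge set whose
#' reflexive-transitive closure equals the order. Antisymmetry is verified;
#' a violating pair raises a cycle error.
#'
#' @param up Named list: for each node, the character vector of nodes above it
#'   (inclusive). May also be a logical matrix with dimnames (`up[i, j]` means
#'   `i <= j`).
#' @return Tibble of direct edges (`from` below, `to` above).
#' @export
transitive_reduction <- function(up) {
  if (is.matrix(up)) {
    up <- lapply(setNames(rownames(up), rownames(up)),
                 function(i) colnames(up)[up[i, ]])
  }
  nodes <- names(up)
  up <- lapply(up, function(s) sort_ids(s))
  # antisymmetry check
  for (i in nodes) {
    for (j in up[[i]]) {
      if (j != i && i %in% up[[j]]) {
        abort(sprintf("order is not antisymmetric: %s <= %s and %s <= %s",
                      i, j, j, i),
              class = "oncolattice_cycle")
      }
    }
  }
  res <- map(nodes, function(i) {
    above <- setdiff(up[[i]], i)
    if (!length(above)) return(NULL)
    # j is a direct parent iff no k strictly between i and j
    direct <- keep(above, function(j) {
      !any(map_lgl(setdiff(above, j), function(k) j %in% up[[k]]))
    })
    if (!length(direct)) return(NULL)
    tibble(from = i, to = direct)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) return(tibble(from = character(), to = character()))
  arrange(out, .data$from, .data$to)
}

#' Minimal elements of a set under a partial order
#'
#' Returns every candidate with no distinct candidate strictly below it; the
#' result is an antichain. `leq(x, y)` must implement the order (`x` below
#' `y`).
#'
#' @param candidates Character vector of element ids.
#' @param leq Vectorized predicate of two character vectors.
#' @return Character vector (lexicographically sorted antichain).
#' @export
minimal_elements <- function(candidates, leq) {
  candidates <- sort_ids(candidates)
  if (length(candidates) <= 1L) return(candidates)
  keep_flag <- map_lgl(candidates, function(x) {
    others <- setdiff(candidates, x)
    !any(leq(others, rep(x, length(others))))
  })
  candidates[keep_flag]
}

# Minimal elements of a set of dx ids under the diagnosis order; grouping by
# morphology first keeps the pairwise scan short (classes with different,
# non-behavior morphologies are incomparable unless one is a behavior root).
minimal_dx <- function(ids, axis, index) {
  ids <- sort_ids(ids)
  if (length(ids) <= 1L) return(ids)
  minimal_elements(ids, function(x, y) dx_subsumes(axis, index, x, y))
}
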