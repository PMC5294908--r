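# Independent brute-force oracle: naive rule saturation and exhaustive double
# loops, sharing no code paths with the indexed engine. Guarded to small
# models; used to certify subsumption, satisfaction, retention and
# direct-type computations in tests.

#' Brute-force oracle over a source ontology
#'
#' Recomputes, by naive boolean-matrix fixpoint saturation and exhaustive
#' loops: the anatomy reachability relation, morphology subsumption, the
#' refined (ancestor-closed) morphology/site sets, candidate satisfaction,
#' the retained candidate set and per-concept direct types. Refuses models
#' whose concept x candidate product exceeds `guard`.
#'
#' @param onto A `src_ontology`.
#' @param ancestor_completion Match the engine's topography collection.
#' @param guard Maximum allowed `n_concepts * n_candidates`.
#' @return List with `anat_leq` (logical matrix), `refined_morphs`,
#'   `refined_sites` (named lists), `topos`, `candidates` (tibble),
#'   `satisfaction` (logical matrix concepts x candidates), `retained`
#'   (tibble `morph`, `base`, `support`), `direct_types` (named list).
#' @export
brute_force_oracle <- function(onto, ancestor_completion = TRUE, guard = 5e6) {
  ax <- setNames(onto$concepts$axis, onto$concepts$id)
  anat <- sort(names(ax)[ax == "ANATOMY"])
  neo <- sort(names(ax)[ax == "NEOPLASM"])

  # --- anatomy reachability by fixpoint saturation -----------------------
  n <- length(anat)
  leq <- matrix(FALSE, n, n, dimnames = list(anat, anat))
  diag(leq) <- TRUE
  for (i in seq_len(nrow(onto$is_a))) {
    a <- onto$is_a$child[[i]]; b <- onto$is_a$parent[[i]]
    if (a %in% anat && b %in% anat) leq[a, b] <- TRUE
  }
  for (i in seq_len(nrow(onto$parts))) {
    a <- onto$parts$child[[i]]; b <- onto$parts$parent[[i]]
    if (a %in% anat && b %in% anat) leq[a, b] <- TRUE
  }
  repeat {
    nxt <- leq | ((leq %*% leq) > 0)
    if (identical(nxt, leq)) break
    leq <- nxt
  }

  # --- refined sets by per-concept is_a fixpoint -------------------------
  parents <- split(onto$is_a$parent, factor(onto$is_a$child, levels = neo))
  own_morphs <- split(onto$morphs$code, factor(onto$morphs$concept, levels = neo))
  own_sites <- split(onto$sites$site, factor(onto$sites$concept, levels = neo))
  anc_of <- function(c0) {
    acc <- c0
    repeat {
      more <- unique(unlist(parents[intersect(acc, neo)], use.names = FALSE))
      more <- setdiff(more, acc)
      if (!length(more)) break
      acc <- c(acc, more)
    }
    acc
  }
  refined_morphs <- lapply(setNames(neo, neo), function(c0) {
    sort(unique(unlist(own_morphs[intersect(anc_of(c0), neo)], use.names = FALSE)))
  })
  refined_sites <- lapply(setNames(neo, neo), function(c0) {
    sort(unique(unlist(own_sites[intersect(anc_of(c0), neo)], use.names = FALSE)))
  })

  # --- topographies ------------------------------------------------------
  fillers <- sort(unique(onto$sites$site))
  fillers <- fillers[fillers %in% anat]
  topos <- if (ancestor_completion && length(fillers)) {
    sort(unique(unlist(lapply(fillers, function(f) anat[leq[f, ]]), use.names = FALSE)))
  } else {
    fillers
  }

  # --- candidate morphologies (codes + behavior roots) -------------------
  codes <- sort(unique(onto$morphs$code))
  beh_of_code <- setNames(
    unname(BEHAVIOR_DIGIT_TABLE[substr(codes, 6L, 6L)]), codes
  )
  cand_morphs <- sort(c(codes, BEHAVIOR_CLASSES))
  morph_leq <- function(a, b) {
    a == b ||
      b == MORPH_ROOT_ID ||
      (b %in% BEHAVIOR_CLASSES &&
         ((a %in% codes && beh_of_code[[a]] == b)))
  }

  # --- satisfaction by exhaustive double loop ----------------------------
  candidates <- expand.grid(morph = cand_morphs, base = topos,
                            stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$morph, candidates$base), , drop = FALSE]
  if (length(neo) * nrow(candidates) > guard) {
    abort(sprintf("oracle size guard exceeded: %d concepts x %d candidates",
                  length(neo), nrow(candidates)))
  }
  sat <- matrix(FALSE, length(neo), nrow(candidates),
                dimnames = list(neo, paste(candidates$morph, candidates$base)))
  for (c0 in neo) {
    ms <- refined_morphs[[c0]]
    ss <- intersect(refined_sites[[c0]], anat)
    if (!length(ms) || !length(ss)) next
    for (k in seq_len(nrow(candidates))) {
      m <- candidates$morph[[k]]
      t <- candidates$base[[k]]
      m_ok <- any(vapply(ms, function(mc) morph_leq(mc, m), logical(1)))
      if (!m_ok) next
      t_ok <- any(vapply(ss, function(s) leq[s, t], logical(1)))
      if (t_ok) sat[c0, k] <- TRUE
    }
  }

  keep <- colSums(sat) > 0
  retained <- tibble(
    morph = candidates$morph[keep],
    base = candidates$base[keep],
    support = lapply(which(keep), function(k) sort(neo[sat[, k]]))
  )

  # --- diagnosis order and direct types ----------------------------------
  dx_leq <- function(m1, t1, m2, t2) morph_leq(m1, m2) && leq[t1, t2]
  direct_types <- lapply(setNames(neo, neo), function(c0) {
    idx <- which(sat[c0, ])
    if (!length(idx)) return(character())
    ms <- candidates$morph[idx]
    ts <- candidates$base[idx]
    minimal <- vapply(seq_along(idx), function(i) {
      !any(vapply(seq_along(idx), function(j) {
        j != i && dx_leq(ms[[j]], ts[[j]], ms[[i]], ts[[i]]) &&
          !(ms[[j]] == ms[[i]] && ts[[j]] == ts[[i]])
      }, logical(1)))
    }, logical(1))
    sort(paste0("DX:", ms[minimal], "@", ts[minimal]))
  })

  list(
    anat_leq = leq,
    refined_morphs = refined_morphs,
    refined_sites = refined_sites,
    topos = topos,
    candidates = as_tibble(candidates),
    satisfaction = sat,
    retained = retained,
    direct_types = direct_types,
    morph_leq = morph_leq
  )
}
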