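# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

get_demo <- function() {
  if (is.null(.cache$demo)) .cache$demo <- demo_bundle(verify = FALSE)
  .cache$demo
}

get_model <- function() get_demo()$model

binding_of <- function(bundle, system, code) {
  dplyr::filter(bundle$bindings, .data$system == !!system, .data$code == !!code)
}

# naive closure of a relation given as a from->to edge tibble (test-side
# oracle for transitive_reduction round trips)
naive_closure <- function(nodes, edges) {
  leq <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  diag(leq) <- TRUE
  for (i in seq_len(nrow(edges))) leq[edges$from[[i]], edges$to[[i]]] <- TRUE
  repeat {
    nxt <- leq | ((leq %*% leq) > 0)
    if (identical(nxt, leq)) break
    leq <- nxt
  }
  leq
}

# random partial order on n nodes (closure of a random DAG over a ranking)
random_order <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- list()
  for (i in seq_len(n)) {
    if (i == 1) next
    to <- nodes[seq_len(i - 1)][runif(i - 1) < p]
    if (length(to)) edges[[length(edges) + 1]] <- tibble::tibble(from = nodes[[i]], to = to)
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) edges <- tibble::tibble(from = character(), to = character())
  list(nodes = nodes, closure = naive_closure(nodes, edges))
}

up_sets_from_matrix <- function(leq) {
  lapply(stats::setNames(rownames(leq), rownames(leq)),
         function(i) colnames(leq)[leq[i, ]])
}
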