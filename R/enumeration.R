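# Exhaustive enumeration and ranking of candidate networks on small gene
# sets. A candidate assigns one of three states to every unordered gene pair
# (i < j in node order): 1 = forward (i -> j), 2 = backward (j -> i),
# 3 = absent. Enumeration order is fixed - pair index major, state order
# forward < backward < absent - so candidate ids and rank ties are
# bit-reproducible.

# package-level cache for per-n enumeration tables (they are data-independent)
.trigrn_cache <- new.env(parent = emptyenv())

# unordered pair index matrix: 2 x C(n,2), columns in lexicographic order
pair_matrix <- function(n) combn(n, 2)

# all state assignments for n nodes: 3^C(n,2) x C(n,2) integer matrix, plus
# the acyclicity flag of each row; cached per n
config_table <- function(n) {
  key <- paste0("n", n)
  hit <- .trigrn_cache[[key]]
  if (!is.null(hit)) return(hit)
  pairs <- pair_matrix(n)
  np <- ncol(pairs)
  # last pair varies fastest => first pair is the most significant digit
  states <- as.matrix(do.call(expand.grid, rep(list(1:3), np)))[, np:1, drop = FALSE]
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  # a configuration is acyclic iff some total order orients every present
  # edge forward; test all n! candidate orders vectorised over configurations
  perms <- permutations_of(n)
  acyclic <- rep(FALSE, nrow(states))
  for (r in seq_len(nrow(perms))) {
    pos <- order(perms[r, ]) # pos[v] = position of node v in this order
    ok <- rep(TRUE, nrow(states))
    for (p in seq_len(np)) {
      i <- pairs[1, p]
      j <- pairs[2, p]
      banned <- if (pos[i] < pos[j]) 2L else 1L
      ok <- ok & (states[, p] != banned)
    }
    acyclic <- acyclic | ok
    if (all(acyclic)) break
  }
  out <- list(pairs = pairs, states = states, acyclic = acyclic)
  .trigrn_cache[[key]] <- out
  out
}

# all permutations of 1..n as rows (n <= 6 in practice)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# human-readable edge string for state rows, e.g. "a->b;c->a" (vectorised)
structure_strings <- function(states, nodes, pairs) {
  labels <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- nodes[pairs[1, p]]
    j <- nodes[pairs[2, p]]
    c(paste0(i, "->", j), paste0(j, "->", i), "")[states[, p]]
  })
  joined <- do.call(paste, c(labels, list(sep = ";")))
  joined <- gsub(";{2,}", ";", joined)
  gsub("^;|;$", "", joined)
}

# compact per-row key for candidate lookup
state_keys <- function(states) {
  do.call(paste0, lapply(seq_len(ncol(states)), function(p) states[, p]))
}

check_enum_nodes <- function(nodes) {
  n <- length(nodes)
  if (n < 2 || n > 6) {
    abort("exhaustive enumeration supports 2 to 6 genes")
  }
  if (anyDuplicated(nodes)) abort("duplicate gene id in node list")
  n
}

#' Enumerate every candidate configuration on a small gene set
#'
#' Yields all `3^C(n,2)` assignments of an edge state - forward, backward or
#' absent - to every unordered gene pair, cyclic configurations included, in
#' a fixed deterministic order (pair index major; forward < backward <
#' absent). Three genes give 27 configurations, five give 59049.
#'
#' @param nodes Ordered character vector of 2 to 6 gene ids.
#' @return A tibble with columns `id` (enumeration position), `structure`
#'   (semicolon-separated edge string) and `acyclic`. The integer state
#'   matrix is attached as attribute `"states"` (one row per configuration,
#'   one column per pair), with `"nodes"` and `"pairs"` alongside.
#' @examples
#' nrow(enumerate_configurations(c("a", "b", "c"))) # 27
#' @export
enumerate_configurations <- function(nodes) {
  n <- check_enum_nodes(nodes)
  tab <- config_table(n)
  out <- tibble(
    id = seq_len(nrow(tab$states)),
    structure = structure_strings(tab$states, nodes, tab$pairs),
    acyclic = tab$acyclic
  )
  attr(out, "states") <- tab$states
  attr(out, "nodes") <- nodes
  attr(out, "pairs") <- tab$pairs
  out
}

#' Enumerate the acyclic candidate networks (DAGs) on a small gene set
#'
#' The subset of [enumerate_configurations()] rows whose edge set is acyclic,
#' in the same relative order: 25 DAGs for three genes, 29281 for five.
#'
#' @inheritParams enumerate_configurations
#' @return As [enumerate_configurations()], restricted to acyclic rows
#'   (`id` keeps the configuration-enumeration position).
#' @export
enumerate_dags <- function(nodes) {
  n <- check_enum_nodes(nodes)
  tab <- config_table(n)
  keep <- which(tab$acyclic)
  out <- tibble(
    id = keep,
    structure = structure_strings(tab$states[keep, , drop = FALSE], nodes, tab$pairs),
    acyclic = TRUE
  )
  attr(out, "states") <- tab$states[keep, , drop = FALSE]
  attr(out, "nodes") <- nodes
  attr(out, "pairs") <- tab$pairs
  out
}

# materialise one state row as a grn_network
states_to_network <- function(state_row, nodes, pairs, acyclic = NA) {
  present <- which(state_row != 3L)
  from <- ifelse(state_row[present] == 1L, pairs[1, present], pairs[2, present])
  to <- ifelse(state_row[present] == 1L, pairs[2, present], pairs[1, present])
  net <- grn_network(
    nodes,
    tibble(from = nodes[from], to = nodes[to]),
    acyclic = FALSE
  )
  if (isTRUE(acyclic)) net$acyclic <- TRUE
  net
}

# state vector of a network w.r.t. a node order and pair matrix
network_to_states <- function(net, nodes, pairs) {
  adj <- network_adjacency(net)[nodes, nodes]
  vapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    if (adj[i, j] == 1L && adj[j, i] == 1L) {
      abort("network assigns both directions to one pair; no single edge state")
    }
    if (adj[i, j] == 1L) 1L else if (adj[j, i] == 1L) 2L else 3L
  }, integer(1))
}

#' Extract one candidate network from an enumeration or ranking
#'
#' @param candidates Output of [enumerate_configurations()],
#'   [enumerate_dags()] or [rank_candidates()].
#' @param row Row number (not candidate id) to materialise.
#' @return A [grn_network()] (with `acyclic = FALSE` so cyclic candidates can
#'   be materialised too).
#' @export
candidate_network <- function(candidates, row) {
  states <- attr(candidates, "states")
  if (is.null(states)) abort("candidates carries no state matrix")
  if (row < 1 || row > nrow(states)) abort("row out of range")
  states_to_network(states[row, ], attr(candidates, "nodes"), attr(candidates, "pairs"))
}

#' Score and rank every DAG on a small gene set by exhaustive search
#'
#' Scores each network from [enumerate_dags()] with the Gaussian-equivalent
#' network score, sorts by log score (descending) and assigns ranks 1..K.
#' Exact ties keep enumeration order, so the ranking is deterministic.
#'
#' @param data Expression tibble (see [read_expression()]).
#' @param genes Ordered character vector of 2 to 6 gene ids; the scoring
#'   scope.
#' @param params [score_params()].
#' @return A tibble of class `grn_ranking` with columns `rank`, `id`
#'   (enumeration position), `log_score`, `weight` (posterior weight of the
#'   candidate within this gene set: scores softmaxed over all K DAGs) and
#'   `structure`; state matrix attributes as in [enumerate_dags()], rows
#'   aligned to the ranking.
#' @export
rank_candidates <- function(data, genes, params = score_params()) {
  n <- check_enum_nodes(genes)
  data <- validate_expression(data)
  tab <- config_table(n)
  keep <- which(tab$acyclic)
  states <- tab$states[keep, , drop = FALSE]
  scores <- score_state_rows(data, genes, states, tab$pairs, params)
  ord <- order(-scores, keep)
  out <- tibble(
    rank = seq_along(keep),
    id = keep[ord],
    log_score = scores[ord],
    weight = softmax_log(scores[ord]),
    structure = structure_strings(states[ord, , drop = FALSE], genes, tab$pairs)
  )
  attr(out, "states") <- states[ord, , drop = FALSE]
  attr(out, "nodes") <- genes
  attr(out, "pairs") <- tab$pairs
  class(out) <- c("grn_ranking", class(out))
  out
}

softmax_log <- function(ls) {
  w <- exp(ls - log_sum_exp(ls))
  w / sum(w)
}

# log network score of every state row (rows must be acyclic), vectorised
# through the 2^n subset marginals of the scoring context
score_state_rows <- function(data, genes, states, pairs, params) {
  n <- length(genes)
  ctx <- bge_context(data, genes, params)
  f_all <- vapply(0:(2^n - 1), function(mask) {
    ctx$f_subset(which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0))
  }, numeric(1))
  nr <- nrow(states)
  parent_mask <- matrix(0L, nr, n)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    s <- states[, p]
    parent_mask[, j] <- parent_mask[, j] + bitwShiftL(1L, i - 1L) * (s == 1L)
    parent_mask[, i] <- parent_mask[, i] + bitwShiftL(1L, j - 1L) * (s == 2L)
  }
  total <- numeric(nr)
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    total <- total + f_all[parent_mask[, v] + bit + 1L] - f_all[parent_mask[, v] + 1L]
  }
  total
}
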