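#' Unite per-triplet rankings into a single whole-gene network
#'
#' The union step of the triplet method. Every unordered gene pair is
#' assigned one of three states - forward edge, backward edge, or no edge -
#' by score voting: at rank level 1, each triplet containing the pair
#' contributes the weight of its best network to the state that network
#' assigns the pair, and the state with the strictly highest total wins.
#'
#' Ties escalate. A tied pair (x, y) first consults context: among triplets
#' {x, y, w} whose third gene w already has an edge with x or y in the
#' partially built network, the current-rank network with the highest weight
#' dictates the pair's state. If no such triplet exists (or their votes
#' cannot decide), the pair is revoted at the next rank level, and so on. A
#' pair still undecided past the stored ranks is set to absent with a
#' warning. Pairs are processed in lexicographic order within each sweep and
#' the partial network grows sequentially, so the result is a deterministic,
#' pure function of the store.
#'
#' The output network may contain directed cycles: each triplet is scored as
#' a DAG, but pairwise decisions stitched together over different triplets
#' are not jointly acyclicity-constrained.
#'
#' @param store A `tuple_store` from [build_tuple_store()] or
#'   [manual_tuple_store()].
#' @param raw_scores If `TRUE`, vote with raw log scores (log-sum-exp
#'   summation) instead of normalised within-triplet posterior weights.
#' @return An object of class `triplet_union`: a list with `network` (the
#'   united [grn_network()], cycles permitted), `decisions` (one row per
#'   pair: vote totals at the deciding rank, chosen state, `decided_at_rank`,
#'   `tie_break`), and the voting settings. [tidy()] returns the decision
#'   table, [glance()] a one-row summary, [autoplot()] the network drawing.
#' @examples
#' model <- random_planted_model(4, 0.5, seed = 2)
#' expr <- simulate_expression(model)
#' fit <- unite(build_tuple_store(expr, model$truth$nodes))
#' fit$network
#' @export
unite <- function(store, raw_scores = FALSE) {
  if (!inherits(store, "tuple_store")) abort("store must be a tuple_store")
  genes <- store$genes
  n <- length(genes)
  pairs <- pair_matrix(n)
  np <- ncol(pairs)

  state <- rep(NA_integer_, np) # decided edge state per pair
  decided_rank <- rep(NA_integer_, np)
  tie_break <- rep(FALSE, np)
  dec_totals <- matrix(NA_real_, np, 3)

  # adjacency of the partially built network (grows within sweeps)
  has_edge <- matrix(FALSE, n, n)
  commit <- function(p, st) {
    state[p] <<- st
    if (st != 3L) {
      i <- pairs[1, p]
      j <- pairs[2, p]
      has_edge[i, j] <<- TRUE
      has_edge[j, i] <<- TRUE
    }
  }

  rank <- 1L
  while (anyNA(state) && rank <= store$max_rank) {
    totals <- all_pair_totals(store, rank, raw_scores)
    for (p in which(is.na(state))) {
      tot <- totals[p, ]
      best <- which(tot == max(tot))
      if (length(best) == 1) {
        commit(p, best)
        decided_rank[p] <- rank
        dec_totals[p, ] <- tot
        next
      }
      # tie: consult triplets whose third gene already touches the pair
      pick <- tie_break_state(store, genes, pairs[1, p], pairs[2, p], rank, has_edge, raw_scores)
      if (!is.na(pick)) {
        commit(p, pick)
        decided_rank[p] <- rank
        tie_break[p] <- TRUE
        dec_totals[p, ] <- tot
      }
      # otherwise leave undecided; revoted at the next rank level
    }
    rank <- rank + 1L
  }
  if (anyNA(state)) {
    warn(paste0(
      sum(is.na(state)),
      " pair(s) still tied after rank ", store$max_rank, "; set to absent"
    ))
    for (p in which(is.na(state))) state[p] <- 3L
  }

  present <- which(state != 3L)
  edges <- tibble(
    from = genes[ifelse(state[present] == 1L, pairs[1, present], pairs[2, present])],
    to = genes[ifelse(state[present] == 1L, pairs[2, present], pairs[1, present])]
  )
  decisions <- tibble(
    from = genes[pairs[1, ]],
    to = genes[pairs[2, ]],
    forward = dec_totals[, 1],
    backward = dec_totals[, 2],
    absent = dec_totals[, 3],
    chosen = c("forward", "backward", "absent")[state],
    decided_at_rank = decided_rank,
    tie_break = tie_break
  )
  structure(
    list(
      network = grn_network(genes, edges, acyclic = FALSE),
      decisions = decisions,
      max_rank = store$max_rank,
      raw_scores = raw_scores,
      n_undecided = sum(is.na(decided_rank))
    ),
    class = "triplet_union"
  )
}

# Tie-break for pair (i, j) at one rank level: among triplets {i, j, w} where
# w already has an edge with i or j in the partial network, adopt the pair
# state of the single highest-weight rank-level network. NA if no qualifying
# triplet or the qualifying votes are themselves exactly tied.
tie_break_state <- function(store, genes, i, j, rank, has_edge, raw_scores) {
  e <- store$entries[store$entries$rank == rank, , drop = FALSE]
  gi <- cbind(match(e$g1, genes), match(e$g2, genes), match(e$g3, genes))
  slot <- integer(nrow(e))
  w_idx <- integer(nrow(e))
  for (r in seq_len(nrow(e))) {
    trip <- gi[r, ]
    if (!(i %in% trip) || !(j %in% trip)) next
    w <- setdiff(trip, c(i, j))
    pos <- sort(match(c(i, j), trip))
    slot[r] <- c("12" = 1L, "13" = 2L, "23" = 3L)[paste0(pos[1], pos[2])]
    w_idx[r] <- w
  }
  cand <- which(slot > 0)
  qual <- cand[has_edge[cbind(w_idx[cand], i)] | has_edge[cbind(w_idx[cand], j)]]
  if (length(qual) == 0) return(NA_integer_)
  value <- if (raw_scores) e$log_score[qual] else e$weight[qual]
  top <- qual[which(value == max(value))]
  states <- cbind(e$s12, e$s13, e$s23)[cbind(top, slot[top])]
  if (length(unique(states)) > 1) return(NA_integer_) # equal-weight conflict
  states[1]
}

#' @export
print.triplet_union <- function(x, ...) {
  cat("<triplet_union>\n")
  print(x$network)
  cat(
    "decided by tie-break:", sum(x$decisions$tie_break),
    "| undecided fallback:", x$n_undecided, "\n"
  )
  invisible(x)
}

#' @rdname unite
#' @param x A `triplet_union`.
#' @param ... Unused.
#' @export
tidy.triplet_union <- function(x, ...) {
  x$decisions
}

#' @rdname unite
#' @export
glance.triplet_union <- function(x, ...) {
  tibble(
    n_genes = length(x$network$nodes),
    n_edges = nrow(x$network$edges),
    acyclic = is_acyclic(x$network),
    n_tie_break = sum(x$decisions$tie_break),
    n_undecided = x$n_undecided,
    max_rank = x$max_rank,
    max_rank_used = max(c(x$decisions$decided_at_rank, 1L), na.rm = TRUE)
  )
}

#' @rdname unite
#' @param object A `triplet_union`.
#' @export
autoplot.triplet_union <- function(object, ...) {
  autoplot(object$network, ...)
}

#' Infer a gene regulatory network by triplet decomposition and union
#'
#' One-call front door: builds the tuple store over all 3-gene subsets of
#' `genes` with [build_tuple_store()] and unites it with [unite()].
#'
#' @inheritParams build_tuple_store
#' @inheritParams unite
#' @return A `triplet_union` (see [unite()]).
#' @export
infer_network <- function(data, genes = NULL, params = score_params(),
                          max_rank = 25L, raw_scores = FALSE) {
  data <- validate_expression(data)
  genes <- genes %||% data$gene
  unite(build_tuple_store(data, genes, params, max_rank), raw_scores = raw_scores)
}
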