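# Triplet decomposition: the whole-gene problem is divided into all 3-gene
# subsets, each scored exhaustively, and the ranked candidates of every
# triplet are collected into a tuple store - the sole input to unite().

#' List all 3-gene subsets of a gene set
#'
#' @param genes Ordered character vector of at least 3 distinct gene ids.
#' @return A tibble with one row per triplet (`C(n, 3)` rows, lexicographic
#'   index order) and columns `triplet` (integer id) and `g1`, `g2`, `g3`
#'   (gene ids, in gene-list order).
#' @examples
#' nrow(make_triplets(paste0("g", 1:5))) # 10
#' @export
make_triplets <- function(genes) {
  if (length(genes) < 3) abort("triplet decomposition needs at least 3 genes")
  if (anyDuplicated(genes)) abort("duplicate gene id in gene list")
  idx <- combn(length(genes), 3)
  tibble(
    triplet = seq_len(ncol(idx)),
    g1 = genes[idx[1, ]],
    g2 = genes[idx[2, ]],
    g3 = genes[idx[3, ]]
  )
}

new_tuple_store <- function(genes, entries, max_rank, dags_per_triplet = 25L) {
  n_triplets <- length(unique(entries$triplet))
  structure(
    list(
      genes = genes,
      entries = entries,
      max_rank = max_rank,
      n_triplets = n_triplets,
      candidate_slots = n_triplets * 27L,
      scored_entries = nrow(entries)
    ),
    class = "tuple_store"
  )
}

#' @export
print.tuple_store <- function(x, ...) {
  cat(
    "<tuple_store> ", length(x$genes), " genes, ", x$n_triplets,
    " triplets, max rank ", x$max_rank, "\n",
    "  candidate slots (3 states per pair): ", x$candidate_slots, "\n",
    "  scored DAG entries stored: ", x$scored_entries, "\n",
    sep = ""
  )
  invisible(x)
}

#' Build the tuple store of ranked triplet networks
#'
#' Runs the exhaustive 25-DAG search of [rank_candidates()] on every 3-gene
#' subset and stores, per triplet, the tuples (network, log score, rank) for
#' ranks `1..max_rank`. Candidate weights are the within-triplet posterior
#' weights (softmax over all 25 DAGs of that triplet), computed before any
#' rank truncation.
#'
#' For five genes the store spans 10 triplets; counted as 27 edge-state
#' configurations per triplet that is 270 candidate slots
#' (`$candidate_slots`), of which the 25 acyclic candidates per triplet are
#' scored (`$scored_entries` = 250 at full `max_rank`).
#'
#' @param data Expression tibble (see [read_expression()]).
#' @param genes Ordered character vector of at least 3 gene ids; pair
#'   orientation ("forward" = earlier gene to later gene) follows this order.
#' @param params [score_params()]; each triplet is scored in its own 3-gene
#'   scope.
#' @param max_rank How many ranks to keep per triplet (1 to 25; default 25).
#'   Ranks beyond 1 are consulted only to break voting ties.
#' @return A `tuple_store`: gene list plus an entries tibble with columns
#'   `triplet`, `g1` `g2` `g3` (triplet genes), `rank`, `log_score`,
#'   `weight`, and the pair edge states `s12`, `s13`, `s23` (1 forward,
#'   2 backward, 3 absent).
#' @export
build_tuple_store <- function(data, genes, params = score_params(), max_rank = 25L) {
  data <- validate_expression(data)
  if (max_rank < 1 || max_rank > 25) abort("max_rank must lie in 1..25")
  trips <- make_triplets(genes)
  miss <- setdiff(genes, data$gene)
  if (length(miss) > 0) abort(paste0("gene not found in expression data: ", miss[1]))
  entries <- pmap(trips, function(triplet, g1, g2, g3) {
    trip_genes <- c(g1, g2, g3)
    ranking <- tryCatch(
      rank_candidates(data, trip_genes, params),
      error = function(e) {
        abort(paste0(
          "scoring failed for triplet {", paste(trip_genes, collapse = ", "),
          "}: ", conditionMessage(e)
        ))
      }
    )
    keep <- seq_len(min(max_rank, nrow(ranking)))
    st <- attr(ranking, "states")
    tibble(
      triplet = triplet, g1 = g1, g2 = g2, g3 = g3,
      rank = ranking$rank[keep],
      log_score = ranking$log_score[keep],
      weight = ranking$weight[keep],
      s12 = st[keep, 1], s13 = st[keep, 2], s23 = st[keep, 3]
    )
  })
  new_tuple_store(genes, bind_rows(entries), as.integer(max_rank))
}

#' Assemble a tuple store by hand
#'
#' Builds a `tuple_store` from explicitly specified entries instead of data -
#' the tool for constructing voting fixtures (ties, cyclic unions) with known
#' weights.
#'
#' @param genes Ordered character vector of gene ids.
#' @param entries A data frame with columns `g1`, `g2`, `g3` (the triplet's
#'   genes, in `genes` order), `rank`, `weight`, `structure` (edge string
#'   over the triplet, e.g. `"a->b;c->b"`, `""` for edgeless) and optionally
#'   `log_score` (defaults to `log(weight)`).
#' @return A `tuple_store`.
#' @export
manual_tuple_store <- function(genes, entries) {
  entries <- as_tibble(entries)
  trips <- make_triplets(genes)
  entries <- left_join(entries, trips, by = c("g1", "g2", "g3"))
  if (any(is.na(entries$triplet))) {
    abort("entry triplet not a valid (g1 < g2 < g3 in gene order) subset")
  }
  if (!"log_score" %in% names(entries)) entries$log_score <- log(entries$weight)
  states <- map(seq_len(nrow(entries)), function(r) {
    trip_genes <- c(entries$g1[r], entries$g2[r], entries$g3[r])
    net <- parse_structure(entries$structure[r], trip_genes)
    network_to_states(net, trip_genes, pair_matrix(3))
  })
  entries$s12 <- map_int(states, 1)
  entries$s13 <- map_int(states, 2)
  entries$s23 <- map_int(states, 3)
  entries <- entries[, c(
    "triplet", "g1", "g2", "g3", "rank", "log_score", "weight",
    "s12", "s13", "s23"
  )]
  if (anyDuplicated(entries[, c("triplet", "rank")])) {
    abort("each (triplet, rank) may appear only once")
  }
  new_tuple_store(genes, arrange(entries, .data$triplet, .data$rank),
                  max(entries$rank))
}

# "a->b;c->b" -> grn_network over `nodes` (cycles allowed)
parse_structure <- function(structure, nodes) {
  structure <- trimws(structure)
  if (!nzchar(structure)) return(grn_network(nodes, NULL, acyclic = FALSE))
  parts <- strsplit(strsplit(structure, ";", fixed = TRUE)[[1]], "->", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) abort(paste0("malformed edge: ", structure))
  grn_network(
    nodes,
    tibble(from = trimws(map_chr(parts, 1)), to = trimws(map_chr(parts, 2))),
    acyclic = FALSE
  )
}

# vote totals for every unordered pair at one rank level: n_pairs x 3 matrix
# (columns forward/backward/absent). Normalised mode sums posterior weights;
# raw mode log-sum-exps the raw log scores (literal score summation, kept on
# the log scale).
all_pair_totals <- function(store, rank, raw_scores = FALSE) {
  genes <- store$genes
  n <- length(genes)
  pairs <- pair_matrix(n)
  np <- ncol(pairs)
  e <- store$entries[store$entries$rank == rank, , drop = FALSE]
  gi1 <- match(e$g1, genes)
  gi2 <- match(e$g2, genes)
  gi3 <- match(e$g3, genes)
  pair_id <- matrix(0L, n, n)
  pair_id[cbind(pairs[1, ], pairs[2, ])] <- seq_len(np)
  slots <- cbind(
    pair_id[cbind(gi1, gi2)],
    pair_id[cbind(gi1, gi3)],
    pair_id[cbind(gi2, gi3)]
  )
  state_cols <- cbind(e$s12, e$s13, e$s23)
  if (raw_scores) {
    totals <- matrix(-Inf, np, 3)
    for (slot in 1:3) {
      for (st in 1:3) {
        sel <- state_cols[, slot] == st
        if (!any(sel)) next
        agg <- tapply(e$log_score[sel], slots[sel, slot], log_sum_exp)
        ids <- as.integer(names(agg))
        totals[ids, st] <- ifelse(
          is.finite(totals[ids, st]),
          mapply(function(a, b) log_sum_exp(c(a, b)), totals[ids, st], agg),
          agg
        )
      }
    }
  } else {
    totals <- matrix(0, np, 3)
    for (slot in 1:3) {
      for (st in 1:3) {
        sel <- state_cols[, slot] == st
        if (!any(sel)) next
        agg <- tapply(e$weight[sel], slots[sel, slot], sum)
        totals[as.integer(names(agg)), st] <- totals[as.integer(names(agg)), st] + agg
      }
    }
  }
  colnames(totals) <- c("forward", "backward", "absent")
  totals
}

#' Edge-type vote totals for one gene pair
#'
#' Every triplet containing the pair casts one vote at the given rank level:
#' the weight of its rank-`rank` network is added to whichever of the three
#' edge states that network assigns the pair. The chosen state is the strict
#' maximiser, or undecided (`NA`) on a tie.
#'
#' @param store A `tuple_store`.
#' @param pair Character vector of two gene ids.
#' @param rank Rank level to vote with (default 1).
#' @param raw_scores If `TRUE`, sum raw scores in log space instead of
#'   normalised within-triplet weights.
#' @return A one-row tibble: `from`, `to` (the pair, oriented by gene-list
#'   order), `forward`, `backward`, `absent` (totals), `chosen` (one of
#'   `"forward"`, `"backward"`, `"absent"` or `NA` for an exact tie) and
#'   `rank`.
#' @export
edge_type_totals <- function(store, pair, rank = 1L, raw_scores = FALSE) {
  genes <- store$genes
  if (length(pair) != 2 || !all(pair %in% genes)) {
    abort("pair must name two genes present in the store")
  }
  if (rank < 1 || rank > store$max_rank) abort("rank outside the stored range")
  idx <- sort(match(pair, genes))
  pairs <- pair_matrix(length(genes))
  p <- which(pairs[1, ] == idx[1] & pairs[2, ] == idx[2])
  totals <- all_pair_totals(store, rank, raw_scores)[p, ]
  best <- which(totals == max(totals))
  tibble(
    from = genes[idx[1]],
    to = genes[idx[2]],
    forward = totals[["forward"]],
    backward = totals[["backward"]],
    absent = totals[["absent"]],
    chosen = if (length(best) == 1) c("forward", "backward", "absent")[best] else NA_character_,
    rank = as.integer(rank)
  )
}
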