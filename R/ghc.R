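# Greedy hill climbing over DAGs: the reference local-search baseline the
# triplet-union method is compared against.

#' Greedy hill-climbing search parameters
#'
#' The default parameter set caps the search at 50 accepted actions (edge
#' additions, deletions or reversals) with no restarts; the "high accuracy"
#' setting used for comparison raises these to 100 actions and 10 restarts.
#'
#' @param max_actions Maximum number of accepted moves per start
#'   (non-negative; default 50).
#' @param restarts Number of additional independent random starts
#'   (non-negative; default 0).
#' @param seed Integer seed making the whole search reproducible.
#' @return An object of class `ghc_params`.
#' @export
ghc_params <- function(max_actions = 50L, restarts = 0L, seed = 1L) {
  if (max_actions < 0 || restarts < 0) {
    abort("max_actions and restarts must be non-negative")
  }
  structure(
    list(
      max_actions = as.integer(max_actions),
      restarts = as.integer(restarts),
      seed = as.integer(seed)
    ),
    class = "ghc_params"
  )
}

#' Sample a random initial DAG
#'
#' Draws a uniformly random permutation as a topological order, then includes
#' each order-respecting edge independently with probability `edge_prob`.
#' Every DAG on the genes has positive probability; the draw is reproducible
#' from the seed and leaves the caller's RNG state untouched.
#'
#' @param genes Ordered character vector of gene ids.
#' @param seed Integer seed.
#' @param edge_prob Inclusion probability of each order-respecting edge
#'   (default 0.5).
#' @return An acyclic [grn_network()].
#' @export
random_initial_dag <- function(genes, seed, edge_prob = 0.5) {
  n <- length(genes)
  if (n < 1) abort("need at least one gene")
  with_local_seed(seed, {
    perm <- sample.int(n)
    edges <- list(from = character(0), to = character(0))
    if (n >= 2) {
      idx <- combn(n, 2)
      take <- runif(ncol(idx)) < edge_prob
      edges <- list(
        from = genes[perm[idx[1, take]]],
        to = genes[perm[idx[2, take]]]
      )
    }
    grn_network(genes, tibble(from = edges$from, to = edges$to), acyclic = TRUE)
  })
}

# is `to` reachable from `from` in 0/1 adjacency matrix?
adj_reachable <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- rep(FALSE, nrow(adj))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Greedy hill climbing over network structures
#'
#' From a random initial DAG, repeatedly evaluates every neighbour that
#' differs by a single directed edge - one added, deleted or reversed -
#' discards neighbours that would create a cycle, and accepts the move with
#' the strictly largest score improvement. The search stops when no move
#' improves the score or the action budget is spent. With `restarts = r`, it
#' performs `r + 1` independent starts and returns the best result. Neighbour
#' ties are broken by a fixed enumeration order, so runs are
#' seed-reproducible.
#'
#' @param data Expression tibble (see [read_expression()]).
#' @param genes Ordered character vector of gene ids (the scoring scope);
#'   defaults to all genes in `data`.
#' @param params [ghc_params()].
#' @param score_params [score_params()], or `NULL` for the defaults.
#' @return An object of class `ghc_fit`: `network` (the best DAG found),
#'   `log_score`, and `restarts`, a tibble with one row per start (`restart`,
#'   `initial_score`, `log_score`, `n_moves`, `trajectory` list-column of
#'   accepted-move scores). [tidy()] returns the per-restart table,
#'   [glance()] a one-row summary.
#' @examples
#' expr <- simulate_expression(random_planted_model(4, 0.5, seed = 3))
#' ghc_search(expr, params = ghc_params(seed = 1))$log_score
#' @export
ghc_search <- function(data, genes = NULL, params = ghc_params(),
                       score_params = NULL) {
  data <- validate_expression(data)
  genes <- genes %||% data$gene
  n <- length(genes)
  ctx <- bge_context(data, genes, score_params %||% trigrn::score_params())

  one_start <- function(start_net) {
    adj <- network_adjacency(start_net)
    local <- vapply(seq_len(n), function(v) ctx$node_score(v, which(adj[, v] == 1L)),
                    numeric(1))
    score <- sum(local)
    trajectory <- score
    moves <- 0L
    while (moves < params$max_actions) {
      best_gain <- 0
      best_move <- NULL
      for (u in seq_len(n)) {
        for (v in seq_len(n)) {
          if (u == v) next
          if (adj[u, v] == 1L) {
            # delete u -> v
            gain <- ctx$node_score(v, setdiff(which(adj[, v] == 1L), u)) - local[v]
            if (gain > best_gain) {
              best_gain <- gain
              best_move <- list(type = "delete", u = u, v = v)
            }
            # reverse u -> v (legal iff no other path u ~> v)
            adj[u, v] <- 0L
            legal <- !adj_reachable(adj, u, v)
            if (legal) {
              gain <- (ctx$node_score(v, which(adj[, v] == 1L)) - local[v]) +
                (ctx$node_score(u, c(which(adj[, u] == 1L), v)) - local[u])
              if (gain > best_gain) {
                best_gain <- gain
                best_move <- list(type = "reverse", u = u, v = v)
              }
            }
            adj[u, v] <- 1L
          } else if (adj[v, u] == 0L) {
            # add u -> v (legal iff v cannot already reach u)
            if (!adj_reachable(adj, v, u)) {
              gain <- ctx$node_score(v, c(which(adj[, v] == 1L), u)) - local[v]
              if (gain > best_gain) {
                best_gain <- gain
                best_move <- list(type = "add", u = u, v = v)
              }
            }
          }
        }
      }
      if (is.null(best_move)) break
      u <- best_move$u
      v <- best_move$v
      if (best_move$type == "add") {
        adj[u, v] <- 1L
      } else if (best_move$type == "delete") {
        adj[u, v] <- 0L
      } else {
        adj[u, v] <- 0L
        adj[v, u] <- 1L
      }
      local[v] <- ctx$node_score(v, which(adj[, v] == 1L))
      if (best_move$type == "reverse") {
        local[u] <- ctx$node_score(u, which(adj[, u] == 1L))
      }
      score <- sum(local)
      trajectory <- c(trajectory, score)
      moves <- moves + 1L
    }
    edges <- which(adj == 1L, arr.ind = TRUE)
    list(
      network = grn_network(
        genes,
        tibble(from = genes[edges[, 1]], to = genes[edges[, 2]]),
        acyclic = TRUE
      ),
      log_score = score,
      n_moves = moves,
      trajectory = trajectory
    )
  }

  runs <- map(seq_len(params$restarts + 1L), function(r) {
    start <- random_initial_dag(genes, derive_seed(params$seed, paste0("ghc-start-", r)))
    res <- one_start(start)
    res$restart <- r
    res$initial_score <- res$trajectory[1]
    res
  })
  restarts <- tibble(
    restart = map_int(runs, "restart"),
    initial_score = map_dbl(runs, "initial_score"),
    log_score = map_dbl(runs, "log_score"),
    n_moves = map_int(runs, "n_moves"),
    trajectory = map(runs, "trajectory")
  )
  best <- runs[[which.max(restarts$log_score)]]
  structure(
    list(
      network = best$network,
      log_score = best$log_score,
      restarts = restarts,
      params = params
    ),
    class = "ghc_fit"
  )
}

#' @export
print.ghc_fit <- function(x, ...) {
  cat("<ghc_fit> log score", format(x$log_score), "after",
      nrow(x$restarts), "start(s)\n")
  print(x$network)
  invisible(x)
}

#' @rdname ghc_search
#' @param x,object A `ghc_fit`.
#' @param ... Unused.
#' @export
tidy.ghc_fit <- function(x, ...) {
  select(x$restarts, -"trajectory")
}

#' @rdname ghc_search
#' @export
glance.ghc_fit <- function(x, ...) {
  tibble(
    log_score = x$log_score,
    n_edges = nrow(x$network$edges),
    n_starts = nrow(x$restarts),
    max_actions = x$params$max_actions,
    budget_exhausted = any(x$restarts$n_moves == x$params$max_actions)
  )
}

#' @rdname ghc_search
#' @export
autoplot.ghc_fit <- function(object, ...) {
  df <- object$restarts |>
    mutate(trajectory = map(.data$trajectory, ~ tibble(step = seq_along(.x) - 1, log_score = .x))) |>
    select("restart", "trajectory") |>
    tidyr::unnest("trajectory")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$step, y = .data$log_score,
    group = .data$restart, colour = factor(.data$restart)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "accepted moves", y = "log network score", colour = "start") +
    ggplot2::theme_minimal()
}
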