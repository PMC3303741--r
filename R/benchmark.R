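# Synthetic-data benchmark: planted linear-Gaussian networks, expression
# simulation, and the two evaluation instruments - position in the
# exhaustive ranking, and sensitivity/selectivity against the known truth.

#' Sample a planted regulatory model
#'
#' Draws a random DAG (uniform random topological order, each
#' order-respecting edge included with probability `edge_prob`) and equips
#' every edge with a linear coefficient of random sign and magnitude uniform
#' in `beta_range`. Together with the noise level and sample count this fully
#' specifies the linear-Gaussian generative model used by
#' [simulate_expression()].
#'
#' The defaults define the strong-signal benchmark regime: coefficient
#' magnitudes in `[0.8, 1.2]`, noise standard deviation 0.5, 100 samples.
#'
#' @param n_genes Number of genes (named `g1`, `g2`, ...).
#' @param edge_prob Probability that each order-respecting gene pair carries
#'   an edge, strictly between 0 and 1.
#' @param beta_range Length-2 numeric, `0 < min <= max`: coefficient
#'   magnitude bounds.
#' @param noise_sd Standard deviation of each gene's independent Gaussian
#'   noise term.
#' @param n_samples Number of independent samples to simulate.
#' @param seed Integer seed; the model is a pure function of its arguments.
#' @return An object of class `planted_model`: `truth` (a DAG
#'   [grn_network()]), `coefficients` (tibble `from`, `to`, `beta`),
#'   `noise_sd`, `n_samples`, `seed`.
#' @export
random_planted_model <- function(n_genes, edge_prob, beta_range = c(0.8, 1.2),
                                 noise_sd = 0.5, n_samples = 100L, seed = 1L) {
  if (edge_prob <= 0 || edge_prob >= 1) {
    abort("edge_prob must lie strictly between 0 and 1")
  }
  if (length(beta_range) != 2 || beta_range[1] <= 0 || beta_range[1] > beta_range[2]) {
    abort("beta_range must be 0 < min <= max")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  genes <- paste0("g", seq_len(n_genes))
  truth <- random_initial_dag(genes, derive_seed(seed, "planted-structure"),
                              edge_prob = edge_prob)
  coefficients <- with_local_seed(derive_seed(seed, "planted-coefficients"), {
    k <- nrow(truth$edges)
    mutate(
      truth$edges,
      beta = sample(c(-1, 1), k, replace = TRUE) *
        runif(k, beta_range[1], beta_range[2])
    )
  })
  structure(
    list(
      truth = truth, coefficients = coefficients,
      noise_sd = noise_sd, n_samples = as.integer(n_samples),
      seed = as.integer(seed)
    ),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat("<planted_model> ", length(x$truth$nodes), " genes, ",
      nrow(x$truth$edges), " edges, sd ", x$noise_sd, ", m ", x$n_samples,
      "\n", sep = "")
  invisible(x)
}

#' Simulate expression data from a planted model
#'
#' Each sample is drawn by traversing the planted DAG in topological order:
#' `x_v = sum(beta_uv * x_u) + eps_v` over the parents `u` of `v`, with
#' `eps_v ~ Normal(0, noise_sd^2)`. Samples are i.i.d.; two calls on the same
#' model give identical matrices.
#'
#' @param model A [random_planted_model()].
#' @return An expression tibble (column `gene` plus sample columns `s1`,
#'   `s2`, ...), ready for [build_tuple_store()] and friends.
#' @export
simulate_expression <- function(model) {
  genes <- model$truth$nodes
  n <- length(genes)
  m <- model$n_samples
  adj <- network_adjacency(model$truth)
  beta <- matrix(0, n, n)
  if (nrow(model$coefficients) > 0) {
    beta[cbind(
      match(model$coefficients$from, genes),
      match(model$coefficients$to, genes)
    )] <- model$coefficients$beta
  }
  x <- with_local_seed(derive_seed(model$seed, "expression-noise"), {
    eps <- matrix(rnorm(m * n, sd = model$noise_sd), m, n)
    x <- matrix(0, m, n)
    for (v in adjacency_topo_order(adj)) {
      pa <- which(adj[, v] == 1L)
      x[, v] <- eps[, v] + if (length(pa) > 0) x[, pa, drop = FALSE] %*% beta[pa, v] else 0
    }
    x
  })
  out <- as_tibble(setNames(as.data.frame(t(x)), paste0("s", seq_len(m))))
  dplyr::bind_cols(tibble(gene = genes), out)
}

#' Position of an estimated network in an exhaustive ranking
#'
#' Looks an estimated structure up in the full score ranking of all DAGs on
#' the same genes - the evaluation used to compare search methods against
#' exhaustive search. A cyclic estimate (possible for the union method on
#' more than 3 genes) has no position in a DAG ranking and is reported as
#' not rankable (`NA`).
#'
#' @param estimated A [grn_network()] on the ranking's gene set.
#' @param ranking A `grn_ranking` from [rank_candidates()].
#' @return The 1-based rank as an integer, or `NA` if the network is not in
#'   the ranking (cyclic).
#' @export
rank_in_exhaustive <- function(estimated, ranking) {
  nodes <- attr(ranking, "nodes")
  if (!setequal(estimated$nodes, nodes)) {
    abort("estimated network and ranking are over different gene sets")
  }
  if (!is_acyclic(estimated)) {
    return(NA_integer_)
  }
  st <- network_to_states(estimated, nodes, attr(ranking, "pairs"))
  hit <- match(paste0(st, collapse = ""), state_keys(attr(ranking, "states")))
  if (is.na(hit)) {
    return(NA_integer_)
  }
  ranking$rank[hit]
}

#' Directed-edge sensitivity and selectivity against a known network
#'
#' Strict directed matching: an estimated edge is a true positive only if
#' the same ordered pair is in the truth. Estimated edges whose reverse is a
#' truth edge are counted separately as `reversed_edges` but still count as
#' false positives (and their truth counterparts as false negatives).
#'
#' @param estimated,truth [grn_network()] objects on the same node set.
#' @return A one-row tibble: `sensitivity` (`tp / (tp + fn)`), `selectivity`
#'   (`tp / (tp + fp)`, i.e. precision), `tp`, `fp`, `fn`, `reversed_edges`.
#'   A ratio with a zero denominator is `NA`.
#' @examples
#' a <- grn_network(c("x", "y"), data.frame(from = "x", to = "y"))
#' b <- grn_network(c("x", "y"), data.frame(from = "y", to = "x"))
#' sensitivity_selectivity(b, a)
#' @export
sensitivity_selectivity <- function(estimated, truth) {
  if (!setequal(estimated$nodes, truth$nodes)) {
    abort("estimated and truth networks are over different gene sets")
  }
  est <- paste(estimated$edges$from, estimated$edges$to)
  tru <- paste(truth$edges$from, truth$edges$to)
  rev_tru <- paste(truth$edges$to, truth$edges$from)
  tp <- sum(est %in% tru)
  fp <- sum(!est %in% tru)
  fn <- sum(!tru %in% est)
  tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    selectivity = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn,
    reversed_edges = sum(est %in% rev_tru)
  )
}

#' Head-to-head benchmark of union versus greedy hill climbing
#'
#' For each replicate: sample a planted model, simulate expression, run the
#' triplet-union method and greedy hill climbing on the identical data, and
#' evaluate both against the planted truth. For gene sets small enough to
#' enumerate (`n_genes <= 5` by default) both estimates are also located in
#' the exhaustive score ranking of all DAGs.
#'
#' @param n_genes Number of genes per replicate (>= 3).
#' @param n_replicates Number of independent replicates.
#' @param edge_prob Planted edge probability (default 0.3).
#' @param beta_range,noise_sd,n_samples Generative settings, as in
#'   [random_planted_model()].
#' @param max_rank Ranks stored per triplet for the union method.
#' @param ghc [ghc_params()] for the baseline (its `seed` field is ignored;
#'   per-replicate seeds are derived from `seed`).
#' @param score_params [score_params()] shared by all methods.
#' @param exhaustive Whether to compute the exhaustive ranking per replicate
#'   (defaults to `n_genes <= 5`).
#' @param seed Global integer seed; everything is derived from it.
#' @return An object of class `grn_comparison`: `replicates` (one row per
#'   replicate and method: sensitivity/selectivity columns, `acyclic`,
#'   `exhaustive_rank` with `NA` for non-rankable cyclic unions, and
#'   `rank_worst_case` where those `NA`s are charged the worst rank + 1) and
#'   `summary` (per-method means with standard errors and median ranks).
#'   [tidy()] returns the replicate table, [glance()] a one-row overview.
#' @export
run_comparison <- function(n_genes, n_replicates = 20L, edge_prob = 0.3,
                           beta_range = c(0.8, 1.2), noise_sd = 0.5,
                           n_samples = 100L, max_rank = 25L,
                           ghc = ghc_params(), score_params = NULL,
                           exhaustive = n_genes <= 5, seed = 1L) {
  if (n_genes < 3) abort("comparison needs at least 3 genes")
  score_params <- score_params %||% trigrn::score_params()
  genes <- paste0("g", seq_len(n_genes))
  rows <- map(seq_len(n_replicates), function(rep) {
    model <- random_planted_model(
      n_genes, edge_prob, beta_range, noise_sd, n_samples,
      seed = derive_seed(seed, paste0("replicate-", rep))
    )
    expr <- simulate_expression(model)
    fit_u <- infer_network(expr, genes, score_params, max_rank)
    fit_g <- ghc_search(
      expr, genes,
      ghc_params(ghc$max_actions, ghc$restarts,
                 seed = derive_seed(seed, paste0("ghc-", rep))),
      score_params
    )
    ranking <- if (exhaustive) rank_candidates(expr, genes, score_params)
    eval_one <- function(method, net) {
      ev <- sensitivity_selectivity(net, model$truth)
      ev$method <- method
      ev$replicate <- rep
      ev$n_edges <- nrow(net$edges)
      ev$acyclic <- is_acyclic(net)
      ev$exhaustive_rank <- if (exhaustive) rank_in_exhaustive(net, ranking) else NA_integer_
      ev$n_ranked <- if (exhaustive) nrow(ranking) else NA_integer_
      ev
    }
    bind_rows(
      eval_one("union", fit_u$network),
      eval_one("ghc", fit_g$network)
    )
  })
  replicates <- bind_rows(rows) |>
    mutate(rank_worst_case = ifelse(
      is.na(.data$exhaustive_rank), .data$n_ranked + 1L, .data$exhaustive_rank
    )) |>
    select(
      "replicate", "method", "sensitivity", "selectivity", "tp", "fp", "fn",
      "reversed_edges", "n_edges", "acyclic", "exhaustive_rank",
      "rank_worst_case", "n_ranked"
    )
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summary <- replicates |>
    group_by(.data$method) |>
    summarise(
      sensitivity_mean = mean(.data$sensitivity, na.rm = TRUE),
      sensitivity_se = se(.data$sensitivity),
      selectivity_mean = mean(.data$selectivity, na.rm = TRUE),
      selectivity_se = se(.data$selectivity),
      median_rank = median(.data$rank_worst_case),
      top_decile_rate = if (exhaustive) {
        mean(.data$rank_worst_case <= 0.1 * .data$n_ranked)
      } else NA_real_,
      n_cyclic = sum(!.data$acyclic),
      .groups = "drop"
    )
  structure(
    list(
      replicates = replicates,
      summary = summary,
      settings = list(
        n_genes = n_genes, n_replicates = n_replicates, edge_prob = edge_prob,
        beta_range = beta_range, noise_sd = noise_sd, n_samples = n_samples,
        max_rank = max_rank, ghc = ghc, exhaustive = exhaustive, seed = seed
      )
    ),
    class = "grn_comparison"
  )
}

#' @export
print.grn_comparison <- function(x, ...) {
  cat("<grn_comparison>", x$settings$n_replicates, "replicates,",
      x$settings$n_genes, "genes\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_comparison
#' @param x,object A `grn_comparison`.
#' @param ... Unused.
#' @export
tidy.grn_comparison <- function(x, ...) {
  x$replicates
}

#' @rdname run_comparison
#' @export
glance.grn_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary,
    names_from = "method",
    values_from = -"method",
    names_glue = "{method}_{.value}"
  )
  dplyr::bind_cols(
    tibble(
      n_genes = x$settings$n_genes,
      n_replicates = x$settings$n_replicates
    ),
    wide
  )
}

#' @rdname run_comparison
#' @export
autoplot.grn_comparison <- function(object, ...) {
  df <- object$replicates
  if (object$settings$exhaustive) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_worst_case)) +
      ggplot2::geom_histogram(bins = 30, boundary = 0) +
      ggplot2::facet_wrap(~method, ncol = 1) +
      ggplot2::labs(
        x = "position in exhaustive score ranking (worst-case for cyclic)",
        y = "replicates"
      ) +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(
      df, c("sensitivity", "selectivity"),
      names_to = "metric", values_to = "value"
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~metric) +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  }
}
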