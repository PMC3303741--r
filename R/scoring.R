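#' Hyperparameters of the Gaussian-equivalent network score
#'
#' The score is the BGe marginal likelihood: each gene's expression is
#' modelled as Gaussian given its parents, and parameters are integrated out
#' under a conjugate normal-Wishart prior. The defaults follow the standard
#' weakly-informative choice: with `am = 1` and `aw = n_vars + 2` the default
#' `prior_scale` `am * (aw - n_vars - 1) / (am + 1) * I` makes the implied
#' prior covariance of each gene the identity.
#'
#' `aw` defaults to `n_vars + 2` and `prior_mean` to the per-gene sample
#' means; both are resolved when the score is bound to a concrete gene scope,
#' so `NULL` here means "use the default for that scope".
#'
#' @param am Positive prior precision on the mean (default 1).
#' @param aw Prior degrees of freedom; must exceed `n_vars - 1`. `NULL` means
#'   `n_vars + 2`.
#' @param prior_mean Numeric vector of prior means per gene in scope, or
#'   `NULL` for the per-gene sample means.
#' @param prior_scale Positive-definite prior scale matrix, or a single
#'   number for a scalar multiple of the identity, or `NULL` for the default
#'   above.
#' @param structure_prior Structure prior over DAGs; only `"uniform"` is
#'   supported (a constant that cancels in all rankings).
#' @return An object of class `score_params`.
#' @export
score_params <- function(am = 1, aw = NULL, prior_mean = NULL,
                         prior_scale = NULL, structure_prior = "uniform") {
  if (!is.numeric(am) || length(am) != 1 || am <= 0) {
    abort("am must be a positive number")
  }
  if (!is.null(aw) && (!is.numeric(aw) || length(aw) != 1)) {
    abort("aw must be NULL or a single number")
  }
  structure_prior <- match.arg(structure_prior, "uniform")
  structure(
    list(
      am = am, aw = aw, prior_mean = prior_mean,
      prior_scale = prior_scale, structure_prior = structure_prior
    ),
    class = "score_params"
  )
}

#' @export
print.score_params <- function(x, ...) {
  cat("<score_params> am =", x$am,
      "aw =", if (is.null(x$aw)) "n_vars + 2" else x$aw,
      "prior =", x$structure_prior, "\n")
  invisible(x)
}

# log of the multivariate gamma function Gamma_l(a)
lmvgamma <- function(a, l) {
  l * (l - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(l)) / 2))
}

# Bind score hyperparameters to a concrete gene scope. Returns a context
# holding the prior scale T, the posterior scale R = T + S + shrinkage term,
# and a memoised evaluator of the subset log marginal f(Y); per-node scores
# are differences f(pa + v) - f(pa), which makes decomposability and score
# equivalence structural.
bge_context <- function(data, genes, params = score_params()) {
  x <- t(expression_matrix(data, genes)) # samples x genes
  m <- nrow(x)
  n <- ncol(x)
  if (m < 2) {
    abort("scoring needs at least 2 samples")
  }
  am <- params$am
  aw <- params$aw %||% (n + 2)
  if (aw <= n - 1) {
    abort(paste0("aw must exceed n_vars - 1 = ", n - 1))
  }
  nu <- params$prior_mean %||% colMeans(x)
  if (length(nu) == 1) nu <- rep(nu, n)
  if (length(nu) != n) {
    abort("prior_mean length must equal the number of genes in scope")
  }
  tmat <- params$prior_scale
  if (is.null(tmat)) tmat <- am * (aw - n - 1) / (am + 1)
  if (is.matrix(tmat)) {
    if (nrow(tmat) != n || ncol(tmat) != n) {
      abort("prior_scale matrix must be n_vars x n_vars")
    }
  } else {
    if (tmat <= 0) abort("prior_scale must be positive")
    tmat <- diag(tmat, n)
  }
  xbar <- colMeans(x)
  s <- crossprod(sweep(x, 2, xbar))
  rpost <- tmat + s + (m * am / (am + m)) * tcrossprod(xbar - nu)

  cache <- new.env(parent = emptyenv())
  logdet_pd <- function(mat, which, idx) {
    ch <- tryCatch(chol(mat), error = function(e) {
      abort(paste0(
        "singular ", which, " matrix for genes {",
        paste(genes[idx], collapse = ", "),
        "}; check for duplicated or constant expression columns"
      ))
    })
    2 * sum(log(diag(ch)))
  }
  f_subset <- function(idx) {
    l <- length(idx)
    if (l == 0) return(0)
    key <- paste0("m", paste(idx, collapse = "."))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- -(l * m / 2) * log(pi) +
      (l / 2) * log(am / (am + m)) +
      lmvgamma((aw - n + l + m) / 2, l) -
      lmvgamma((aw - n + l) / 2, l) +
      ((aw - n + l) / 2) * logdet_pd(tmat[idx, idx, drop = FALSE], "prior scale", idx) -
      ((aw - n + l + m) / 2) * logdet_pd(rpost[idx, idx, drop = FALSE], "posterior scale", idx)
    cache[[key]] <- val
    val
  }
  list(
    genes = genes, m = m, n = n, am = am, aw = aw,
    f_subset = f_subset,
    node_score = function(node_idx, parent_idx) {
      f_subset(sort(c(parent_idx, node_idx))) - f_subset(sort(parent_idx))
    }
  )
}

#' Log marginal likelihood contribution of one gene given its parents
#'
#' The per-node factor of the joint factorisation, in log space: the log
#' marginal likelihood of the gene's expression column given its parents'
#' columns under the Gaussian-equivalent conjugate prior. Depends only on the
#' data of `node` and `parents`; the other genes in `scope` enter only
#' through the prior's dimension defaults.
#'
#' @param data Expression tibble (see [read_expression()]).
#' @param node Gene id.
#' @param parents Character vector of parent gene ids (may be empty).
#' @param params [score_params()].
#' @param scope Gene set fixing the prior dimension; defaults to all genes in
#'   `data`. Scores summed into one network score must share a scope.
#' @return A finite log score.
#' @export
log_node_score <- function(data, node, parents = character(), params = score_params(),
                           scope = NULL) {
  data <- validate_expression(data)
  scope <- scope %||% data$gene
  miss <- setdiff(c(node, parents, scope), data$gene)
  if (length(miss) > 0) {
    abort(paste0("gene not found in expression data: ", miss[1]))
  }
  if (node %in% parents) {
    abort("node must not be its own parent")
  }
  if (!all(c(node, parents) %in% scope)) {
    abort("node and parents must lie inside the scoring scope")
  }
  ctx <- bge_context(data, scope, params)
  ctx$node_score(match(node, scope), match(parents, scope))
}

#' Log network score of a DAG
#'
#' The log relative probability of a structure given data: the sum of
#' per-node log marginal likelihood contributions plus the log structure
#' prior (uniform, hence an additive constant that is dropped). Decomposable:
#' changing one gene's parent set changes only that gene's term.
#'
#' @param data Expression tibble.
#' @param net An acyclic [grn_network()]; the scoring scope is its node set.
#' @param params [score_params()].
#' @return The log network score.
#' @export
log_network_score <- function(data, net, params = score_params()) {
  if (!is_acyclic(net)) {
    abort("the network score is defined for DAGs only; input has a cycle")
  }
  ctx <- bge_context(data, net$nodes, params)
  adj <- network_adjacency(net)
  sum(map_dbl(seq_along(net$nodes), function(v) {
    ctx$node_score(v, which(adj[, v] == 1L))
  }))
}
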