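# Shared fixtures and independent oracles.

# small deterministic expression tibble (3 genes x 4 samples)
tiny_expression <- function() {
  tibble::tibble(
    gene = c("a", "b", "c"),
    s1 = c(0.1, 1.2, -0.3),
    s2 = c(-0.5, 0.4, 0.9),
    s3 = c(1.3, -0.2, 0.05),
    s4 = c(0.7, 0.8, -1.1)
  )
}

# expression data simulated from a chain a -> b -> c with strong coefficients
chain_expression <- function(m = 200, beta = 1, sigma = 0.3, seed = 42) {
  withr::with_seed(seed, {
    a <- rnorm(m)
    b <- beta * a + rnorm(m, sd = sigma)
    c <- beta * b + rnorm(m, sd = sigma)
    tibble::tibble(gene = c("a", "b", "c")) |>
      dplyr::bind_cols(tibble::as_tibble(
        setNames(as.data.frame(rbind(a, b, c)), paste0("s", seq_len(m)))
      ))
  })
}

# Quadrature oracle for the parentless node score: integrates the Gaussian
# likelihood of one column against the prior implied on that coordinate by
# the normal-Wishart prior of an n-variable scope (mean nu, precision-of-mean
# am; variance Inverse-Gamma with shape (aw - n + 1)/2, rate t11/2). The
# integrand is evaluated in log space and rescaled by its approximate mode so
# the quadrature stays accurate for long columns.
quadrature_parentless_score <- function(x, n_scope, am = 1, aw = n_scope + 2,
                                        nu = mean(x),
                                        t11 = am * (aw - n_scope - 1) / (am + 1)) {
  m <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  a <- (aw - n_scope + 1) / 2
  b <- t11 / 2
  logf <- function(mu, s2) {
    sum(dnorm(x, mu, sqrt(s2), log = TRUE)) +
      dnorm(mu, nu, sqrt(s2 / am), log = TRUE) +
      a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2
  }
  s2_mode <- (ss + 2 * b) / (m + 2 * a + 2)
  offset <- logf(xbar, s2_mode)
  inner <- function(s2_vec) {
    vapply(s2_vec, function(s2) {
      f <- function(mu_vec) {
        vapply(mu_vec, function(mu) exp(logf(mu, s2) - offset), numeric(1))
      }
      half <- sqrt(s2) * 20 / sqrt(m) + abs(xbar - nu) + 1
      integrate(f, xbar - half, xbar, rel.tol = 1e-10)$value +
        integrate(f, xbar, xbar + half, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  total <- integrate(inner, 0, s2_mode, rel.tol = 1e-9)$value +
    integrate(inner, s2_mode, Inf, rel.tol = 1e-9)$value
  log(total) + offset
}

# Markov-equivalence characteristic of a 3-node DAG given as a state row:
# skeleton plus the set of v-structures (unshielded colliders).
markov_class_key <- function(net) {
  adj <- trigrn:::network_adjacency(net)
  n <- nrow(adj)
  und <- adj | t(adj)
  skel <- which(und[upper.tri(und)])
  vs <- character(0)
  for (v in seq_len(n)) {
    pa <- which(adj[, v] == 1L)
    if (length(pa) >= 2) {
      for (cmb in utils::combn(pa, 2, simplify = FALSE)) {
        if (!und[cmb[1], cmb[2]]) {
          vs <- c(vs, paste(cmb[1], cmb[2], v, sep = "-"))
        }
      }
    }
  }
  paste(
    paste(skel, collapse = ","),
    paste(sort(vs), collapse = ","),
    sep = "|"
  )
}

# independent cycle check through igraph
igraph_is_dag <- function(net) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(net$edges),
    directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  igraph::is_dag(g)
}

# manual voting fixture: 4 genes whose per-triplet winners stitch into the
# 3-cycle a -> b -> c -> a
cyclic_store_fixture <- function() {
  manual_tuple_store(
    c("a", "b", "c", "d"),
    tibble::tribble(
      ~g1, ~g2, ~g3, ~rank, ~weight, ~structure,
      "a", "b", "c", 1, 0.5, "a->b;b->c",
      "a", "b", "d", 1, 0.9, "a->b",
      "a", "c", "d", 1, 0.9, "c->a",
      "b", "c", "d", 1, 0.9, "b->c"
    )
  )
}
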