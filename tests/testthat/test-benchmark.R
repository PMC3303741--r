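test_that("planted models are reproducible and match their edge-density law", {
  m1 <- random_planted_model(6, 0.3, seed = 4)
  m2 <- random_planted_model(6, 0.3, seed = 4)
  expect_true(network_equal(m1$truth, m2$truth))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_true(is_acyclic(m1$truth))
  expect_true(all(abs(m1$coefficients$beta) >= 0.8 &
                    abs(m1$coefficients$beta) <= 1.2))
  expect_error(random_planted_model(4, 0), "strictly between")
  expect_error(random_planted_model(4, 0.5, beta_range = c(0, 1)), "beta_range")

  # binomial expectation of the edge count: mean over seeds within 3 SE
  p <- 0.3
  n_pairs <- choose(10, 2)
  counts <- vapply(1:1000, function(s) {
    nrow(random_planted_model(10, p, seed = s)$truth$edges)
  }, numeric(1))
  se <- sqrt(n_pairs * p * (1 - p) / 1000)
  expect_lt(abs(mean(counts) - p * n_pairs), 3 * se)
})

test_that("simulated expression follows the planted linear-Gaussian law", {
  # a -> b with beta = 1: regression slope near 1 at m = 1000
  model <- random_planted_model(2, 0.5, n_samples = 1000, seed = 1)
  model$truth <- grn_network(c("g1", "g2"), data.frame(from = "g1", to = "g2"))
  model$coefficients <- tibble::tibble(from = "g1", to = "g2", beta = 1)
  expr <- simulate_expression(model)
  x <- as.numeric(expr[1, -1])
  y <- as.numeric(expr[2, -1])
  fit <- summary(lm(y ~ x))$coefficients
  expect_lt(abs(fit["x", "Estimate"] - 1), 3 * fit["x", "Std. Error"])

  # identical model, identical matrix
  expect_identical(expr, simulate_expression(model))

  # edgeless truth: all pairwise correlations vanish at large m
  lone <- random_planted_model(3, 0.01, n_samples = 2000, seed = 2)
  lone$truth <- grn_network(paste0("g", 1:3))
  lone$coefficients <- tibble::tibble(from = character(), to = character(),
                                      beta = numeric())
  mat <- t(as.matrix(simulate_expression(lone)[, -1]))
  cors <- cor(mat)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 0.1))
})

test_that("rank lookup locates every DAG and flags cyclic estimates", {
  expr <- chain_expression(m = 60, seed = 17)
  ranking <- rank_candidates(expr, c("a", "b", "c"))
  expect_equal(rank_in_exhaustive(candidate_network(ranking, 1), ranking), 1L)
  for (r in c(2, 13, 25)) {
    expect_equal(rank_in_exhaustive(candidate_network(ranking, r), ranking), r)
  }
  cyc <- grn_network(
    c("a", "b", "c"),
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")),
    acyclic = FALSE
  )
  expect_true(is.na(rank_in_exhaustive(cyc, ranking)))
  wrong <- grn_network(c("a", "b", "x"))
  expect_error(rank_in_exhaustive(wrong, ranking), "different gene sets")
})

test_that("sensitivity and selectivity follow the strict directed definition", {
  genes <- c("a", "b", "c")
  truth <- grn_network(genes, data.frame(from = c("a", "b"), to = c("b", "c")))
  perfect <- sensitivity_selectivity(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$selectivity, 1)
  expect_equal(perfect$reversed_edges, 0)

  reversed <- sensitivity_selectivity(
    grn_network(c("a", "b"), data.frame(from = "b", to = "a")),
    grn_network(c("a", "b"), data.frame(from = "a", to = "b"))
  )
  expect_equal(reversed$tp, 0)
  expect_equal(reversed$fp, 1)
  expect_equal(reversed$fn, 1)
  expect_equal(reversed$reversed_edges, 1)

  none <- sensitivity_selectivity(grn_network(genes), grn_network(genes))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$selectivity))
})

test_that("counting identities and metric bounds hold on random pairs", {
  for (seed in 1:20) {
    truth <- random_planted_model(6, 0.4, seed = seed)$truth
    est <- random_planted_model(6, 0.35, seed = seed + 1000)$truth
    ev <- sensitivity_selectivity(est, truth)
    expect_equal(ev$tp + ev$fn, nrow(truth$edges))
    expect_equal(ev$tp + ev$fp, nrow(est$edges))
    expect_true(all(is.na(c(ev$sensitivity, ev$selectivity)) |
                      (c(ev$sensitivity, ev$selectivity) >= 0 &
                         c(ev$sensitivity, ev$selectivity) <= 1)))
  }
})

test_that("sensitivity of an independent random estimate matches its closed form", {
  # each planted edge is directionally matched by an independent estimate
  # with probability edge_prob_est / 2 (pair present, then direction by a
  # symmetric random order)
  p_est <- 0.4
  sens <- vapply(1:100, function(seed) {
    truth <- random_planted_model(10, 0.3, seed = seed)$truth
    est <- random_planted_model(10, p_est, seed = seed + 5000)$truth
    sensitivity_selectivity(est, truth)$sensitivity
  }, numeric(1))
  sens <- sens[!is.na(sens)]
  se <- sd(sens) / sqrt(length(sens))
  expect_lt(abs(mean(sens) - p_est / 2), 3 * se)
})

test_that("the replicated comparison is seed-stable and well-formed", {
  cmp <- run_comparison(4, n_replicates = 2, seed = 6)
  again <- run_comparison(4, n_replicates = 2, seed = 6)
  expect_identical(tidy(cmp), tidy(again))
  expect_equal(nrow(tidy(cmp)), 4) # 2 replicates x 2 methods
  expect_setequal(unique(tidy(cmp)$method), c("union", "ghc"))
  expect_equal(nrow(cmp$summary), 2)
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("union_median_rank", "ghc_median_rank") %in% names(gl)))
  expect_s3_class(autoplot(cmp), "ggplot")
})
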