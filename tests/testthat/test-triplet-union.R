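test_that("triplet generation covers every 3-subset exactly once", {
  expect_equal(nrow(make_triplets(paste0("g", 1:5))), 10)
  expect_equal(nrow(make_triplets(c("a", "b", "c"))), 1)
  expect_equal(nrow(make_triplets(paste0("g", 1:10))), choose(10, 3))
  trips <- make_triplets(paste0("g", 1:6))
  expect_false(anyDuplicated(paste(trips$g1, trips$g2, trips$g3)) > 0)
  expect_error(make_triplets(c("a", "b")), "at least 3")
})

test_that("the tuple store satisfies its counting invariants", {
  model <- random_planted_model(5, 0.4, seed = 8)
  expr <- simulate_expression(model)
  genes <- model$truth$nodes
  store <- build_tuple_store(expr, genes)
  expect_equal(store$n_triplets, 10)
  expect_equal(store$candidate_slots, 270)
  expect_equal(store$scored_entries, 250)
  expect_equal(nrow(dplyr::distinct(store$entries[, c("triplet", "rank")])), 250)
  # each unordered pair is covered by exactly n - 2 triplets
  e1 <- store$entries[store$entries$rank == 1, ]
  trip_genes <- cbind(e1$g1, e1$g2, e1$g3)
  for (pair in combn(genes, 2, simplify = FALSE)) {
    hits <- sum(apply(trip_genes, 1, function(tr) all(pair %in% tr)))
    expect_equal(hits, length(genes) - 2)
  }
  # truncated store
  small <- build_tuple_store(expr, genes, max_rank = 1)
  expect_equal(small$scored_entries, 10)
  one <- build_tuple_store(expr, c("g1", "g2", "g3"), max_rank = 1)
  expect_equal(one$scored_entries, 1)
})

test_that("edge vote totals reproduce hand-computed fixtures", {
  # pair (a, b) seen by two triplets: weights 0.6 forward and 0.3 absent
  store <- manual_tuple_store(
    c("a", "b", "c", "d"),
    tibble::tribble(
      ~g1, ~g2, ~g3, ~rank, ~weight, ~structure,
      "a", "b", "c", 1, 0.6, "a->b",
      "a", "b", "d", 1, 0.3, ""
    )
  )
  dec <- edge_type_totals(store, c("a", "b"))
  expect_equal(dec$forward, 0.6)
  expect_equal(dec$backward, 0)
  expect_equal(dec$absent, 0.3)
  expect_equal(dec$chosen, "forward")

  # exact tie leaves the pair undecided
  tied <- manual_tuple_store(
    c("a", "b", "c", "d"),
    tibble::tribble(
      ~g1, ~g2, ~g3, ~rank, ~weight, ~structure,
      "a", "b", "c", 1, 0.5, "a->b",
      "a", "b", "d", 1, 0.5, "b->a"
    )
  )
  expect_true(is.na(edge_type_totals(tied, c("a", "b"))$chosen))
  expect_error(edge_type_totals(store, c("a", "zz")), "present in the store")
})

test_that("single-triplet stores vote exactly like their rank-1 network", {
  expr <- chain_expression(m = 80, seed = 13)
  store <- build_tuple_store(expr, c("a", "b", "c"))
  ranking <- rank_candidates(expr, c("a", "b", "c"))
  top <- candidate_network(ranking, 1)
  for (pair in combn(c("a", "b", "c"), 2, simplify = FALSE)) {
    dec <- edge_type_totals(store, pair)
    fwd <- paste(pair[1], pair[2]) %in% paste(top$edges$from, top$edges$to)
    bwd <- paste(pair[2], pair[1]) %in% paste(top$edges$from, top$edges$to)
    expect_equal(dec$chosen, if (fwd) "forward" else if (bwd) "backward" else "absent")
  }
  expect_true(network_equal(unite(store)$network, top))
})

test_that("union equals the exhaustive optimum on three genes (oracle equivalence)", {
  for (seed in c(1, 7, 19, 33)) {
    model <- random_planted_model(3, 0.5, seed = seed)
    expr <- simulate_expression(model)
    fit <- unite(build_tuple_store(expr, model$truth$nodes))
    ranking <- rank_candidates(expr, model$truth$nodes)
    expect_true(
      network_equal(fit$network, candidate_network(ranking, 1)),
      info = paste("seed", seed)
    )
  }
})

test_that("union recovers most of a strong-signal planted diamond", {
  truth <- grn_network(
    c("a", "b", "c", "d"),
    data.frame(from = c("a", "a", "b", "c"), to = c("b", "c", "d", "d"))
  )
  model <- random_planted_model(4, 0.5, n_samples = 300, seed = 501)
  model$truth <- truth
  model$coefficients <- withr::with_seed(77, dplyr::mutate(
    truth$edges,
    beta = sample(c(-1, 1), 4, TRUE) * runif(4, 0.8, 1.2)
  ))
  expr <- simulate_expression(model)
  fit <- unite(build_tuple_store(expr, truth$nodes))
  skel <- function(net) paste(pmin(net$edges$from, net$edges$to),
                              pmax(net$edges$from, net$edges$to))
  expect_gte(length(intersect(skel(fit$network), skel(truth))), 3)
})

test_that("ties break through an already-linked third gene", {
  # (c, d) ties at rank 1; triplet {a, c, d} qualifies because a -> c is
  # already decided, and its rank-1 network says c -> d
  store <- manual_tuple_store(
    c("a", "b", "c", "d"),
    tibble::tribble(
      ~g1, ~g2, ~g3, ~rank, ~weight, ~structure,
      "a", "b", "c", 1, 0.9, "a->c",
      "a", "c", "d", 1, 0.4, "c->d",
      "b", "c", "d", 1, 0.4, "d->c"
    )
  )
  fit <- unite(store)
  dec <- dplyr::filter(fit$decisions, from == "c", to == "d")
  expect_equal(dec$chosen, "forward")
  expect_true(dec$tie_break)
  expect_equal(dec$decided_at_rank, 1L)
  expect_true("c" %in% fit$network$edges$from & "d" %in% fit$network$edges$to)
})

test_that("unresolvable rank-1 ties escalate to rank-2 votes", {
  # no gene touches (c, d) at rank 1, so the tie revotes at rank 2
  store <- manual_tuple_store(
    c("a", "b", "c", "d"),
    tibble::tribble(
      ~g1, ~g2, ~g3, ~rank, ~weight, ~structure,
      "a", "b", "c", 1, 0.9, "",
      "a", "b", "d", 1, 0.9, "",
      "a", "c", "d", 1, 0.4, "c->d",
      "b", "c", "d", 1, 0.4, "d->c",
      "a", "c", "d", 2, 0.30, "c->d",
      "b", "c", "d", 2, 0.25, "c->d"
    )
  )
  fit <- unite(store)
  dec <- dplyr::filter(fit$decisions, from == "c", to == "d")
  expect_equal(dec$chosen, "forward")
  expect_equal(dec$decided_at_rank, 2L)
  expect_false(dec$tie_break)
})

test_that("ties persisting past the stored ranks fall back to absent", {
  store <- manual_tuple_store(
    c("a", "b", "c", "d"),
    tibble::tribble(
      ~g1, ~g2, ~g3, ~rank, ~weight, ~structure,
      "a", "b", "c", 1, 0.9, "",
      "a", "b", "d", 1, 0.9, "",
      "a", "c", "d", 1, 0.4, "c->d",
      "b", "c", "d", 1, 0.4, "d->c"
    )
  )
  expect_warning(fit <- unite(store), "set to absent")
  dec <- dplyr::filter(fit$decisions, from == "c", to == "d")
  expect_equal(dec$chosen, "absent")
  expect_true(is.na(dec$decided_at_rank))
  expect_equal(fit$n_undecided, 1L)
})

test_that("stitched triplet winners can form a directed cycle", {
  fit <- unite(cyclic_store_fixture())
  expect_false(is_acyclic(fit$network))
  edges <- paste(fit$network$edges$from, fit$network$edges$to)
  expect_true(all(c("a b", "b c", "c a") %in% edges))
})

test_that("union is a deterministic pure function of the store", {
  model <- random_planted_model(5, 0.4, seed = 23)
  expr <- simulate_expression(model)
  store <- build_tuple_store(expr, model$truth$nodes)
  f1 <- unite(store)
  f2 <- unite(store)
  expect_identical(f1$decisions, f2$decisions)
  expect_true(network_equal(f1$network, f2$network))
  # every pair gets exactly one state; never both directions
  expect_equal(nrow(f1$decisions), choose(5, 2))
  expect_false(any(is.na(f1$decisions$chosen)))
  both <- paste(f1$network$edges$from, f1$network$edges$to) %in%
    paste(f1$network$edges$to, f1$network$edges$from)
  expect_false(any(both))
})

test_that("relabeling genes permutes the united network identically", {
  model <- random_planted_model(4, 0.5, seed = 31)
  expr <- simulate_expression(model)
  fit <- infer_network(expr)
  mapping <- c(g1 = "w", g2 = "x", g3 = "y", g4 = "z")
  relabeled <- expr
  relabeled$gene <- unname(mapping[expr$gene])
  fit2 <- infer_network(relabeled)
  remapped <- grn_network(
    unname(mapping[fit$network$nodes]),
    tibble::tibble(
      from = unname(mapping[fit$network$edges$from]),
      to = unname(mapping[fit$network$edges$to])
    ),
    acyclic = FALSE
  )
  expect_true(network_equal(fit2$network, remapped))
})

test_that("raw-score voting agrees with weight voting on clear-cut data", {
  expr <- chain_expression(m = 150, seed = 3)
  store <- build_tuple_store(expr, c("a", "b", "c"))
  expect_true(network_equal(
    unite(store)$network,
    unite(store, raw_scores = TRUE)$network
  ))
})

test_that("tidy and glance expose the decision audit", {
  fit <- unite(cyclic_store_fixture())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_named(
    td,
    c("from", "to", "forward", "backward", "absent", "chosen",
      "decided_at_rank", "tie_break")
  )
  gl <- glance(fit)
  expect_equal(gl$n_genes, 4)
  expect_false(gl$acyclic)
  expect_s3_class(autoplot(fit), "ggplot")
})
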