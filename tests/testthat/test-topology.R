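test_that("shortest paths match Floyd-Warshall on random graphs", {
  set.seed(1)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    a <- rand_adjacency(n, runif(1, 0.2, 0.8))
    expect_equal(all_shortest_path_lengths(a), fw_distances(a))
  }
  a <- path_graph(3)
  expect_equal(all_shortest_path_lengths(a)[1, 3], 2)
  two_dyads <- matrix(0, 4, 4)
  two_dyads[1, 2] <- two_dyads[2, 1] <- two_dyads[3, 4] <- two_dyads[4, 3] <- 1
  expect_equal(all_shortest_path_lengths(two_dyads)[1, 3], Inf)
})

test_that("analytic fixed points: complete graph and P3", {
  g4 <- global_metrics(complete_graph(4))
  expect_equal(g4$Eglob, 1)
  expect_equal(g4$Eloc, 1)
  expect_equal(g4$Cp, 1)
  expect_equal(g4$Lp, 1)
  expect_false(g4$disconnected_flag)
  # rewiring a complete graph has no legal swap: Sigma = 1
  suppressWarnings(
    gs <- global_metrics(complete_graph(5),
                         nulls = null_ensemble_params(5, 2, 1)))
  expect_equal(gs$Sigma, 1)

  p3 <- global_metrics(path_graph(3))
  expect_equal(p3$Eglob, 5 / 6, tolerance = 1e-12)
  expect_equal(p3$Lp, 4 / 3, tolerance = 1e-12)
  expect_equal(p3$Cp, 0)
  nb <- nodal_metrics(path_graph(3))
  expect_equal(nb$betweenness, c(0, 1, 0))
  expect_equal(nb$degree, c(1, 2, 1))

  expect_equal(global_metrics(star_graph(4))$Eloc, 0)
  k4 <- nodal_metrics(complete_graph(4))
  expect_equal(k4$betweenness, rep(0, 4))
  expect_equal(k4$degree, rep(3, 4))

  expect_error(global_metrics(matrix(0, 2, 2)), class = "sfconn_input_error")
})

test_that("empty graph has zero efficiency and flagged path length", {
  g <- global_metrics(matrix(0, 5, 5))
  expect_equal(g$Eglob, 0)
  expect_true(g$disconnected_flag)
  expect_true(is.na(g$Lp))
  nm <- nodal_metrics(matrix(0, 5, 5))
  expect_true(all(is.na(nm$NLp)))
  expect_equal(nm$NEglob, rep(0, 5))
})

test_that("all metrics match brute-force oracles on seeded random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    a <- rand_adjacency(n, runif(1, 0.2, 0.8))
    d <- fw_distances(a)
    g <- global_metrics(a)
    expect_equal(g$Eglob, brute_efficiency(d), tolerance = 1e-12)
    expect_equal(g$Cp, mean(brute_clustering(a)), tolerance = 1e-12)
    expect_equal(g$Eloc, brute_eloc(a), tolerance = 1e-12)
    off <- d[row(d) != col(d)]
    expect_equal(g$Lp, mean(off[is.finite(off)]), tolerance = 1e-12)
    nm <- nodal_metrics(a)
    expect_equal(nm$betweenness_raw, brute_betweenness(a),
                 tolerance = 1e-9)
    expect_equal(nm$NCp, unname(brute_clustering(a)), tolerance = 1e-12)
    inv <- 1 / d; diag(inv) <- 0
    expect_equal(nm$NEglob, rowSums(inv) / (n - 1), tolerance = 1e-12)
  }
})

test_that("degree-preserving nulls conserve degrees and reduce lattice Cp", {
  a <- ring_lattice(50, 4)
  ens <- maslov_sneppen_rewire(a, null_ensemble_params(20, 10, 3))
  for (m in ens) {
    expect_equal(rowSums(m), rowSums(a))
    expect_equal(diag(m), rep(0, 50))
  }
  cp_null <- mean(vapply(ens, function(m) mean(brute_clustering(m)),
                         numeric(1)))
  expect_lt(cp_null, mean(brute_clustering(a)))
  # seeded reproducibility
  ens2 <- maslov_sneppen_rewire(a, null_ensemble_params(20, 10, 3))
  expect_identical(ens, ens2)
  expect_warning(maslov_sneppen_rewire(complete_graph(4),
                                       null_ensemble_params(2, 2, 1)),
                 "no degree-preserving swap")
})

test_that("sparsity sweep returns one metric set per level with nesting", {
  set.seed(5)
  v <- matrix(rnorm(900), 30, 30)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  z <- connectivity_matrix(v, modality = "functional_weighted")
  g <- sparsity_grid(0.05, 0.40, 0.05)
  sm <- metrics_over_sparsity(z, g)
  expect_equal(nrow(sm$global), 8)
  expect_length(sm$nodal, 8)
  expect_true(all(diff(sm$global$Eglob) >= 0))   # nesting => monotone
  expect_true(all(diff(vapply(sm$nodal, function(x) sum(x$degree),
                              numeric(1))) >= 0))
})

test_that("default grid has 40 levels and minimal graphs enumerate by hand", {
  g <- sparsity_grid()
  expect_equal(length(g$values), (0.40 - 0.01) / 0.01 + 1)

  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.9
  v[1, 3] <- v[3, 1] <- 0.5
  v[2, 3] <- v[3, 2] <- 0.1
  z <- connectivity_matrix(v, modality = "functional_weighted")
  one <- sparsity_threshold(z, 1 / 3)    # floor(3/3) = 1 edge
  expect_equal(sum(one$values) / 2, 1)
  m1 <- global_metrics(one)
  expect_equal(m1$Eglob, 2 * 1 / 6)      # single dyad among 3 nodes
  two <- sparsity_threshold(z, 0.99)      # floor(0.99 * 3) = 2 edges
  expect_equal(sum(two$values) / 2, 2)
  expect_equal(global_metrics(two)$Eglob, 5 / 6)  # path via node 1
})

test_that("AUC is the trapezoid over the grid domain", {
  g <- sparsity_grid()
  expect_equal(auc_curve(rep(2.5, 40), g), 0.39 * 2.5, tolerance = 1e-12)
  expect_equal(auc_curve(g$values, g), 0.079950, tolerance = 1e-9)
  expect_error(auc_curve(rep(1, 39), g), class = "sfconn_input_error")
  bad <- rep(1, 40); bad[c(3, 8)] <- NA
  expect_error(auc_curve(bad, g), "0.03", class = "sfconn_input_error")
  g1 <- sparsity_grid(0.1, 0.1, 0.01)
  expect_error(auc_curve(1, g1), class = "sfconn_input_error")
})
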