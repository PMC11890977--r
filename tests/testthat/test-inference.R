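covs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 55, 75),
             sex = sample(c("male", "female"), n, replace = TRUE),
             education = sample(6:18, n, replace = TRUE))
}

test_that("residualization matches the normal equations", {
  cv <- covs(40, 2)
  y <- 3 + 0.5 * cv$age
  expect_lt(max(abs(residualize(y, cv))), 1e-10)

  set.seed(3)
  y2 <- rnorm(40)
  r2 <- residualize(y2, cv)
  expect_lt(abs(mean(r2)), 1e-10)
  # independent normal-equations solve
  x <- cbind(1, cv$age, as.numeric(cv$sex == "male"), cv$education)
  beta <- solve(t(x) %*% x, t(x) %*% y2)
  expect_lt(max(abs(r2 - (y2 - x %*% beta))), 1e-10)

  cv_bad <- cv
  cv_bad$education <- 2 * cv_bad$age
  expect_error(residualize(y2, cv_bad), "education|age",
               class = "sfconn_input_error")
})

test_that("tests are routed by Shapiro-Wilk normality", {
  set.seed(11)
  a <- rnorm(30); b <- rnorm(30, 0.2)
  stopifnot(shapiro.test(a)$p.value > 0.05, shapiro.test(b)$p.value > 0.05)
  rt <- route_test(a, b)
  expect_equal(rt$test_used, "t")
  expect_equal(rt$p_raw, t.test(a, b, var.equal = TRUE)$p.value)

  set.seed(12)
  e1 <- rexp(30); e2 <- rexp(30)
  stopifnot(shapiro.test(e1)$p.value <= 0.05 ||
              shapiro.test(e2)$p.value <= 0.05)
  rt2 <- route_test(e1, e2)
  expect_equal(rt2$test_used, "mann_whitney")

  same <- rnorm(20)
  rt3 <- route_test(same, same)
  expect_gt(rt3$p_raw, 0.99)

  expect_error(route_test(rep(1, 10), rep(1, 10)),
               class = "sfconn_input_error")
  expect_error(route_test(rnorm(2), rnorm(10)), class = "sfconn_input_error")

  cat_res <- route_test(c("m", "m", "f", "m"), c("f", "f", "m", "f"),
                        kind = "categorical")
  expect_equal(cat_res$test_used, "chi_squared")
})

test_that("Bonferroni and single-feature corrections are exact", {
  res <- data.frame(feature = c("a", "b"), p_raw = c(0.01, 0.04))
  out <- fwe_correct(res, method = "bonferroni")
  expect_equal(out$p_fwe, c(0.02, 0.08))

  one <- fwe_correct(data.frame(feature = "a", p_raw = 0.03),
                     method = "bonferroni")
  expect_equal(one$p_fwe, 0.03)
  expect_error(fwe_correct(res[0, ], method = "bonferroni"),
               class = "sfconn_input_error")
})

test_that("permutation maxT controls FWER under the global null", {
  set.seed(41)
  n <- 30; m <- 40; sims <- 60; B <- 200
  g <- rep(c(TRUE, FALSE), each = n / 2)
  fam_pos <- 0
  for (s in seq_len(sims)) {
    x <- matrix(rnorm(n * m), n, m)
    p_raw <- apply(x, 2, function(col)
      t.test(col[g], col[!g], var.equal = TRUE)$p.value)
    res <- fwe_correct(data.frame(feature = seq_len(m), p_raw = p_raw),
                       method = "permutation_maxT", features = x, groups = g,
                       permutations = B, seed = 1000 + s)
    fam_pos <- fam_pos + any(res$p_fwe < 0.05)
    expect_true(all(res$p_fwe >= res$p_raw))
  }
  expect_lte(fam_pos / sims, 0.05 + 2 * sqrt(0.05 * 0.95 / sims))
})

test_that("maxT with rank statistic ignores monotone rescaling", {
  set.seed(13)
  n <- 24; m <- 8
  x <- matrix(rnorm(n * m), n, m)
  g <- rep(c(TRUE, FALSE), each = 12)
  res <- data.frame(feature = seq_len(m), p_raw = runif(m))
  a <- fwe_correct(res, "permutation_maxT", features = x, groups = g,
                   permutations = 99, stat = "rank", seed = 5)
  y <- x
  y[, 1] <- exp(x[, 1]); y[, 2] <- x[, 2]^3; y[, 3] <- 10 * x[, 3] + 4
  b <- fwe_correct(res, "permutation_maxT", features = y, groups = g,
                   permutations = 99, stat = "rank", seed = 5)
  expect_equal(a$p_fwe, b$p_fwe)
})

test_that("compare_groups recovers planted effects and errors on constants", {
  p <- sim_params(n_hc = 30, n_vci = 30, n_timepoints = 500, seed = 31)
  sim <- generate_cohort(p)
  cfg <- sfc_config(permutations = 300, seed = 17)
  nets <- build_networks(sim$cohort, cfg)
  coup <- cohort_coupling_matrix(sim$cohort, nets, cfg)
  res <- compare_groups(coup, sim$cohort$subjects, cfg)
  boost_labs <- sim$cohort$atlas_labels[p$boost_nodes]
  sig <- res$feature[res$p_fwe < 0.05 & res$direction > 0]
  expect_gte(sum(boost_labs %in% sig), 7)
  expect_lte(sum(!(sig %in% boost_labs)), 2)
  expect_true(all(res$p_fwe >= res$p_raw))

  cf <- coup
  cf[, 1] <- 0.5
  expect_error(compare_groups(cf, sim$cohort$subjects, cfg),
               "constant", class = "sfconn_input_error")
})

test_that("partial correlation matches the two-stage residual oracle", {
  cv <- covs(50, 7)
  set.seed(8)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50, 0, 0.5)
  pc <- partial_correlation(x, y, cv, method = "pearson")
  rx <- residualize(x, cv); ry <- residualize(y, cv)
  expect_equal(pc$rho_partial, cor(rx, ry), tolerance = 1e-10)

  # identical variables: rho exactly 1
  expect_equal(partial_correlation(x, x, cv, method = "pearson")$rho_partial, 1)

  # independent of covariates: partial equals zero-order
  expect_equal(pc$rho_partial, cor(rx, ry), tolerance = 1e-10)

  # confound driving both: partial attenuated vs zero-order
  z <- cv$age
  xz <- 0.8 * z + rnorm(50, 0, 3)
  yz <- 0.8 * z + rnorm(50, 0, 3)
  pz <- partial_correlation(xz, yz, cv, method = "pearson")
  expect_lt(abs(pz$rho_partial), abs(cor(xz, yz)))
  r1 <- residualize(xz, cv); r2 <- residualize(yz, cv)
  expect_equal(pz$rho_partial, cor(r1, r2), tolerance = 1e-10)

  expect_error(partial_correlation(rnorm(4), rnorm(4), covs(4)),
               class = "sfconn_input_error")
  sp <- partial_correlation(x, y, cv, method = "spearman")
  expect_equal(sp$rho_partial,
               cor(residualize(rank(x), cv), residualize(rank(y), cv)),
               tolerance = 1e-10)
})

test_that("cognition-coupling table flags planted negative correlations", {
  p <- sim_params(n_hc = 25, n_vci = 25, n_timepoints = 300, seed = 53)
  sim <- generate_cohort(p)
  cfg <- sfc_config(permutations = 200, seed = 19)
  nets <- build_networks(sim$cohort, cfg)
  coup <- cohort_coupling_matrix(sim$cohort, nets, cfg)
  boost_labs <- sim$cohort$atlas_labels[p$boost_nodes]
  tab <- coupling_cognition(coup, sim$cohort$subjects,
                            scores = c("AVLT", "BNT"),
                            nodes = boost_labs, config = cfg)
  avlt <- tab[tab$score == "AVLT", ]
  expect_lt(mean(avlt$rho_partial), 0)
  expect_true(all(tab$p_fwe >= tab$p_raw))
})
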