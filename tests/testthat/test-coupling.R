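test_that("node coupling reproduces Spearman fixed points and tie handling", {
  expect_equal(node_coupling(c(1, 2, 3), c(0.1, 0.2, 0.3), min_pairs = 3)$rho, 1)
  expect_equal(node_coupling(c(1, 2, 3), c(0.3, 0.2, 0.1), min_pairs = 3)$rho, -1)
  r <- node_coupling(c(1, 2, 2, 5), c(0.3, 0.1, 0.4, 0.5), min_pairs = 4)
  expect_equal(r$rho, 0.6325, tolerance = 1e-4)
  expect_equal(r$n_pairs, 4)
  expect_error(node_coupling(1:3, 1:4), class = "sfconn_input_error")
})

test_that("selection rule and undefined flags follow the contract", {
  sc <- c(0, 3, 0, 7, 2)
  fc <- c(0.9, 0.1, 0.8, 0.5, 0.3)
  r <- node_coupling(sc, fc, min_pairs = 3)
  expect_equal(r$n_pairs, 3)             # sc-nonzero entries only
  expect_equal(r$rho, cor(c(3, 7, 2), c(0.1, 0.5, 0.3), method = "spearman"))

  fc0 <- c(0.9, 0.1, 0.8, 0, 0.3)
  rb <- node_coupling(sc, fc0, min_pairs = 2, selection = "both_nonzero")
  expect_equal(rb$n_pairs, 2)

  few <- node_coupling(c(0, 0, 0, 1, 2), fc, min_pairs = 3)
  expect_true(is.na(few$rho))
  expect_equal(few$reason, "too_few_pairs")

  const <- node_coupling(c(2, 2, 2, 2), c(1, 2, 3, 4), min_pairs = 3)
  expect_true(is.na(const$rho))
  expect_equal(const$reason, "constant_profile")
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(3)
  for (rep in 1:10) {
    sc <- rpois(20, 10) + 1
    fc <- rnorm(20)
    base <- node_coupling(sc, fc, min_pairs = 5)$rho
    expect_equal(node_coupling(sc, exp(fc), min_pairs = 5)$rho, base)
    expect_equal(node_coupling(sc^3, fc, min_pairs = 5)$rho, base)
    expect_equal(node_coupling(2 * sc + 3, 5 * fc - 1, min_pairs = 5)$rho, base)
    expect_equal(node_coupling(log(sc), fc, min_pairs = 5)$rho, base)
  }
})

test_that("subject coupling handles isolated nodes and monotone FC", {
  set.seed(8)
  n <- 12
  counts <- matrix(0, n, n)
  ut <- upper.tri(counts)
  counts[ut] <- rpois(sum(ut), 8)
  counts <- counts + t(counts)
  counts[3, ] <- counts[, 3] <- 0       # isolated node
  sc <- connectivity_matrix(counts, modality = "structural_count")
  fcv <- log1p(counts) / (1 + max(log1p(counts)))
  diag(fcv) <- 0
  fc <- connectivity_matrix(fcv, modality = "functional_weighted")
  prof <- subject_coupling(sc, fc, min_pairs = 3)
  expect_true(is.na(prof$rho[3]))
  expect_equal(prof$reason[3], "too_few_pairs")
  expect_true(all(abs(prof$rho[-3] - 1) < 1e-12))

  expect_error(subject_coupling(fc, fc), class = "sfconn_modality_error")
  bad <- fc
  bad$node_labels <- rev(bad$node_labels)
  expect_error(subject_coupling(sc, bad), class = "sfconn_validation_error")
})

test_that("binary structural weighting is degenerate and flagged", {
  counts <- matrix(5, 6, 6)
  diag(counts) <- 0
  sc <- connectivity_matrix(counts, modality = "structural_count")
  set.seed(2)
  v <- matrix(runif(36), 6, 6); v <- (v + t(v)) / 2; diag(v) <- 0
  fc <- connectivity_matrix(v, modality = "functional_weighted")
  expect_warning(p <- subject_coupling(sc, fc, min_pairs = 3,
                                       sc_weighting = "binary"),
                 "undefined at every node")
  expect_true(all(is.na(p$rho)))
})

test_that("cohort averaging uses defined values only and reports counts", {
  mk <- function(id, rho) data.frame(subject_id = id, node = c("A", "B"),
                                     rho = rho, n_pairs = 10L,
                                     reason = NA_character_)
  profs <- list(mk("s1", c(0.5, NA)), mk("s2", c(0.5, 0.2)),
                mk("s3", c(0.5, 0.4)))
  cc <- cohort_coupling(profs)
  expect_equal(cc$mean_rho[cc$node == "A"], 0.5)
  expect_equal(cc$n_subjects[cc$node == "B"], 2)
  expect_equal(cc$mean_rho[cc$node == "B"], 0.3)

  none <- list(mk("s1", c(NA, 1)), mk("s2", c(NA, 0)))
  cn <- cohort_coupling(none)
  expect_true(cn$all_undefined[cn$node == "A"])

  grp <- c(s1 = "HC", s2 = "VCI", s3 = "VCI")
  cg <- cohort_coupling(profs, groups = grp)
  expect_equal(cg$mean_rho_VCI[cg$node == "B"], 0.3)
  expect_equal(cg$n_HC[cg$node == "B"], 0L)
})

test_that("planted mixing difference is recovered node-wise", {
  p <- tiny_params(n_timepoints = 400)
  tmpl <- make_structural_template(p, "HC")
  sc <- sample_subject_sc(tmpl, p, seed = 4)
  m <- rep(0, p$n_nodes)
  m[5] <- 1                               # node A coupled, node B not
  b <- sample_subject_bold(sc, m, 2000, seed = 6)
  fc <- fisher_z(pearson_fc(b))
  prof <- subject_coupling(sc, fc, min_pairs = 3)
  expect_gt(prof$rho[5], prof$rho[9] + 0.3)
})

test_that("coupling estimator error shrinks with scan length", {
  p <- tiny_params()
  tmpl <- make_structural_template(p, "HC")
  sc <- sample_subject_sc(tmpl, p, seed = 21)
  ref <- subject_coupling(
    sc, fisher_z(pearson_fc(sample_subject_bold(sc, 0.6, 8000, seed = 77))),
    min_pairs = 3)$rho
  mae <- vapply(c(100, 500, 2000), function(tt) {
    est <- subject_coupling(
      sc, fisher_z(pearson_fc(sample_subject_bold(sc, 0.6, tt, seed = 78))),
      min_pairs = 3)$rho
    mean(abs(est - ref), na.rm = TRUE)
  }, numeric(1))
  expect_true(mae[3] < mae[1])
})
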