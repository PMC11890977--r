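make_cm <- function(v, modality = "structural_count") {
  connectivity_matrix(v, modality = modality)
}

test_that("fiber-count binarization uses the at-least rule", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 3   # at threshold: edge present
  v[1, 3] <- v[3, 1] <- 2   # below: absent
  b <- binarize_sc(make_cm(v), fiber_threshold = 3)
  expect_equal(b$values[1, 2], 1)
  expect_equal(b$values[1, 3], 0)
  expect_equal(b$modality, "structural_binary")

  empty <- binarize_sc(make_cm(matrix(0, 4, 4)), 3)
  expect_equal(sum(empty$values), 0)
})

test_that("group-consistency mask is strict and permutation-equivariant", {
  n <- 4
  mk <- function(present) {
    v <- matrix(0, n, n)
    if (present) v[1, 2] <- v[2, 1] <- 1
    v[3, 4] <- v[4, 3] <- 1
    make_cm(v, "structural_binary")
  }
  subs <- c(lapply(1:4, function(i) mk(TRUE)), list(mk(FALSE)))
  m <- group_consistency_mask(subs, 0.8)
  expect_equal(m$mask[3, 4], 1)          # 5/5 > 0.8
  expect_equal(m$mask[1, 2], 0)          # exactly 4/5 = 0.8 dropped
  expect_equal(m$consistency[1, 2], 0.8)

  m0 <- group_consistency_mask(subs, 0)
  expect_equal(m0$mask[1, 2], 1)         # present in >= 1 subject

  perm <- sample(length(subs))
  expect_identical(group_consistency_mask(subs[perm], 0.8)$mask, m$mask)
  expect_error(group_consistency_mask(list(), 0.8),
               class = "sfconn_input_error")
})

test_that("Pearson FC matches the closed form and rejects constant rows", {
  s <- rbind(c(1, 2, 4), c(1, 3, 5), c(3, 2, 1))
  fc <- pearson_fc(s)
  expect_equal(fc$values[1, 2], 0.9820, tolerance = 1e-4)
  expect_equal(fc$values[2, 3], -cor(c(1, 3, 5), c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(unname(diag(fc$values)), rep(0, 3))
  expect_identical(fc$values, t(fc$values))

  dup <- rbind(c(1, 2, 4), c(1, 2, 4), c(9, 1, 2))
  expect_equal(pearson_fc(dup)$values[1, 2], 1)
  expect_equal(pearson_fc(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 5, 9)))$values[1, 2], -1)

  expect_error(pearson_fc(rbind(c(1, 1, 1), c(1, 2, 3), c(2, 1, 3))), "1",
               class = "sfconn_input_error")
  expect_error(pearson_fc(rbind(c(1, 2), c(3, 4))),
               class = "sfconn_input_error")
})

test_that("Fisher z transform matches arctanh and reports clipping", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.5
  v[1, 3] <- v[3, 1] <- 1
  z <- fisher_z(make_cm(v, "functional_weighted"))
  expect_equal(z$values[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(z$values[2, 3], 0)
  expect_true(is.finite(z$values[1, 3]))
  expect_equal(attr(z, "n_clipped"), 1)
})

test_that("sparsity thresholding keeps the E strongest positive weights", {
  set.seed(42)
  n <- 90
  v <- matrix(rnorm(n * n), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  w <- make_cm(v, "functional_weighted")
  b <- sparsity_threshold(w, 0.01)
  expect_equal(sum(b$values) / 2, 40)     # floor(0.01 * 90 * 89 / 2)
  expect_false(attr(b, "shortfall"))

  neg <- make_cm(-abs(v), "functional_weighted")
  bn <- sparsity_threshold(neg, 0.1)
  expect_equal(sum(bn$values), 0)
  expect_true(attr(bn, "shortfall"))

  # deterministic lexicographic tie-break
  tie <- matrix(0, 4, 4)
  tie[1, 2] <- tie[2, 1] <- 0.7
  tie[3, 4] <- tie[4, 3] <- 0.7
  bt1 <- sparsity_threshold(make_cm(tie, "functional_weighted"), 1 / 6)
  bt2 <- sparsity_threshold(make_cm(tie, "functional_weighted"), 1 / 6)
  expect_identical(bt1$values, bt2$values)
  expect_equal(bt1$values[1, 2], 1)       # smaller (i,j) kept
  expect_equal(bt1$values[3, 4], 0)
})

test_that("edge sets nest across sparsity levels", {
  set.seed(7)
  for (rep in 1:5) {
    v <- matrix(rnorm(400), 20, 20)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    w <- make_cm(v, "functional_weighted")
    prev <- NULL
    for (s in c(0.05, 0.1, 0.2, 0.4)) {
      b <- sparsity_threshold(w, s)$values
      if (!is.null(prev)) expect_true(all(b[prev == 1] == 1))
      prev <- b
    }
  }
})

test_that("binarization commutes with the Fisher z transform", {
  set.seed(11)
  for (rep in 1:5) {
    v <- matrix(runif(100, -0.9, 0.9), 10, 10)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    w <- make_cm(v, "functional_weighted")
    z <- fisher_z(w)
    for (s in c(0.1, 0.3)) {
      expect_identical(sparsity_threshold(z, s)$values,
                       sparsity_threshold(w, s)$values)
    }
  }
})

test_that("sparsity grid enforces uniform spacing and bounds", {
  g <- sparsity_grid()
  expect_length(g$values, 40)
  expect_equal(g$values[1], 0.01)
  expect_equal(g$values[40], 0.40)
  expect_error(sparsity_grid(0, 0.4, 0.01), class = "sfconn_parameter_error")
  expect_error(sparsity_grid(0.1, 0.9, -0.1), class = "sfconn_parameter_error")
})
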