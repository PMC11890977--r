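# Covariate-adjusted two-group inference: normality-routed tests on OLS
# residuals, max-statistic permutation (or Bonferroni) family-wise error
# control, and partial correlations between network features and cognition.

covariate_design <- function(covariates) {
  stopifnot(all(c("age", "sex", "education") %in% names(covariates)))
  sex_num <- if (is.numeric(covariates$sex)) covariates$sex
             else as.numeric(covariates$sex == "male")
  x <- cbind(intercept = 1, age = covariates$age, sex = sex_num,
             education = covariates$education)
  if (anyNA(x)) {
    stop_sfconn("missing covariate values for included subjects",
                class = "sfconn_input_error")
  }
  x
}

#' Residualize an outcome on age, sex and education
#'
#' Ordinary least-squares residuals of the outcome on an intercept, age,
#' a single male/female indicator, and education (years).
#'
#' @param outcome numeric vector.
#' @param covariates data.frame with columns age, sex, education (sex as
#'   "male"/"female" or a 0/1 indicator).
#' @return residual vector (mean zero within 1e-10).
#' @export
residualize <- function(outcome, covariates) {
  x <- covariate_design(covariates)
  if (length(outcome) != nrow(x)) {
    stop_sfconn("outcome length %d != %d subjects", length(outcome), nrow(x),
                class = "sfconn_input_error")
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop_sfconn("rank-deficient covariate design; collinear column(s): %s",
                paste(bad, collapse = ", "), class = "sfconn_input_error")
  }
  as.numeric(qr.resid(qx, outcome))
}

#' Normality-routed two-group test
#'
#' Continuous features: Shapiro-Wilk on each group; if both p-values exceed
#' 0.05 the groups are compared with the pooled-variance independent
#' t-test, otherwise with the Mann-Whitney U test. Categorical features:
#' chi-squared on the 2-by-k table. All tests two-tailed.
#'
#' @param values_a,values_b feature values of the two groups (group A is
#'   reported as the direction reference, i.e. direction =
#'   sign(mean(a) - mean(b))).
#' @param kind `"continuous"` or `"categorical"`.
#' @param feature optional feature label carried into the result.
#' @return one-row data.frame: feature, test_used, statistic, p_raw,
#'   direction, n_a, n_b.
#' @export
route_test <- function(values_a, values_b,
                       kind = c("continuous", "categorical"),
                       feature = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    tab <- table(factor(rep(c("a", "b"), c(length(values_a), length(values_b)))),
                 c(values_a, values_b))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(data.frame(feature = feature, test_used = "chi_squared",
                      statistic = unname(ht$statistic),
                      p_raw = ht$p.value, direction = NA_real_,
                      n_a = length(values_a), n_b = length(values_b)))
  }
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop_sfconn("continuous routing needs >= 3 values per group",
                class = "sfconn_input_error")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) < 2) {
    stop_sfconn("degenerate feature: all values identical%s",
                if (is.na(feature)) "" else sprintf(" (%s)", feature),
                class = "sfconn_input_error")
  }
  sw_ok <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }
  normal <- sw_ok(values_a) && sw_ok(values_b)
  if (normal) {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    test_used <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = FALSE, correct = TRUE))
    test_used <- "mann_whitney"
  }
  data.frame(feature = feature, test_used = test_used,
             statistic = unname(ht$statistic), p_raw = ht$p.value,
             direction = sign(mean(values_a) - mean(values_b)),
             n_a = length(values_a), n_b = length(values_b))
}

# vectorized pooled-variance t statistics of many features under many
# group-A index sets; X is subjects x features, amat subjects x B 0/1
pooled_t_matrix <- function(x, amat) {
  n <- nrow(x)
  na <- colSums(amat)
  nb <- n - na
  tot <- colSums(x)
  tot2 <- colSums(x^2)
  sa <- crossprod(amat, x)          # B x m group-A sums
  sa2 <- crossprod(amat, x^2)
  ma <- sa / na
  mb <- sweep(-sa, 2, tot, "+") / nb
  ssa <- sa2 - na * ma^2
  ssb <- sweep(-sa2, 2, tot2, "+") - nb * mb^2
  s2 <- (ssa + ssb) / (n - 2)
  (ma - mb) / sqrt(s2 * (1 / na + 1 / nb))
}

#' Family-wise error correction
#'
#' `bonferroni`: `p_fwe = min(1, m * p_raw)`. `permutation_maxT`: group
#' labels are permuted `permutations` times; for each permutation the
#' maximal absolute statistic over the feature family is recorded and
#' `p_fwe = (1 + #\{max_b >= |obs|\}) / (permutations + 1)`. The statistic
#' is pooled t on the supplied (already residualized) feature matrix, or t
#' on rank-transformed features when `stat = "rank"`. Adjusted p-values are
#' floored at the raw p-values so `p_fwe >= p_raw` always holds.
#'
#' @param results data.frame with at least `p_raw` (and one row per
#'   feature, in the column order of `features`).
#' @param method `"bonferroni"` or `"permutation_maxT"`.
#' @param features subjects-by-features matrix of residualized values
#'   (required for `permutation_maxT`).
#' @param groups logical or 0/1 vector marking group A subjects (required
#'   for `permutation_maxT`).
#' @param permutations number of label permutations.
#' @param stat `"t"` or `"rank"`.
#' @param seed integer seed.
#' @return `results` with columns `p_fwe` and `fwe_method` added.
#' @export
fwe_correct <- function(results, method = c("permutation_maxT", "bonferroni"),
                        features = NULL, groups = NULL,
                        permutations = 1000, stat = c("t", "rank"),
                        seed = 1L) {
  method <- match.arg(method)
  stat <- match.arg(stat)
  if (nrow(results) == 0) {
    stop_sfconn("empty feature list", class = "sfconn_input_error")
  }
  m <- nrow(results)
  if (method == "bonferroni") {
    results$p_fwe <- pmin(1, m * results$p_raw)
  } else {
    if (is.null(features) || is.null(groups)) {
      stop_sfconn("permutation_maxT needs `features` and `groups`",
                  class = "sfconn_input_error")
    }
    x <- as.matrix(features)
    if (ncol(x) != m) {
      stop_sfconn("features has %d columns but results %d rows", ncol(x), m,
                  class = "sfconn_input_error")
    }
    if (stat == "rank") x <- apply(x, 2, rank)
    ga <- as.numeric(as.logical(groups))
    n <- nrow(x)
    obs <- abs(pooled_t_matrix(x, matrix(ga, n, 1)))[1, ]
    set.seed(seed)
    amat <- vapply(seq_len(permutations), function(b) sample(ga),
                   numeric(n))
    tmat <- abs(pooled_t_matrix(x, amat))
    max_null <- apply(tmat, 1, max)
    results$p_fwe <- vapply(obs, function(o)
      (1 + sum(max_null >= o)) / (permutations + 1), numeric(1))
    results$statistic_maxT <- obs
  }
  results$p_fwe <- pmax(results$p_fwe, results$p_raw)
  results$fwe_method <- method
  results
}

#' Covariate-adjusted group comparison across a feature family
#'
#' For every feature column: residualize on age/sex/education, route the
#' two-group test on the residuals via Shapiro-Wilk, then control the
#' family-wise error across all features with the configured method.
#' Direction is the sign of the adjusted (residual) VCI - HC mean
#' difference.
#'
#' @param features subjects-by-features numeric matrix or data.frame
#'   (rownames or `subject_id` column matching the manifest).
#' @param manifest manifest data.frame with subject_id, group, age, sex,
#'   education.
#' @param config an [sfc_config()].
#' @param feature_na `"drop"` features with any undefined value (flagged)
#'   or `"error"`.
#' @return data.frame of class `sfc_comparison`, one row per feature:
#'   feature, test_used, statistic, p_raw, p_fwe, direction, n_vci, n_hc.
#' @export
compare_groups <- function(features, manifest, config = sfc_config(),
                           feature_na = c("drop", "error")) {
  feature_na <- match.arg(feature_na)
  x <- as.matrix(features)
  if (is.null(rownames(x))) rownames(x) <- manifest$subject_id
  ids <- intersect(manifest$subject_id, rownames(x))
  man <- manifest[match(ids, manifest$subject_id), ]
  x <- x[ids, , drop = FALSE]
  keep_feat <- colSums(is.na(x)) == 0
  if (!all(keep_feat)) {
    if (feature_na == "error") {
      stop_sfconn("undefined values in feature(s): %s",
                  paste(colnames(x)[!keep_feat], collapse = ", "),
                  class = "sfconn_input_error")
    }
    dropped <- colnames(x)[!keep_feat]
    x <- x[, keep_feat, drop = FALSE]
  } else dropped <- character()
  if (ncol(x) == 0) {
    stop_sfconn("no analyzable features", class = "sfconn_input_error")
  }
  covs <- man[c("age", "sex", "education")]
  resid <- apply(x, 2, function(col) {
    if (length(unique(col)) < 2) {
      stop_sfconn("degenerate feature: constant column",
                  class = "sfconn_input_error")
    }
    residualize(col, covs)
  })
  is_vci <- man$group == "VCI"
  rows <- lapply(seq_len(ncol(resid)), function(j)
    route_test(resid[is_vci, j], resid[!is_vci, j], kind = "continuous",
               feature = colnames(resid)[j]))
  res <- do.call(rbind, rows)
  names(res)[names(res) == "n_a"] <- "n_vci"
  names(res)[names(res) == "n_b"] <- "n_hc"
  res <- fwe_correct(res, method = config$fwe_method, features = resid,
                     groups = is_vci, permutations = config$permutations,
                     stat = config$fwe_stat,
                     seed = substream(config$seed, 301L))
  attr(res, "dropped_features") <- dropped
  attr(res, "alpha") <- config$alpha
  class(res) <- c("sfc_comparison", "data.frame")
  res
}

#' @export
print.sfc_comparison <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  sig <- x[x$p_fwe < alpha, ]
  cat(sprintf("<sfc_comparison> %d feature(s), %d significant at FWE %g (%s)\n",
              nrow(x), nrow(sig), alpha, x$fwe_method[1]))
  if (nrow(sig)) {
    sig <- sig[order(sig$p_fwe, sig$feature), ]
    print.data.frame(utils::head(sig[c("feature", "test_used", "statistic",
                                       "p_raw", "p_fwe", "direction")], 20),
                     row.names = FALSE)
  }
  invisible(x)
}

#' Partial correlation controlling for age, sex and education
#'
#' Correlation of the covariate residuals of `x` and `y` (rank-transformed
#' first for Spearman); two-tailed p from the t approximation with
#' `n - covariates - 2` degrees of freedom. With `method = "auto"` both
#' coefficients are computed and the primary one is routed by Shapiro-Wilk
#' on the two residual vectors (both normal: Pearson, else Spearman).
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame with age, sex, education.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return one-row data.frame: rho_partial, p_raw, method, n (plus both
#'   coefficients under `rho_pearson`/`rho_spearman` when routed).
#' @export
partial_correlation <- function(x, y, covariates,
                                method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]; covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  n_cov <- 3L
  if (n <= n_cov + 2) {
    stop_sfconn("insufficient complete cases (n = %d) for partial correlation",
                n, class = "sfconn_input_error")
  }
  pc <- function(u, v, rank_first) {
    if (rank_first) { u <- rank(u); v <- rank(v) }
    ru <- residualize(u, covariates)
    rv <- residualize(v, covariates)
    r <- stats::cor(ru, rv)
    df <- n - n_cov - 2
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
    list(r = r, p = p)
  }
  pe <- pc(x, y, FALSE)
  sp <- pc(x, y, TRUE)
  if (method == "auto") {
    rx <- residualize(x, covariates)
    ry <- residualize(y, covariates)
    normal <- stats::shapiro.test(rx)$p.value > 0.05 &&
      stats::shapiro.test(ry)$p.value > 0.05
    method <- if (normal) "pearson" else "spearman"
  }
  primary <- if (method == "pearson") pe else sp
  data.frame(rho_partial = primary$r, p_raw = primary$p, method = method,
             n = n, rho_pearson = pe$r, rho_spearman = sp$r)
}

#' Coupling-cognition partial correlation table
#'
#' Partial correlations (age/sex/education controlled) between per-node
#' coupling and each cognitive score, with family-wise error control per
#' score across nodes (Bonferroni; permutation is not defined for this
#' correlation family and the node family is the reported one). Subjects
#' with a missing score are excluded pairwise and the complete-case n is
#' reported.
#'
#' @param coupling subjects-by-nodes rho matrix
#'   ([cohort_coupling_matrix()]).
#' @param manifest manifest data.frame.
#' @param scores score names (default [score_names()]).
#' @param nodes node subset (default all columns).
#' @param config an [sfc_config()].
#' @return data.frame of class `sfc_partial_table`: region, score,
#'   rho_partial, p_raw, p_fwe, method, n.
#' @export
coupling_cognition <- function(coupling, manifest, scores = score_names(),
                               nodes = colnames(coupling),
                               config = sfc_config()) {
  man <- manifest[match(rownames(coupling), manifest$subject_id), ]
  covs <- man[c("age", "sex", "education")]
  out <- list()
  for (sc in scores) {
    rows <- lapply(nodes, function(nd) {
      r <- tryCatch(
        partial_correlation(coupling[, nd], man[[sc]], covs, method = "auto"),
        sfconn_error = function(e) NULL)
      if (is.null(r)) return(NULL)
      cbind(data.frame(region = nd, score = sc), r)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) next
    tab <- fwe_correct(tab, method = "bonferroni")
    out[[sc]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sfc_partial_table", "data.frame")
  res
}
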