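# Seeded generator of coupled structural/functional cohorts with planted
# group effects, emulating a two-group (HC vs VCI) connectome study design.

#' Simulation parameters for a synthetic coupled SC/FC cohort
#'
#' Defaults emulate the study design the package targets: 90 network nodes,
#' 53 healthy controls vs 68 cases, 200-timepoint BOLD series. The
#' structural backbone is a ring-lattice small-world graph; streamline
#' counts are overdispersed (negative-binomial) integers on backbone edges;
#' BOLD series are drawn from a covariance that blends the normalized count
#' matrix with a decoupled random correlation component, per-node mixing
#' weight `m` controlling how strongly a node's functional profile follows
#' its structural profile. Cases receive `coupling_boost` extra mixing on
#' `boost_nodes` and a multiplicative count deficit on edges incident to
#' `deficit_nodes`; memory (AVLT) and processing-speed (SDMT) scores depend
#' negatively on the mean mixing weight over the boost nodes.
#'
#' @param n_nodes network order.
#' @param n_hc,n_vci group sizes.
#' @param n_timepoints BOLD volumes per subject.
#' @param backbone_k even ring-lattice neighbor count of the small-world
#'   backbone.
#' @param backbone_p rewiring probability of the backbone.
#' @param count_scale mean streamline count on a backbone edge.
#' @param count_dispersion negative-binomial size (smaller = more
#'   overdispersed).
#' @param weight_sdlog log-sd of the heavy-tailed edge-weight template.
#' @param vci_structural_deficit multiplicative count reduction (in `[0,1)`)
#'   on edges incident to `deficit_nodes` in the VCI group.
#' @param coupling_base baseline SC->FC mixing weight in `[0,1]`.
#' @param coupling_boost additive mixing increment on `boost_nodes` for VCI
#'   subjects; `coupling_base + coupling_boost <= 1`.
#' @param coupling_jitter_sd sd of per-subject Gaussian jitter of the mixing
#'   weight (truncated to `[0,1]`), giving within-group coupling variation.
#' @param deficit_nodes,boost_nodes node index sets (1-based).
#' @param cognition_effect slope of AVLT/SDMT on mean boost-node mixing
#'   weight (negative by default).
#' @param noise_sd residual sd of the cognition-linked scores.
#' @param seed integer master seed.
#' @return list of class `sfc_sim_params`.
#' @export
sim_params <- function(n_nodes = 90,
                       n_hc = 53,
                       n_vci = 68,
                       n_timepoints = 200,
                       backbone_k = 24,
                       backbone_p = 0.05,
                       count_scale = 30,
                       count_dispersion = 2.5,
                       weight_sdlog = 0.6,
                       vci_structural_deficit = 0.3,
                       coupling_base = 0.35,
                       coupling_boost = 0.3,
                       coupling_jitter_sd = 0.04,
                       deficit_nodes = c(1, 2, 35, 36, 45, 46, 51, 52, 57, 58, 59, 60),
                       boost_nodes = c(29, 30, 43, 44, 47, 48, 53, 54, 81, 82),
                       cognition_effect = -30,
                       noise_sd = 5,
                       seed = 1L) {
  p <- structure(list(n_nodes = n_nodes, n_hc = n_hc, n_vci = n_vci,
                      n_timepoints = n_timepoints,
                      backbone_k = backbone_k, backbone_p = backbone_p,
                      count_scale = count_scale,
                      count_dispersion = count_dispersion,
                      weight_sdlog = weight_sdlog,
                      vci_structural_deficit = vci_structural_deficit,
                      coupling_base = coupling_base,
                      coupling_boost = coupling_boost,
                      coupling_jitter_sd = coupling_jitter_sd,
                      deficit_nodes = as.integer(deficit_nodes),
                      boost_nodes = as.integer(boost_nodes),
                      cognition_effect = cognition_effect,
                      noise_sd = noise_sd,
                      seed = as.integer(seed)),
                 class = "sfc_sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$backbone_k >= p$n_nodes) {
    stop_sfconn("backbone_k (%d) must be < n_nodes (%d)",
                p$backbone_k, p$n_nodes, class = "sfconn_parameter_error")
  }
  if (p$backbone_k %% 2 != 0 || p$backbone_k < 2) {
    stop_sfconn("backbone_k must be a positive even integer",
                class = "sfconn_parameter_error")
  }
  if (p$coupling_base < 0 || p$coupling_boost < 0 ||
      p$coupling_base + p$coupling_boost > 1) {
    stop_sfconn("need coupling_base, coupling_boost >= 0 and base + boost <= 1",
                class = "sfconn_parameter_error")
  }
  bad <- c(p$deficit_nodes, p$boost_nodes)
  if (length(bad) && (min(bad) < 1 || max(bad) > p$n_nodes)) {
    stop_sfconn("deficit/boost node indices must lie in [1, n_nodes]",
                class = "sfconn_parameter_error")
  }
  if (p$noise_sd <= 0 || p$coupling_jitter_sd < 0 || p$count_dispersion <= 0) {
    stop_sfconn("dispersion and sd parameters must be positive",
                class = "sfconn_parameter_error")
  }
  if (!(p$vci_structural_deficit >= 0 && p$vci_structural_deficit < 1)) {
    stop_sfconn("vci_structural_deficit must lie in [0,1)",
                class = "sfconn_parameter_error")
  }
  invisible(p)
}

#' Group-level structural weight template
#'
#' Small-world backbone (ring lattice of degree `backbone_k` rewired with
#' probability `backbone_p`) with heavy-tailed (lognormal) positive edge
#' weights of mean `count_scale`. Backbone and weights are drawn from the
#' params seed only, so the two group templates share every edge; for group
#' `"VCI"` the weights on edges incident to `deficit_nodes` are then
#' multiplied by `1 - vci_structural_deficit`.
#'
#' @param params [sim_params()].
#' @param group `"HC"` or `"VCI"`.
#' @return symmetric non-negative weight matrix (zero diagonal).
#' @export
make_structural_template <- function(params, group = c("HC", "VCI")) {
  group <- match.arg(group)
  set.seed(substream(params$seed, 101L))
  g <- igraph::sample_smallworld(1, params$n_nodes, params$backbone_k / 2,
                                 params$backbone_p)
  g <- igraph::simplify(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  w <- matrix(0, params$n_nodes, params$n_nodes)
  ut <- upper.tri(a) & a > 0
  mu_log <- log(params$count_scale) - params$weight_sdlog^2 / 2
  w[ut] <- stats::rlnorm(sum(ut), meanlog = mu_log, sdlog = params$weight_sdlog)
  w <- w + t(w)
  if (group == "VCI" && params$vci_structural_deficit > 0) {
    idx <- params$deficit_nodes
    fac <- 1 - params$vci_structural_deficit
    w[idx, ] <- w[idx, ] * fac
    w[, idx] <- w[, idx] * fac
    # edges between two deficit nodes were scaled twice; undo one factor
    w[idx, idx] <- w[idx, idx] / fac
  }
  w
}

#' Sample one subject's streamline-count matrix from a template
#'
#' Counts are negative-binomial with mean equal to the template weight and
#' size `count_dispersion`, drawn independently per upper-triangle edge and
#' mirrored; zero-weight template entries stay exactly zero.
#'
#' @param template weight matrix from [make_structural_template()].
#' @param params [sim_params()].
#' @param seed integer seed for this subject.
#' @param node_labels optional node labels.
#' @return a `structural_count` [connectivity_matrix()].
#' @export
sample_subject_sc <- function(template, params, seed, node_labels = NULL) {
  set.seed(seed)
  n <- nrow(template)
  counts <- matrix(0, n, n)
  ut <- which(upper.tri(template) & template > 0)
  counts[ut] <- stats::rnbinom(length(ut), size = params$count_dispersion,
                               mu = template[ut])
  counts <- counts + t(counts)
  connectivity_matrix(counts, node_labels = node_labels,
                      modality = "structural_count")
}

#' Sample one subject's BOLD series coupled to its structural matrix
#'
#' Builds a target covariance `Sigma = W * S + (1 - W) * R` where `S` is the
#' square-root-compressed count matrix scaled to peak off-diagonal
#' magnitude `sc_amplitude` (a rank-preserving compression that keeps one
#' extreme count from squashing the rest of the profile, at an amplitude
#' that keeps the blend near positive definite) with unit diagonal, `R` is a seeded random
#' correlation matrix (the subject's decoupled functional component), and
#' `W[i,j] = max(m[i], m[j])` blends the two by the per-node mixing
#' weights `m`, so that a node designated as coupled has its entire
#' connectivity profile track structure. A diagonal ridge is escalated
#' geometrically from `ridge_start` (factor 2) until the smallest
#' eigenvalue exceeds 1e-6, then
#' `n_timepoints` independent multivariate normal samples are drawn. Since
#' the empirical correlation of the samples rescales by the inflated
#' diagonal, the ridge uniformly attenuates all off-diagonal correlations
#' and never reorders them.
#'
#' @param sc a `structural_count` [connectivity_matrix()].
#' @param mixing per-node mixing weights in `[0,1]`.
#' @param n_timepoints number of samples (columns).
#' @param seed integer seed.
#' @param sc_amplitude peak off-diagonal magnitude of the structural
#'   component; 0.4 keeps the blend near positive definite so the ridge
#'   (which attenuates all off-diagonal correlations) stays small.
#' @param ridge_start initial ridge.
#' @param ridge_max largest ridge tried before erroring.
#' @return node-by-time matrix with attributes `ridge` (value used) and
#'   `min_eigenvalue` (of the pre-ridge blend).
#' @export
sample_subject_bold <- function(sc, mixing, n_timepoints, seed,
                                sc_amplitude = 0.4,
                                ridge_start = 1e-6, ridge_max = 10) {
  stopifnot(inherits(sc, "connectivity_matrix"))
  if (sc$modality != "structural_count") {
    stop_sfconn("sample_subject_bold needs a structural_count matrix, got %s",
                sc$modality, class = "sfconn_modality_error")
  }
  n <- length(sc$node_labels)
  if (length(mixing) == 1) mixing <- rep(mixing, n)
  if (length(mixing) != n || any(mixing < 0 | mixing > 1)) {
    stop_sfconn("mixing must be %d weights in [0,1]", n,
                class = "sfconn_parameter_error")
  }
  set.seed(seed)
  s <- sqrt(sc$values)
  mx <- max(s)
  s <- if (mx > 0) sc_amplitude * s / mx else s
  diag(s) <- 1
  # decoupled component: well-conditioned random correlation matrix
  g <- matrix(stats::rnorm(2 * n * n), 2 * n, n)
  r <- stats::cov2cor(crossprod(g) / (2 * n))
  w <- outer(mixing, mixing, pmax)
  sigma <- w * s + (1 - w) * r
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  ridge <- 0
  if (ev_min <= 1e-6) {
    ridge <- ridge_start
    while (ridge <= ridge_max) {
      ev <- min(eigen(sigma + diag(ridge, n), symmetric = TRUE,
                      only.values = TRUE)$values)
      if (ev > 1e-6) break
      ridge <- ridge * 2
    }
    if (ridge > ridge_max) {
      stop_sfconn("covariance not positive definite (smallest eigenvalue %g) even at ridge %g",
                  ev_min, ridge_max, class = "sfconn_generation_error")
    }
    sigma <- sigma + diag(ridge, n)
  }
  l <- chol(sigma)
  x <- t(l) %*% matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
  attr(x, "ridge") <- ridge
  attr(x, "min_eigenvalue") <- ev_min
  x
}

#' Sample a subject's cognitive scores
#'
#' AVLT and SDMT carry the planted effect: intercept +
#' `cognition_effect * mean(mixing over boost_nodes)` + small age and
#' education terms + Gaussian noise. The remaining scores (MMSE, AVLT_N5,
#' BNT and the right-skewed STT_B) have null slopes with respect to
#' coupling.
#'
#' @param age,education subject covariates.
#' @param mixing the subject's per-node true mixing weights.
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return named numeric vector over [score_names()].
#' @export
sample_cognition <- function(age, education, mixing, params, seed) {
  set.seed(seed)
  mb <- mean(mixing[params$boost_nodes])
  eff <- params$cognition_effect * mb
  avlt <- 42 + eff - 0.25 * (age - 68) + 0.8 * (education - 10.5) +
    stats::rnorm(1, 0, params$noise_sd)
  sdmt <- 46 + eff - 0.30 * (age - 68) + 1.0 * (education - 10.5) +
    stats::rnorm(1, 0, params$noise_sd)
  mmse <- min(30, round(stats::rnorm(1, 27.5, 1.5)))
  avlt_n5 <- max(0, round(stats::rnorm(1, 4.5, 1.8)))
  stt_b <- stats::rlnorm(1, meanlog = log(140), sdlog = 0.35)
  bnt <- round(stats::rnorm(1, 23, 2.5))
  c(MMSE = mmse, AVLT = avlt, AVLT_N5 = avlt_n5, SDMT = sdmt,
    STT_B = stt_b, BNT = bnt)
}

#' Generate a full synthetic cohort with ground truth
#'
#' HC subjects receive mixing `coupling_base` at every node; VCI subjects
#' `coupling_base + coupling_boost` on `boost_nodes` and `coupling_base`
#' elsewhere; every weight then gets per-subject truncated Gaussian jitter
#' (`coupling_jitter_sd`). Fully deterministic under `params$seed`.
#'
#' @param params [sim_params()].
#' @param atlas_labels node labels (defaults to the shipped 90-region
#'   labels when `n_nodes == 90`, else `V1..Vn`).
#' @return list of class `sfc_simulation` with elements `cohort` (an
#'   `sfc_cohort`) and `truth` (mixing matrix, node sets, templates,
#'   cognition slopes).
#' @export
generate_cohort <- function(params = sim_params(), atlas_labels = NULL) {
  if (is.null(atlas_labels)) {
    atlas_labels <- if (params$n_nodes == 90) aal90_labels()
                    else paste0("V", seq_len(params$n_nodes))
  }
  tmpl <- list(HC = make_structural_template(params, "HC"),
               VCI = make_structural_template(params, "VCI"))
  n_total <- params$n_hc + params$n_vci
  groups <- rep(c("HC", "VCI"), c(params$n_hc, params$n_vci))
  ids <- sprintf("S%03d", seq_len(n_total))

  mixing_truth <- matrix(NA_real_, n_total, params$n_nodes,
                         dimnames = list(ids, atlas_labels))
  sc <- bold <- list()
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    id <- ids[i]
    grp <- groups[i]
    set.seed(substream(params$seed, 201L, i))
    age <- Inf
    while (age < 50 || age > 75) age <- stats::rnorm(1, 68, 6)
    sex <- if (stats::runif(1) < 0.44) "male" else "female"
    education <- max(0, round(stats::rnorm(1, 10.5, 2.5)))

    m <- rep(params$coupling_base, params$n_nodes)
    if (grp == "VCI") {
      m[params$boost_nodes] <- params$coupling_base + params$coupling_boost
    }
    if (params$coupling_jitter_sd > 0) {
      m <- m + stats::rnorm(params$n_nodes, 0, params$coupling_jitter_sd)
      m <- pmin(1, pmax(0, m))
    }
    mixing_truth[i, ] <- m

    sc[[id]] <- sample_subject_sc(tmpl[[grp]], params,
                                  seed = substream(params$seed, 202L, i),
                                  node_labels = atlas_labels)
    bold[[id]] <- sample_subject_bold(sc[[id]], m, params$n_timepoints,
                                      seed = substream(params$seed, 203L, i))
    scores <- sample_cognition(age, education, m, params,
                               seed = substream(params$seed, 204L, i))
    rows[[i]] <- data.frame(subject_id = id, group = grp, age = age,
                            sex = sex, education = education,
                            t(scores),
                            sc_source = paste0(id, "_sc.txt"),
                            bold_source = paste0(id, "_bold.txt"),
                            stringsAsFactors = FALSE)
  }
  subjects <- do.call(rbind, rows)
  truth <- list(mixing = mixing_truth,
                boost_nodes = params$boost_nodes,
                deficit_nodes = params$deficit_nodes,
                cognition_slopes = c(AVLT = params$cognition_effect,
                                     SDMT = params$cognition_effect,
                                     MMSE = 0, AVLT_N5 = 0, STT_B = 0, BNT = 0),
                templates = tmpl,
                params = unclass(params))
  structure(list(cohort = cohort(subjects, sc, bold, atlas_labels),
                 truth = truth),
            class = "sfc_simulation")
}

#' @export
print.sfc_simulation <- function(x, ...) {
  cat("<sfc_simulation>\n  ")
  print(x$cohort)
  cat(sprintf("  planted: %d boost node(s), %d deficit node(s)\n",
              length(x$truth$boost_nodes), length(x$truth$deficit_nodes)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the manifest CSV, one count-matrix and one series file per
#' subject, and the ground truth as JSON.
#'
#' @param sim an `sfc_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- sim$cohort
  write_manifest(co$subjects, file.path(dir, "manifest.csv"))
  for (id in co$subjects$subject_id) {
    write_matrix(co$sc[[id]], file.path(dir, paste0(id, "_sc.txt")))
    write_series(co$bold[[id]], file.path(dir, paste0(id, "_bold.txt")))
  }
  writeLines(co$atlas_labels, file.path(dir, "atlas_labels.txt"))
  truth <- sim$truth
  truth$templates <- NULL  # regenerable from params; keep the JSON small
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
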