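# End-to-end orchestration: simulate -> build -> topology -> coupling ->
# stats, with a run record (config snapshot, seeds, stage timings, output
# hashes) and a report mirroring the analysis structure: structural global
# contrasts, structural nodal contrasts, functional AUC contrasts, the
# coupling contrast map, and coupling-cognition partial correlations.

nodal_metric_names <- c("degree", "betweenness", "NEglob", "NEloc", "NCp", "NLp")
global_metric_names <- c("Eglob", "Eloc", "Cp", "Lp", "Sigma")

structural_features <- function(cohort, networks, config) {
  ids <- cohort$subjects$subject_id
  np <- function(i) if (config$compute_sigma)
    null_ensemble_params(config$null_count, config$swaps_per_edge,
                         substream(config$seed, 401L, i)) else NULL
  glob <- nodal <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    a <- networks$sc_binary[[ids[i]]]
    gm <- global_metrics(a, nulls = np(i), cp_zero_mode = config$cp_zero_mode)
    glob[[i]] <- data.frame(subject_id = ids[i], Eglob = gm$Eglob,
                            Eloc = gm$Eloc, Cp = gm$Cp, Lp = gm$Lp,
                            Sigma = gm$Sigma,
                            disconnected = gm$disconnected_flag)
    nm <- nodal_metrics(a)
    nm$subject_id <- ids[i]
    nodal[[i]] <- nm
  }
  list(global = do.call(rbind, glob), nodal = do.call(rbind, nodal))
}

functional_auc_features <- function(cohort, networks, config) {
  ids <- cohort$subjects$subject_id
  grid <- networks$grid
  glob <- vector("list", length(ids))
  nodal <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    np <- if (config$compute_sigma)
      null_ensemble_params(config$null_count, config$swaps_per_edge,
                           substream(config$seed, 402L, i)) else NULL
    sm <- metrics_over_sparsity(networks$fc_z[[ids[i]]], grid, nulls = np,
                                cp_zero_mode = config$cp_zero_mode)
    aucs <- vapply(global_metric_names, function(mt) {
      v <- sm$global[[mt]]
      if (all(is.finite(v))) auc_curve(v, grid) else NA_real_
    }, numeric(1))
    glob[[i]] <- data.frame(subject_id = ids[i], t(aucs))
    per_node <- lapply(nodal_metric_names, function(mt) {
      m <- vapply(sm$nodal, function(df) df[[mt]], numeric(length(cohort$atlas_labels)))
      apply(m, 1, function(v) if (all(is.finite(v))) trapz(grid$values, v)
                              else NA_real_)
    })
    names(per_node) <- paste0("a", nodal_metric_names)
    nodal[[i]] <- data.frame(subject_id = ids[i],
                             node = cohort$atlas_labels, per_node)
  }
  list(global = do.call(rbind, glob), nodal = do.call(rbind, nodal))
}

wide_feature_matrix <- function(long, id_col, node_col, value_col) {
  ids <- unique(long[[id_col]])
  nodes <- unique(long[[node_col]])
  m <- matrix(NA_real_, length(ids), length(nodes),
              dimnames = list(ids, nodes))
  m[cbind(match(long[[id_col]], ids), match(long[[node_col]], nodes))] <-
    long[[value_col]]
  m
}

run_contrasts <- function(feat_global, feat_nodal, manifest, config, prefix) {
  out <- list()
  gm <- as.matrix(feat_global[setdiff(names(feat_global),
                                      c("subject_id", "disconnected"))])
  rownames(gm) <- feat_global$subject_id
  gm <- gm[, colSums(is.na(gm)) == 0, drop = FALSE]
  gm <- gm[, apply(gm, 2, function(v) length(unique(v)) > 1), drop = FALSE]
  out$global <- if (ncol(gm) > 0) {
    r <- compare_groups(gm, manifest, config)
    r$family <- paste0(prefix, "_global")
    r
  } else NULL
  nod <- list()
  for (mt in intersect(nodal_metric_names, c(names(feat_nodal),
                                             sub("^a", "", names(feat_nodal))))) {
    col <- if (mt %in% names(feat_nodal)) mt else paste0("a", mt)
    if (!col %in% names(feat_nodal)) next
    m <- wide_feature_matrix(feat_nodal, "subject_id", "node", col)
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
    m <- m[, apply(m, 2, function(v) length(unique(v)) > 1), drop = FALSE]
    if (ncol(m) == 0) next
    r <- compare_groups(m, manifest, config)
    r$family <- paste0(prefix, "_nodal_", mt)
    nod[[mt]] <- r
  }
  out$nodal <- if (length(nod)) do.call(rbind, nod) else NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, builds structural and functional
#' networks, computes the topology battery (structural metrics on the
#' masked binary network; functional metrics AUC-summarized over the
#' sparsity grid), estimates per-node structure-function coupling, and
#' performs covariate-adjusted group inference with family-wise error
#' control plus coupling-cognition partial correlations at the nodes whose
#' coupling differs between groups.
#'
#' @param sim_params a [sim_params()] (ignored when `cohort` is given).
#' @param config an [sfc_config()].
#' @param cohort optionally, an existing `sfc_cohort`.
#' @param out_dir optional output directory; when given, all tables, the
#'   report JSON and a run record with content hashes are written.
#' @return list of class `sfc_run`: cohort, truth (when simulated),
#'   networks summary, feature tables, comparison tables, coupling tables,
#'   partial-correlation table, report, record.
#' @export
run_pipeline <- function(sim_params = sfconn::sim_params(),
                         config = sfc_config(),
                         cohort = NULL, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  truth <- NULL
  if (is.null(cohort)) {
    s <- generate_cohort(sim_params)
    cohort <- s$cohort
    truth <- s$truth
  }
  report_v <- validate_cohort(cohort)
  if (length(report_v)) {
    stop_sfconn("stage simulate/load: cohort invalid: %s",
                paste(report_v, collapse = "; "), class = "sfconn_stage_error")
  }
  tick("simulate")

  networks <- build_networks(cohort, config)
  tick("build")

  sc_feat <- structural_features(cohort, networks, config)
  fc_feat <- functional_auc_features(cohort, networks, config)
  tick("topology")

  coup <- cohort_coupling_matrix(cohort, networks, config)
  grp <- stats::setNames(cohort$subjects$group, cohort$subjects$subject_id)
  coup_summary <- cohort_coupling(attr(coup, "profiles"), groups = grp)
  tick("coupling")

  man <- cohort$subjects
  sc_res <- run_contrasts(sc_feat$global, sc_feat$nodal, man, config,
                          "structural")
  fc_res <- run_contrasts(fc_feat$global, fc_feat$nodal, man, config,
                          "functional_auc")
  coup_ok <- coup[, colSums(is.na(coup)) == 0, drop = FALSE]
  coup_res <- compare_groups(coup_ok, man, config)
  coup_res$family <- "coupling"
  sig_nodes <- coup_res$feature[coup_res$p_fwe < config$alpha]
  partial <- if (length(sig_nodes)) {
    coupling_cognition(coup, man, scores = c("AVLT", "SDMT", "STT_B", "BNT"),
                       nodes = sig_nodes, config = config)
  } else NULL
  tick("stats")

  run <- structure(list(cohort = cohort, truth = truth,
                        config = config,
                        sim_params = if (is.null(truth)) NULL else truth$params,
                        features = list(structural = sc_feat,
                                        functional_auc = fc_feat,
                                        coupling = coup),
                        coupling_summary = coup_summary,
                        comparisons = list(structural = sc_res,
                                           functional_auc = fc_res,
                                           coupling = coup_res),
                        partial_correlations = partial,
                        timings = timings),
                   class = "sfc_run")
  run$report <- make_report(run)
  if (!is.null(out_dir)) {
    run$record <- write_run(run, out_dir)
  }
  run
}

#' @export
print.sfc_run <- function(x, ...) {
  cat("<sfc_run>\n  ")
  print(x$cohort)
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    tab <- if (is.data.frame(cc)) list(cc) else Filter(Negate(is.null), cc)
    n_sig <- sum(vapply(tab, function(d) sum(d$p_fwe < attr(d, "alpha")),
                        numeric(1)))
    cat(sprintf("  %-16s %d significant feature(s) at FWE %.2g\n",
                nm, n_sig, x$config$alpha))
  }
  invisible(x)
}

sig_table <- function(res, alpha) {
  if (is.null(res)) return(NULL)
  s <- res[res$p_fwe < alpha, , drop = FALSE]
  s <- s[order(s$p_fwe, s$feature), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Build the machine-readable run report
#'
#' Five sections mirroring the analysis structure; significant-feature
#' lists are sorted by adjusted p then label; sections whose stage output
#' is missing are marked unavailable rather than failing. The JSON schema
#' is stable across runs.
#'
#' @param run an `sfc_run`.
#' @return list of class `sfc_report`.
#' @export
make_report <- function(run) {
  alpha <- run$config$alpha
  section <- function(res) {
    if (is.null(res)) return(list(available = FALSE))
    list(available = TRUE, n_features = nrow(res),
         n_significant = sum(res$p_fwe < alpha),
         significant = sig_table(res, alpha))
  }
  rep <- list(
    alpha = alpha,
    fwe_method = run$config$fwe_method,
    seed = run$config$seed,
    n_subjects = nrow(run$cohort$subjects),
    n_nodes = length(run$cohort$atlas_labels),
    structural_global = section(run$comparisons$structural$global),
    structural_nodal = section(run$comparisons$structural$nodal),
    functional_auc = section(rbind(run$comparisons$functional_auc$global,
                                   run$comparisons$functional_auc$nodal)),
    coupling_contrast = section(run$comparisons$coupling),
    coupling_cognition = if (is.null(run$partial_correlations))
      list(available = FALSE)
    else list(available = TRUE,
              n_pairs = nrow(run$partial_correlations),
              significant = {
                p <- run$partial_correlations
                s <- p[p$p_fwe < alpha, , drop = FALSE]
                s <- s[order(s$p_fwe, s$region, s$score), , drop = FALSE]
                rownames(s) <- NULL
                s
              })
  )
  structure(rep, class = "sfc_report")
}

#' @export
print.sfc_report <- function(x, ...) {
  cat(sprintf("<sfc_report> %d subjects, %d nodes, FWE %s at alpha %g\n",
              x$n_subjects, x$n_nodes, x$fwe_method, x$alpha))
  for (nm in c("structural_global", "structural_nodal", "functional_auc",
               "coupling_contrast")) {
    s <- x[[nm]]
    if (!isTRUE(s$available)) {
      cat(sprintf("  %-18s unavailable\n", nm))
    } else if (s$n_significant == 0) {
      cat(sprintf("  %-18s no significant features (%d tested)\n",
                  nm, s$n_features))
    } else {
      cat(sprintf("  %-18s %d/%d significant: %s\n", nm, s$n_significant,
                  s$n_features,
                  paste(utils::head(s$significant$feature, 8), collapse = ", ")))
    }
  }
  cc <- x$coupling_cognition
  if (isTRUE(cc$available)) {
    cat(sprintf("  %-18s %d significant pair(s)\n", "coupling_cognition",
                if (is.null(cc$significant)) 0 else nrow(cc$significant)))
  } else {
    cat("  coupling_cognition unavailable\n")
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wcsv(run$cohort$subjects, "manifest.csv")
  wcsv(run$features$structural$global, "structural_global_metrics.csv")
  wcsv(run$features$structural$nodal, "structural_nodal_metrics.csv")
  wcsv(run$features$functional_auc$global, "functional_global_auc.csv")
  wcsv(run$features$functional_auc$nodal, "functional_nodal_auc.csv")
  coup <- run$features$coupling
  wcsv(data.frame(subject_id = rownames(coup), coup, check.names = FALSE),
       "coupling.csv")
  wcsv(run$coupling_summary, "coupling_summary.csv")
  for (nm in names(run$comparisons)) {
    cc <- run$comparisons[[nm]]
    if (is.data.frame(cc)) wcsv(cc, paste0("contrast_", nm, ".csv"))
    else {
      if (!is.null(cc$global)) wcsv(cc$global, paste0("contrast_", nm, "_global.csv"))
      if (!is.null(cc$nodal)) wcsv(cc$nodal, paste0("contrast_", nm, "_nodal.csv"))
    }
  }
  if (!is.null(run$partial_correlations)) {
    wcsv(run$partial_correlations, "coupling_cognition.csv")
  }
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(run$report), rp, auto_unbox = TRUE,
                       digits = NA, na = "null")
  paths <- c(paths, rp)
  hashes <- tools::md5sum(paths)
  names(hashes) <- basename(names(hashes))
  record <- list(package_version = as.character(utils::packageVersion("sfconn")),
                 config = unclass(run$config),
                 sim_params = run$sim_params,
                 seed = run$config$seed,
                 timings = as.list(run$timings),
                 outputs = as.list(hashes))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  record
}
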