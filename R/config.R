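#' Analysis configuration
#'
#' Collects every tunable constant of the analysis pipeline. Defaults are
#' the study design values: streamline-count threshold 3, group-consistency
#' proportion 0.8 (strict "over"), sparsity grid 0.01..0.40 step 0.01,
#' 100 degree-preserving nulls for small-worldness, 1000 label permutations
#' for family-wise error control at alpha 0.05.
#'
#' @param fiber_threshold minimal streamline count for a structural edge.
#' @param group_consistency proportion of subjects an edge must *exceed* to
#'   be retained in the group mask.
#' @param consistency_scope `"all"` (mask from all subjects) or
#'   `"per_group"`.
#' @param sparsity_grid numeric `c(min, max, step)` for the functional
#'   sparsity sweep.
#' @param null_count null networks per graph for small-worldness.
#' @param swaps_per_edge attempted double-edge swaps per edge per null.
#' @param permutations label permutations for max-statistic FWE.
#' @param alpha significance level.
#' @param fwe_method `"permutation_maxT"` or `"bonferroni"`.
#' @param fwe_stat statistic maximized in permutation FWE: `"t"` (pooled t
#'   on residuals) or `"rank"` (t on rank-transformed residuals).
#' @param seed master seed.
#' @param coupling_sc_weighting `"count"` (default) or `"binary"` structural
#'   profile used for coupling.
#' @param coupling_selection `"sc_nonzero"` (default) or `"both_nonzero"`
#'   profile-component selection rule.
#' @param min_coupling_pairs minimal profile pairs for a defined rho.
#' @param cp_zero_mode `"include"` degree-<2 nodes as C_i = 0 in Cp (default)
#'   or `"exclude"` them from the average.
#' @param compute_sigma compute small-worldness (needs the null ensemble).
#' @return list of class `sfc_config`.
#' @export
sfc_config <- function(fiber_threshold = 3,
                       group_consistency = 0.8,
                       consistency_scope = c("all", "per_group"),
                       sparsity_grid = c(0.01, 0.40, 0.01),
                       null_count = 100,
                       swaps_per_edge = 10,
                       permutations = 1000,
                       alpha = 0.05,
                       fwe_method = c("permutation_maxT", "bonferroni"),
                       fwe_stat = c("t", "rank"),
                       seed = 1L,
                       coupling_sc_weighting = c("count", "binary"),
                       coupling_selection = c("sc_nonzero", "both_nonzero"),
                       min_coupling_pairs = 10,
                       cp_zero_mode = c("include", "exclude"),
                       compute_sigma = TRUE) {
  cfg <- list(
    fiber_threshold = fiber_threshold,
    group_consistency = group_consistency,
    consistency_scope = match.arg(consistency_scope),
    sparsity_grid = sparsity_grid,
    null_count = null_count,
    swaps_per_edge = swaps_per_edge,
    permutations = permutations,
    alpha = alpha,
    fwe_method = match.arg(fwe_method),
    fwe_stat = match.arg(fwe_stat),
    seed = as.integer(seed),
    coupling_sc_weighting = match.arg(coupling_sc_weighting),
    coupling_selection = match.arg(coupling_selection),
    min_coupling_pairs = min_coupling_pairs,
    cp_zero_mode = match.arg(cp_zero_mode),
    compute_sigma = isTRUE(compute_sigma)
  )
  validate_config(cfg)
  structure(cfg, class = "sfc_config")
}

validate_config <- function(cfg) {
  g <- cfg$sparsity_grid
  if (length(g) != 3 || !(0 < g[1] && g[1] <= g[2] && g[2] < 1) || g[3] <= 0) {
    stop_sfconn("sparsity_grid must be c(min, max, step) with 0 < min <= max < 1, step > 0",
                class = "sfconn_parameter_error")
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop_sfconn("alpha must lie in (0,1)", class = "sfconn_parameter_error")
  }
  if (!is_count(cfg$fiber_threshold) || cfg$fiber_threshold < 1) {
    stop_sfconn("fiber_threshold must be an integer >= 1",
                class = "sfconn_parameter_error")
  }
  if (!(cfg$group_consistency >= 0 && cfg$group_consistency < 1)) {
    stop_sfconn("group_consistency must lie in [0,1)",
                class = "sfconn_parameter_error")
  }
  invisible(cfg)
}

#' @export
print.sfc_config <- function(x, ...) {
  cat("<sfc_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, paste(x[[k]], collapse = " ")))
  }
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [sfc_config()] for `read_config`; `path` invisibly for
#'   `write_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sfc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_sfconn("unknown config key(s): %s", paste(unknown, collapse = ", "),
                class = "sfconn_schema_error")
  }
  do.call(sfc_config, vals)
}

#' @rdname read_config
#' @param cfg an [sfc_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
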