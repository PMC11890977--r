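# Per-node structure-function coupling: Spearman rank correlation between
# a node's structural and functional connectivity profiles, restricted to
# non-zero structural components, averaged across the cohort.

#' Spearman coupling of one node's SC and FC profiles
#'
#' Selects the profile components with non-zero structural entry (or
#' non-zero in both profiles, per `selection`) and computes Spearman's rho
#' with average ranks for ties. Undefined (NA, with a reason) when fewer
#' than `min_pairs` components survive selection or a selected vector is
#' constant.
#'
#' @param sc_profile numeric vector: one node's structural column with the
#'   self-entry removed.
#' @param fc_profile numeric vector of the same length: the functional
#'   column.
#' @param min_pairs minimal pairs for a defined rho (default 10).
#' @param selection `"sc_nonzero"` (default) or `"both_nonzero"`.
#' @return list with `rho` (NA when undefined), `n_pairs`, `reason` (NA or
#'   why rho is undefined).
#' @export
node_coupling <- function(sc_profile, fc_profile, min_pairs = 10,
                          selection = c("sc_nonzero", "both_nonzero")) {
  selection <- match.arg(selection)
  if (length(sc_profile) != length(fc_profile)) {
    stop_sfconn("profile length mismatch (%d vs %d)", length(sc_profile),
                length(fc_profile), class = "sfconn_input_error")
  }
  idx <- if (selection == "sc_nonzero") which(sc_profile != 0)
         else which(sc_profile != 0 & fc_profile != 0)
  n_pairs <- length(idx)
  if (n_pairs < min_pairs) {
    return(list(rho = NA_real_, n_pairs = n_pairs, reason = "too_few_pairs"))
  }
  x <- sc_profile[idx]
  y <- fc_profile[idx]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, n_pairs = n_pairs, reason = "constant_profile"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  list(rho = rho, n_pairs = n_pairs, reason = NA_character_)
}

#' Coupling profile of one subject
#'
#' Applies [node_coupling()] to every node: the structural profile is the
#' node's column of the count matrix (or the binarized matrix when
#' `sc_weighting = "binary"`), the functional profile the node's column of
#' the weighted (Fisher-z) FC matrix; the diagonal self-entry is excluded.
#' Binary structural weighting is retained for sensitivity analysis; it is
#' degenerate for Spearman (constant profile) and yields all-undefined
#' output, which is flagged with a warning.
#'
#' @param sc a `structural_count` or `structural_binary`
#'   [connectivity_matrix()].
#' @param fc a `functional_weighted` [connectivity_matrix()].
#' @param min_pairs,selection see [node_coupling()].
#' @param sc_weighting `"count"` (default) or `"binary"`.
#' @param subject_id optional id carried into the result.
#' @return data.frame of class `coupling_profile`: node, rho, n_pairs,
#'   reason.
#' @export
subject_coupling <- function(sc, fc, min_pairs = 10,
                             selection = "sc_nonzero",
                             sc_weighting = c("count", "binary"),
                             subject_id = NA_character_) {
  sc_weighting <- match.arg(sc_weighting)
  stopifnot(inherits(sc, "connectivity_matrix"),
            inherits(fc, "connectivity_matrix"))
  if (!startsWith(sc$modality, "structural")) {
    stop_sfconn("sc must be a structural matrix, got %s", sc$modality,
                class = "sfconn_modality_error")
  }
  if (!startsWith(fc$modality, "functional")) {
    stop_sfconn("fc must be a functional matrix, got %s", fc$modality,
                class = "sfconn_modality_error")
  }
  if (!identical(sc$node_labels, fc$node_labels)) {
    stop_sfconn("node order differs between SC and FC",
                class = "sfconn_validation_error")
  }
  s <- sc$values
  if (sc_weighting == "binary") s <- (s != 0) * 1
  f <- fc$values
  n <- nrow(s)
  res <- lapply(seq_len(n), function(i)
    node_coupling(s[-i, i], f[-i, i], min_pairs = min_pairs,
                  selection = selection))
  out <- data.frame(subject_id = subject_id, node = sc$node_labels,
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    n_pairs = vapply(res, `[[`, integer(1), "n_pairs"),
                    reason = vapply(res, `[[`, character(1), "reason"),
                    row.names = NULL)
  if (all(is.na(out$rho))) {
    warning("coupling undefined at every node (degenerate profiles?)",
            call. = FALSE)
  }
  class(out) <- c("coupling_profile", "data.frame")
  out
}

#' Cohort-level coupling summaries
#'
#' Per-node mean rho over defined values only, with the count of
#' contributing subjects; per-group means when group labels are supplied.
#' Nodes with zero defined subjects are flagged.
#'
#' @param profiles list of [subject_coupling()] results (or a long
#'   data.frame binding them).
#' @param groups optional named vector mapping subject_id to group.
#' @return data.frame of class `cohort_coupling`: node, mean_rho,
#'   n_subjects, all_undefined, plus per-group mean/n columns when groups
#'   are given.
#' @export
cohort_coupling <- function(profiles, groups = NULL) {
  long <- if (is.data.frame(profiles)) profiles else do.call(rbind, profiles)
  nodes <- unique(long$node)
  agg <- function(sub) {
    ok <- !is.na(sub$rho)
    c(mean_rho = if (any(ok)) mean(sub$rho[ok]) else NA_real_,
      n = sum(ok))
  }
  base <- t(vapply(nodes, function(nd) agg(long[long$node == nd, ]),
                   numeric(2)))
  out <- data.frame(node = nodes, mean_rho = base[, 1],
                    n_subjects = as.integer(base[, 2]),
                    all_undefined = base[, 2] == 0, row.names = NULL)
  if (!is.null(groups)) {
    long$group <- groups[long$subject_id]
    for (grp in sort(unique(long$group))) {
      sub <- long[long$group == grp, ]
      m <- t(vapply(nodes, function(nd) agg(sub[sub$node == nd, ]),
                    numeric(2)))
      out[[paste0("mean_rho_", grp)]] <- m[, 1]
      out[[paste0("n_", grp)]] <- as.integer(m[, 2])
    }
  }
  class(out) <- c("cohort_coupling", "data.frame")
  out
}

#' Coupling profiles for every subject of a cohort
#'
#' @param cohort an `sfc_cohort`.
#' @param networks an `sfc_networks` from [build_networks()] (for the
#'   Fisher-z FC matrices).
#' @param config an [sfc_config()].
#' @return subjects-by-nodes matrix of rho values (NA where undefined),
#'   with the long profile table in attribute `profiles`.
#' @export
cohort_coupling_matrix <- function(cohort, networks, config = sfc_config()) {
  ids <- cohort$subjects$subject_id
  profs <- lapply(ids, function(id)
    subject_coupling(cohort$sc[[id]], networks$fc_z[[id]],
                     min_pairs = config$min_coupling_pairs,
                     selection = config$coupling_selection,
                     sc_weighting = config$coupling_sc_weighting,
                     subject_id = id))
  m <- do.call(rbind, lapply(profs, function(p) p$rho))
  dimnames(m) <- list(ids, cohort$atlas_labels)
  attr(m, "profiles") <- do.call(rbind, profs)
  m
}
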