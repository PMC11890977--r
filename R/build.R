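# Network construction: structural binarization with group-consistency
# masking; functional Pearson/Fisher-z matrices and sparsity-thresholded
# binary networks.

#' Sparsity grid
#'
#' Ordered, uniformly spaced sparsity levels in (0,1). The default is the
#' study grid 0.01..0.40 with step 0.01 (40 levels).
#'
#' @param min,max,step grid specification.
#' @return list of class `sparsity_grid` with elements `values` and `step`.
#' @export
sparsity_grid <- function(min = 0.01, max = 0.40, step = 0.01) {
  if (!(0 < min && min <= max && max < 1) || step <= 0) {
    stop_sfconn("need 0 < min <= max < 1 and step > 0",
                class = "sfconn_parameter_error")
  }
  values <- seq(min, max, by = step)
  if (length(values) > 1 && max(abs(diff(values) - step)) > 1e-12) {
    stop_sfconn("grid spacing not uniform within 1e-12",
                class = "sfconn_parameter_error")
  }
  structure(list(values = values, step = step), class = "sparsity_grid")
}

#' Binarize a streamline-count matrix at a fiber-count threshold
#'
#' An edge is present iff the count is greater than or equal to
#' `fiber_threshold` (default 3).
#'
#' @param counts a `structural_count` [connectivity_matrix()].
#' @param fiber_threshold minimal count.
#' @return a `structural_binary` [connectivity_matrix()].
#' @export
binarize_sc <- function(counts, fiber_threshold = 3) {
  stopifnot(inherits(counts, "connectivity_matrix"))
  if (any(counts$values < 0)) {
    stop_sfconn("negative streamline count", class = "sfconn_input_error")
  }
  b <- (counts$values >= fiber_threshold) * 1
  diag(b) <- 0
  connectivity_matrix(b, node_labels = counts$node_labels,
                      modality = "structural_binary")
}

#' Group-consistency edge mask
#'
#' An edge is retained iff the proportion of subjects in which it is
#' present *strictly exceeds* `proportion` (reading "over 80%" literally;
#' exactly 80% is dropped).
#'
#' @param binaries list of `structural_binary` [connectivity_matrix()]
#'   objects with identical node order.
#' @param proportion consistency proportion in `[0,1)`.
#' @return list of class `group_mask` with `mask` (binary matrix) and
#'   `consistency` (per-edge proportion matrix).
#' @export
group_consistency_mask <- function(binaries, proportion = 0.8) {
  if (length(binaries) == 0) {
    stop_sfconn("empty subject list", class = "sfconn_input_error")
  }
  labs <- binaries[[1]]$node_labels
  for (b in binaries) {
    stopifnot(inherits(b, "connectivity_matrix"))
    if (!identical(b$node_labels, labs)) {
      stop_sfconn("node order differs across subjects",
                  class = "sfconn_validation_error")
    }
  }
  acc <- Reduce(`+`, lapply(binaries, `[[`, "values"))
  consistency <- acc / length(binaries)
  mask <- (consistency > proportion) * 1
  diag(mask) <- 0
  structure(list(mask = mask, consistency = consistency,
                 proportion = proportion, n_subjects = length(binaries)),
            class = "group_mask")
}

#' Apply a group mask to a binary network
#' @param x a binary [connectivity_matrix()].
#' @param mask a [group_consistency_mask()].
#' @return masked [connectivity_matrix()].
#' @export
apply_mask <- function(x, mask) {
  connectivity_matrix(x$values * mask$mask, node_labels = x$node_labels,
                      modality = x$modality)
}

#' Pearson functional connectivity from regional BOLD series
#'
#' @param series node-by-time matrix (at least 3 timepoints, no constant
#'   rows).
#' @param node_labels optional node labels.
#' @return a `functional_weighted` [connectivity_matrix()] with zero
#'   diagonal and exact symmetry.
#' @export
pearson_fc <- function(series, node_labels = NULL) {
  if (ncol(series) < 3) {
    stop_sfconn("need >= 3 timepoints, got %d", ncol(series),
                class = "sfconn_input_error")
  }
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) {
    stop_sfconn("constant BOLD series at node(s): %s",
                paste(which(sds == 0), collapse = ", "),
                class = "sfconn_input_error")
  }
  r <- stats::cor(t(series))
  r <- (r + t(r)) / 2
  diag(r) <- 0
  connectivity_matrix(r, node_labels = node_labels,
                      modality = "functional_weighted")
}

#' Fisher z-transform a correlation matrix
#'
#' `z = arctanh(r)` entrywise off-diagonal; entries with `|r| >= 1 - 1e-7`
#' are clipped to `+/-(1 - 1e-7)` first and the clip count is reported in
#' the `n_clipped` attribute.
#'
#' @param r_matrix a `functional_weighted` [connectivity_matrix()].
#' @return a `functional_weighted` [connectivity_matrix()] of z values with
#'   attribute `n_clipped`.
#' @export
fisher_z <- function(r_matrix) {
  stopifnot(inherits(r_matrix, "connectivity_matrix"))
  r <- r_matrix$values
  lim <- 1 - 1e-7
  off <- row(r) != col(r)
  clipped <- off & abs(r) >= lim
  r[clipped] <- sign(r[clipped]) * lim
  z <- atanh(r)
  diag(z) <- 0
  out <- connectivity_matrix(z, node_labels = r_matrix$node_labels,
                             modality = "functional_weighted")
  attr(out, "n_clipped") <- sum(clipped) / 2
  out
}

#' Threshold a weighted matrix to a binary network at a sparsity level
#'
#' Retains the `E = floor(sparsity * N(N-1)/2)` largest positive
#' off-diagonal weights as edges. Negative and zero weights never become
#' edges. Ties at the cutoff are broken by ascending (row, column)
#' lexicographic order, so the result is deterministic and edge sets are
#' nested across sparsity levels. If fewer than `E` positive weights exist,
#' all positive weights are retained and the `shortfall` attribute is set.
#'
#' @param weighted a weighted [connectivity_matrix()] (e.g. Fisher-z FC).
#' @param sparsity level in (0,1).
#' @return a `functional_binary` [connectivity_matrix()] with attributes
#'   `n_edges`, `target_edges` and `shortfall`.
#' @export
sparsity_threshold <- function(weighted, sparsity) {
  stopifnot(inherits(weighted, "connectivity_matrix"))
  if (!(sparsity > 0 && sparsity < 1)) {
    stop_sfconn("sparsity must lie in (0,1)", class = "sfconn_parameter_error")
  }
  w <- weighted$values
  n <- nrow(w)
  target <- floor(sparsity * n * (n - 1) / 2)
  ut <- which(upper.tri(w))
  vals <- w[ut]
  pos <- which(vals > 0)
  # ascending (i,j) lexicographic order == ascending column-major upper-tri
  # index after sorting by row within column; upper.tri indices are already
  # ordered by (j, i); reorder to (i, j) for the documented rule
  ri <- ((ut - 1) %% n) + 1
  ci <- ((ut - 1) %/% n) + 1
  ord <- order(-vals[pos], ri[pos], ci[pos])
  keep <- pos[ord][seq_len(min(target, length(pos)))]
  b <- matrix(0, n, n)
  b[ut[keep]] <- 1
  b <- b + t(b)
  out <- connectivity_matrix(b, node_labels = weighted$node_labels,
                             modality = "functional_binary")
  attr(out, "n_edges") <- length(keep)
  attr(out, "target_edges") <- target
  attr(out, "shortfall") <- length(keep) < target
  out
}

#' Build all analyzable networks for a cohort
#'
#' Structural: per-subject binarization at `fiber_threshold` followed by
#' the group-consistency mask. Functional: per-subject Pearson + Fisher-z
#' weighted matrices (binary thresholding over the sparsity grid happens
#' downstream, level by level).
#'
#' @param cohort an `sfc_cohort`.
#' @param config an [sfc_config()].
#' @return list of class `sfc_networks`: `sc_binary` (masked, per subject),
#'   `sc_binary_raw` (pre-mask), `mask` (or per-group masks), `fc_z`
#'   (per subject), `grid`.
#' @export
build_networks <- function(cohort, config = sfc_config()) {
  ids <- cohort$subjects$subject_id
  raw <- lapply(ids, function(id)
    binarize_sc(cohort$sc[[id]], config$fiber_threshold))
  names(raw) <- ids
  if (config$consistency_scope == "all") {
    mask <- group_consistency_mask(raw, config$group_consistency)
    masked <- lapply(raw, apply_mask, mask = mask)
  } else {
    mask <- lapply(split(ids, cohort$subjects$group), function(g_ids)
      group_consistency_mask(raw[g_ids], config$group_consistency))
    masked <- raw
    for (grp in names(mask)) {
      g_ids <- ids[cohort$subjects$group == grp]
      masked[g_ids] <- lapply(raw[g_ids], apply_mask, mask = mask[[grp]])
    }
  }
  fc_z <- lapply(ids, function(id)
    fisher_z(pearson_fc(cohort$bold[[id]], node_labels = cohort$atlas_labels)))
  names(fc_z) <- ids
  g <- config$sparsity_grid
  structure(list(sc_binary = masked, sc_binary_raw = raw, mask = mask,
                 fc_z = fc_z,
                 grid = sparsity_grid(g[1], g[2], g[3])),
            class = "sfc_networks")
}
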