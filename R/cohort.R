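# Subject manifests, cohort assembly and validation.

manifest_columns <- c("subject_id", "group", "age", "sex", "education",
                      "MMSE", "AVLT", "AVLT_N5", "SDMT", "STT_B", "BNT",
                      "sc_source", "bold_source")

cognitive_scores <- c("MMSE", "AVLT", "AVLT_N5", "SDMT", "STT_B", "BNT")

#' Cognitive score names used throughout the package
#' @return character vector of the six score names.
#' @export
score_names <- function() cognitive_scores

#' Read a subject manifest
#'
#' CSV with a fixed header: subject_id, group (HC/VCI), age, sex
#' (male/female), education, the six cognitive scores (MMSE, AVLT, AVLT_N5,
#' SDMT, STT_B, BNT) and the per-subject matrix/series paths (sc_source,
#' bold_source). Blank score cells are recorded as missing, never imputed.
#'
#' @param path CSV path.
#' @return data.frame with one row per subject, classes validated.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_sfconn("manifest not found: %s", path, class = "sfconn_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(manifest_columns, names(df))
  if (length(missing_cols)) {
    stop_sfconn("manifest missing required column(s): %s",
                paste(missing_cols, collapse = ", "),
                class = "sfconn_schema_error")
  }
  df <- df[manifest_columns]
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop_sfconn("duplicate subject_id: %s", paste(unique(dup), collapse = ", "),
                class = "sfconn_validation_error")
  }
  bad_group <- setdiff(unique(df$group), c("HC", "VCI"))
  if (length(bad_group)) {
    stop_sfconn("unknown group label(s): %s", paste(bad_group, collapse = ", "),
                class = "sfconn_validation_error")
  }
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex)) {
    stop_sfconn("unknown sex label(s): %s", paste(bad_sex, collapse = ", "),
                class = "sfconn_validation_error")
  }
  num_cols <- c("age", "education", cognitive_scores)
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Write a subject manifest
#' @param manifest data.frame as returned by [read_manifest()].
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[manifest_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Assemble a cohort
#'
#' @param subjects manifest data.frame (see [read_manifest()]).
#' @param sc named list of structural [connectivity_matrix()] objects,
#'   one per subject_id.
#' @param bold named list of node-by-time series matrices, one per
#'   subject_id.
#' @param atlas_labels ordered node labels shared by all matrices.
#' @return object of class `sfc_cohort`.
#' @export
cohort <- function(subjects, sc, bold, atlas_labels) {
  structure(list(subjects = subjects, sc = sc, bold = bold,
                 atlas_labels = as.character(atlas_labels)),
            class = "sfc_cohort")
}

#' @export
print.sfc_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<sfc_cohort> %d subjects (%s), %d nodes\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$atlas_labels)))
  invisible(x)
}

#' Validate a cohort before analysis
#'
#' Report-based: returns every violation found (missing modalities,
#' node-order mismatches, undersized groups, duplicate ids) rather than
#' stopping at the first. An empty report means the cohort is analyzable.
#'
#' @param x an [cohort()] object.
#' @return character vector of violations, class `sfc_validation_report`;
#'   empty if the cohort is valid.
#' @export
validate_cohort <- function(x) {
  v <- character()
  ids <- x$subjects$subject_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) v <- c(v, sprintf("duplicate subject_id: %s", dup))
  for (id in ids) {
    if (is.null(x$sc[[id]])) v <- c(v, sprintf("subject %s missing SC matrix", id))
    if (is.null(x$bold[[id]])) v <- c(v, sprintf("subject %s missing BOLD series", id))
  }
  n <- length(x$atlas_labels)
  for (id in ids) {
    m <- x$sc[[id]]
    if (!is.null(m)) {
      if (length(m$node_labels) != n) {
        v <- c(v, sprintf("subject %s SC order %d != atlas order %d",
                          id, length(m$node_labels), n))
      } else if (!identical(m$node_labels, x$atlas_labels)) {
        v <- c(v, sprintf("subject %s SC node order differs from atlas", id))
      }
    }
    b <- x$bold[[id]]
    if (!is.null(b) && nrow(b) != n) {
      v <- c(v, sprintf("subject %s BOLD has %d rows != atlas order %d",
                        id, nrow(b), n))
    }
  }
  tab <- table(factor(x$subjects$group, levels = c("HC", "VCI")))
  small <- names(tab)[tab < 2]
  if (length(small)) {
    v <- c(v, sprintf("group %s has < 2 subjects (group analysis impossible)", small))
  }
  structure(v, class = "sfc_validation_report")
}

#' @export
print.sfc_validation_report <- function(x, ...) {
  if (length(x) == 0) {
    cat("cohort valid: no violations\n")
  } else {
    cat(sprintf("%d violation(s):\n", length(x)))
    cat(paste0("  - ", x, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Load a cohort from a manifest and on-disk matrices/series
#'
#' @param manifest path to a manifest CSV or a manifest data.frame.
#' @param base_dir directory against which relative sc_source/bold_source
#'   paths are resolved.
#' @param atlas_labels node labels; defaults to the 90-region atlas labels
#'   shipped with the package.
#' @return an `sfc_cohort`.
#' @export
load_cohort <- function(manifest, base_dir = ".", atlas_labels = aal90_labels()) {
  df <- if (is.character(manifest)) read_manifest(manifest) else manifest
  n <- length(atlas_labels)
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  sc <- bold <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$subject_id[i]
    sc[[id]] <- read_matrix(resolve(df$sc_source[i]), expected_order = n,
                            modality = "structural_count",
                            node_labels = atlas_labels)
    bold[[id]] <- read_series(resolve(df$bold_source[i]), n_nodes = n)
  }
  cohort(df, sc, bold, atlas_labels)
}

#' Node labels of the 90-region anatomical parcellation
#'
#' The 90 cerebral regions of the AAL atlas (45 left/right pairs), used as
#' the default node ordering for all matrices.
#'
#' @return character vector of length 90.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "sfconn")
  if (path == "") path <- file.path("inst", "extdata", "aal90_labels.txt")
  readLines(path)
}
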