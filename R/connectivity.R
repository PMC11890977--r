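#' Connectivity matrix container
#'
#' A square, symmetric, zero-diagonal node-by-node connectivity matrix with
#' node labels and a modality tag. Structural count matrices hold
#' non-negative integer streamline counts; binary modalities hold only 0/1;
#' functional weighted matrices hold correlation-scale weights.
#'
#' @param values square numeric matrix.
#' @param node_labels character vector of node names, one per row; defaults
#'   to existing dimnames or `V1..Vn`.
#' @param modality one of `"structural_count"`, `"structural_binary"`,
#'   `"functional_weighted"`, `"functional_binary"`.
#' @param check validate invariants (symmetry within 1e-10, zero diagonal,
#'   modality-specific entry constraints).
#' @return an object of class `connectivity_matrix`: a list with elements
#'   `values`, `node_labels`, `modality`.
#' @export
connectivity_matrix <- function(values,
                                node_labels = NULL,
                                modality = c("structural_count",
                                             "structural_binary",
                                             "functional_weighted",
                                             "functional_binary"),
                                check = TRUE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_sfconn("`values` must be a numeric matrix", class = "sfconn_shape_error")
  }
  if (nrow(values) != ncol(values)) {
    stop_sfconn("matrix must be square, got %d x %d", nrow(values), ncol(values),
                class = "sfconn_shape_error")
  }
  n <- nrow(values)
  if (is.null(node_labels)) {
    node_labels <- rownames(values) %||% paste0("V", seq_len(n))
  }
  if (length(node_labels) != n) {
    stop_sfconn("node_labels length %d != matrix order %d",
                length(node_labels), n, class = "sfconn_shape_error")
  }
  dimnames(values) <- list(node_labels, node_labels)
  x <- structure(list(values = values,
                      node_labels = as.character(node_labels),
                      modality = modality),
                 class = "connectivity_matrix")
  if (check) validate_connectivity_matrix(x)
  x
}

#' Validate a connectivity matrix
#'
#' @param x a [connectivity_matrix()].
#' @param tol symmetry tolerance.
#' @return `x` invisibly; errors on violation.
#' @export
validate_connectivity_matrix <- function(x, tol = 1e-10) {
  v <- x$values
  if (max(abs(v - t(v))) > tol) {
    stop_sfconn("matrix asymmetric beyond tolerance %g (max |A - t(A)| = %g)",
                tol, max(abs(v - t(v))), class = "sfconn_validation_error")
  }
  if (any(diag(v) != 0)) {
    stop_sfconn("diagonal must be zero", class = "sfconn_validation_error")
  }
  if (x$modality == "structural_count") {
    if (any(v < 0) || any(v != floor(v))) {
      stop_sfconn("structural_count entries must be non-negative integers",
                  class = "sfconn_validation_error")
    }
  }
  if (x$modality %in% c("structural_binary", "functional_binary")) {
    if (!all(v %in% c(0, 1))) {
      stop_sfconn("binary modality contains values outside {0,1}",
                  class = "sfconn_validation_error")
    }
  }
  invisible(x)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- length(x$node_labels)
  nz <- sum(x$values[upper.tri(x$values)] != 0)
  cat(sprintf("<connectivity_matrix> %s, %d nodes, %d non-zero edges\n",
              x$modality, n, nz))
  invisible(x)
}

#' Read a square connectivity matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited numeric text. The matrix is
#' symmetrized by averaging when the maximal asymmetry is below `tol`
#' (larger asymmetry signals corrupt input and errors); a non-zero diagonal
#' is zeroed with a warning.
#'
#' @param path file path.
#' @param expected_order if non-NULL, required matrix order.
#' @param modality modality tag for the result.
#' @param node_labels optional node labels.
#' @param tol asymmetry tolerance (default 1e-10).
#' @return a [connectivity_matrix()].
#' @export
read_matrix <- function(path, expected_order = NULL,
                        modality = "structural_count",
                        node_labels = NULL, tol = 1e-10) {
  if (!file.exists(path)) {
    stop_sfconn("file not found: %s", path, class = "sfconn_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric", strip.white = TRUE),
    error = function(e) stop_sfconn("non-numeric or malformed cell in %s: %s",
                                    path, conditionMessage(e),
                                    class = "sfconn_parse_error"))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop_sfconn("matrix in %s is not square (%d x %d)", path, nrow(m), ncol(m),
                class = "sfconn_shape_error")
  }
  if (!is.null(expected_order) && nrow(m) != expected_order) {
    stop_sfconn("matrix in %s has order %d, expected %d", path, nrow(m),
                expected_order, class = "sfconn_shape_error")
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop_sfconn("matrix in %s asymmetric (max |A - t(A)| = %g > %g)",
                path, asym, tol, class = "sfconn_validation_error")
  }
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) {
    warning(sprintf("non-zero diagonal in %s zeroed", path), call. = FALSE)
    diag(m) <- 0
  }
  connectivity_matrix(m, node_labels = node_labels, modality = modality)
}

#' Write a connectivity matrix as delimited text
#'
#' Full double precision, whitespace-delimited; round-trips through
#' [read_matrix()] to 1e-12.
#'
#' @param x a [connectivity_matrix()] or plain matrix.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_matrix <- function(x, path) {
  v <- if (inherits(x, "connectivity_matrix")) x$values else x
  lines <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a node-by-time BOLD series matrix from delimited text
#'
#' @param path file path.
#' @param n_nodes if non-NULL, required number of rows.
#' @return numeric matrix, nodes in rows, timepoints in columns.
#' @export
read_series <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) {
    stop_sfconn("file not found: %s", path, class = "sfconn_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (!is.null(n_nodes) && nrow(m) != n_nodes) {
    stop_sfconn("series in %s has %d rows, expected %d nodes", path, nrow(m),
                n_nodes, class = "sfconn_shape_error")
  }
  m
}

#' @rdname read_series
#' @param x series matrix.
#' @export
write_series <- function(x, path) {
  lines <- apply(x, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
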