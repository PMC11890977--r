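# Graph-topology battery on binary undirected networks: global and nodal
# efficiency, clustering, path length, betweenness, small-worldness against
# degree-preserving (double-edge-swap) null ensembles, and AUC summaries
# over a sparsity grid.
#
# Conventions follow the standard binary-graph definitions: efficiency with
# 1/Inf = 0; C_i = 0 for nodes of degree < 2; Eloc/NEloc as the global
# efficiency of each node's neighbor-induced subgraph; Lp as the mean of
# finite pairwise distances with an explicit disconnectedness flag; Sigma =
# (Cp / <Cp_null>) / (Lp / <Lp_null>) over a Maslov-Sneppen ensemble.

adj_values <- function(a) {
  if (inherits(a, "connectivity_matrix")) a$values else a
}

as_binary_graph <- function(a) {
  v <- adj_values(a)
  igraph::graph_from_adjacency_matrix(v, mode = "undirected", diag = FALSE)
}

#' All-pairs shortest path lengths of a binary graph
#'
#' Breadth-first distances; unreachable pairs are `Inf`, `d(i,i) = 0`.
#'
#' @param adjacency binary symmetric matrix or [connectivity_matrix()].
#' @return node-by-node numeric distance matrix.
#' @export
all_shortest_path_lengths <- function(adjacency) {
  g <- as_binary_graph(adjacency)
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- NULL
  d
}

efficiency_from_distances <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

local_clustering <- function(a) {
  v <- adj_values(a)
  k <- rowSums(v)
  tri <- diag(v %*% v %*% v) / 2          # triangles through each node
  c_i <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  as.numeric(c_i)
}

neighbor_subgraph_efficiency <- function(v, i) {
  nb <- which(v[i, ] > 0)
  if (length(nb) < 2) return(0)
  sub <- v[nb, nb, drop = FALSE]
  efficiency_from_distances(all_shortest_path_lengths(sub))
}

#' Global graph metrics
#'
#' Computes global efficiency (Eglob), local efficiency (Eloc), clustering
#' coefficient (Cp), characteristic path length (Lp, mean over finite
#' pairs, flagged when disconnected) and, when `nulls` is supplied,
#' small-worldness Sigma against a degree-preserving null ensemble.
#'
#' @param adjacency binary symmetric matrix or [connectivity_matrix()].
#' @param nulls `NULL` (skip Sigma) or a list with `n_nulls`,
#'   `swaps_per_edge`, `seed` — see [null_ensemble_params()].
#' @param cp_zero_mode `"include"` degree-<2 nodes as 0 in the Cp average
#'   (default) or `"exclude"` them.
#' @return list of class `global_metrics`: Eglob, Eloc, Cp, Lp, Sigma (NA
#'   when not requested or undefined), disconnected_flag, n_nodes, n_edges.
#' @export
global_metrics <- function(adjacency, nulls = NULL,
                           cp_zero_mode = c("include", "exclude")) {
  cp_zero_mode <- match.arg(cp_zero_mode)
  v <- adj_values(adjacency)
  n <- nrow(v)
  if (n < 3) {
    stop_sfconn("graph metrics degenerate for n < 3 nodes",
                class = "sfconn_input_error")
  }
  d <- all_shortest_path_lengths(v)
  eglob <- efficiency_from_distances(d)
  c_i <- local_clustering(v)
  k <- rowSums(v)
  cp <- if (cp_zero_mode == "include") mean(c_i)
        else if (any(k >= 2)) mean(c_i[k >= 2]) else 0
  eloc <- mean(vapply(seq_len(n), function(i)
    neighbor_subgraph_efficiency(v, i), numeric(1)))
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  disconnected <- !all(finite)
  lp <- if (any(finite)) mean(off[finite]) else NA_real_
  sigma <- NA_real_
  if (!is.null(nulls)) {
    ens <- maslov_sneppen_rewire(v, nulls)
    cp_null <- mean(vapply(ens, function(m) {
      ci <- local_clustering(m)
      if (cp_zero_mode == "include") mean(ci) else {
        kk <- rowSums(m)
        if (any(kk >= 2)) mean(ci[kk >= 2]) else 0
      }
    }, numeric(1)))
    lp_null <- mean(vapply(ens, function(m) {
      dd <- all_shortest_path_lengths(m)
      o <- dd[row(dd) != col(dd)]
      o <- o[is.finite(o)]
      if (length(o)) mean(o) else NA_real_
    }, numeric(1)))
    if (!is.na(lp) && !is.na(lp_null) && cp_null > 0 && lp > 0) {
      sigma <- (cp / cp_null) / (lp / lp_null)
    }
  }
  structure(list(Eglob = eglob, Eloc = eloc, Cp = cp, Lp = lp, Sigma = sigma,
                 disconnected_flag = disconnected,
                 n_nodes = n, n_edges = sum(v) / 2),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("<global_metrics> n=%d, E=%d | Eglob=%.4f Eloc=%.4f Cp=%.4f Lp=%s Sigma=%s%s\n",
              x$n_nodes, x$n_edges, x$Eglob, x$Eloc, x$Cp,
              ifelse(is.na(x$Lp), "NA", sprintf("%.4f", x$Lp)),
              ifelse(is.na(x$Sigma), "NA", sprintf("%.4f", x$Sigma)),
              if (x$disconnected_flag) " [disconnected]" else ""))
  invisible(x)
}

#' Per-node graph metrics
#'
#' Degree, betweenness (exact, raw and normalized by `(N-1)(N-2)/2`),
#' nodal efficiency NEglob (mean inverse distance to all others), nodal
#' local efficiency NEloc (global efficiency of the neighbor subgraph),
#' nodal clustering NCp, and nodal path length NLp (mean finite distance
#' to reachable nodes, NA for isolated nodes).
#'
#' @inheritParams global_metrics
#' @return data.frame of class `nodal_metrics` with one row per node.
#' @export
nodal_metrics <- function(adjacency) {
  v <- adj_values(adjacency)
  n <- nrow(v)
  g <- as_binary_graph(v)
  d <- all_shortest_path_lengths(v)
  inv <- 1 / d
  diag(inv) <- 0
  neglob <- rowSums(inv) / (n - 1)
  btw_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  btw <- btw_raw / ((n - 1) * (n - 2) / 2)
  neloc <- vapply(seq_len(n), function(i)
    neighbor_subgraph_efficiency(v, i), numeric(1))
  ncp <- local_clustering(v)
  nlp <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di)) mean(di) else NA_real_
  }, numeric(1))
  labs <- if (inherits(adjacency, "connectivity_matrix"))
    adjacency$node_labels else paste0("V", seq_len(n))
  structure(data.frame(node = labs, degree = rowSums(v),
                       betweenness = as.numeric(btw),
                       betweenness_raw = as.numeric(btw_raw),
                       NEglob = as.numeric(neglob), NEloc = neloc,
                       NCp = ncp, NLp = nlp, row.names = NULL),
            class = c("nodal_metrics", "data.frame"))
}

#' Null-ensemble parameters for small-worldness
#'
#' @param n_nulls number of null networks (default 100).
#' @param swaps_per_edge attempted double-edge swaps per edge (default 10).
#' @param seed integer seed.
#' @return plain list.
#' @export
null_ensemble_params <- function(n_nulls = 100, swaps_per_edge = 10, seed = 1L) {
  if (n_nulls < 1 || swaps_per_edge < 1) {
    stop_sfconn("n_nulls and swaps_per_edge must be >= 1",
                class = "sfconn_parameter_error")
  }
  list(n_nulls = n_nulls, swaps_per_edge = swaps_per_edge,
       seed = as.integer(seed))
}

#' Degree-preserving (Maslov-Sneppen) null networks
#'
#' Each null applies `swaps_per_edge * E` attempted double-edge swaps,
#' rejecting swaps that would create self-loops or multi-edges, so the
#' degree sequence is preserved exactly. Graphs admitting no swap (fewer
#' than 2 edges, or complete) are returned as unmodified copies with a
#' warning.
#'
#' @param adjacency binary symmetric matrix or [connectivity_matrix()].
#' @param params [null_ensemble_params()].
#' @return list of adjacency matrices.
#' @export
maslov_sneppen_rewire <- function(adjacency, params = null_ensemble_params()) {
  v <- adj_values(adjacency)
  n <- nrow(v)
  e <- sum(v) / 2
  complete <- e == n * (n - 1) / 2
  if (e < 2 || complete) {
    warning("graph admits no degree-preserving swap; returning copies",
            call. = FALSE)
    return(replicate(params$n_nulls, v, simplify = FALSE))
  }
  g <- as_binary_graph(v)
  deg <- unname(rowSums(v))
  set.seed(params$seed)
  lapply(seq_len(params$n_nulls), function(b) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = params$swaps_per_edge * e))
    m <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    dimnames(m) <- NULL
    stopifnot(all(rowSums(m) == deg))
    m
  })
}

#' Metric battery across a sparsity grid
#'
#' Thresholds a weighted (Fisher-z) matrix at every grid level and computes
#' the global and nodal batteries on each binary graph. Disconnected levels
#' carry flags, never silent omissions.
#'
#' @param z_matrix weighted [connectivity_matrix()].
#' @param grid a [sparsity_grid()].
#' @param nulls `NULL` (skip Sigma) or [null_ensemble_params()]; each level
#'   gets a sub-seed derived from `nulls$seed` and the level index.
#' @param cp_zero_mode see [global_metrics()].
#' @return list of class `sparsity_metrics`: `global` (data.frame, one row
#'   per level) and `nodal` (list of `nodal_metrics` keyed by level).
#' @export
metrics_over_sparsity <- function(z_matrix, grid, nulls = NULL,
                                  cp_zero_mode = "include") {
  levels <- grid$values
  glob <- vector("list", length(levels))
  nodal <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    b <- sparsity_threshold(z_matrix, levels[li])
    np <- if (is.null(nulls)) NULL else
      null_ensemble_params(nulls$n_nulls, nulls$swaps_per_edge,
                           substream(nulls$seed, li))
    gm <- global_metrics(b, nulls = np, cp_zero_mode = cp_zero_mode)
    glob[[li]] <- data.frame(sparsity = levels[li], Eglob = gm$Eglob,
                             Eloc = gm$Eloc, Cp = gm$Cp, Lp = gm$Lp,
                             Sigma = gm$Sigma,
                             disconnected = gm$disconnected_flag,
                             shortfall = attr(b, "shortfall"))
    nodal[[li]] <- nodal_metrics(b)
  }
  names(nodal) <- sprintf("%.2f", levels)
  structure(list(global = do.call(rbind, glob), nodal = nodal, grid = grid),
            class = "sparsity_metrics")
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of a per-level metric over the sparsity domain.
#'
#' @param values numeric vector, one value per grid level.
#' @param grid a [sparsity_grid()].
#' @return scalar AUC.
#' @export
auc_curve <- function(values, grid) {
  x <- grid$values
  if (length(values) != length(x)) {
    stop_sfconn("values length %d != grid length %d", length(values),
                length(x), class = "sfconn_input_error")
  }
  if (length(x) < 2) {
    stop_sfconn("grid has a single level: zero-width integration domain",
                class = "sfconn_input_error")
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop_sfconn("undefined metric at level(s): %s",
                paste(sprintf("%.2f", x[bad]), collapse = ", "),
                class = "sfconn_input_error")
  }
  trapz(x, values)
}
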