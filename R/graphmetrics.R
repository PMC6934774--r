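# Nodal measures on weighted undirected networks.
#
# Shortest-path based measures need a weight-to-length mapping; for
# FA-weighted connectomes the dominant convention is length = 1/weight
# (strong connections are short), used as the default everywhere and
# switchable to -log(w).

metric_names <- c("strength", "local_efficiency", "clustering",
                  "betweenness", "degree")

edge_lengths <- function(w, weight_to_length = c("inverse", "neglog")) {
  weight_to_length <- match.arg(weight_to_length)
  L <- matrix(Inf, nrow(w), ncol(w))
  pos <- w > 0
  L[pos] <- if (weight_to_length == "inverse") 1 / w[pos] else -log(w[pos])
  diag(L) <- 0
  L
}

#' Node strength
#'
#' Sum of the weights of all edges incident to each node.
#'
#' @param m a [conn_matrix()] or plain symmetric weight matrix.
#' @return named numeric vector, one value per node.
#' @export
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' node_strength(conn_matrix(w))  # 1.0 each
node_strength <- function(m) {
  rowSums(unclass(m))
}

#' Node degree
#'
#' Number of edges (positive weights) incident to each node.
#'
#' @inheritParams node_strength
#' @return named integer vector.
#' @export
node_degree <- function(m) {
  d <- rowSums(unclass(m) > 0)
  storage.mode(d) <- "integer"
  d
}

#' All-pairs shortest path lengths
#'
#' Maps each positive weight to an edge length (default `1/w`), then runs
#' Floyd–Warshall over all node pairs. Disconnected pairs have distance
#' `Inf`; the diagonal is 0.
#'
#' @inheritParams node_strength
#' @param weight_to_length `"inverse"` (length = 1/w, default) or
#'   `"neglog"` (length = -log w).
#' @return symmetric numeric distance matrix.
#' @export
shortest_path_lengths <- function(m, weight_to_length = "inverse") {
  L <- .fw_distances(edge_lengths(unclass(m), weight_to_length))
  dimnames(L) <- dimnames(m)
  L
}

#' Nodal local efficiency
#'
#' For each node, the subgraph induced by its neighbours (original edge
#' weights) is extracted and the mean inverse shortest-path length over all
#' pairs of neighbours is computed (`1/Inf` counts as 0). Nodes with fewer
#' than two neighbours get 0, so downstream statistics never see missing
#' values.
#'
#' @inheritParams shortest_path_lengths
#' @return named numeric vector in \[0, 1\].
#' @export
local_efficiency <- function(m, weight_to_length = "inverse") {
  w <- unclass(m)
  eff <- .local_efficiency_cpp(w, edge_lengths(w, weight_to_length))
  names(eff) <- rownames(m)
  eff
}

#' Weighted clustering coefficient (Barrat)
#'
#' Barrat et al.'s weighted generalisation of the fraction of triangles
#' around a node:
#' `C_i = 1/(s_i (d_i - 1)) * sum_{j,k} (w_ij + w_ik)/2 a_ij a_ik a_jk`
#' with `a` the binary adjacency. Nodes with degree < 2 get 0. The Onnela
#' geometric-mean variant is available via `variant = "onnela"`.
#'
#' @inheritParams node_strength
#' @param variant `"barrat"` (default) or `"onnela"`.
#' @return named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(m, variant = c("barrat", "onnela")) {
  variant <- match.arg(variant)
  w <- unclass(m)
  n <- nrow(w)
  A <- (w > 0) * 1
  d <- rowSums(A)
  s <- rowSums(w)
  if (variant == "barrat") {
    # sum_j w_ij * (# common neighbours of i and j that close a triangle)
    A2 <- A %*% A
    num <- rowSums(w * A * A2)
    C <- ifelse(d >= 2, num / (s * (d - 1)), 0)
  } else {
    wh <- (w / max(w))^(1 / 3)
    num <- diag(wh %*% wh %*% wh)
    C <- ifelse(d >= 2, num / (d * (d - 1)), 0)
  }
  names(C) <- rownames(m)
  C
}

#' Weighted betweenness centrality
#'
#' Fraction of all shortest paths passing through each node, computed with
#' Brandes' accumulation on edge lengths (default 1/w) so that tied
#' shortest paths are counted with their exact multiplicity. With
#' `normalized = TRUE` values are divided by `(n-1)(n-2)/2`, the number of
#' node pairs a node could mediate in an undirected graph.
#'
#' @inheritParams shortest_path_lengths
#' @param normalized divide by `(n-1)(n-2)/2`?
#' @return named numeric vector (in \[0, 1\] when normalized).
#' @export
betweenness_centrality <- function(m, normalized = TRUE,
                                   weight_to_length = "inverse") {
  w <- unclass(m)
  n <- nrow(w)
  if (n < 3) {
    return(setNames(numeric(n), rownames(m)))
  }
  bc <- .betweenness_cpp(w, edge_lengths(w, weight_to_length))
  if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(m)
  bc
}

#' Compute all five nodal metrics for a cohort
#'
#' Applies [node_strength()], [local_efficiency()],
#' [clustering_coefficient()], [betweenness_centrality()] and
#' [node_degree()] to every matrix (after optional masking) and stacks the
#' results into subjects x nodes tables.
#'
#' @param matrices named list of [conn_matrix()] with identical node
#'   labels.
#' @param mask optional `edge_mask` applied to each matrix first.
#' @param weight_to_length see [shortest_path_lengths()].
#' @param clustering_variant see [clustering_coefficient()].
#' @return named list of five numeric matrices (subjects x nodes), rownames
#'   = subject ids, in the order strength, local_efficiency, clustering,
#'   betweenness, degree.
#' @export
compute_all_metrics <- function(matrices, mask = NULL,
                                weight_to_length = "inverse",
                                clustering_variant = "barrat") {
  if (!length(matrices)) cc_stop("no matrices supplied",
                                 "conncog_input_error")
  labs <- rownames(matrices[[1]])
  n_sub <- length(matrices)
  ids <- names(matrices)
  if (is.null(ids)) {
    ids <- vapply(matrices, subject_id, character(1))
  }
  out <- lapply(metric_names, function(nm)
    matrix(NA_real_, n_sub, length(labs),
           dimnames = list(ids, labs)))
  names(out) <- metric_names
  for (i in seq_len(n_sub)) {
    m <- matrices[[i]]
    res <- tryCatch({
      validate_conn_matrix(m)
      if (!identical(rownames(m), labs)) {
        cc_stop("node labels differ across matrices", "conncog_label_error")
      }
      if (!is.null(mask)) m <- apply_mask(m, mask)
      list(strength = node_strength(m),
           local_efficiency = local_efficiency(m, weight_to_length),
           clustering = clustering_coefficient(m, clustering_variant),
           betweenness = betweenness_centrality(m, TRUE, weight_to_length),
           degree = as.numeric(node_degree(m)))
    }, conncog_error = function(e) {
      cc_stop(sprintf("subject '%s': %s",
                      subject_id(matrices[[i]]), conditionMessage(e)),
              class(e)[1])
    })
    for (nm in metric_names) out[[nm]][i, ] <- res[[nm]]
  }
  out
}

#' Write metric tables as CSV files
#'
#' One `<prefix><metric>.csv` per metric, rows = subjects, columns = node
#' labels.
#'
#' @param tables list as returned by [compute_all_metrics()].
#' @param prefix path prefix.
#' @return invisibly, the vector of file paths written.
#' @export
write_metric_tables <- function(tables, prefix) {
  paths <- character(0)
  for (nm in names(tables)) {
    p <- paste0(prefix, nm, ".csv")
    write.csv(data.frame(subject_id = rownames(tables[[nm]]),
                         tables[[nm]], check.names = FALSE),
              p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_metric_tables
#' @export
read_metric_tables <- function(prefix) {
  out <- list()
  for (nm in metric_names) {
    p <- paste0(prefix, nm, ".csv")
    if (!file.exists(p)) cc_stop(sprintf("missing metric table %s", p),
                                 "conncog_malformed_error")
    df <- read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    out[[nm]] <- m
  }
  out
}
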