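#' Connectivity matrix objects
#'
#' A `conn_matrix` is one subject's symmetric FA-weighted adjacency matrix:
#' a square numeric matrix with identical row/column node labels, zero
#' diagonal, entries in \[0, 1\] and absent connections encoded as exactly 0.
#' The subject identifier is carried in the `"subject_id"` attribute.
#'
#' @param weights square numeric matrix of FA edge weights.
#' @param node_labels character vector of region names; defaults to existing
#'   dimnames or `"node_1"..."node_n"`.
#' @param subject_id opaque subject identifier.
#' @return a validated `conn_matrix` object.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.4
#' m <- conn_matrix(w, c("A", "B", "C"), "sub01")
conn_matrix <- function(weights, node_labels = NULL, subject_id = "subject") {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    cc_stop("weights must be a numeric matrix", "conncog_malformed_error")
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) {
      node_labels <- paste0("node_", seq_len(nrow(weights)))
    }
  }
  dimnames(weights) <- list(node_labels, node_labels)
  m <- structure(weights, class = c("conn_matrix", "matrix", "array"),
                 subject_id = as.character(subject_id))
  validate_conn_matrix(m)
  m
}

#' @rdname conn_matrix
#' @param m object to validate.
#' @param tol asymmetry tolerance.
#' @export
validate_conn_matrix <- function(m, tol = 1e-8) {
  if (nrow(m) != ncol(m)) {
    cc_stop("connectivity matrix must be square", "conncog_nonsquare_error")
  }
  if (!identical(rownames(m), colnames(m))) {
    cc_stop("row and column node labels differ", "conncog_label_error")
  }
  if (anyNA(m)) {
    cc_stop("connectivity matrix contains missing values",
            "conncog_malformed_error")
  }
  if (max(abs(m - t(m))) > tol) {
    cc_stop(sprintf("matrix is asymmetric beyond tolerance %g", tol),
            "conncog_asymmetry_error")
  }
  if (any(m < 0)) {
    cc_stop("negative edge weights are not allowed",
            "conncog_negative_weight_error")
  }
  if (any(m > 1)) {
    cc_stop("FA edge weights must lie in [0, 1]",
            "conncog_range_error")
  }
  if (any(diag(as.matrix(m)) != 0)) {
    cc_stop("diagonal must be exactly zero", "conncog_diagonal_error")
  }
  invisible(m)
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> subject '%s': %d nodes, %d present edges\n",
              attr(x, "subject_id"), nrow(x),
              sum(x[upper.tri(x)] > 0)))
  invisible(x)
}

subject_id <- function(m) attr(m, "subject_id")

#' Read / write a connectivity matrix as labelled TSV
#'
#' Matrices are stored as tab-separated text with the node labels as both
#' header row and first column. `read_matrix(write_matrix(m, f))` reproduces
#' `m` to within 1e-12. Validation distinguishes malformed files, label
#' mismatches, non-square layouts and asymmetric or out-of-range weights via
#' error subclasses.
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file base name.
#' @return `read_matrix` returns a [conn_matrix()]; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    cc_stop(sprintf("no such file: %s", path), "conncog_malformed_error")
  }
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", row.names = 1,
               check.names = FALSE, comment.char = "#"),
    error = function(e) cc_stop(sprintf("malformed matrix file %s: %s",
                                        path, conditionMessage(e)),
                                "conncog_malformed_error"))
  w <- as.matrix(df)
  if (!is.numeric(w)) {
    cc_stop(sprintf("non-numeric entries in %s", path),
            "conncog_malformed_error")
  }
  if (nrow(w) != ncol(w)) {
    cc_stop(sprintf("matrix in %s is not square (%d x %d)",
                    path, nrow(w), ncol(w)), "conncog_nonsquare_error")
  }
  if (!identical(rownames(w), colnames(w))) {
    cc_stop(sprintf("header and row labels disagree in %s", path),
            "conncog_label_error")
  }
  if (is.null(subject_id)) {
    meta <- grep("^# subject_id=", readLines(path, n = 10), value = TRUE)
    subject_id <- if (length(meta)) {
      sub("^# subject_id=", "", meta[1])
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  conn_matrix(w, rownames(w), subject_id)
}

#' @rdname read_matrix
#' @param m a [conn_matrix()].
#' @param header optional character vector of comment lines (prefixed `#`)
#'   written above the table, e.g. provenance metadata.
#' @export
write_matrix <- function(m, path, header = NULL) {
  validate_conn_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste0("# subject_id=", attr(m, "subject_id")), con)
  writeLines(paste(c("node", colnames(m)), collapse = "\t"), con)
  write.table(format(unclass(m), digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
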