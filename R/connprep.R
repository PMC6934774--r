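# connprep: edge prevalence filtering and confound regression

#' Healthy-cohort edge prevalence mask
#'
#' Retains the unordered node pairs whose connection is present (weight
#' strictly greater than `presence_eps`) in more than `threshold` of the
#' healthy-volunteer matrices. The inequality is strict: with 45 HV an edge
#' present in 28 (62.2%) is retained, one present in exactly 27 (60.0%) is
#' dropped.
#'
#' @param hv_matrices list of [conn_matrix()] from the healthy reference
#'   group; identical node labels required.
#' @param threshold prevalence fraction that must be exceeded.
#' @param presence_eps weights strictly above this count as "present";
#'   the default 0 treats any positive weight as a connection.
#' @return an `edge_mask`: logical symmetric matrix (TRUE = retained) with
#'   node-label dimnames, zero diagonal.
#' @export
prevalence_mask <- function(hv_matrices, threshold = 0.6,
                            presence_eps = 0) {
  if (!length(hv_matrices)) {
    cc_stop("need at least one HV matrix", "conncog_input_error")
  }
  labs <- rownames(hv_matrices[[1]])
  for (m in hv_matrices) {
    validate_conn_matrix(m)
    if (!identical(rownames(m), labs)) {
      cc_stop("HV matrices have inconsistent node labels",
              "conncog_label_error")
    }
  }
  n_hv <- length(hv_matrices)
  counts <- Reduce(`+`, lapply(hv_matrices,
                               function(m) (unclass(m) > presence_eps) * 1L))
  mask <- counts / n_hv > threshold
  diag(mask) <- FALSE
  structure(mask, class = c("edge_mask", "matrix", "array"),
            threshold = threshold)
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %d nodes, %d of %d pairs retained\n",
              nrow(x), sum(x[upper.tri(x)]), n_node_pairs(nrow(x))))
  invisible(x)
}

#' Number of retained pairs in an edge mask
#' @param mask an `edge_mask`.
#' @return integer count of retained unordered pairs.
#' @export
mask_size <- function(mask) sum(mask[upper.tri(mask)])

#' Apply an edge mask to a connectivity matrix
#'
#' Sets non-retained pairs to exactly 0 and leaves retained pairs
#' untouched; idempotent.
#'
#' @param m a [conn_matrix()].
#' @param mask an `edge_mask` of matching dimension.
#' @return masked [conn_matrix()].
#' @export
apply_mask <- function(m, mask) {
  if (!all(dim(m) == dim(mask))) {
    cc_stop("matrix and mask dimensions disagree", "conncog_dim_error")
  }
  w <- unclass(m) * array(as.numeric(mask), dim = dim(mask))
  conn_matrix(w, rownames(m), subject_id(m))
}

#' Build a covariate table for confound regression
#'
#' @param age numeric vector of ages (years).
#' @param sex factor or character with levels F/M (coded internally 0/1).
#' @return data.frame with numeric `age` and 0/1 `sex`.
#' @export
covariate_table <- function(age, sex) {
  if (length(age) != length(sex)) {
    cc_stop("age and sex lengths differ", "conncog_input_error")
  }
  if (anyNA(age) || anyNA(sex)) {
    cc_stop("covariates contain missing values", "conncog_input_error")
  }
  sex_num <- if (is.numeric(sex)) sex else as.integer(factor(sex, levels = c("F", "M"))) - 1
  data.frame(age = as.numeric(age), sex = sex_num)
}

#' Regress age and sex out of edge weights
#'
#' For each edge independently, fits ordinary least squares
#' `weight ~ 1 + age + sex` across the subjects in which the edge is
#' present, and replaces those weights by residual + fitted value at the
#' covariate means. Because the fitted value at the covariate means equals
#' the edge's mean weight, the correction preserves each edge's mean and
#' the FA scale; results are clipped to \[0, 1\]. Entries that are 0
#' (absent connections) are left at 0, so degree is unchanged. Edges
#' present in fewer than `min_present` subjects are returned unmodified.
#'
#' The model is fitted pooling all supplied subjects (HV and patients
#' together), the standard confound-removal reading when group membership
#' itself must not be regressed out.
#'
#' @param matrices list of [conn_matrix()] (typically after
#'   [apply_mask()]).
#' @param covariates a [covariate_table()], one row per matrix.
#' @param min_present minimum number of present-edge subjects needed to fit
#'   (default 4 = intercept + 2 slopes + 1).
#' @param on_constant what to do with a zero-variance covariate:
#'   `"drop"` (default) removes it from the design with a warning,
#'   `"error"` aborts naming the covariate.
#' @return list of corrected [conn_matrix()] objects.
#' @export
regress_confounds <- function(matrices, covariates, min_present = 4,
                              on_constant = c("drop", "error")) {
  on_constant <- match.arg(on_constant)
  n_sub <- length(matrices)
  if (nrow(covariates) != n_sub) {
    cc_stop("need one covariate row per matrix", "conncog_input_error")
  }
  if (n_sub < 4) {
    cc_stop("confound regression needs at least 4 subjects",
            "conncog_input_error")
  }
  X <- cbind(age = covariates$age, sex = covariates$sex)
  keep_cov <- apply(X, 2, function(v) sd(v) > 0)
  if (!all(keep_cov)) {
    bad <- paste(colnames(X)[!keep_cov], collapse = ", ")
    if (on_constant == "error") {
      cc_stop(sprintf("constant covariate(s): %s", bad),
              "conncog_design_error")
    }
    cc_warn(sprintf("dropping constant covariate(s) from design: %s", bad))
    X <- X[, keep_cov, drop = FALSE]
  }
  if (ncol(X) > 1 && qr(cbind(1, X))$rank < ncol(X) + 1) {
    cc_stop("rank-deficient design: age and sex are collinear",
            "conncog_design_error")
  }

  n <- nrow(matrices[[1]])
  labs <- rownames(matrices[[1]])
  ut <- which(upper.tri(matrix(0, n, n)))
  W <- vapply(matrices, function(m) unclass(m)[ut], numeric(length(ut)))
  W <- t(W)  # subjects x edges

  out <- W
  for (j in seq_len(ncol(W))) {
    present <- W[, j] > 0
    np <- sum(present)
    if (np == 0 || np < min_present) next
    y <- W[present, j]
    Xp <- cbind(1, X[present, , drop = FALSE])
    fit <- stats::lm.fit(Xp, y)
    # residual + fitted-at-covariate-means == residual + mean(y)
    out[present, j] <- pmin(1, pmax(0, fit$residuals + mean(y)))
  }

  lapply(seq_len(n_sub), function(i) {
    w <- matrix(0, n, n)
    w[ut] <- out[i, ]
    w <- w + t(w)
    conn_matrix(w, labs, subject_id(matrices[[i]]))
  })
}

#' Serialize an edge mask as TSV
#'
#' Written as the list of retained node pairs (`node_a`, `node_b`), which
#' round-trips through [read_mask()].
#'
#' @param mask an `edge_mask`.
#' @param path output path.
#' @param header optional `#`-prefixed comment lines.
#' @export
write_mask <- function(mask, path, header = NULL) {
  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  df <- data.frame(node_a = rownames(mask)[idx[, 1]],
                   node_b = colnames(mask)[idx[, 2]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste0("# n_nodes=", nrow(mask), " labels=",
                    paste(rownames(mask), collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @return `read_mask` returns the `edge_mask`.
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# n_nodes=", lines, value = TRUE)
  if (!length(meta)) {
    cc_stop("mask file lacks its n_nodes metadata line",
            "conncog_malformed_error")
  }
  labs <- strsplit(sub(".*labels=", "", meta[1]), ",")[[1]]
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  n <- length(labs)
  mask <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  if (nrow(df)) {
    ia <- match(df$node_a, labs); ib <- match(df$node_b, labs)
    if (anyNA(ia) || anyNA(ib)) {
      cc_stop("mask refers to unknown node labels", "conncog_label_error")
    }
    mask[cbind(ia, ib)] <- TRUE
    mask[cbind(ib, ia)] <- TRUE
  }
  structure(mask, class = c("edge_mask", "matrix", "array"))
}
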