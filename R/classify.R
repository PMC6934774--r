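# Balanced-undersampling ensemble SVM classification.
#
# Tasks: ms_vs_hv (all patients vs healthy volunteers; positive = MS) and
# ci_vs_cp (impaired vs preserved patients; positive = CI). Class imbalance
# is handled by building many "instances", each keeping the minority class
# whole and undersampling the majority class to the same size (stratified
# by cognitive group for ms_vs_hv). Each instance is evaluated by
# stratified k-fold CV with an RBF SVM whose (C, gamma) are grid-searched
# on the training folds only.

#' Default grid-search sequences for the RBF SVM
#'
#' Growing geometric sequences following the common libsvm practice:
#' `C = 2^(-5), 2^(-3), ..., 2^15` and `gamma = 2^(-15), 2^(-13), ...,
#' 2^3`.
#'
#' @return list with numeric `C` and `gamma` vectors.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

task_labels <- function(subjects, task = c("ms_vs_hv", "ci_vs_cp")) {
  task <- match.arg(task)
  g <- as.character(subjects$group)
  if (task == "ms_vs_hv") {
    lab <- ifelse(g == "HV", "HV", "MS")
    list(labels = factor(lab, levels = c("HV", "MS")), positive = "MS")
  } else {
    keep <- g %in% c("CP", "CI")
    list(labels = factor(ifelse(g == "CI", "CI", "CP"),
                         levels = c("CP", "CI"))[keep],
         positive = "CI", subset = which(keep))
  }
}

#' Significance-driven feature selection
#'
#' Selects (metric, node) pairs whose corrected p-value is below `alpha`
#' in the group contrasts of interest. The default rule (`contrasts =
#' "both"`) requires significance in both CP-HV and CI-CP; `"either"`,
#' `"cp_hv"` and `"ci_cp"` relax it. Feature sets: `"LE"` (local
#' efficiency), `"NS"` (node strength) or `"LE+NS"` (union of the two
#' lists; pairs are distinct across metrics so the count is the sum).
#'
#' @param stats data.frame from [test_metric_nodes()].
#' @param feature_set `"LE"`, `"NS"` or `"LE+NS"`.
#' @param alpha significance level on corrected p-values.
#' @param contrasts which contrasts must be significant.
#' @return data.frame with columns `metric` and `node`.
#' @export
select_features <- function(stats, feature_set = c("LE", "NS", "LE+NS"),
                            alpha = 0.05,
                            contrasts = c("both", "either", "cp_hv", "ci_cp")) {
  feature_set <- match.arg(feature_set)
  contrasts <- match.arg(contrasts)
  metrics <- switch(feature_set,
                    "LE" = "local_efficiency",
                    "NS" = "strength",
                    "LE+NS" = c("local_efficiency", "strength"))
  out <- list()
  for (met in metrics) {
    sub <- stats[stats$metric == met, ]
    if (!nrow(sub)) {
      cc_stop(sprintf("no statistics found for metric '%s'", met),
              "conncog_input_error")
    }
    sig_by <- function(ct) {
      s <- sub[sub$contrast == ct, ]
      s$node[!is.na(s$corrected_p) & s$corrected_p < alpha]
    }
    n1 <- sig_by("CP-HV"); n2 <- sig_by("CI-CP")
    nodes <- switch(contrasts,
                    both = intersect(n1, n2),
                    either = union(n1, n2),
                    cp_hv = n1,
                    ci_cp = n2)
    if (length(nodes)) {
      out[[length(out) + 1]] <- data.frame(metric = met, node = nodes,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    cc_stop(paste("no feature passed selection; relax alpha, use a less",
                  "strict contrast rule, or increase the effect size"),
            "conncog_empty_selection_error")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build balanced classification instances by random undersampling
#'
#' Keeps the minority class whole and draws, without replacement, an
#' equally sized random subsample of the majority class for each instance.
#' For `ms_vs_hv` the patient subsample is stratified over CP/CI in
#' proportion to their cohort counts with largest-remainder rounding (a
#' 45/104/84 cohort yields 90-observation instances: 45 HV + 25 CP + 20
#' CI); for `ci_vs_cp` the larger patient group is undersampled to the
#' smaller (84 + 84 = 168 in the same cohort). Deterministic given `seed`.
#'
#' @param subjects subject table with `group`.
#' @param task `"ms_vs_hv"` or `"ci_vs_cp"`.
#' @param n_instances number of balanced datasets.
#' @param seed integer seed.
#' @return list of instances, each a list with `idx` (row indices into
#'   `subjects`), `labels` (factor) and `positive` (label of the positive
#'   class).
#' @export
build_instances <- function(subjects, task = c("ms_vs_hv", "ci_vs_cp"),
                            n_instances = 100, seed = 1L) {
  task <- match.arg(task)
  g <- as.character(subjects$group)
  set.seed(seed)
  if (task == "ms_vs_hv") {
    minor_idx <- which(g == "HV")
    strata <- list(CP = which(g == "CP"), CI = which(g == "CI"))
    major_n <- sum(lengths(strata))
    if (!length(minor_idx) || !major_n) {
      cc_stop("both classes must be non-empty", "conncog_input_error")
    }
    if (length(minor_idx) > major_n) {
      cc_stop("minority class larger than majority class",
              "conncog_input_error")
    }
    alloc <- largest_remainder(lengths(strata), length(minor_idx))
    instances <- lapply(seq_len(n_instances), function(i) {
      pick <- unlist(mapply(function(pool, k) sort(sample(pool, k)),
                            strata, alloc, SIMPLIFY = FALSE),
                     use.names = FALSE)
      idx <- c(minor_idx, pick)
      list(idx = idx,
           labels = factor(ifelse(g[idx] == "HV", "HV", "MS"),
                           levels = c("HV", "MS")),
           positive = "MS")
    })
  } else {
    cp <- which(g == "CP"); ci <- which(g == "CI")
    if (!length(cp) || !length(ci)) {
      cc_stop("both classes must be non-empty", "conncog_input_error")
    }
    if (length(ci) <= length(cp)) {
      minor <- ci; major <- cp
    } else {
      minor <- cp; major <- ci
    }
    instances <- lapply(seq_len(n_instances), function(i) {
      pick <- sort(sample(major, length(minor)))
      idx <- c(minor, pick)
      list(idx = idx,
           labels = factor(ifelse(g[idx] == "CI", "CI", "CP"),
                           levels = c("CP", "CI")),
           positive = "CI")
    })
  }
  instances
}

#' Assemble the feature matrix for selected (metric, node) features
#'
#' @param tables metric tables from [compute_all_metrics()].
#' @param features data.frame from [select_features()] (columns metric,
#'   node).
#' @return numeric matrix subjects x features with `metric.node` column
#'   names.
#' @export
feature_matrix <- function(tables, features) {
  cols <- lapply(seq_len(nrow(features)), function(i) {
    tab <- tables[[features$metric[i]]]
    if (is.null(tab) || !(features$node[i] %in% colnames(tab))) {
      cc_stop(sprintf("feature %s/%s not found in metric tables",
                      features$metric[i], features$node[i]),
              "conncog_input_error")
    }
    tab[, features$node[i]]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- paste(features$metric, features$node, sep = ".")
  X
}

# stratified fold assignment: shuffles within class and deals each class
# round-robin over the folds with the fewest observations so far, keeping
# both the class counts and the overall fold sizes as even as possible
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  tot <- integer(k)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    if (!length(idx)) next
    ord <- order(tot, sample(k))
    assign_to <- rep_len(ord, length(idx))
    fold[idx] <- assign_to
    tot <- tot + tabulate(assign_to, k)
  }
  fold
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scale <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, `-`), 2, sc$sd, `/`)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Evaluates every (C, gamma) combination by stratified `k`-fold
#' cross-validated accuracy on the supplied (training) data, standardizing
#' within each inner training fold. Ties are broken towards the smaller C,
#' then the smaller gamma.
#'
#' @param X numeric feature matrix (training data only).
#' @param y factor of class labels.
#' @param grid list with `C` and `gamma` vectors; see
#'   [default_svm_grid()].
#' @param k number of inner folds.
#' @return list with the chosen `C`, `gamma` and the grid of mean CV
#'   accuracies (`cv_accuracy`, rows C, columns gamma).
#' @export
grid_search_svm <- function(X, y, grid = default_svm_grid(), k = 10) {
  if (nlevels(droplevels(y)) < 2) {
    cc_stop("training data contain a single class", "conncog_fold_error")
  }
  k <- min(k, min(table(y)))
  if (k < 2) cc_stop("too few observations per class for inner CV",
                     "conncog_fold_error")
  fold <- stratified_folds(y, k)
  acc <- matrix(0, length(grid$C), length(grid$gamma),
                dimnames = list(paste0("C=", grid$C),
                                paste0("g=", grid$gamma)))
  n_eval <- 0
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (nlevels(droplevels(y[tr])) < 2) next
    sc <- scale_train(X[tr, , drop = FALSE])
    Xtr <- apply_scale(X[tr, , drop = FALSE], sc)
    Xte <- apply_scale(X[te, , drop = FALSE], sc)
    n_eval <- n_eval + 1
    for (ci in seq_along(grid$C)) {
      for (gi in seq_along(grid$gamma)) {
        fit <- e1071::svm(Xtr, y[tr], type = "C-classification",
                          kernel = "radial", cost = grid$C[ci],
                          gamma = grid$gamma[gi], scale = FALSE)
        pred <- predict(fit, Xte)
        acc[ci, gi] <- acc[ci, gi] + mean(pred == y[te])
      }
    }
  }
  acc <- acc / n_eval
  best <- c(1, 1); best_acc <- -Inf
  for (ci in seq_along(grid$C)) {
    for (gi in seq_along(grid$gamma)) {
      if (acc[ci, gi] > best_acc + 1e-12) {
        best <- c(ci, gi); best_acc <- acc[ci, gi]
      }
    }
  }
  list(C = grid$C[best[1]], gamma = grid$gamma[best[2]],
       cv_accuracy = acc)
}

confusion_metrics <- function(tp, tn, fp, fn) {
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (is.na(sens) || prec + sens == 0) 0 else
    2 * prec * sens / (prec + sens)
  100 * c(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1)
}

#' Cross-validated evaluation of one balanced instance
#'
#' Stratified `k`-fold CV: within each fold, features are standardized on
#' the training part, (C, gamma) are grid-searched on the training part
#' only (inner CV), an RBF SVM is fitted and the held-out fold predicted.
#' Confusion counts are pooled over folds and reported as percentage
#' accuracy, sensitivity (recall of the positive class), specificity and
#' F1.
#'
#' @param X feature matrix for the instance's observations.
#' @param y factor labels.
#' @param positive label of the positive class.
#' @param k number of outer folds.
#' @param grid hyperparameter grid, see [default_svm_grid()].
#' @param inner_k folds for the nested grid search.
#' @return list with `metrics` (named percentages), `confusion` (tp, tn,
#'   fp, fn), `params` (per-fold chosen C and gamma) and `fold_sizes`.
#' @export
run_cv <- function(X, y, positive, k = 10, grid = default_svm_grid(),
                   inner_k = 10) {
  if (length(y) < k) cc_stop("fewer observations than folds",
                             "conncog_fold_error")
  fold <- stratified_folds(y, k)
  if (any(tabulate(fold, k) == 0)) {
    cc_stop("empty fold; reduce k", "conncog_fold_error")
  }
  tp <- tn <- fp <- fn <- 0
  params <- data.frame(fold = seq_len(k), C = NA_real_, gamma = NA_real_)
  fold_sizes <- data.frame(fold = seq_len(k), n_train = NA_integer_,
                           n_test = NA_integer_)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (nlevels(droplevels(y[tr])) < 2 || !any(te)) {
      cc_stop(sprintf("fold %d lacks both classes", f),
              "conncog_fold_error")
    }
    gs <- grid_search_svm(X[tr, , drop = FALSE], y[tr], grid, inner_k)
    sc <- scale_train(X[tr, , drop = FALSE])
    fit <- e1071::svm(apply_scale(X[tr, , drop = FALSE], sc), y[tr],
                      type = "C-classification", kernel = "radial",
                      cost = gs$C, gamma = gs$gamma, scale = FALSE)
    pred <- predict(fit, apply_scale(X[te, , drop = FALSE], sc))
    truth <- y[te]
    tp <- tp + sum(pred == positive & truth == positive)
    tn <- tn + sum(pred != positive & truth != positive)
    fp <- fp + sum(pred == positive & truth != positive)
    fn <- fn + sum(pred != positive & truth == positive)
    params$C[f] <- gs$C; params$gamma[f] <- gs$gamma
    fold_sizes$n_train[f] <- sum(tr); fold_sizes$n_test[f] <- sum(te)
  }
  list(metrics = confusion_metrics(tp, tn, fp, fn),
       confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
       params = params, fold_sizes = fold_sizes)
}

#' Aggregate instance results into a performance summary
#'
#' @param results list of per-instance results from [run_cv()] (or any
#'   list of lists with a `metrics` element).
#' @return data.frame with one row per indicator: mean and sample SD over
#'   instances, in percent.
#' @export
aggregate_performance <- function(results) {
  if (length(results) < 2) {
    cc_stop("need at least two instances to aggregate",
            "conncog_input_error")
  }
  M <- t(vapply(results, function(r) r$metrics, numeric(4)))
  data.frame(indicator = colnames(M),
             mean = colMeans(M),
             sd = apply(M, 2, sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Linear-kernel companion feature weights
#'
#' RBF SVMs expose no primal feature weights, so each instance's
#' standardized data are refitted with a linear-kernel SVM and the
#' absolute primal coefficients `|w| = |t(coefs) %*% SV|` recorded per
#' feature. Reported as per-feature mean and SD across instances, ranked
#' by mean.
#'
#' @param X full feature matrix (subjects x features).
#' @param instances list from [build_instances()].
#' @param cost linear-SVM cost parameter.
#' @param top_k how many top-ranked features to flag (default 15). If
#'   fewer features exist, all are returned with a warning.
#' @return data.frame: feature, mean_weight, sd_weight, rank, top (logical
#'   top-`top_k` indicator), ordered by decreasing mean weight.
#' @export
feature_weights <- function(X, instances, cost = 1, top_k = 15) {
  W <- matrix(NA_real_, length(instances), ncol(X),
              dimnames = list(NULL, colnames(X)))
  for (i in seq_along(instances)) {
    ins <- instances[[i]]
    Xi <- X[ins$idx, , drop = FALSE]
    sc <- scale_train(Xi)
    fit <- e1071::svm(apply_scale(Xi, sc), ins$labels,
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    W[i, ] <- abs(t(fit$coefs) %*% fit$SV)
  }
  res <- data.frame(feature = colnames(X),
                    mean_weight = colMeans(W),
                    sd_weight = apply(W, 2, sd),
                    stringsAsFactors = FALSE)
  res <- res[order(res$mean_weight, decreasing = TRUE), ]
  res$rank <- seq_len(nrow(res))
  if (top_k > nrow(res)) {
    cc_warn(sprintf("top_k = %d requested but only %d features available",
                    top_k, nrow(res)))
    top_k <- nrow(res)
  }
  res$top <- res$rank <= top_k
  rownames(res) <- NULL
  res
}

#' Run a full classification task
#'
#' Composes [build_instances()], [run_cv()] per instance,
#' [aggregate_performance()] and [feature_weights()] for one task and
#' feature list.
#'
#' @param tables metric tables from [compute_all_metrics()].
#' @param subjects subject table aligned with the tables' rows.
#' @param task `"ms_vs_hv"` or `"ci_vs_cp"`.
#' @param features data.frame (metric, node), e.g. from
#'   [select_features()].
#' @param n_instances number of balanced instances.
#' @param k outer CV folds.
#' @param grid hyperparameter grid.
#' @param inner_k nested grid-search folds.
#' @param seed seed for undersampling and fold assignment.
#' @return list with `summary` (aggregate), `instances` (per-instance
#'   metric rows), `weights` (feature ranking), `n_features`, `task` and
#'   `seed`.
#' @export
run_task <- function(tables, subjects, task = c("ms_vs_hv", "ci_vs_cp"),
                     features, n_instances = 100, k = 10,
                     grid = default_svm_grid(), inner_k = 10, seed = 1L) {
  task <- match.arg(task)
  X <- feature_matrix(tables, features)
  if (nrow(X) != nrow(subjects)) {
    cc_stop("metric tables and subject table are misaligned",
            "conncog_input_error")
  }
  instances <- build_instances(subjects, task, n_instances, seed)
  results <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    ins <- instances[[i]]
    set.seed(derive_seed(seed, i))
    results[[i]] <- run_cv(X[ins$idx, , drop = FALSE], ins$labels,
                           ins$positive, k = k, grid = grid,
                           inner_k = inner_k)
  }
  inst_df <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(instance = i, t(results[[i]]$metrics))
  }))
  set.seed(derive_seed(seed, 0L))
  wts <- feature_weights(X, instances,
                         top_k = min(15, nrow(features)))
  list(summary = aggregate_performance(results),
       instances = inst_df,
       weights = wts,
       n_features = nrow(features),
       task = task, seed = seed)
}
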