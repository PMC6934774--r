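# Feature selection, balanced instances, SVM CV and feature weights

small_grid <- list(C = 2^c(-1, 3, 7), gamma = 2^c(-7, -3, 1))

fake_stats <- function(sig_le = character(0), sig_ns = character(0),
                       nodes = paste0("n", 1:6),
                       sig_le_cicp = sig_le, sig_ns_cicp = sig_ns) {
  rows <- list()
  for (met in c("local_efficiency", "strength")) {
    for (ct in c("CP-HV", "CI-CP")) {
      sig <- switch(paste(met, ct),
                    "local_efficiency CP-HV" = sig_le,
                    "local_efficiency CI-CP" = sig_le_cicp,
                    "strength CP-HV" = sig_ns,
                    "strength CI-CP" = sig_ns_cicp)
      rows[[length(rows) + 1]] <- data.frame(
        metric = met, node = nodes, omnibus_test = "anova", omnibus_p = 0.5,
        posthoc_test = "tukey_hsd", contrast = ct,
        raw_p = ifelse(nodes %in% sig, 0.001, 0.5),
        corrected_p = ifelse(nodes %in% sig, 0.004, 0.6),
        direction = -1L)
    }
  }
  do.call(rbind, rows)
}

test_that("feature selection follows the both-contrasts rule", {
  st <- fake_stats(sig_le = c("n3", "n7"), nodes = paste0("n", 1:8))
  got <- select_features(st, "LE")
  expect_equal(got$node, c("n3", "n7"))
  expect_true(all(got$metric == "local_efficiency"))
  # LE+NS is the union with distinct (metric, node) pairs
  st2 <- fake_stats(sig_le = c("n1", "n2"), sig_ns = c("n1", "n5"),
                    nodes = paste0("n", 1:6))
  both <- select_features(st2, "LE+NS")
  expect_equal(nrow(both), 4)
  expect_equal(nrow(both), nrow(select_features(st2, "LE")) +
                            nrow(select_features(st2, "NS")))
  # nothing significant -> explicit error
  expect_error(select_features(fake_stats(), "LE"),
               class = "conncog_empty_selection_error")
  # a node significant in only one contrast passes "cp_hv" but not "both"
  st3 <- fake_stats(sig_le = "n2", sig_le_cicp = character(0))
  expect_error(select_features(st3, "LE", contrasts = "both"),
               class = "conncog_empty_selection_error")
  expect_equal(select_features(st3, "LE", contrasts = "cp_hv")$node, "n2")
})

test_that("instances are balanced with stratified largest-remainder counts", {
  subjects <- data.frame(
    group = factor(c(rep("HV", 45), rep("CP", 104), rep("CI", 84)),
                   levels = c("HV", "CP", "CI")))
  ins <- build_instances(subjects, "ms_vs_hv", n_instances = 8, seed = 3)
  for (x in ins) {
    expect_length(x$idx, 90)
    g <- subjects$group[x$idx]
    expect_equal(sum(g == "HV"), 45)
    expect_equal(sum(g == "CP"), 25)
    expect_equal(sum(g == "CI"), 20)
    expect_equal(as.vector(table(x$labels)), c(45, 45))
    expect_false(any(duplicated(x$idx)))
  }
  ins2 <- build_instances(subjects, "ci_vs_cp", n_instances = 4, seed = 3)
  for (x in ins2) {
    expect_length(x$idx, 168)
    expect_equal(as.vector(table(x$labels)), c(84, 84))
  }
  # instances differ only in the undersampled subjects and are seeded
  expect_false(identical(ins[[1]]$idx, ins[[2]]$idx))
  again <- build_instances(subjects, "ms_vs_hv", n_instances = 8, seed = 3)
  expect_identical(lapply(ins, `[[`, "idx"), lapply(again, `[[`, "idx"))
  # already balanced classes -> every instance is the full dataset
  bal <- data.frame(group = factor(rep(c("CP", "CI"), each = 30),
                                   levels = c("HV", "CP", "CI")))
  insb <- build_instances(bal, "ci_vs_cp", n_instances = 3, seed = 1)
  for (x in insb) expect_setequal(x$idx, seq_len(60))
})

test_that("grid search finds a separating model and is deterministic", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  y <- factor(rep(c("a", "b"), each = 30))
  set.seed(1); g1 <- grid_search_svm(X, y, small_grid, k = 5)
  expect_equal(max(g1$cv_accuracy), 1)
  set.seed(1); g2 <- grid_search_svm(X, y, small_grid, k = 5)
  expect_identical(g1, g2)
  # permuted labels -> near-chance best accuracy
  set.seed(2)
  yp <- sample(y)
  gp <- grid_search_svm(X, yp, small_grid, k = 5)
  expect_lt(max(gp$cv_accuracy), 0.75)
  expect_error(grid_search_svm(X, factor(rep("a", 60)), small_grid),
               class = "conncog_fold_error")
})

test_that("10-fold CV on a 90-observation instance trains on 81, tests on 9", {
  set.seed(5)
  X <- matrix(rnorm(90 * 3), 90, 3)
  X[1:45, ] <- X[1:45, ] + 3
  y <- factor(rep(c("HV", "MS"), each = 45))
  res <- run_cv(X, y, positive = "MS", k = 10, grid = small_grid,
                inner_k = 3)
  expect_equal(res$fold_sizes$n_train, rep(81L, 10))
  expect_equal(res$fold_sizes$n_test, rep(9L, 10))
  expect_equal(sum(res$confusion), 90)
  # separable effect -> near-perfect accuracy
  expect_gt(res$metrics[["accuracy"]], 95)
  # F1 consistent with pooled confusion counts
  cf <- res$confusion
  prec <- cf["tp"] / (cf["tp"] + cf["fp"])
  rec <- cf["tp"] / (cf["tp"] + cf["fn"])
  expect_equal(unname(res$metrics[["f1"]]),
               unname(100 * 2 * prec * rec / (prec + rec)))
})

test_that("standardization and grid search never see the test fold", {
  # leakage canary: corrupting the held-out rows must not change the
  # hyperparameters chosen or the scaler fitted on the training part
  set.seed(77)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- factor(rep(c("a", "b"), 20))
  fold <- rep(1:4, each = 10)
  te <- fold == 1
  Xc <- X; Xc[te, ] <- 1e3  # absurd test-fold values
  set.seed(9)
  g1 <- grid_search_svm(X[!te, , drop = FALSE], y[!te], small_grid, k = 4)
  set.seed(9)
  g2 <- grid_search_svm(Xc[!te, , drop = FALSE], y[!te], small_grid, k = 4)
  expect_identical(g1, g2)
  sc1 <- conncog:::scale_train(X[!te, , drop = FALSE])
  sc2 <- conncog:::scale_train(Xc[!te, , drop = FALSE])
  expect_identical(sc1, sc2)
})

test_that("aggregation returns mean and sample SD over instances", {
  mk <- function(acc) list(metrics = c(accuracy = acc, sensitivity = acc,
                                       specificity = acc, f1 = acc))
  s <- aggregate_performance(list(mk(70), mk(80)))
  expect_equal(s$mean, rep(75, 4))
  expect_equal(s$sd, rep(sd(c(70, 80)), 4), tolerance = 1e-12)
  same <- aggregate_performance(list(mk(66), mk(66), mk(66)))
  expect_equal(same$sd, rep(0, 4))
  expect_error(aggregate_performance(list(mk(1))),
               class = "conncog_input_error")
})

test_that("feature weights rank a planted informative feature first", {
  set.seed(123)
  n <- 80
  subjects <- data.frame(group = factor(rep(c("HV", "CP"), each = n / 2),
                                        levels = c("HV", "CP", "CI")))
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[subjects$group == "CP", 4] <- X[subjects$group == "CP", 4] + 3
  ins <- build_instances(subjects, "ms_vs_hv", n_instances = 12, seed = 2)
  w <- feature_weights(X, ins, top_k = 5)
  expect_equal(w$feature[1], "f4")
  # requesting more top features than available returns all with a warning
  expect_warning(w2 <- feature_weights(X[, 1:3], ins, top_k = 15),
                 "only 3 features")
  expect_equal(nrow(w2), 3)
  expect_true(all(w2$top))
})

test_that("run_task is deterministic given a seed and reports n_features", {
  set.seed(55)
  co <- generate_cohort(sim_config(n_hv = 12, n_cp = 14, n_ci = 14,
                                   n_nodes = 15, vulnerable_nodes = 1:4,
                                   delta_cp = 0.2, delta_ci = 0.2,
                                   seed = 66))
  tabs <- compute_all_metrics(co$matrices)
  features <- data.frame(metric = "strength",
                         node = sprintf("node_%02d", 1:6))
  r1 <- run_task(tabs, co$subjects, "ms_vs_hv", features,
                 n_instances = 3, k = 5, grid = small_grid, inner_k = 3,
                 seed = 12)
  r2 <- run_task(tabs, co$subjects, "ms_vs_hv", features,
                 n_instances = 3, k = 5, grid = small_grid, inner_k = 3,
                 seed = 12)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$weights, r2$weights)
  expect_equal(r1$n_features, 6)
  expect_gt(r1$summary$mean[r1$summary$indicator == "accuracy"], 60)
})
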