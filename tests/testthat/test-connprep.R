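# Matrix IO, prevalence masking and confound regression

mk_matrix <- function(w, id = "s") conn_matrix(w, subject_id = id)

test_that("matrix TSV round-trip is exact to 1e-12 and errors are typed", {
  set.seed(42)
  w <- rand_weighted_graph(10, p = 0.6)
  m <- mk_matrix(w, "sub_rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f, header = "roundtrip fixture")
  back <- read_matrix(f)
  expect_lt(max(abs(unclass(back) - unclass(m))), 1e-12)
  expect_identical(rownames(back), rownames(m))
  expect_equal(attr(back, "subject_id"), "sub_rt")

  # asymmetry beyond tolerance
  wa <- w; wa[1, 2] <- wa[1, 2] + 1e-4
  expect_error(conn_matrix(wa), class = "conncog_asymmetry_error")
  # negative weights, nonzero diagonal, non-square
  wn <- w; wn[1, 2] <- wn[2, 1] <- -0.1
  expect_error(conn_matrix(wn), class = "conncog_negative_weight_error")
  wd <- w; diag(wd) <- 0.5
  expect_error(conn_matrix(wd), class = "conncog_diagonal_error")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node\tA\tB", "A\t0\t0.5\t0.1", "B\t0.5\t0"), f2)
  expect_error(read_matrix(f2), class = "conncog_error")
})

test_that("76-node parcellation enumerates 2850 unordered pairs", {
  expect_identical(n_node_pairs(76), 2850L)
  # and a fully retained mask on 76 nodes has that many pairs
  w <- matrix(0.5, 76, 76); diag(w) <- 0
  mask <- prevalence_mask(list(mk_matrix(w)), threshold = 0.6)
  expect_equal(mask_size(mask), 2850)
})

test_that("prevalence threshold is strictly 'more than 60%'", {
  n <- 4
  base <- matrix(0, n, n)
  mats <- vector("list", 45)
  # edge (1,2) present in 28/45 = 62.2%; edge (3,4) in 27/45 = 60.0%
  for (i in 1:45) {
    w <- base
    if (i <= 28) w[1, 2] <- w[2, 1] <- 0.5
    if (i <= 27) w[3, 4] <- w[4, 3] <- 0.5
    mats[[i]] <- mk_matrix(w, paste0("hv", i))
  }
  mask <- prevalence_mask(mats, threshold = 0.6)
  expect_true(mask[1, 2])
  expect_false(mask[3, 4])
  # all-zero HV matrices give an empty mask
  empty <- prevalence_mask(lapply(1:5, function(i) mk_matrix(base)))
  expect_equal(mask_size(empty), 0)
  expect_error(prevalence_mask(list()), class = "conncog_error")
})

test_that("retained fraction matches the binomial prediction under dropout", {
  # template edge present per HV subject with prob 1 - 0.05; retained iff
  # present in > 0.6 of 45 -> P(Bin(45, .95) > 27), essentially 1
  cfg <- sim_config(n_hv = 45, n_cp = 0, n_ci = 0, n_nodes = 20,
                    edge_presence_prob = 1, dropout_prob = 0.05,
                    delta_cp = 0, delta_ci = 0,
                    vulnerable_nodes = integer(0), seed = 77)
  co <- generate_cohort(cfg)
  mask <- prevalence_mask(co$matrices)
  p_keep <- 1 - pbinom(27, 45, 0.95)
  expect_gt(p_keep, 0.999999)
  expect_equal(mask_size(mask), n_node_pairs(20))
})

test_that("apply_mask equals elementwise product, is idempotent", {
  set.seed(9)
  w <- rand_weighted_graph(5, p = 0.8)
  m <- mk_matrix(w)
  full <- prevalence_mask(list(m))  # retains exactly the present edges
  keep <- matrix(FALSE, 5, 5)
  keep[1, 2] <- keep[2, 1] <- keep[3, 4] <- keep[4, 3] <- TRUE
  mask <- structure(keep, class = c("edge_mask", "matrix", "array"),
                    dimnames = dimnames(unclass(m)))
  got <- apply_mask(m, mask)
  expect_equal(unclass(got), unclass(m) * keep, ignore_attr = TRUE)
  expect_equal(unclass(apply_mask(got, mask)), unclass(got))
  # full mask on present edges: identity; empty mask: zero matrix
  expect_equal(unclass(apply_mask(m, full)), unclass(m))
  none <- structure(matrix(FALSE, 5, 5), class = class(mask),
                    dimnames = dimnames(unclass(m)))
  expect_true(all(unclass(apply_mask(m, none)) == 0))
  expect_error(apply_mask(m, structure(matrix(TRUE, 4, 4),
                                       class = class(mask))),
               class = "conncog_dim_error")
})

test_that("mask round-trips through TSV", {
  set.seed(12)
  mats <- lapply(1:8, function(i) mk_matrix(rand_weighted_graph(7, 0.5),
                                            paste0("hv", i)))
  mask <- prevalence_mask(mats)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mask(mask, f)
  back <- read_mask(f)
  expect_equal(unclass(back), unclass(mask), ignore_attr = TRUE)
})

test_that("confound regression removes a planted age effect and preserves
           edge means", {
  set.seed(21)
  n_sub <- 40; n <- 6
  age <- runif(n_sub, 20, 60)
  sex <- rep(c("F", "M"), length.out = n_sub)
  base <- rand_weighted_graph(n, p = 1, wmin = 0.4, wmax = 0.6)
  mats <- lapply(seq_len(n_sub), function(i) {
    w <- base - 0.004 * (age[i] - 40) * (base > 0)  # exact linear age effect
    mk_matrix(w, paste0("s", i))
  })
  cov <- covariate_table(age, sex)
  out <- regress_confounds(mats, cov)
  W <- sapply(out, function(m) unclass(m)[upper.tri(m)])
  # exactly linear in age -> post-correction variance ~ 0
  expect_lt(max(apply(W, 1, var)), 1e-10)
  # edge-wise means preserved
  Win <- sapply(mats, function(m) unclass(m)[upper.tri(m)])
  expect_equal(rowMeans(W), rowMeans(Win), tolerance = 1e-10)
  for (m in out) expect_silent(validate_conn_matrix(m))
})

test_that("constant covariates degrade gracefully; absent edges stay absent", {
  set.seed(22)
  mats <- lapply(1:10, function(i) mk_matrix(rand_weighted_graph(6, 0.6),
                                             paste0("s", i)))
  cov_const <- covariate_table(rep(40, 10), rep("F", 10))
  expect_warning(out <- regress_confounds(mats, cov_const),
                 "constant covariate")
  for (i in 1:10) {
    expect_equal(unclass(out[[i]]), unclass(mats[[i]]), tolerance = 1e-12)
  }
  expect_error(regress_confounds(mats, cov_const, on_constant = "error"),
               class = "conncog_design_error")
  # zero entries are never turned into edges
  cov <- covariate_table(runif(10, 20, 60), rep(c("F", "M"), 5))
  out2 <- regress_confounds(mats, cov)
  for (i in 1:10) {
    expect_true(all(unclass(out2[[i]])[unclass(mats[[i]]) == 0] == 0))
  }
})

test_that("confound regression recovers group differences planted with an
           age confound", {
  # with a strong age slope, raw group means differ partly through age;
  # after correction the vulnerable-node deficit matches the
  # confound-free simulation
  base <- list(n_hv = 40, n_cp = 40, n_ci = 0, n_nodes = 15,
               vulnerable_nodes = 1:3, delta_cp = 0.12, delta_ci = 0,
               dropout_prob = 0, seed = 55)
  co_conf <- generate_cohort(do.call(sim_config, c(base, age_slope = -0.004)))
  co_free <- generate_cohort(do.call(sim_config, c(base, age_slope = 0)))
  gap <- function(mats, g) {
    s <- t(sapply(mats, function(m) node_strength(m)[1:3]))
    colMeans(s[g == "HV", ]) - colMeans(s[g == "CP", ])
  }
  corr <- regress_confounds(co_conf$matrices,
                            covariate_table(co_conf$subjects$age,
                                            co_conf$subjects$sex))
  gap_corr <- gap(corr, co_conf$subjects$group)
  gap_free <- gap(co_free$matrices, co_free$subjects$group)
  expect_equal(gap_corr, gap_free, tolerance = 0.25)
})
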