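#' Simulation configuration for a synthetic connectome cohort
#'
#' Defines the statistical structure of a simulated three-group study:
#' healthy volunteers (HV), cognitively preserved (CP) and cognitively
#' impaired (CI) MS patients. Defaults reproduce the demographic and
#' cognitive profile of a 45/104/84 cohort on a 76-region parcellation:
#' ages drawn from group-specific normals truncated to 18--65 years, sex
#' from group-specific Bernoulli draws, and nine correlated
#' neuropsychological z-scores whose per-subject mean follows the group's
#' global-cognition distribution (CP: 0.014 +/- 0.436; CI: -1.099 +/-
#' 0.571) while respecting the impairment labelling rule (z < -1.5 in two
#' or more tests).
#'
#' Edge weights emulate mean-FA connectomes: a cohort-level edge template
#' (presence + mean weight per edge) is drawn once, each subject drops a
#' small fraction of present edges, and present edges get Gaussian noise
#' truncated to \[0, 1\]. Disease is modelled as multiplicative attenuation
#' of edges incident to a designated set of "vulnerable" nodes: all
#' patients lose a fraction `delta_cp`, CI patients an additional fraction
#' `delta_ci` on top of it, so impairment deepens damage where it already
#' exists. An optional linear age slope on edge means gives the confound
#' regression a known ground truth to remove.
#'
#' @param n_hv,n_cp,n_ci group sizes.
#' @param n_nodes number of parcellation regions.
#' @param edge_presence_prob probability an edge exists in the cohort
#'   template.
#' @param dropout_prob per-subject probability that a template edge is
#'   missing for that subject (edge missingness).
#' @param base_weight_low,base_weight_high uniform bounds for template edge
#'   mean FA.
#' @param subject_noise_sd SD (FA units) of per-subject edge noise.
#' @param delta_cp fractional attenuation at vulnerable-node edges for all
#'   patients, in \[0, 1).
#' @param delta_ci additional fractional attenuation for CI patients, in
#'   \[0, 1).
#' @param vulnerable_nodes integer indices (1-based) of affected nodes.
#' @param age_slope change in edge mean FA per year of age (applied around
#'   the 40-year reference); set 0 to disable the age confound.
#' @param n_cog_tests number of neuropsychological subtests.
#' @param cog_means,cog_sds named numeric (CP, CI): mean and SD of the
#'   per-subject global cognition z-score.
#' @param cog_loading common-factor loading inducing correlation among
#'   subtests.
#' @param age_means,age_sds,female_props named numeric (HV, CP, CI)
#'   demographic parameters.
#' @param max_reject maximum rejection-sampling attempts per subject for
#'   label-consistent cognitive scores.
#' @param seed integer seed; the whole cohort is deterministic given the
#'   config.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_hv = 5, n_cp = 5, n_ci = 5, n_nodes = 20,
#'                   vulnerable_nodes = 1:3, seed = 1)
sim_config <- function(n_hv = 45, n_cp = 104, n_ci = 84,
                       n_nodes = 76,
                       edge_presence_prob = 0.7,
                       dropout_prob = 0.05,
                       base_weight_low = 0.30, base_weight_high = 0.60,
                       subject_noise_sd = 0.03,
                       delta_cp = 0.10, delta_ci = 0.15,
                       vulnerable_nodes = 1:10,
                       age_slope = -0.001,
                       n_cog_tests = 9,
                       cog_means = c(CP = 0.014, CI = -1.099),
                       cog_sds = c(CP = 0.436, CI = 0.571),
                       cog_loading = 0.7,
                       age_means = c(HV = 37.77, CP = 41.90, CI = 44.57),
                       age_sds = c(HV = 11.01, CP = 9.07, CI = 11.27),
                       female_props = c(HV = 0.60, CP = 0.74, CI = 0.62),
                       max_reject = 1000,
                       seed = 1L) {
  cfg <- list(n_hv = n_hv, n_cp = n_cp, n_ci = n_ci, n_nodes = n_nodes,
              edge_presence_prob = edge_presence_prob,
              dropout_prob = dropout_prob,
              base_weight_low = base_weight_low,
              base_weight_high = base_weight_high,
              subject_noise_sd = subject_noise_sd,
              delta_cp = delta_cp, delta_ci = delta_ci,
              vulnerable_nodes = as.integer(vulnerable_nodes),
              age_slope = age_slope,
              n_cog_tests = n_cog_tests,
              cog_means = cog_means, cog_sds = cog_sds,
              cog_loading = cog_loading,
              age_means = age_means, age_sds = age_sds,
              female_props = female_props,
              max_reject = max_reject,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_hv, n_cp, n_ci) < 0)) {
      cc_stop("group sizes must be non-negative", "conncog_config_error")
    }
    if (n_nodes < 2) cc_stop("need at least 2 nodes", "conncog_config_error")
    probs <- c(edge_presence_prob, dropout_prob, female_props)
    if (any(probs < 0 | probs > 1) || edge_presence_prob == 0) {
      cc_stop("probabilities must lie in [0,1] (edge presence in (0,1])",
              "conncog_config_error")
    }
    if (delta_cp < 0 || delta_ci < 0 || delta_cp + delta_ci >= 1) {
      cc_stop("attenuations must satisfy 0 <= delta_cp + delta_ci < 1",
              "conncog_config_error")
    }
    if (length(vulnerable_nodes) &&
        (min(vulnerable_nodes) < 1 || max(vulnerable_nodes) > n_nodes)) {
      cc_stop("vulnerable_nodes out of range", "conncog_config_error")
    }
    if (!length(vulnerable_nodes) && (delta_cp > 0 || delta_ci > 0)) {
      cc_stop("nonzero attenuation requires at least one vulnerable node",
              "conncog_config_error")
    }
    if (base_weight_low < 0 || base_weight_high > 1 ||
        base_weight_low > base_weight_high) {
      cc_stop("base weight bounds must satisfy 0 <= low <= high <= 1",
              "conncog_config_error")
    }
    if (n_cog_tests < 1) cc_stop("need >= 1 cognitive test",
                                 "conncog_config_error")
  })
  invisible(cfg)
}

#' Classify cognitive status from neuropsychological z-scores
#'
#' A patient is impaired when strictly more negative than `threshold` in at
#' least `min_tests` tests (default: z below -1.5 in two or more tests);
#' otherwise preserved. The inequality is strict: a score exactly at the
#' threshold does not count.
#'
#' @param z numeric vector of per-test z-scores.
#' @param threshold cut-off z-score.
#' @param min_tests minimum number of below-threshold tests for impairment.
#' @return `"impaired"` or `"preserved"`.
#' @export
#' @examples
#' classify_cognitive_status(c(-1.6, -1.7, rep(0, 7)))  # impaired
#' classify_cognitive_status(rep(-1.5, 9))              # preserved (strict)
classify_cognitive_status <- function(z, threshold = -1.5, min_tests = 2) {
  if (!length(z) || !is.numeric(z)) {
    cc_stop("z must be a non-empty numeric vector", "conncog_input_error")
  }
  if (anyNA(z)) cc_stop("z contains missing values", "conncog_input_error")
  if (sum(z < threshold) >= min_tests) "impaired" else "preserved"
}

# per-test scale such that the mean of n_tests scores, generated as
# mu + s*(lambda*F + sqrt(1-lambda^2)*e), has SD exactly cog_sd
cog_test_scale <- function(cog_sd, lambda, n_tests) {
  cog_sd / sqrt(lambda^2 + (1 - lambda^2) / n_tests)
}

# Monte-Carlo calibration of the latent location so that the mean global z
# *after* rejection on the labelling rule matches the configured group mean.
# Deterministic given the cognition parameters alone: runs on a private RNG
# stream seeded from them (the caller's stream is saved and restored), so
# results are cacheable and cohort generation stays bit-reproducible.
.cog_shift_cache <- new.env(parent = emptyenv())

calibrate_cog_shift <- function(group, cfg, n_mc = 4000) {
  key <- paste(group, cfg$cog_means[[group]], cfg$cog_sds[[group]],
               cfg$cog_loading, cfg$n_cog_tests, n_mc, sep = "|")
  hit <- .cog_shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(derive_seed(1L, sum(utf8ToInt(key))))
  res <- calibrate_cog_shift_impl(group, cfg, n_mc)
  .cog_shift_cache[[key]] <- res
  res
}

calibrate_cog_shift_impl <- function(group, cfg, n_mc = 4000) {
  mu <- cfg$cog_means[[group]]
  sdg <- cfg$cog_sds[[group]]
  lam <- cfg$cog_loading
  nt <- cfg$n_cog_tests
  s <- cog_test_scale(sdg, lam, nt)
  want_impaired <- group == "CI"
  bias_at <- function(shift) {
    f <- rnorm(n_mc)
    e <- matrix(rnorm(n_mc * nt), n_mc, nt)
    z <- (mu + shift) + s * (lam * f + sqrt(1 - lam^2) * e)
    nlow <- rowSums(z < -1.5)
    keep <- if (want_impaired) nlow >= 2 else nlow < 2
    if (sum(keep) < 50) return(NA_real_)
    mean(rowMeans(z[keep, , drop = FALSE])) - mu
  }
  # bisection on the conditional-mean bias (increasing in shift); the
  # bracket grows outward from 0 until the bias changes sign
  b0 <- bias_at(0)
  if (is.na(b0) || abs(b0) < 1e-3) return(0)
  step <- if (b0 < 0) 0.25 else -0.25
  lo <- 0; blo <- b0; hi <- 0; bhi <- b0
  for (i in 1:12) {
    hi <- hi + step
    bhi <- bias_at(hi)
    if (is.na(bhi)) return(lo)  # acceptance too rare beyond here
    if (blo * bhi <= 0) break
    lo <- hi; blo <- bhi
  }
  if (blo * bhi > 0) return(hi)
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    bm <- bias_at(mid)
    if (is.na(bm)) break
    if (bm * blo <= 0) { hi <- mid; bhi <- bm } else { lo <- mid; blo <- bm }
  }
  (lo + hi) / 2
}

#' Draw label-consistent cognitive z-scores for one patient
#'
#' Generates `n_cog_tests` correlated z-scores via a single-common-factor
#' model and rejection-samples until the impairment rule applied to the
#' output reproduces the requested group label (CI: at least two tests
#' below -1.5; CP: fewer than two). `shift` is the latent location
#' adjustment (see [generate_cohort()]) compensating for the conditioning
#' so the accepted global z matches the configured group distribution.
#'
#' Uses the current RNG stream.
#'
#' @param group `"CP"` or `"CI"`.
#' @param config a [sim_config()].
#' @param shift latent location adjustment (default 0).
#' @return numeric vector of `n_cog_tests` z-scores.
#' @export
generate_cog_scores <- function(group, config, shift = 0) {
  group <- match.arg(group, c("CP", "CI"))
  cfg <- config
  mu <- cfg$cog_means[[group]] + shift
  s <- cog_test_scale(cfg$cog_sds[[group]], cfg$cog_loading, cfg$n_cog_tests)
  lam <- cfg$cog_loading
  want <- if (group == "CI") "impaired" else "preserved"
  for (attempt in seq_len(cfg$max_reject)) {
    f <- rnorm(1)
    z <- mu + s * (lam * f + sqrt(1 - lam^2) * rnorm(cfg$n_cog_tests))
    if (classify_cognitive_status(z) == want) return(z)
  }
  cc_stop(sprintf(
    "could not draw %s-consistent scores in %d attempts; cog_means/cog_sds are incompatible with the labelling rule",
    group, cfg$max_reject), "conncog_rejection_error")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic connectome cohort
#'
#' Draws a full cohort (subject table plus one connectivity matrix per
#' subject) under the model described in [sim_config()]. A shared edge
#' template (presence and mean FA per edge) is drawn once per cohort; each
#' subject's present edges are the template means scaled by the group
#' attenuation at vulnerable nodes, shifted by the age slope, plus
#' truncated Gaussian noise. Output is deterministic given the config
#' (including its seed).
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{subjects}{data.frame: subject_id, group (factor HV/CP/CI), age,
#'       sex (factor F/M), cognitive_status, cog_z_1..n (NA for HV).}
#'     \item{matrices}{named list of [conn_matrix()] objects, aligned with
#'       the subject table.}
#'     \item{template}{list with `presence` and `mean_weight` matrices (the
#'       cohort ground truth, useful for testing).}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_hv = 4, n_cp = 4, n_ci = 4,
#'                                      n_nodes = 12, vulnerable_nodes = 1:2,
#'                                      seed = 42))
#' nrow(cohort$subjects)
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_nodes
  labels <- sprintf("node_%02d", seq_len(n))

  # cohort-level template: symmetric presence + mean weights
  ut <- upper.tri(matrix(0, n, n))
  presence <- matrix(FALSE, n, n)
  presence[ut] <- runif(sum(ut)) < cfg$edge_presence_prob
  presence <- presence | t(presence)
  mean_w <- matrix(0, n, n)
  mean_w[ut] <- runif(sum(ut), cfg$base_weight_low, cfg$base_weight_high)
  mean_w <- mean_w + t(mean_w)
  mean_w[!presence] <- 0

  groups <- c(rep("HV", cfg$n_hv), rep("CP", cfg$n_cp), rep("CI", cfg$n_ci))
  n_sub <- length(groups)
  ids <- sprintf("sub_%03d", seq_len(n_sub))

  ages <- numeric(n_sub); sexes <- character(n_sub)
  for (g in c("HV", "CP", "CI")) {
    idx <- which(groups == g)
    if (!length(idx)) next
    ages[idx] <- rtruncnorm1(length(idx), cfg$age_means[[g]],
                             cfg$age_sds[[g]], 18, 65)
    sexes[idx] <- ifelse(runif(length(idx)) < cfg$female_props[[g]],
                         "F", "M")
  }

  # cognitive scores: calibrate latent shift once per patient group
  shifts <- c(CP = 0, CI = 0)
  for (g in c("CP", "CI")) {
    if (any(groups == g)) shifts[[g]] <- calibrate_cog_shift(g, cfg)
  }
  cogz <- matrix(NA_real_, n_sub, cfg$n_cog_tests)
  status <- rep("not_applicable", n_sub)
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    if (g == "HV") next
    cogz[i, ] <- generate_cog_scores(g, cfg, shift = shifts[[g]])
    status[i] <- classify_cognitive_status(cogz[i, ])
  }

  # per-subject matrices
  vuln <- logical(n)
  vuln[cfg$vulnerable_nodes] <- TRUE
  vuln_edge <- outer(vuln, vuln, `|`)  # incident to >= 1 vulnerable node
  matrices <- vector("list", n_sub)
  pres_idx <- which(presence & ut)
  for (i in seq_len(n_sub)) {
    atten <- matrix(1, n, n)
    if (groups[i] != "HV") {
      atten[vuln_edge] <- atten[vuln_edge] * (1 - cfg$delta_cp)
      if (groups[i] == "CI") {
        atten[vuln_edge] <- atten[vuln_edge] * (1 - cfg$delta_ci)
      }
    }
    w <- matrix(0, n, n)
    keep <- pres_idx[runif(length(pres_idx)) >= cfg$dropout_prob]
    mu_edge <- mean_w[keep] * atten[keep] +
      cfg$age_slope * (ages[i] - 40)
    w[keep] <- pmin(1, pmax(0, mu_edge + rnorm(length(keep),
                                               sd = cfg$subject_noise_sd)))
    w <- w + t(w)  # only the upper triangle was filled
    diag(w) <- 0
    matrices[[i]] <- conn_matrix(w, labels, ids[i])
  }
  names(matrices) <- ids

  subjects <- data.frame(
    subject_id = ids,
    group = factor(groups, levels = c("HV", "CP", "CI")),
    age = ages,
    sex = factor(sexes, levels = c("F", "M")),
    cognitive_status = status,
    stringsAsFactors = FALSE)
  colnames(cogz) <- paste0("cog_z_", seq_len(cfg$n_cog_tests))
  subjects <- cbind(subjects, as.data.frame(cogz))

  list(subjects = subjects, matrices = matrices,
       template = list(presence = presence, mean_weight = mean_w),
       config = cfg)
}

#' Write / read a cohort subject table
#'
#' @param subjects subject data.frame as produced by [generate_cohort()].
#' @param path CSV path.
#' @param header optional comment lines written with a `#` prefix.
#' @return `write_subjects` returns `path` invisibly; `read_subjects`
#'   returns the subject data.frame with group/sex as factors.
#' @export
write_subjects <- function(subjects, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(subjects, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("HV", "CP", "CI"))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df
}
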