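# Per-node three-group statistics with assumption gating.
#
# Gate 1: Shapiro-Wilk in each group; any violation routes to
# Kruskal-Wallis + Dunn. Gate 2: Levene; violation routes to Welch ANOVA
# + pairwise Welch t. Otherwise one-way ANOVA + Tukey HSD. Only the two
# contrasts of scientific interest are reported: CP - HV (disease effect)
# and CI - CP (impairment effect).

contrast_names <- c("CP-HV", "CI-CP")

# Dunn's rank-based post-hoc z test with tie correction; returns the
# two-sided p for one pairwise contrast given the pooled ranking
dunn_p <- function(ranks, groups, a, b) {
  N <- length(ranks)
  tie_tab <- table(ranks)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  na <- sum(groups == a); nb <- sum(groups == b)
  za <- mean(ranks[groups == a]) - mean(ranks[groups == b])
  se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
  2 * pnorm(-abs(za / se))
}

#' Three-group comparison for one node's metric values
#'
#' Runs the gated testing scheme on one node: Shapiro-Wilk normality per
#' group (at `alpha_gate`), then Levene's test of homoscedasticity, and
#' picks one-way ANOVA + Tukey HSD, Welch ANOVA + pairwise Welch t, or
#' Kruskal-Wallis + Dunn accordingly. Directions are the sign of the
#' contrast's difference in group means (medians on the rank-based
#' branch).
#'
#' @param values_by_group named list with numeric elements `HV`, `CP`,
#'   `CI`, each of length >= 3.
#' @param alpha_gate significance level for the assumption gates.
#' @return one-row-per-contrast data.frame: omnibus_test, omnibus_p,
#'   posthoc_test, contrast, raw_p, direction.
#' @export
test_node <- function(values_by_group, alpha_gate = 0.05) {
  need <- c("HV", "CP", "CI")
  if (!all(need %in% names(values_by_group))) {
    cc_stop("values_by_group must contain HV, CP and CI samples",
            "conncog_input_error")
  }
  vals <- values_by_group[need]
  ns <- lengths(vals)
  if (any(ns < 3)) {
    cc_stop("each group needs at least 3 observations",
            "conncog_input_error")
  }
  y <- unlist(vals, use.names = FALSE)
  g <- factor(rep(need, ns), levels = need)
  if (var(y) == 0) {
    cc_stop("values are constant across all groups; nothing to test",
            "conncog_degenerate_error")
  }

  normal <- vapply(vals, function(v) {
    if (length(unique(v)) < 3) return(FALSE)  # constant-ish: not normal
    tryCatch(shapiro.test(v)$p.value >= alpha_gate,
             error = function(e) FALSE)
  }, logical(1))

  if (!all(normal)) {
    om <- kruskal.test(y, g)
    omnibus_test <- "kruskal_wallis"; posthoc <- "dunn"
    r <- rank(y)
    raw <- c(dunn_p(r, g, "CP", "HV"), dunn_p(r, g, "CI", "CP"))
    dir <- c(sign(median(vals$CP) - median(vals$HV)),
             sign(median(vals$CI) - median(vals$CP)))
    omnibus_p <- om$p.value
  } else {
    lev <- car::leveneTest(y ~ g, center = "mean")
    if (lev[1, "Pr(>F)"] < alpha_gate) {
      om <- oneway.test(y ~ g, var.equal = FALSE)
      omnibus_test <- "welch_anova"; posthoc <- "welch_t"
      raw <- c(t.test(vals$CP, vals$HV, var.equal = FALSE)$p.value,
               t.test(vals$CI, vals$CP, var.equal = FALSE)$p.value)
      omnibus_p <- om$p.value
    } else {
      fit <- aov(y ~ g)
      omnibus_test <- "anova"; posthoc <- "tukey_hsd"
      omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- TukeyHSD(fit)$g
      raw <- c(tk["CP-HV", "p adj"], tk["CI-CP", "p adj"])
      omnibus_p <- omnibus_p
    }
    dir <- c(sign(mean(vals$CP) - mean(vals$HV)),
             sign(mean(vals$CI) - mean(vals$CP)))
  }
  data.frame(omnibus_test = omnibus_test,
             omnibus_p = omnibus_p,
             posthoc_test = posthoc,
             contrast = contrast_names,
             raw_p = raw,
             direction = as.integer(dir),
             stringsAsFactors = FALSE)
}

#' Multiple-comparison correction
#'
#' Step-up Benjamini-Hochberg (default) or Bonferroni via
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return corrected p-values (monotone in input ranks, capped at 1).
#' @export
#' @examples
#' correct_pvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04 under BH
correct_pvalues <- function(pvals,
                            method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    cc_stop("p-values must lie in [0, 1]", "conncog_input_error")
  }
  p.adjust(pvals, method = switch(method,
                                  benjamini_hochberg = "BH",
                                  bonferroni = "bonferroni"))
}

#' Node-wise group statistics for all metrics
#'
#' Applies [test_node()] to every node of every metric table and corrects
#' the contrast p-values across nodes, separately within each metric x
#' contrast family.
#'
#' @param tables list of subjects x nodes matrices from
#'   [compute_all_metrics()] (any subset of metrics).
#' @param groups factor (levels HV, CP, CI) aligned with table rows.
#' @param alpha_gate gate level for normality/homoscedasticity checks.
#' @param correction correction method, see [correct_pvalues()].
#' @return data.frame with columns metric, node, omnibus_test, omnibus_p,
#'   posthoc_test, contrast, raw_p, corrected_p, direction. Nodes whose
#'   values are constant in all groups (e.g. fully masked) are reported
#'   with NA p-values and direction 0.
#' @export
test_metric_nodes <- function(tables, groups, alpha_gate = 0.05,
                              correction = "benjamini_hochberg") {
  groups <- factor(groups, levels = c("HV", "CP", "CI"))
  res <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (nrow(tab) != length(groups)) {
      cc_stop("group vector length must match table rows",
              "conncog_input_error")
    }
    for (node in colnames(tab)) {
      v <- split(tab[, node], groups)
      row <- tryCatch(test_node(v, alpha_gate),
                      conncog_degenerate_error = function(e) {
        data.frame(omnibus_test = "none", omnibus_p = NA_real_,
                   posthoc_test = "none", contrast = contrast_names,
                   raw_p = NA_real_, direction = 0L,
                   stringsAsFactors = FALSE)
      })
      row <- cbind(metric = nm, node = node, row)
      res[[length(res) + 1]] <- row
    }
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$corrected_p <- NA_real_
  for (nm in unique(res$metric)) {
    for (ct in contrast_names) {
      sel <- res$metric == nm & res$contrast == ct & !is.na(res$raw_p)
      if (any(sel)) res$corrected_p[sel] <- correct_pvalues(res$raw_p[sel],
                                                            correction)
    }
  }
  res[, c("metric", "node", "omnibus_test", "omnibus_p", "posthoc_test",
          "contrast", "raw_p", "corrected_p", "direction")]
}

#' Count significant nodes per metric and contrast
#'
#' Summarises a [test_metric_nodes()] result into counts and one-decimal
#' percentages of nodes with corrected p below `alpha`, split by the
#' direction of the difference, formatted as e.g. `"42 (55.3%)"`.
#'
#' @param results data.frame from [test_metric_nodes()].
#' @param alpha significance level on corrected p-values.
#' @param n_nodes expected node count; defaults to the number of distinct
#'   nodes present. Used to verify complete coverage.
#' @return data.frame: metric, contrast, n_nodes, n_sig, n_decreased,
#'   n_increased, pct_sig, label (count + percentage string).
#' @export
summarize_differences <- function(results, alpha = 0.05, n_nodes = NULL) {
  nodes <- unique(results$node)
  if (is.null(n_nodes)) n_nodes <- length(nodes)
  out <- list()
  for (nm in unique(results$metric)) {
    for (ct in contrast_names) {
      sub <- results[results$metric == nm & results$contrast == ct, ]
      if (nrow(sub) != n_nodes) {
        cc_stop(sprintf(
          "metric %s contrast %s covers %d of %d nodes",
          nm, ct, nrow(sub), n_nodes), "conncog_coverage_error")
      }
      sig <- !is.na(sub$corrected_p) & sub$corrected_p < alpha
      out[[length(out) + 1]] <- data.frame(
        metric = nm, contrast = ct,
        n_nodes = n_nodes,
        n_sig = sum(sig),
        n_decreased = sum(sig & sub$direction < 0),
        n_increased = sum(sig & sub$direction > 0),
        pct_sig = round(100 * sum(sig) / n_nodes, 1),
        label = format_count_pct(sum(sig), n_nodes),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort demographic description
#'
#' Table-1-style description of the cohort: group sizes, age
#' (ANOVA/Kruskal-Wallis according to the same gating as [test_node()]),
#' sex (chi-squared), and global cognition z per patient group. Purely
#' descriptive; nothing downstream depends on it.
#'
#' @param subjects subject table from [generate_cohort()].
#' @return list with `counts`, `age` (means, sds, test, p), `sex`
#'   (proportions female, chi-squared p) and `cognition` (global z mean/sd
#'   by patient group).
#' @export
describe_cohort <- function(subjects) {
  g <- subjects$group
  counts <- table(g)
  age_fit <- tryCatch(test_node(split(subjects$age, g)),
                      conncog_error = function(e) NULL)
  sex_tab <- table(g, subjects$sex)
  sex_p <- tryCatch(suppressWarnings(stats::chisq.test(sex_tab)$p.value),
                    error = function(e) NA_real_)
  cogcols <- grep("^cog_z_", names(subjects), value = TRUE)
  glob <- rowMeans(subjects[, cogcols, drop = FALSE])
  cog <- lapply(c(CP = "CP", CI = "CI"), function(gr) {
    v <- glob[g == gr]
    c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  })
  list(counts = counts,
       age = list(mean = tapply(subjects$age, g, mean),
                  sd = tapply(subjects$age, g, sd),
                  test = if (is.null(age_fit)) NA else age_fit$omnibus_test[1],
                  p = if (is.null(age_fit)) NA else age_fit$omnibus_p[1]),
       sex = list(prop_female = prop.table(sex_tab, 1)[, "F"],
                  chisq_p = sex_p),
       cognition = cog)
}
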