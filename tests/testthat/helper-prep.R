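# Shared fixture: run a cohort through the standard preparation chain
# (HV prevalence mask -> age/sex confound regression) and compute the
# requested nodal metric tables.

prep_metric_tables <- function(cohort, metrics = c("strength",
                                                   "local_efficiency")) {
  subjects <- cohort$subjects
  mask <- prevalence_mask(cohort$matrices[subjects$group == "HV"])
  masked <- lapply(cohort$matrices, apply_mask, mask = mask)
  corrected <- regress_confounds(masked,
                                 covariate_table(subjects$age,
                                                 subjects$sex))
  names(corrected) <- names(cohort$matrices)
  n <- nrow(cohort$matrices[[1]])
  fns <- list(strength = node_strength,
              local_efficiency = local_efficiency,
              clustering = clustering_coefficient,
              betweenness = betweenness_centrality,
              degree = function(m) as.numeric(node_degree(m)))
  out <- lapply(fns[metrics], function(f)
    t(vapply(corrected, function(m) as.numeric(f(m)), numeric(n))))
  for (nm in names(out)) {
    colnames(out[[nm]]) <- rownames(cohort$matrices[[1]])
  }
  out
}
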