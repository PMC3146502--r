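# study configuration with a planted class A duration effect only
# (all other classes share the control-group parameters)
power_config <- function(seed, epochs_per_subject = 18) {
  means <- default_duration_means()
  sds <- default_duration_sds()
  means["patient", c("B", "C", "D")] <- means["control", c("B", "C", "D")]
  sds["patient", c("B", "C", "D")] <- sds["control", c("B", "C", "D")]
  means[, "A"] <- c(63.8, 54.6)
  sds[, "A"] <- c(14.7, 10.1)
  synth_config(n_subjects_per_group = 18,
               epochs_per_subject = epochs_per_subject,
               class_mean_duration_ms = means,
               class_duration_sd_ms = sds,
               seed = seed)
}

# one full planted-effect replicate: cohort -> pipeline -> post-hoc duration
# t-tests; returns the per-class p-values and the class A t sign
power_replicate <- function(seed, epochs_per_subject = 18) {
  cfg <- power_config(seed, epochs_per_subject)
  coh <- generate_cohort(cfg)
  rep <- run_pipeline(coh, seed = seed + 1L, run_stats = FALSE)
  ph <- posthoc_ttests(rep$profiles, "duration_ms")
  list(p = stats::setNames(ph$p.value, ph$class),
       t = stats::setNames(ph$t, ph$class))
}
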