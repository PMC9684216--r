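# Memoised full-protocol cohort runs shared by the acceptance tests (several
# tests read different cells of the same simulated cohorts).

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function(preset, blocks = "baseline",
                              n_subjects = NULL, reps = NULL, seed = 1) {
  key <- paste(preset, paste(blocks, collapse = "+"), n_subjects, reps, seed,
               sep = "|")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- vt_default_config()
  if (is.null(n_subjects)) n_subjects <- cfg$cohort$n_subjects
  if (is.null(reps)) reps <- cfg$cohort$reps
  res <- run_experiment(cfg$params, preset, blocks,
                        n_subjects = n_subjects, reps = reps,
                        master_seed = seed,
                        tactile_strength = cfg$stimuli$tactile_strength,
                        visual_bright_strength =
                          cfg$stimuli$visual_bright_strength,
                        jitter_fraction = cfg$cohort$jitter_fraction,
                        noise_variance = cfg$stimuli$noise_variance)
  .cohort_cache[[key]] <- res
  res
}
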