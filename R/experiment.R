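#' Create a simulated subject by jittering the synaptic matrices
#'
#' Inter-individual variability: every connection weight w of the model
#' (lateral kernel entries, feedforward, feedback, callosal and inhibitory
#' weights, in both hemispheres) is replaced by \code{w + eta} with
#' \code{eta ~ Normal(0, sd = jitter_fraction * |w|)}, then clipped to
#' preserve the sign of the basal weight (excitatory weights stay
#' non-negative, inhibitory magnitudes stay non-negative, negative kernel
#' surround entries stay non-positive).  The jitter is drawn once per subject
#' and fixed across all of that subject's trials.
#'
#' The default \code{jitter_fraction = 0.4} reads "variability of 40\% of the
#' synaptic efficacy" as the standard deviation of the perturbation; set
#' \code{jitter_as = "variance"} for the alternative reading
#' \code{sd = sqrt(0.4 |w|)}.
#'
#' @param matrices Basal (or preset-modified) \code{"vt_matrices"}.
#' @param jitter_fraction Non-negative jitter magnitude (0 = no jitter).
#' @param seed Integer seed making the subject reproducible.
#' @param jitter_as \code{"sd"} (default) or \code{"variance"}.
#' @return A list of class \code{"vt_subject"} with \code{subject_id} unset,
#'   \code{matrices} (jittered), and \code{seed}.
#' @export
make_subject <- function(matrices, jitter_fraction = 0.4, seed,
                         jitter_as = c("sd", "variance")) {
  jitter_as <- match.arg(jitter_as)
  if (jitter_fraction < 0) stop("jitter_fraction must be non-negative")
  stopifnot(inherits(matrices, "vt_matrices"))
  m <- matrices
  if (jitter_fraction > 0) {
    set.seed(as.integer(seed))
    jit <- function(w) {
      s <- if (jitter_as == "sd") jitter_fraction * abs(w)
           else sqrt(jitter_fraction * abs(w))
      out <- w + stats::rnorm(length(w), 0, s)
      # preserve the sign class of each basal connection
      out <- ifelse(w >= 0, pmax(out, 0), pmin(out, 0))
      if (is.matrix(w)) dim(out) <- dim(w)
      out
    }
    for (h in c("bright", "dim")) {
      for (f in c("K_t", "K_v", "ff_t", "ff_v", "fb_t", "fb_v",
                  "inh_t", "inh_v", "w_inter")) {
        m[[h]][[f]] <- jit(m[[h]][[f]])
      }
    }
  }
  structure(list(subject_id = NA_integer_, matrices = m,
                 seed = as.integer(seed)),
            class = "vt_subject")
}

#' Build a cohort of jittered subjects
#'
#' Derives one reproducible seed per subject from the master seed and returns
#' the list of jittered subjects.  Using the same master seed with different
#' presets yields paired cohorts: subject k receives the same jitter noise
#' stream in each.
#'
#' @param matrices Basal (or preset-modified) \code{"vt_matrices"}.
#' @param n_subjects Number of simulated subjects (the study protocol uses 16).
#' @param master_seed Integer master seed.
#' @param jitter_fraction,jitter_as Passed to [make_subject()].
#' @return A list of \code{"vt_subject"} objects.
#' @export
make_cohort <- function(matrices, n_subjects = 16, master_seed = 1,
                        jitter_fraction = 0.4, jitter_as = c("sd", "variance")) {
  jitter_as <- match.arg(jitter_as)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  lapply(seq_len(n_subjects), function(k) {
    s <- make_subject(matrices, jitter_fraction, seeds[k], jitter_as)
    s$subject_id <- k
    s
  })
}

#' Run a block of 4AFC trials for a cohort
#'
#' For every subject x condition x repetition: draws fresh stimulus noise,
#' builds the trial drives, integrates the network to steady state, computes
#' the two Tactile Awareness Degrees and classifies the 4AFC response.
#' Conditions run in a fixed nested loop (there is no carry-over state
#' between trials, so randomizing the schedule is irrelevant).
#'
#' @param subjects A list of \code{"vt_subject"}s from [make_cohort()].
#' @param params A \code{"vt_params"} list.
#' @param block \code{"baseline"} (tactile-only conditions) or \code{"VT"}
#'   (all 16 conditions), ignored when \code{conditions} is supplied.
#' @param reps Repetitions per condition per subject (protocol: 20).
#' @param tactile_strength Calibrated nominal tactile strength.
#' @param visual_bright_strength Nominal bright visual strength (dim = /2.5).
#' @param noise_variance Stimulus noise variance (default 0.2).
#' @param seed Integer seed for the trial noise stream.
#' @param conditions Optional data frame of conditions overriding the block's
#'   standard set (e.g. only the unimanual conditions during calibration).
#' @return A data frame of per-trial records: subject_id, block, tactile,
#'   visual, rep, tad_bright, tad_dim, response, correct, converged.
#' @export
run_block <- function(subjects, params, block = c("baseline", "VT"),
                      reps = 20, tactile_strength,
                      visual_bright_strength = 0, noise_variance = 0.2,
                      seed = 1, conditions = NULL) {
  block <- match.arg(block)
  if (reps < 1) stop("reps must be >= 1")
  conds <- if (is.null(conditions)) trial_conditions(block) else conditions
  set.seed(as.integer(seed))
  n_trials <- length(subjects) * nrow(conds) * reps
  rec <- vector("list", n_trials)
  k <- 0
  for (subj in subjects) {
    for (ci in seq_len(nrow(conds))) {
      cond <- conds[ci, , drop = FALSE]
      for (r in seq_len(reps)) {
        drives <- make_trial_drives(cond, tactile_strength,
                                    visual_bright_strength,
                                    noise_variance, params)
        st <- simulate_trial(drives, subj$matrices, params)
        tb <- compute_tad(st$bright, params$detection_threshold,
                          params$detection_threshold_multisensory)
        td <- compute_tad(st$dim, params$detection_threshold,
                          params$detection_threshold_multisensory)
        resp <- classify_response(tb, td)
        k <- k + 1
        rec[[k]] <- data.frame(
          subject_id = subj$subject_id, block = block,
          tactile = cond$tactile, visual = cond$visual, rep = r,
          tad_bright = tb, tad_dim = td, response = resp,
          correct = resp == correct_response(cond$tactile),
          converged = st$converged)
      }
    }
  }
  do.call(rbind, rec)
}

#' Aggregate trial records into a response-proportion table
#'
#' Per condition (tactile x visual): the proportion of trials assigned to
#' each of the four responses (cohort mean of the per-subject proportions;
#' with a balanced design this equals the pooled proportion) and the
#' standard error of the mean across subjects.
#'
#' @param records A record data frame from [run_block()].
#' @param conditions Optional data frame of conditions (columns tactile,
#'   visual) that must all be present; missing cells raise an error listing
#'   them.  By default the conditions found in the records are used.
#' @return A data frame of class \code{"vt_response_table"} with columns
#'   tactile, visual, p_bright_only, p_dim_only, p_both, p_none, matching
#'   sem_* columns, and n_trials.  Each row's four proportions sum to 1.
#' @export
aggregate_records <- function(records, conditions = NULL) {
  conds <- if (is.null(conditions)) unique(records[, c("tactile", "visual")])
           else conditions[, c("tactile", "visual")]
  conds <- conds[order(match(conds$visual, visual_levels),
                       match(conds$tactile, tactile_levels)), , drop = FALSE]
  have <- paste(records$tactile, records$visual)
  missing <- setdiff(paste(conds$tactile, conds$visual), unique(have))
  if (length(missing))
    stop("missing condition cells: ", paste(missing, collapse = ", "))
  subj <- sort(unique(records$subject_id))
  rows <- lapply(seq_len(nrow(conds)), function(ci) {
    sel <- records$tactile == conds$tactile[ci] &
      records$visual == conds$visual[ci]
    sub <- records[sel, , drop = FALSE]
    per_subj <- t(vapply(subj, function(s) {
      r <- sub$response[sub$subject_id == s]
      if (!length(r)) return(rep(NA_real_, 4))
      vapply(response_levels, function(l) mean(r == l), numeric(1))
    }, numeric(4)))
    n_eff <- sum(!is.na(per_subj[, 1]))
    pm <- colMeans(per_subj, na.rm = TRUE)
    sem <- apply(per_subj, 2, stats::sd, na.rm = TRUE) / sqrt(n_eff)
    data.frame(tactile = conds$tactile[ci], visual = conds$visual[ci],
               p_bright_only = pm[1], p_dim_only = pm[2],
               p_both = pm[3], p_none = pm[4],
               sem_bright_only = sem[1], sem_dim_only = sem[2],
               sem_both = sem[3], sem_none = sem[4],
               n_trials = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vt_response_table", "data.frame")
  out
}

prop_cols <- c("p_bright_only", "p_dim_only", "p_both", "p_none")

# look up one proportion cell of a response table
table_prop <- function(tab, tactile, visual, col) {
  i <- which(tab$tactile == tactile & tab$visual == visual)
  if (length(i) != 1) stop("missing row in response table: ", tactile, " / ",
                           visual)
  tab[[col]][i]
}

#' Calibrate the tactile stimulus efficacy
#'
#' Finds, by bisection, the minimal nominal tactile strength at which the
#' cohort's unimanual hit rate (mean over the bright- and dim-hand unimanual
#' conditions, no visual input) matches the target within the tolerance,
#' mimicking the per-participant adaptive thresholding of the behavioral
#' protocol.  Every evaluation reuses the same cohort and the same trial
#' noise stream (common random numbers), which makes the evaluated hit rate
#' non-decreasing in the strength, so bisection is well posed.
#'
#' @param params A \code{"vt_params"} list.
#' @param target Target unimanual hit rate in (0, 1) (default 0.80).
#' @param n_subjects,reps,master_seed Cohort protocol used for evaluation.
#' @param jitter_fraction Subject-level synaptic jitter (default 0.4).
#' @param noise_variance Stimulus noise variance (default 0.2).
#' @param tol Acceptable deviation from the target hit rate (default 0.02,
#'   i.e. +/- 2 percentage points).
#' @param bracket Initial strength search interval; the upper end is doubled
#'   until it overshoots the target.
#' @param max_iter Maximum bisection iterations.
#' @return A list with \code{strength} (the calibrated value),
#'   \code{achieved} (hit rate at that strength), \code{converged}, and
#'   \code{trace} (data frame of the evaluated strengths and hit rates).
#'   If the target is unreachable within the bracket, an error reports the
#'   achieved range.
#' @export
calibrate_tactile_efficacy <- function(params, target = 0.80,
                                       n_subjects = 16, reps = 20,
                                       master_seed = 1,
                                       jitter_fraction = 0.4,
                                       noise_variance = 0.2,
                                       tol = 0.02,
                                       bracket = c(0, 8), max_iter = 20) {
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  matrices <- build_synaptic_matrices(params)
  cohort <- make_cohort(matrices, n_subjects, master_seed, jitter_fraction)
  unimanual <- data.frame(tactile = c("B", "D"), visual = "none",
                          stringsAsFactors = FALSE)
  trace <- data.frame(strength = numeric(0), hit_rate = numeric(0))
  hit <- function(s) {
    if (s <= 0) return(0)
    recs <- run_block(cohort, params, "baseline", reps, s,
                      visual_bright_strength = 0,
                      noise_variance = noise_variance,
                      seed = master_seed + 1L, conditions = unimanual)
    h <- mean(recs$correct)
    trace[nrow(trace) + 1L, ] <<- c(s, h)
    h
  }
  lo <- bracket[1]; hi <- bracket[2]
  h_hi <- hit(hi)
  tries <- 0
  while (h_hi < target && tries < 6) {
    lo <- hi; hi <- 2 * hi
    h_hi <- hit(hi)
    tries <- tries + 1
  }
  if (h_hi < target)
    stop(sprintf(paste0("calibration target %.2f unreachable: hit rate at ",
                        "strength %.2f is only %.3f"), target, hi, h_hi))
  best <- c(strength = hi, achieved = h_hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    h <- hit(mid)
    if (abs(h - target) < abs(best[["achieved"]] - target))
      best <- c(strength = mid, achieved = h)
    if (abs(h - target) <= tol) {
      return(list(strength = mid, achieved = h, converged = TRUE,
                  trace = trace))
    }
    if (h < target) lo <- mid else hi <- mid
  }
  list(strength = best[["strength"]], achieved = best[["achieved"]],
       converged = abs(best[["achieved"]] - target) <= tol, trace = trace)
}

#' Calibrate the visual stimulus efficacies
#'
#' Finds, by noise-free bisection on the basal network, the minimal visual
#' strength that yields a visual detection (visual-map peak and multisensory
#' activity both above threshold), then sets the nominal dim strength to
#' \code{margin_factor} times that minimum so that detection survives all but
#' the most extreme downward noise excursions of the multiplicative stimulus
#' noise; the bright strength is 2.5 times the dim strength.  Because the
#' noise multiplier \code{max(0, 1 + e)} has unbounded-from-below Gaussian
#' support, a literal 100\% detection rate is unattainable for any finite
#' strength; the default margin places detection at the achievable plateau
#' (about 98\% at noise variance 0.2).
#'
#' @param params A \code{"vt_params"} list.
#' @param margin_factor Safety factor over the noise-free detection minimum.
#' @param tol Bisection tolerance on the strength.
#' @return A list with \code{dim}, \code{bright} (nominal strengths) and
#'   \code{threshold_strength} (the noise-free minimum).
#' @export
calibrate_visual_efficacy <- function(params, margin_factor = 10, tol = 0.01) {
  matrices <- build_synaptic_matrices(params)
  detected <- function(s) {
    cond <- list(tactile = "N", visual = "dimLED")
    drives <- make_trial_drives(cond, 0, s * 2.5, 0, params)
    st <- simulate_trial(drives, matrices, params)
    max(st$dim$y_v) > params$detection_threshold &&
      st$dim$y_m > params$detection_threshold_multisensory
  }
  lo <- 0; hi <- 4
  while (!detected(hi) && hi < 2^12) hi <- 2 * hi
  if (!detected(hi)) stop("no visual strength up to ", hi,
                          " produces a visual detection")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (detected(mid)) hi <- mid else lo <- mid
  }
  list(dim = hi * margin_factor, bright = 2.5 * hi * margin_factor,
       threshold_strength = hi)
}

#' Run a full cohort experiment for one plasticity preset
#'
#' Convenience wrapper: applies the preset to the basal matrices, builds the
#' jittered cohort (paired across presets via the master seed), runs the
#' requested block(s), and aggregates the response tables.
#'
#' @param params A \code{"vt_params"} list.
#' @param preset A \code{"vt_preset"} or preset name (default "baseline").
#' @param blocks Character vector among \code{"baseline"}, \code{"VT"}.
#' @param n_subjects,reps,master_seed Cohort protocol (defaults 16 x 20).
#' @param tactile_strength,visual_bright_strength Calibrated strengths.
#' @param jitter_fraction,noise_variance Variability settings.
#' @return A list with \code{records} (one data frame per block) and
#'   \code{tables} (one \code{"vt_response_table"} per block).
#' @export
run_experiment <- function(params, preset = "baseline",
                           blocks = c("baseline", "VT"),
                           n_subjects = 16, reps = 20, master_seed = 1,
                           tactile_strength, visual_bright_strength,
                           jitter_fraction = 0.4, noise_variance = 0.2) {
  if (is.character(preset)) preset <- plasticity_preset(preset)
  blocks <- match.arg(blocks, several.ok = TRUE)
  matrices <- apply_preset(build_synaptic_matrices(params), preset)
  cohort <- make_cohort(matrices, n_subjects, master_seed, jitter_fraction)
  records <- list()
  tables <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    vb <- if (b == "VT") visual_bright_strength else 0
    records[[b]] <- run_block(cohort, params, b, reps, tactile_strength,
                              vb, noise_variance,
                              seed = master_seed + 1L + i)
    tables[[b]] <- aggregate_records(records[[b]])
  }
  list(preset = preset$name, records = records, tables = tables)
}
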