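test_that("subject jitter is reproducible, sign-preserving, and vanishes at
           zero fraction", {
  m <- build_synaptic_matrices(fast_params())
  expect_identical(make_subject(m, 0, seed = 4)$matrices, m)
  s1 <- make_subject(m, 0.4, seed = 11)
  s2 <- make_subject(m, 0.4, seed = 11)
  expect_identical(s1, s2)
  s3 <- make_subject(m, 0.4, seed = 12)
  expect_false(identical(s1$matrices$bright$ff_t, s3$matrices$bright$ff_t))
  # sign classes preserved: excitatory stay >= 0, surround entries stay <= 0
  K <- s1$matrices$bright$K_t
  K0 <- m$bright$K_t
  expect_true(all(K[K0 > 0] >= 0) && all(K[K0 < 0] <= 0))
  expect_true(all(s1$matrices$dim$inh_t >= 0))
})

test_that("jitter statistics match the nominal perturbation law", {
  m <- build_synaptic_matrices(mini_params())
  n <- 2000
  w <- m$bright$ff_t[1]          # a positive connection, basal value
  kneg <- which(m$bright$K_t < -0.01)[1]  # a negative surround connection
  draws <- vapply(seq_len(n), function(i) {
    s <- make_subject(m, 0.4, seed = 2000 + i)
    c(s$matrices$bright$ff_t[1], s$matrices$bright$K_t[kneg])
  }, numeric(2))
  # oracle: moments of the sign-clipped (winsorised at zero) normal
  # w + N(0, 0.4|w|); the clip sits 2.5 sd out, so mean and sd shift little
  z <- 1 / 0.4
  mu_clip <- pnorm(z) + 0.4 * dnorm(z)                  # x |w|
  sd_clip <- sqrt((1 + 0.4^2) * pnorm(z) + 0.4 * dnorm(z) - mu_clip^2)
  expect_equal(sd_clip, 0.4, tolerance = 0.01)          # clip bias is tiny
  for (j in 1:2) {
    wj <- c(w, m$bright$K_t[kneg])[j]
    expect_equal(mean(draws[j, ]), wj * mu_clip,
                 tolerance = 4 * sd_clip / sqrt(n) / mu_clip)
    expect_equal(sd(draws[j, ]) / abs(wj), sd_clip,
                 tolerance = 4 / sqrt(2 * n) + 0.01)
  }
  # the variance reading of the jitter magnitude is also available
  sv <- make_subject(m, 0.4, seed = 1, jitter_as = "variance")
  expect_false(identical(sv$matrices$bright$ff_t,
                         make_subject(m, 0.4, seed = 1)$matrices$bright$ff_t))
})

test_that("block bookkeeping: condition sets, record counts, catch trials", {
  p <- fast_params()
  cohort <- make_cohort(build_synaptic_matrices(p), 2, 7)
  bl <- run_block(cohort, p, "baseline", 3, tactile_strength = 6, seed = 5)
  expect_equal(nrow(bl), 2 * 4 * 3)
  vt <- run_block(cohort, p, "VT", 1, tactile_strength = 6,
                  visual_bright_strength = 40, seed = 5)
  expect_equal(nrow(vt), 2 * 16 * 1)
  # no-stimulation trials are always answered "none" (multiplicative noise
  # leaves zero input exactly zero)
  expect_true(all(bl$response[bl$tactile == "N"] == "none"))
  expect_true(all(bl$correct[bl$tactile == "N"]))
})

test_that("aggregation returns proportions that sum to one, is order
           invariant, and matches an independent s.e.m. recomputation", {
  p <- fast_params()
  cohort <- make_cohort(build_synaptic_matrices(p), 3, 7)
  rec <- run_block(cohort, p, "baseline", 4, tactile_strength = 6, seed = 9)
  tab <- aggregate_records(rec)
  expect_s3_class(tab, "vt_response_table")
  sums <- tab$p_bright_only + tab$p_dim_only + tab$p_both + tab$p_none
  expect_equal(sums, rep(1, nrow(tab)), tolerance = 1e-9)
  expect_equal(tab$n_trials, rep(3 * 4, 4))
  # order invariance
  tab2 <- aggregate_records(rec[sample(nrow(rec)), ])
  expect_equal(tab, tab2)
  # s.e.m. oracle: recompute from per-subject proportions by hand
  sel <- rec$tactile == "BD"
  per <- sapply(sort(unique(rec$subject_id)), function(s)
    mean(rec$response[sel & rec$subject_id == s] == "both"))
  expect_equal(tab$sem_both[tab$tactile == "BD"],
               sd(per) / sqrt(length(per)))
  # a degenerate single-response cell
  fake <- rec[sel, ]
  fake$response <- "both"
  row <- aggregate_records(fake)
  expect_equal(unlist(row[1, c("p_bright_only", "p_dim_only", "p_both",
                               "p_none")], use.names = FALSE),
               c(0, 0, 1, 0))
  # missing condition cells are reported by name
  expect_error(aggregate_records(rec[rec$tactile != "BD", ],
                                 conditions = trial_conditions("baseline")),
               "BD")
  # a subject lacking trials in one cell is dropped from that cell's mean
  part <- aggregate_records(rec[rec$tactile != "BD" | rec$subject_id != 1, ])
  expect_false(anyNA(part$p_both))
})

test_that("hit rate is monotone in tactile strength and zero at zero", {
  p <- fast_params()
  cohort <- make_cohort(build_synaptic_matrices(p), 3, 7)
  uni <- data.frame(tactile = c("B", "D"), visual = "none")
  hits <- vapply(c(0, 3, 4.5, 7), function(S) {
    if (S == 0) return(0)
    mean(run_block(cohort, p, "baseline", 6, S, seed = 31,
                   conditions = uni)$correct)
  }, numeric(1))
  expect_equal(hits[1], 0)
  expect_true(all(diff(hits) >= 0))
  expect_gt(hits[4], 0.7)
})

test_that("the full experiment is deterministic in the master seed", {
  p <- fast_params()
  run <- function() run_experiment(p, "H2_interhemispheric", "baseline",
                                   n_subjects = 2, reps = 2, master_seed = 17,
                                   tactile_strength = 5,
                                   visual_bright_strength = 40)
  r1 <- run(); r2 <- run()
  expect_identical(r1$tables, r2$tables)
  expect_identical(r1$records, r2$records)
})
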