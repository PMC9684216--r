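test_that("lateral kernel follows the difference-of-Gaussians formula", {
  p <- fast_params()
  K <- build_lateral_kernel(p)
  # zero distance: L_ex - L_in, on the whole diagonal
  expect_equal(unname(diag(K)), rep(p$lat_ex_amp - p$lat_in_amp, nrow(K)))
  # symmetric in the unit pair
  expect_identical(K, t(K))
  # analytic zero crossing of the DoG profile
  d_star <- sqrt(2 * log(p$lat_ex_amp / p$lat_in_amp) *
                   p$lat_ex_sigma^2 * p$lat_in_sigma^2 /
                   (p$lat_in_sigma^2 - p$lat_ex_sigma^2))
  dog <- function(d) p$lat_ex_amp * exp(-d^2 / (2 * p$lat_ex_sigma^2)) -
    p$lat_in_amp * exp(-d^2 / (2 * p$lat_in_sigma^2))
  expect_equal(dog(d_star), 0, tolerance = 1e-12)
  expect_gt(dog(d_star * 0.9), 0)
  expect_lt(dog(d_star * 1.1), 0)
  # kernel entries match the profile of the inter-unit distances
  pos <- unit_positions(p)
  d12 <- sqrt(sum((pos[1, ] - pos[2, ])^2))
  expect_equal(K[1, 2], dog(d12))
  expect_error(build_lateral_kernel(vt_params(lat_ex_sigma = -1)),
               "strictly positive")
})

test_that("receptive-field drive is a Gaussian of stimulus distance", {
  p <- fast_params()
  centre <- matrix(c(0, 0), ncol = 2)
  # at the RF centre with unit strength and unit gain
  expect_equal(rf_input(c(0, 0), 1, centre, p), 1)
  # one SD away
  expect_equal(rf_input(c(p$rf_sigma, 0), 2, centre, p), 2 * exp(-1 / 2))
  # far tail
  expect_lt(rf_input(c(10 * p$rf_sigma, 0), 1, centre, p), 1e-20)
  # zero strength, zero drive
  expect_equal(rf_input(c(0.3, 0.1), 0, centre, p), 0)
  expect_error(rf_input(c(0, 0), -1, centre, p), "non-negative")
})

test_that("logistic activation has the standard closed-form values", {
  expect_equal(sigmoid_activation(2, 3, 2), 0.5)
  expect_equal(sigmoid_activation(2 + log(3) / 3, 3, 2), 0.75)
  expect_equal(sigmoid_activation(-1e3, 3, 2), 0)
  expect_equal(sigmoid_activation(1e3, 3, 2), 1)
  # monotone non-decreasing
  u <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(sigmoid_activation(u, 2, 1)) >= 0))
})

test_that("the unstimulated network stays perceptually silent", {
  p <- fast_params()
  m <- build_synaptic_matrices(p)
  dr <- make_trial_drives(list(tactile = "N", visual = "none"), 0, 0, 0.2, p)
  st <- simulate_trial(dr, m, p)
  expect_true(st$converged)
  acts <- c(st$bright$y_t, st$bright$y_v, st$bright$y_m, st$bright$y_i,
            st$dim$y_t, st$dim$y_v, st$dim$y_m, st$dim$y_i)
  # logistic floor: basal activity is tiny but not exactly zero
  expect_lt(max(acts), 1e-2)
  expect_equal(compute_tad(st$bright, p$detection_threshold), 0)
  expect_equal(compute_tad(st$dim, p$detection_threshold), 0)
})

test_that("a suprathreshold tactile stimulus activates its own hemisphere and
           the opposite interneuron, which suppresses the unstimulated side", {
  p <- fast_params()
  m <- build_synaptic_matrices(p)
  silent <- simulate_trial(zero_drv <- make_trial_drives(
    list(tactile = "N", visual = "none"), 0, 0, 0, p), m, p)
  dr <- make_trial_drives(list(tactile = "B", visual = "none"), 6, 0, 0, p)
  st <- simulate_trial(dr, m, p)
  expect_true(st$converged)
  expect_gt(max(st$bright$y_t), p$detection_threshold)
  expect_gt(st$bright$y_m, p$detection_threshold)
  # interneuron of the OPPOSITE (dim) hemisphere activates
  expect_gt(st$dim$y_i, 10 * silent$dim$y_i)
  expect_lt(st$bright$y_i, 0.05)
  # and pushes the unstimulated side's unisensory states below their basal level
  expect_lt(mean(st$dim$u_t), mean(silent$dim$u_t))
  expect_lt(mean(st$dim$u_v), mean(silent$dim$u_v))
})

test_that("activities stay within [0, 1] for strong and mixed inputs", {
  p <- fast_params()
  m <- build_synaptic_matrices(p)
  set.seed(7)
  for (i in 1:3) {
    dr <- zero_drives(m$n_units)
    dr$t_bright <- runif(m$n_units, 0, 30)
    dr$v_dim <- runif(m$n_units, 0, 30)
    st <- simulate_trial(dr, m, p)
    acts <- c(st$bright$y_t, st$bright$y_v, st$bright$y_m, st$bright$y_i,
              st$dim$y_t, st$dim$y_v, st$dim$y_m, st$dim$y_i)
    expect_true(all(acts >= 0 & acts <= 1))
  }
})

test_that("swapping the two hands' stimuli mirrors the steady state exactly", {
  p <- fast_params()
  m <- build_synaptic_matrices(p)
  dr1 <- make_trial_drives(list(tactile = "B", visual = "dimLED"), 5, 30, 0, p)
  # hand-swapped stimulation: tactile to dim hand, visual to bright hand,
  # with the same strengths
  dr2 <- list(t_bright = dr1$t_dim, v_bright = dr1$v_dim,
              t_dim = dr1$t_bright, v_dim = dr1$v_bright)
  st1 <- simulate_trial(dr1, m, p)
  st2 <- simulate_trial(dr2, m, p)
  for (f in c("y_t", "y_v", "y_m", "y_i")) {
    expect_identical(st1$bright[[f]], st2$dim[[f]])
    expect_identical(st1$dim[[f]], st2$bright[[f]])
  }
})

test_that("identical bilateral stimulation yields identical hemisphere states", {
  p <- fast_params()
  m <- build_synaptic_matrices(p)
  dr <- make_trial_drives(list(tactile = "BD", visual = "none"), 6, 0, 0, p)
  st <- simulate_trial(dr, m, p)
  for (f in c("y_t", "y_v", "y_m", "y_i"))
    expect_equal(st$bright[[f]], st$dim[[f]], tolerance = 1e-12)
})

test_that("raising the callosal weight never lowers the opposite interneuron's
           steady activity", {
  p <- fast_params()
  y_i_dim <- vapply(c(0.25, 0.5, 1, 1.5, 2), function(scale) {
    m <- build_synaptic_matrices(p)
    m$bright$w_inter <- m$bright$w_inter * scale
    dr <- make_trial_drives(list(tactile = "B", visual = "none"), 6, 0, 0, p)
    simulate_trial(dr, m, p)$dim$y_i
  }, numeric(1))
  expect_true(all(diff(y_i_dim) >= -1e-9))
})

test_that("the interneuron reads the contralateral multisensory activity at
           the callosal delay", {
  p <- fast_params()
  m <- build_synaptic_matrices(p)
  dr <- make_trial_drives(list(tactile = "B", visual = "none"), 6, 0, 0, p)
  st <- simulate_trial(dr, m, p, record = TRUE, n_steps = 300)
  tr <- st$trace
  lag <- as.integer(round(p$callosal_delay / p$dt))
  # reconstruct the dim interneuron's Euler recursion from the recorded trace:
  # u_i[k+1] = u_i[k] + dt/tau_i * (w_inter * y_m_bright[k - lag] - u_i[k])
  k <- (lag + 1):(nrow(tr) - 1)
  delayed <- tr$y_m_bright[k - lag]
  pred <- tr$u_i_dim[k] +
    p$dt / p$tau_inhibitory * (m$bright$w_inter * delayed - tr$u_i_dim[k])
  expect_equal(tr$u_i_dim[k + 1], pred, tolerance = 1e-10)
  # before the delay has elapsed the interneuron receives nothing
  expect_equal(tr$u_i_dim[seq_len(lag)], rep(0, lag), tolerance = 1e-12)
})

test_that("Euler steady state matches an independent fixed-point solve on a
           miniature network", {
  skip_if_not_installed("pracma")
  p <- mini_params(steady_tol = 1e-9, t_max = 2000)
  m <- build_synaptic_matrices(p)
  for (cond in list(list(tactile = "B", visual = "none"),
                    list(tactile = "BD", visual = "none"))) {
    dr <- make_trial_drives(cond, 6, 0, 0, p)
    st <- simulate_trial(dr, m, p)
    expect_true(st$converged)
    or <- fixed_point_oracle(dr, m, p)
    expect_equal(st$bright$y_t, or$y_t_b, tolerance = 1e-6)
    expect_equal(st$dim$y_t, or$y_t_d, tolerance = 1e-6)
    expect_equal(st$bright$y_m, or$y_m_b, tolerance = 1e-6)
    expect_equal(st$dim$y_m, or$y_m_d, tolerance = 1e-6)
    expect_equal(st$bright$y_i, or$y_i_b, tolerance = 1e-6)
    expect_equal(st$dim$y_i, or$y_i_d, tolerance = 1e-6)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(vt_params(dt = 15), "dt")
  expect_error(vt_params(lat_ex_sigma = 2, lat_in_sigma = 1), "narrower")
  expect_error(vt_params(lat_ex_amp = 0.01, lat_in_amp = 0.05), "amplitude")
  expect_error(vt_params(rf_sigma = 0.3), "diameter")
  expect_error(vt_params(w_inter = -1), "non-negative")
  expect_error(vt_params(callosal_delay = 10.3), "integer multiple")
  # default RF diameter sits at the midpoint of the plausible range
  expect_equal(rf_halfmax_diameter(vt_params()), 2.25, tolerance = 1e-10)
})
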