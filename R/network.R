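#' Mexican-hat lateral connectivity kernel
#'
#' Builds the unit-by-unit lateral weight table of one unisensory map as a
#' difference of Gaussians of the Euclidean distance between receptive-field
#' centres: a circular excitatory centre surrounded by a broader inhibitory
#' annulus, so that a punctate stimulus recruits a compact bump of activity
#' without runaway spread.  Self-connections (zero distance) are kept, giving
#' the simplest consistent difference-of-Gaussians definition.
#'
#' @param params A \code{"vt_params"} list.
#' @return A symmetric (n x n) weight matrix,
#'   \eqn{L_{ex} e^{-d^2 / 2\sigma_{ex}^2} - L_{in} e^{-d^2 / 2\sigma_{in}^2}}.
#' @export
#' @examples
#' K <- build_lateral_kernel(vt_params())
#' K[1, 1]  # L_ex - L_in at zero distance
build_lateral_kernel <- function(params) {
  validate_vt_params(params)
  pos <- unit_positions(params)
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  params$lat_ex_amp * exp(-d2 / (2 * params$lat_ex_sigma^2)) -
    params$lat_in_amp * exp(-d2 / (2 * params$lat_in_sigma^2))
}

#' Gaussian receptive-field drive
#'
#' External input delivered to a unisensory unit by a punctate stimulus: the
#' stimulus strength multiplied by a Gaussian window of the distance between
#' the stimulus position and the unit's receptive-field centre, with unitary
#' peak gain \code{rf_amplitude} setting the input scale.
#'
#' @param stim_center Stimulus position, length-2 (x, y) in hand-centred cm.
#' @param stim_strength Dimensionless stimulus strength (>= 0).
#' @param unit_center Unit RF centre(s): length-2 vector or n x 2 matrix.
#' @param params A \code{"vt_params"} list.
#' @return Drive value(s), one per unit centre.
#' @export
rf_input <- function(stim_center, stim_strength, unit_center, params) {
  if (stim_strength < 0) stop("stimulus strength must be non-negative")
  uc <- if (is.matrix(unit_center)) unit_center else matrix(unit_center, ncol = 2)
  d2 <- (uc[, 1] - stim_center[1])^2 + (uc[, 2] - stim_center[2])^2
  stim_strength * params$rf_amplitude * exp(-d2 / (2 * params$rf_sigma^2))
}

#' Logistic activation of a rate unit
#'
#' Static sigmoidal input-output relationship shared by all unit classes:
#' a logistic map with a lower threshold and upper saturation at 1,
#' \eqn{y = 1 / (1 + e^{-slope (u - thresh)})}.  No hard rectification is
#' applied; the silent resting state is realized by placing the threshold
#' well above zero relative to the slope, so the basal output is negligibly
#' small but not exactly zero.
#'
#' @param u State variable(s), any finite value.
#' @param slope Sigmoid steepness (> 0).
#' @param thresh Sigmoid midpoint.
#' @return Activity in (0, 1), same shape as \code{u}.
#' @export
sigmoid_activation <- function(u, slope, thresh) {
  1 / (1 + exp(-slope * (u - thresh)))
}

#' Build the basal synaptic matrices of both hemispheres
#'
#' Derives every connection table of the network from the parameters: per
#' hemisphere, the lateral kernels of the tactile and visual maps, the uniform
#' feedforward vectors onto the multisensory unit, the uniform feedback
#' vectors from it, the scalar projection to the contralateral interneuron,
#' and the uniform inhibitory vectors from the interneuron onto the ipsilateral
#' maps.  In this basal state the two hemispheres are exactly symmetrical;
#' per-subject variability and plasticity presets perturb copies of this
#' object, never the parameters themselves.
#'
#' Hemispheres are labelled by the hand they represent: \code{"bright"} and
#' \code{"dim"} (the hand paired with the bright or dim visual cue).
#'
#' @param params A \code{"vt_params"} list.
#' @return A list of class \code{"vt_matrices"} with elements \code{bright}
#'   and \code{dim}, each containing \code{K_t}, \code{K_v} (n x n lateral
#'   kernels), \code{ff_t}, \code{ff_v}, \code{fb_t}, \code{fb_v},
#'   \code{inh_t}, \code{inh_v} (length-n vectors) and \code{w_inter}
#'   (scalar, the hemisphere's outgoing callosal weight).
#' @export
build_synaptic_matrices <- function(params) {
  validate_vt_params(params)
  n <- params$grid_rows * params$grid_cols
  K <- build_lateral_kernel(params)
  hemi <- list(K_t = K, K_v = K,
               ff_t = rep(params$w_ff_tactile, n),
               ff_v = rep(params$w_ff_visual, n),
               fb_t = rep(params$w_fb_tactile, n),
               fb_v = rep(params$w_fb_visual, n),
               w_inter = params$w_inter,
               inh_t = rep(params$w_inh_tactile, n),
               inh_v = rep(params$w_inh_visual, n))
  structure(list(bright = hemi, dim = hemi, n_units = n),
            class = "vt_matrices")
}

#' @export
print.vt_matrices <- function(x, ...) {
  cat(sprintf("vt_matrices: 2 hemispheres (bright, dim), %d units per map\n",
              x$n_units))
  cat(sprintf("  mean ff tactile/visual (bright): %.4f / %.4f\n",
              mean(x$bright$ff_t), mean(x$bright$ff_v)))
  cat(sprintf("  mean ff tactile/visual (dim)   : %.4f / %.4f\n",
              mean(x$dim$ff_t), mean(x$dim$ff_v)))
  cat(sprintf("  w_inter bright->dim: %.4f, dim->bright: %.4f\n",
              x$bright$w_inter, x$dim$w_inter))
  invisible(x)
}

zero_drives <- function(n) {
  z <- numeric(n)
  list(t_bright = z, v_bright = z, t_dim = z, v_dim = z)
}

#' Integrate the network to a steady state
#'
#' Runs explicit Euler integration of the leaky-sigmoid rate dynamics
#' \eqn{\tau \dot u = -u + \mathrm{net}(y)}, \eqn{y = \mathrm{logistic}(u)},
#' for both hemispheres under constant external drives, until the maximum
#' absolute activity change per step drops below \code{steady_tol} or
#' \code{t_max} is reached.  The interneuron of each hemisphere reads the
#' opposite hemisphere's multisensory activity through a delay line of
#' \code{callosal_delay} ms.  Non-convergence at the horizon is flagged in
#' the result, never silently accepted.
#'
#' @param drives A list with external drive vectors \code{t_bright},
#'   \code{v_bright}, \code{t_dim}, \code{v_dim} (length n each), e.g. from
#'   [make_trial_drives()].
#' @param matrices A \code{"vt_matrices"} object.
#' @param params A \code{"vt_params"} list.
#' @param record If \code{TRUE}, also return a per-step trace of summary
#'   activities (time, multisensory and interneuron activities and states,
#'   unisensory maxima).
#' @param n_steps If a positive integer, run exactly this many Euler steps
#'   with no convergence stopping (useful for inspecting transients).
#' @return A list of class \code{"vt_state"} with per-hemisphere activities
#'   (\code{bright} and \code{dim}, each with \code{y_t}, \code{y_v},
#'   \code{y_m}, \code{y_i} and the corresponding states \code{u_*}),
#'   \code{converged}, \code{n_steps}, \code{t_ms}, and optionally
#'   \code{trace} (a data frame).
#' @export
simulate_trial <- function(drives, matrices, params, record = FALSE,
                           n_steps = NULL) {
  delay_steps <- as.integer(round(params$callosal_delay / params$dt))
  max_steps <- as.integer(ceiling(params$t_max / params$dt))
  fixed <- if (is.null(n_steps)) -1L else as.integer(n_steps)
  b <- matrices$bright; d <- matrices$dim
  res <- vt_integrate_cpp(
    b$K_t, b$K_v, d$K_t, d$K_v,
    b$ff_t, b$ff_v, d$ff_t, d$ff_v,
    b$fb_t, b$fb_v, d$fb_t, d$fb_v,
    b$w_inter, d$w_inter,
    b$inh_t, b$inh_v, d$inh_t, d$inh_v,
    drives$t_bright, drives$v_bright, drives$t_dim, drives$v_dim,
    params$sigmoid_slope_unisensory, params$sigmoid_thresh_unisensory,
    params$sigmoid_slope_multisensory, params$sigmoid_thresh_multisensory,
    params$sigmoid_slope_inhibitory, params$sigmoid_thresh_inhibitory,
    params$tau_unisensory, params$tau_multisensory, params$tau_inhibitory,
    params$dt, delay_steps, max_steps, params$steady_tol,
    record, fixed)
  state <- list(
    bright = list(y_t = drop(res$y_t_b), y_v = drop(res$y_v_b),
                  y_m = res$y_m_b, y_i = res$y_i_b,
                  u_t = drop(res$u_t_b), u_v = drop(res$u_v_b),
                  u_m = res$u_m_b, u_i = res$u_i_b),
    dim = list(y_t = drop(res$y_t_d), y_v = drop(res$y_v_d),
               y_m = res$y_m_d, y_i = res$y_i_d,
               u_t = drop(res$u_t_d), u_v = drop(res$u_v_d),
               u_m = res$u_m_d, u_i = res$u_i_d),
    converged = res$converged, n_steps = res$n_steps,
    t_ms = res$n_steps * params$dt)
  if (record) {
    tr <- as.data.frame(res$trace)
    names(tr) <- c("time_ms", "y_m_bright", "y_m_dim", "y_i_bright", "y_i_dim",
                   "u_i_bright", "u_i_dim", "y_t_max_bright", "y_t_max_dim",
                   "y_v_max_bright", "y_v_max_dim")
    state$trace <- tr
  }
  class(state) <- "vt_state"
  state
}

#' @export
print.vt_state <- function(x, ...) {
  cat(sprintf("vt_state after %d steps (%.1f ms), %s\n", x$n_steps, x$t_ms,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  bright: max y_t %.3f  max y_v %.3f  y_m %.3f  y_i %.3f\n",
              max(x$bright$y_t), max(x$bright$y_v), x$bright$y_m, x$bright$y_i))
  cat(sprintf("  dim   : max y_t %.3f  max y_v %.3f  y_m %.3f  y_i %.3f\n",
              max(x$dim$y_t), max(x$dim$y_v), x$dim$y_m, x$dim$y_i))
  invisible(x)
}

#' Export a recorded trial trace as a tidy table
#'
#' Reshapes the summary trace of a recorded simulation into long format
#' (time_ms, population, hemisphere, activity), suitable for CSV export and
#' plotting.
#'
#' @param state A \code{"vt_state"} simulated with \code{record = TRUE}.
#' @return A data frame with columns time_ms, population, hemisphere, activity.
#' @export
trace_long <- function(state) {
  tr <- state$trace
  if (is.null(tr)) stop("state has no trace; simulate with record = TRUE")
  cols <- list(
    c("y_m_bright", "multisensory", "bright"),
    c("y_m_dim", "multisensory", "dim"),
    c("y_i_bright", "inhibitory", "bright"),
    c("y_i_dim", "inhibitory", "dim"),
    c("y_t_max_bright", "tactile_max", "bright"),
    c("y_t_max_dim", "tactile_max", "dim"),
    c("y_v_max_bright", "visual_max", "bright"),
    c("y_v_max_dim", "visual_max", "dim"))
  do.call(rbind, lapply(cols, function(cc) {
    data.frame(time_ms = tr$time_ms, population = cc[2], hemisphere = cc[3],
               activity = tr[[cc[1]]])
  }))
}
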