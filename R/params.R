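#' Network parameters for the two-hemisphere visuo-tactile model
#'
#' Constructs and validates the full set of structural and dynamical constants
#' of the model: grid geometry of the unisensory hand maps, Gaussian receptive
#' field shape, Mexican-hat lateral connectivity, sigmoid shapes and time
#' constants of the three unit classes, inter-area synaptic weights, the
#' callosal transmission delay, the perceptual detection threshold, and the
#' integration settings.
#'
#' The default weight values were obtained by the calibration procedure
#' described in the package vignette: they satisfy the model's qualitative
#' constraints (a single unisensory stimulus substantially excites the
#' multisensory unit; feedback is too weak to create phantom percepts in the
#' other modality; bilateral stimulation can activate both hemispheres
#' simultaneously) and, together with the calibrated stimulus strengths,
#' reproduce the intended baseline 4AFC behavior.
#'
#' @param grid_rows,grid_cols Units per row/column of each unisensory map.
#' @param grid_spacing Distance (cm) between adjacent receptive-field centers.
#' @param rf_amplitude Gain of the Gaussian receptive field (unitary scale).
#' @param rf_sigma Receptive-field Gaussian SD (cm).  The default places the
#'   half-maximum RF diameter at 2.25 cm, the midpoint of the 2-2.5 cm range
#'   typical of fingertip/hand tactile RFs.
#' @param lat_ex_amp,lat_in_amp Amplitudes of the excitatory centre and
#'   inhibitory surround of the lateral difference-of-Gaussians kernel.
#' @param lat_ex_sigma,lat_in_sigma Widths (cm) of centre and surround.
#' @param sigmoid_slope_unisensory,sigmoid_thresh_unisensory Logistic shape of
#'   tactile/visual units.
#' @param sigmoid_slope_multisensory,sigmoid_thresh_multisensory Logistic
#'   shape of the multisensory unit.
#' @param sigmoid_slope_inhibitory,sigmoid_thresh_inhibitory Logistic shape of
#'   the interneurons (steep, for a rapid transition to saturation).
#' @param tau_unisensory,tau_multisensory,tau_inhibitory Time constants (ms).
#' @param callosal_delay Inter-hemispheric transmission delay (ms); must be an
#'   integer multiple of \code{dt}.
#' @param w_ff_tactile,w_ff_visual Per-unit feedforward weights from the
#'   unisensory maps to the multisensory unit (uniform over the map).
#' @param w_fb_tactile,w_fb_visual Per-unit feedback weights from the
#'   multisensory unit back to the unisensory maps.
#' @param w_inter Weight of the excitatory projection from a hemisphere's
#'   multisensory unit to the contralateral interneuron.
#' @param w_inh_tactile,w_inh_visual Non-negative magnitudes of the
#'   interneuron's inhibitory weights onto its hemisphere's unisensory maps
#'   (applied with negative sign).
#' @param detection_threshold Activity level that both the unisensory map peak
#'   and the multisensory unit must exceed for a stimulus to be perceived.
#' @param detection_threshold_multisensory Optional separate threshold for the
#'   multisensory criterion; defaults to \code{detection_threshold}.
#' @param dt Euler integration step (ms).
#' @param t_max Integration horizon (ms).
#' @param steady_tol Maximum per-step activity change defining a steady state.
#'
#' @return A validated list of class \code{"vt_params"}.
#' @seealso [build_synaptic_matrices()], [simulate_trial()], [vt_default_config()]
#' @export
#' @examples
#' p <- vt_params()
#' rf_halfmax_diameter(p)  # 2.25 cm
vt_params <- function(grid_rows = 20L, grid_cols = 20L, grid_spacing = 0.5,
                      rf_amplitude = 1,
                      rf_sigma = 2.25 / (2 * sqrt(2 * log(2))),
                      lat_ex_amp = 0.15, lat_in_amp = 0.05,
                      lat_ex_sigma = 0.45, lat_in_sigma = 1.2,
                      sigmoid_slope_unisensory = 3,
                      sigmoid_thresh_unisensory = 3,
                      sigmoid_slope_multisensory = 4,
                      sigmoid_thresh_multisensory = 1.2,
                      sigmoid_slope_inhibitory = 12,
                      sigmoid_thresh_inhibitory = 0.75,
                      tau_unisensory = 20, tau_multisensory = 20,
                      tau_inhibitory = 10,
                      callosal_delay = 10,
                      w_ff_tactile = 0.2, w_ff_visual = 0.2,
                      w_fb_tactile = 0.1, w_fb_visual = 0.1,
                      w_inter = 1,
                      w_inh_tactile = 0.15, w_inh_visual = 0.15,
                      detection_threshold = 0.5,
                      detection_threshold_multisensory = NULL,
                      dt = 0.5, t_max = 600, steady_tol = 1e-5) {
  p <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
            grid_spacing = grid_spacing, rf_amplitude = rf_amplitude,
            rf_sigma = rf_sigma,
            lat_ex_amp = lat_ex_amp, lat_in_amp = lat_in_amp,
            lat_ex_sigma = lat_ex_sigma, lat_in_sigma = lat_in_sigma,
            sigmoid_slope_unisensory = sigmoid_slope_unisensory,
            sigmoid_thresh_unisensory = sigmoid_thresh_unisensory,
            sigmoid_slope_multisensory = sigmoid_slope_multisensory,
            sigmoid_thresh_multisensory = sigmoid_thresh_multisensory,
            sigmoid_slope_inhibitory = sigmoid_slope_inhibitory,
            sigmoid_thresh_inhibitory = sigmoid_thresh_inhibitory,
            tau_unisensory = tau_unisensory, tau_multisensory = tau_multisensory,
            tau_inhibitory = tau_inhibitory,
            callosal_delay = callosal_delay,
            w_ff_tactile = w_ff_tactile, w_ff_visual = w_ff_visual,
            w_fb_tactile = w_fb_tactile, w_fb_visual = w_fb_visual,
            w_inter = w_inter,
            w_inh_tactile = w_inh_tactile, w_inh_visual = w_inh_visual,
            detection_threshold = detection_threshold,
            detection_threshold_multisensory =
              if (is.null(detection_threshold_multisensory)) detection_threshold
              else detection_threshold_multisensory,
            dt = dt, t_max = t_max, steady_tol = steady_tol)
  class(p) <- "vt_params"
  validate_vt_params(p)
  p
}

#' Validate a vt_params object
#'
#' Checks the structural invariants of the parameter set: positivity of time
#' constants, widths and integration settings; the centre-surround shape of
#' the lateral kernel (narrow strong excitation, broad weaker inhibition);
#' the receptive-field half-maximum diameter lying in the 2-2.5 cm range;
#' non-negative synaptic magnitudes; the Euler step small relative to the
#' fastest time constant; and the callosal delay being an integer multiple of
#' the step.
#'
#' @param p A \code{"vt_params"} list.
#' @return \code{p}, invisibly; signals a configuration error otherwise.
#' @export
validate_vt_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid vt_params: ", msg,
                                                 call. = FALSE)
  chk(p$grid_rows >= 1 && p$grid_cols >= 1, "grid must have >= 1 unit per side")
  pos <- c("grid_spacing", "rf_sigma", "lat_ex_sigma", "lat_in_sigma",
           "tau_unisensory", "tau_multisensory", "tau_inhibitory",
           "dt", "t_max", "steady_tol")
  for (f in pos) chk(p[[f]] > 0, paste(f, "must be strictly positive"))
  chk(p$dt < min(p$tau_unisensory, p$tau_multisensory, p$tau_inhibitory) / 2,
      "dt must be smaller than half the fastest time constant")
  chk(p$lat_ex_sigma < p$lat_in_sigma,
      "lateral excitation must be narrower than lateral inhibition")
  chk(p$lat_ex_amp > p$lat_in_amp,
      "lateral excitatory amplitude must exceed the inhibitory amplitude")
  d <- rf_halfmax_diameter(p)
  chk(d >= 2 && d <= 2.5,
      sprintf("RF half-maximum diameter %.3f cm outside [2, 2.5] cm", d))
  nn <- c("w_ff_tactile", "w_ff_visual", "w_fb_tactile", "w_fb_visual",
          "w_inter", "w_inh_tactile", "w_inh_visual")
  for (f in nn) chk(p[[f]] >= 0, paste(f, "must be non-negative"))
  chk(p$callosal_delay >= 0, "callosal_delay must be non-negative")
  ratio <- p$callosal_delay / p$dt
  chk(abs(ratio - round(ratio)) < 1e-9,
      "callosal_delay must be an integer multiple of dt")
  invisible(p)
}

#' Half-maximum receptive-field diameter
#'
#' Operational RF diameter: twice the radius at which the Gaussian receptive
#' field falls to half its maximum, i.e. \eqn{2 \sigma \sqrt{2 \ln 2}}.
#'
#' @param p A \code{"vt_params"} list.
#' @return Diameter in cm.
#' @export
rf_halfmax_diameter <- function(p) 2 * p$rf_sigma * sqrt(2 * log(2))

#' Receptive-field centre positions of the grid units
#'
#' Hand-centred Cartesian coordinates (cm) with the origin at the hand centre:
#' unit (row, col) maps to ((row - (R-1)/2) * spacing, (col - (C-1)/2) *
#' spacing).  Units are ordered column-major (R matrix order).
#'
#' @param p A \code{"vt_params"} list.
#' @return A (rows*cols) x 2 matrix of (x, y) positions.
#' @export
unit_positions <- function(p) {
  rows <- seq_len(p$grid_rows) - 1
  cols <- seq_len(p$grid_cols) - 1
  x <- (rows - (p$grid_rows - 1) / 2) * p$grid_spacing
  y <- (cols - (p$grid_cols - 1) / 2) * p$grid_spacing
  cbind(x = rep(x, times = p$grid_cols),
        y = rep(y, each = p$grid_rows))
}

#' @export
print.vt_params <- function(x, ...) {
  cat("Two-hemisphere visuo-tactile network parameters\n")
  cat(sprintf("  unisensory maps : %d x %d units, %.2f cm spacing\n",
              x$grid_rows, x$grid_cols, x$grid_spacing))
  cat(sprintf("  RF              : sigma %.3f cm (half-max diameter %.2f cm)\n",
              x$rf_sigma, rf_halfmax_diameter(x)))
  cat(sprintf("  lateral DoG     : +%.3f (sd %.2f) / -%.3f (sd %.2f)\n",
              x$lat_ex_amp, x$lat_ex_sigma, x$lat_in_amp, x$lat_in_sigma))
  cat(sprintf("  weights         : Wm(t) %.3f Wm(v) %.3f  W(t) %.3f W(v) %.3f\n",
              x$w_ff_tactile, x$w_ff_visual, x$w_fb_tactile, x$w_fb_visual))
  cat(sprintf("                    Wi %.3f  I(t) %.3f I(v) %.3f\n",
              x$w_inter, x$w_inh_tactile, x$w_inh_visual))
  cat(sprintf("  delay %g ms, dt %g ms, t_max %g ms, detection threshold %.2f\n",
              x$callosal_delay, x$dt, x$t_max, x$detection_threshold))
  invisible(x)
}
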