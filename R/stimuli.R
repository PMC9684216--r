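#' Task conditions of the 4AFC detection experiment
#'
#' The factorial condition set: tactile stimulation of the bright-associated
#' hand (\code{"B"}), the dim-associated hand (\code{"D"}), both hands
#' (\code{"BD"}) or neither (\code{"N"}), crossed with visual cue conditions
#' \code{"none"}, \code{"both"}, \code{"brightLED"}, \code{"dimLED"}.  The
#' baseline block uses only the four tactile conditions with no visual cue;
#' the visuo-tactile (VT) block uses all 16 combinations.
#'
#' @param block \code{"baseline"} (4 conditions) or \code{"VT"} (16).
#' @return A data frame with columns \code{tactile} and \code{visual}.
#' @export
#' @examples
#' trial_conditions("baseline")
#' nrow(trial_conditions("VT"))  # 16
trial_conditions <- function(block = c("baseline", "VT")) {
  block <- match.arg(block)
  tactile <- c("B", "D", "BD", "N")
  visual <- if (block == "baseline") "none" else
    c("none", "both", "brightLED", "dimLED")
  out <- expand.grid(tactile = tactile, visual = visual,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(match(out$visual, c("none", "both", "brightLED", "dimLED")),
            match(out$tactile, tactile)), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

tactile_levels <- c("B", "D", "BD", "N")
visual_levels <- c("none", "both", "brightLED", "dimLED")

#' External drives for one trial
#'
#' Renders a trial condition into external drive vectors for both hemispheres.
#' Each active stimulus is delivered at the hand/grid centre through the
#' Gaussian receptive fields, with an effective strength
#' \code{nominal * max(0, 1 + e)}, where \code{e} is a zero-mean Gaussian
#' multiplicative noise term (one independent draw per active stimulus per
#' trial) with the given variance; the clip at zero forbids negative
#' intensities.  Inactive modalities and hands receive exactly zero drive, so
#' catch trials are unaffected by the noise.  The dim visual strength is the
#' bright strength divided by 2.5 (the fixed perceived-intensity ratio).
#'
#' Noise draws are taken from the current R random number stream; seed the
#' stream (or supply \code{noise_variance = 0}) for reproducibility.
#'
#' @param cond A one-row data frame or list with \code{tactile} in
#'   \{"B","D","BD","N"\} and \code{visual} in
#'   \{"none","both","brightLED","dimLED"\}.
#' @param tactile_strength Nominal tactile stimulus strength (>= 0).
#' @param visual_bright_strength Nominal strength of the bright visual cue
#'   (>= 0); the dim cue is this divided by 2.5.
#' @param noise_variance Variance of the multiplicative Gaussian noise term
#'   (default 0.2).
#' @param params A \code{"vt_params"} list.
#' @return A drive list (\code{t_bright}, \code{v_bright}, \code{t_dim},
#'   \code{v_dim}) for [simulate_trial()], with the effective strengths
#'   attached as attribute \code{"effective_strengths"}.
#' @export
make_trial_drives <- function(cond, tactile_strength, visual_bright_strength = 0,
                              noise_variance = 0.2, params) {
  if (tactile_strength < 0 || visual_bright_strength < 0)
    stop("nominal stimulus strengths must be non-negative")
  if (noise_variance < 0) stop("noise variance must be non-negative")
  tc <- as.character(cond$tactile)
  vc <- as.character(cond$visual)
  if (!tc %in% tactile_levels) stop("unknown tactile condition: ", tc)
  if (!vc %in% visual_levels) stop("unknown visual condition: ", vc)
  pos <- unit_positions(params)
  centre <- c(0, 0)
  dr <- zero_drives(nrow(pos))
  eff <- c(t_bright = 0, t_dim = 0, v_bright = 0, v_dim = 0)
  mult <- function() max(0, 1 + stats::rnorm(1, 0, sqrt(noise_variance)))
  visual_dim_strength <- visual_bright_strength / 2.5
  if (tc %in% c("B", "BD")) {
    eff[["t_bright"]] <- tactile_strength * mult()
    dr$t_bright <- rf_input(centre, eff[["t_bright"]], pos, params)
  }
  if (tc %in% c("D", "BD")) {
    eff[["t_dim"]] <- tactile_strength * mult()
    dr$t_dim <- rf_input(centre, eff[["t_dim"]], pos, params)
  }
  if (vc %in% c("brightLED", "both")) {
    eff[["v_bright"]] <- visual_bright_strength * mult()
    dr$v_bright <- rf_input(centre, eff[["v_bright"]], pos, params)
  }
  if (vc %in% c("dimLED", "both")) {
    eff[["v_dim"]] <- visual_dim_strength * mult()
    dr$v_dim <- rf_input(centre, eff[["v_dim"]], pos, params)
  }
  attr(dr, "effective_strengths") <- eff
  dr
}
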