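#' Tactile Awareness Degree of one hand
#'
#' Perceptual readout of one hemisphere's steady state.  A tactile stimulus on
#' a hand is perceived only if the tactile map and the multisensory unit of
#' the corresponding hemisphere are concurrently active above the detection
#' threshold; in that case the Tactile Awareness Degree (TAD) equals the
#' multisensory unit's activity, otherwise it is zero.  The tactile-map
#' criterion uses the maximum activity over the map (punctate stimulation
#' activates a compact bump).
#'
#' @param hemi One hemisphere of a \code{"vt_state"} (e.g. \code{state$bright}).
#' @param threshold Detection threshold for the tactile-map criterion.
#' @param threshold_multi Detection threshold for the multisensory criterion
#'   (defaults to \code{threshold}; the model normally shares one).
#' @return A non-negative scalar TAD.
#' @export
#' @examples
#' p <- vt_params()
#' m <- build_synaptic_matrices(p)
#' st <- simulate_trial(make_trial_drives(list(tactile = "N", visual = "none"),
#'                                        0, 0, 0, p), m, p)
#' compute_tad(st$bright, p$detection_threshold)  # 0: silent network
compute_tad <- function(hemi, threshold, threshold_multi = threshold) {
  if (max(hemi$y_t) > threshold && hemi$y_m > threshold_multi) hemi$y_m else 0
}

#' Classify the 4AFC response from the two TADs
#'
#' Maps the per-hand perception variables onto the four-alternative report:
#' touch on the bright-associated hand only, the dim-associated hand only,
#' both hands, or none.  The response depends only on which TADs are
#' positive, so it is invariant to any strictly positive rescaling of both.
#'
#' @param tad_bright,tad_dim Non-negative TADs of the same trial.
#' @return One of \code{"bright_only"}, \code{"dim_only"}, \code{"both"},
#'   \code{"none"}.
#' @export
classify_response <- function(tad_bright, tad_dim) {
  if (tad_bright < 0 || tad_dim < 0)
    stop("internal error: negative TAD")
  if (tad_bright > 0 && tad_dim > 0) "both"
  else if (tad_bright > 0) "bright_only"
  else if (tad_dim > 0) "dim_only"
  else "none"
}

response_levels <- c("bright_only", "dim_only", "both", "none")

# correct response for a tactile condition (visual cues are task-irrelevant)
correct_response <- function(tactile) {
  c(B = "bright_only", D = "dim_only", BD = "both", N = "none")[[tactile]]
}
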