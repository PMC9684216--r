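#' Plasticity hypothesis presets
#'
#' The candidate effects of protracted visuo-tactile exposure are encoded as
#' static multiplicative weight configurations applied to the basal network
#' (hypothesis testing by manually set parameters, not online learning):
#'
#' \describe{
#'   \item{baseline}{identity: all multipliers 1, deltas 0.}
#'   \item{H1A_ff_strengthen}{asymmetric strengthening of each hemisphere's
#'     feedforward synapses onto its multisensory unit: both modalities scaled
#'     by \code{ff_scale_bright} in the bright-hand hemisphere (default 1.8,
#'     i.e. +80\%; sweep range +50-80\%) and by \code{ff_scale_dim} in the
#'     dim-hand hemisphere (default 1.1, i.e. +10\%; range +10-30\%).}
#'   \item{H1B_reorganize}{constant-sum reorganization in both hemispheres:
#'     visual feedforward weights scaled by \code{1 + reorg_visual_delta}
#'     and tactile by \code{1 - reorg_visual_delta} (default delta 0.2), so
#'     the summed feedforward efficacy onto each multisensory unit is exactly
#'     conserved when the basal tactile and visual weights are equal.}
#'   \item{H2_interhemispheric}{asymmetric strengthening of the directed
#'     inter-hemispheric competition pathways: the bright-to-dim pathway (the
#'     bright hemisphere's callosal projection \emph{and} the inhibitory
#'     weights onto the dim hemisphere's unisensory maps) scaled by
#'     \code{inter_scale_bright_to_dim} (default 1.5); the reverse pathway by
#'     \code{inter_scale_dim_to_bright} (default 1.1).}
#'   \item{H3_combined}{composition of H1B followed by H2.}
#' }
#'
#' @param name Preset name (see above).
#' @param ff_scale_bright,ff_scale_dim H1A multipliers.
#' @param reorg_visual_delta H1B fractional shift (visual up, tactile down).
#' @param inter_scale_bright_to_dim,inter_scale_dim_to_bright H2 multipliers
#'   on the two directed inter-hemispheric pathways.
#' @return A list of class \code{"vt_preset"}.
#' @seealso [apply_preset()]
#' @export
plasticity_preset <- function(name = c("baseline", "H1A_ff_strengthen",
                                       "H1B_reorganize", "H2_interhemispheric",
                                       "H3_combined"),
                              ff_scale_bright = 1.8, ff_scale_dim = 1.1,
                              reorg_visual_delta = 0.2,
                              inter_scale_bright_to_dim = 1.5,
                              inter_scale_dim_to_bright = 1.1) {
  name <- match.arg(name)
  if (reorg_visual_delta < 0 || reorg_visual_delta > 1)
    stop("reorg_visual_delta must lie in [0, 1]")
  if (min(ff_scale_bright, ff_scale_dim, inter_scale_bright_to_dim,
          inter_scale_dim_to_bright) < 0)
    stop("preset multipliers must be non-negative")
  structure(list(name = name,
                 ff_scale_bright = ff_scale_bright,
                 ff_scale_dim = ff_scale_dim,
                 reorg_visual_delta = reorg_visual_delta,
                 inter_scale_bright_to_dim = inter_scale_bright_to_dim,
                 inter_scale_dim_to_bright = inter_scale_dim_to_bright),
            class = "vt_preset")
}

#' @export
print.vt_preset <- function(x, ...) {
  cat("vt_preset:", x$name, "\n")
  if (x$name == "H1A_ff_strengthen")
    cat(sprintf("  ff scale bright %.2f, dim %.2f\n",
                x$ff_scale_bright, x$ff_scale_dim))
  if (x$name %in% c("H1B_reorganize", "H3_combined"))
    cat(sprintf("  reorg: visual x%.2f, tactile x%.2f (sum conserved)\n",
                1 + x$reorg_visual_delta, 1 - x$reorg_visual_delta))
  if (x$name %in% c("H2_interhemispheric", "H3_combined"))
    cat(sprintf("  inter-hemispheric scale bright->dim %.2f, dim->bright %.2f\n",
                x$inter_scale_bright_to_dim, x$inter_scale_dim_to_bright))
  invisible(x)
}

#' Apply a plasticity preset to basal synaptic matrices
#'
#' Pure function: returns a modified copy of the matrices, leaving every
#' untargeted connection untouched.  The \code{baseline} preset is the
#' identity.  See [plasticity_preset()] for what each preset scales.
#'
#' @param matrices A basal \code{"vt_matrices"} object.
#' @param preset A \code{"vt_preset"} or a preset name.
#' @return A modified \code{"vt_matrices"} object.
#' @export
#' @examples
#' m <- build_synaptic_matrices(vt_params())
#' m2 <- apply_preset(m, "H1B_reorganize")
#' # summed feedforward efficacy conserved:
#' sum(m2$bright$ff_t + m2$bright$ff_v) == sum(m$bright$ff_t + m$bright$ff_v)
apply_preset <- function(matrices, preset) {
  if (is.character(preset)) preset <- plasticity_preset(preset)
  stopifnot(inherits(preset, "vt_preset"), inherits(matrices, "vt_matrices"))
  m <- matrices
  if (preset$name == "baseline") return(m)
  if (preset$name == "H1A_ff_strengthen") {
    m$bright$ff_t <- m$bright$ff_t * preset$ff_scale_bright
    m$bright$ff_v <- m$bright$ff_v * preset$ff_scale_bright
    m$dim$ff_t <- m$dim$ff_t * preset$ff_scale_dim
    m$dim$ff_v <- m$dim$ff_v * preset$ff_scale_dim
    return(m)
  }
  if (preset$name %in% c("H1B_reorganize", "H3_combined")) {
    up <- 1 + preset$reorg_visual_delta
    dn <- 1 - preset$reorg_visual_delta
    for (h in c("bright", "dim")) {
      m[[h]]$ff_v <- m[[h]]$ff_v * up
      m[[h]]$ff_t <- m[[h]]$ff_t * dn
    }
  }
  if (preset$name %in% c("H2_interhemispheric", "H3_combined")) {
    sbd <- preset$inter_scale_bright_to_dim
    sdb <- preset$inter_scale_dim_to_bright
    # bright -> dim pathway: bright's callosal projection + inhibition in dim
    m$bright$w_inter <- m$bright$w_inter * sbd
    m$dim$inh_t <- m$dim$inh_t * sbd
    m$dim$inh_v <- m$dim$inh_v * sbd
    # dim -> bright pathway
    m$dim$w_inter <- m$dim$w_inter * sdb
    m$bright$inh_t <- m$bright$inh_t * sdb
    m$bright$inh_v <- m$bright$inh_v * sdb
  }
  m
}
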