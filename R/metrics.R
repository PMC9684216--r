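#' Baseline-corrected response rate for one hand
#'
#' Sum of the three response rates attributed to a hand under one visual
#' condition of the VT block, minus the same sum in the baseline block:
#' the hit rate when that hand alone was touched, the proportion of bimanual
#' tactile trials answered as that hand only, and the false-alarm rate on
#' no-touch trials, i.e. for the bright-associated hand
#' \deqn{Bcorr_C = (B1hand_C + B2hand_C + Bnone_C) -
#'       (B1hand_{BL} + B2hand_{BL} + Bnone_{BL}).}
#'
#' @param vt_table VT-block \code{"vt_response_table"}.
#' @param baseline_table Baseline-block table (visual condition "none").
#' @param hand \code{"bright"} or \code{"dim"}.
#' @param visual_condition One of \code{"none"}, \code{"both"},
#'   \code{"brightLED"}, \code{"dimLED"}.
#' @return The corrected rate (dimensionless, in [-3, 3]).
#' @export
corrected_rate <- function(vt_table, baseline_table,
                           hand = c("bright", "dim"),
                           visual_condition = visual_levels) {
  hand <- match.arg(hand)
  visual_condition <- match.arg(visual_condition)
  resp <- paste0("p_", hand, "_only")
  uni <- if (hand == "bright") "B" else "D"
  rate_sum <- function(tab, vc) {
    table_prop(tab, uni, vc, resp) +
      table_prop(tab, "BD", vc, resp) +
      table_prop(tab, "N", vc, resp)
  }
  rate_sum(vt_table, visual_condition) - rate_sum(baseline_table, "none")
}

#' Lateralization Bias Index per visual condition
#'
#' For each visual condition C of the VT block, the difference between the
#' baseline-corrected response rates of the bright- and dim-associated hands,
#' \eqn{LBI_C = Bcorr_C - Dcorr_C}.  Positive values indicate responses
#' shifted toward the hand associated with the bright visual cue; relabeling
#' the hands flips the sign of every LBI.
#'
#' @param vt_table VT-block \code{"vt_response_table"} (16 conditions).
#' @param baseline_table Baseline-block table (4 conditions, visual "none").
#' @return A data frame of class \code{"vt_bias_summary"} with one row per
#'   visual condition and columns visual, Bcorr, Dcorr, LBI.
#' @export
compute_lbi <- function(vt_table, baseline_table) {
  vcs <- intersect(visual_levels, unique(vt_table$visual))
  out <- do.call(rbind, lapply(vcs, function(vc) {
    b <- corrected_rate(vt_table, baseline_table, "bright", vc)
    d <- corrected_rate(vt_table, baseline_table, "dim", vc)
    data.frame(visual = vc, Bcorr = b, Dcorr = d, LBI = b - d)
  }))
  rownames(out) <- NULL
  class(out) <- c("vt_bias_summary", "data.frame")
  out
}

#' Mean squared error between two response tables
#'
#' Model-versus-reference fit statistic: the mean, over every condition x
#' response cell shared by the two tables, of the squared difference between
#' the response proportions, reported on the percent scale (multiplied by
#' 100).  Symmetric, non-negative, and zero iff the tables agree.
#'
#' @param model_table,reference_table Two response tables covering identical
#'   condition sets (any \code{"vt_response_table"}-schema data frames).
#' @param scale Multiplier applied to the mean squared proportion difference
#'   (default 100, the percent convention).
#' @return A scalar MSE.
#' @export
compute_mse <- function(model_table, reference_table, scale = 100) {
  key <- function(t) paste(t$tactile, t$visual)
  if (nrow(model_table) != nrow(reference_table) ||
      !setequal(key(model_table), key(reference_table)))
    stop("tables cover different condition sets")
  ref <- reference_table[match(key(model_table), key(reference_table)), ,
                         drop = FALSE]
  diffs <- as.matrix(model_table[, prop_cols]) - as.matrix(ref[, prop_cols])
  scale * mean(diffs^2)
}

#' Read a behavioral reference table from CSV
#'
#' Loads a user-transcribed table of human response proportions with the
#' package's response-table schema: columns \code{tactile} (B, D, BD, N),
#' \code{visual} (none, both, brightLED, dimLED), \code{p_bright_only},
#' \code{p_dim_only}, \code{p_both}, \code{p_none}.  Proportions must lie in
#' [0, 1] and each row must sum to 1 (tolerance 1e-6).  The package ships no
#' transcribed table: published group-level matrices are figure-only data,
#' so transcription is left to the user.
#'
#' @param path CSV file path.
#' @return A validated data frame with the response-table schema.
#' @export
read_reference_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tactile", "visual", prop_cols)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("reference table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tab$tactile %in% tactile_levels) ||
      !all(tab$visual %in% visual_levels))
    stop("reference table contains unknown condition codes")
  pm <- as.matrix(tab[, prop_cols])
  if (any(pm < 0 | pm > 1)) stop("reference proportions must lie in [0, 1]")
  if (any(abs(rowSums(pm) - 1) > 1e-6))
    stop("each reference row's four proportions must sum to 1")
  tab
}
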