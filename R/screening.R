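#' Per-round classification probabilities
#'
#' Probability that one screening round detects an existing cancer, and that
#' it raises a false alarm in a cancer-free woman. Detection is the modality
#' sensitivity; for AB-MRI every positive is referred to a full-protocol MRM,
#' so detection is additionally multiplied by the confirmation sensitivity
#' (1.0 by default). A false positive that the full MRM later resolves still
#' counts as a false-positive episode -- the confirmation cascade affects its
#' work-up cost, not its probability.
#'
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param params `screen_params`.
#' @return Named numeric vector `c(p_detect_given_cancer, p_fp_given_healthy)`.
#' @examples
#' classification_probabilities("DBT", default_parameters())
#' @export
classification_probabilities <- function(strategy, params) {
  strategy <- match_strategy(strategy)
  se <- params$sens[[strategy]]
  if (strategy == "AB_MRI") se <- se * params$sens_full_mrm_confirmation
  c(p_detect_given_cancer = se,
    p_fp_given_healthy = 1 - params$spec[[strategy]])
}

#' Expected diagnostic work-up cost of a positive screen
#'
#' Cost incurred per positive finding, excluding the screening examination
#' itself (charged separately every attended round). A positive DBT goes
#' straight to biopsy. A positive AB-MRI is worked up with a full-protocol
#' MRM; a biopsy follows only when the MRM confirms the finding -- always for
#' a true cancer (confirmation sensitivity 1 by default), and with
#' probability `1 - spec_full_mrm` for a false positive.
#'
#' @param strategy `"DBT"` or `"AB_MRI"`.
#' @param truth `"cancer"` or `"healthy"`.
#' @param params `screen_params`.
#' @return Expected work-up cost in US-$.
#' @examples
#' expected_workup_cost("AB_MRI", "healthy", default_parameters()) # 406.16
#' @export
expected_workup_cost <- function(strategy, truth = c("cancer", "healthy"), params) {
  strategy <- match_strategy(strategy)
  truth <- match.arg(truth)
  if (strategy == "DBT") return(params$cost_biopsy)
  p_biopsy <- if (truth == "cancer") params$sens_full_mrm_confirmation
              else 1 - params$spec_full_mrm
  params$cost_full_mrm + p_biopsy * params$cost_biopsy
}

#' Is a cycle a screening round?
#'
#' Screens fall on cycles `0, interval, 2*interval, ...`; cycle 0 is the
#' prevalence round applied to the initial diseased fraction.
#'
#' @param cycle_index Cycle number, `>= 0`.
#' @param interval_cycles Screening interval in cycles, `>= 1`.
#' @return Logical.
#' @export
is_screening_cycle <- function(cycle_index, interval_cycles) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  if (any(interval_cycles < 1)) stop("interval_cycles must be >= 1")
  cycle_index %% interval_cycles == 0
}

match_strategy <- function(strategy) {
  if (length(strategy) != 1L || !strategy %in% strategies())
    stop("unknown strategy '", paste(strategy, collapse = ","),
         "'; must be one of ", paste(strategies(), collapse = ", "))
  strategy
}
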