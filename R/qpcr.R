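#' Relative expression by the 2^-ddCt method
#'
#' Technical-replicate Ct vectors are averaged arithmetically, the target is
#' normalized to the housekeeping gene within each condition
#' (`dCt = Ct_target - Ct_housekeeping`) and the sample condition to the
#' control: fold change = `2^-(dCt_sample - dCt_control)`.
#'
#' @param ct_target,ct_housekeeping Ct values (replicate vectors allowed)
#'   for the sample condition.
#' @param ct_target_control,ct_housekeeping_control Ct values for the
#'   experimental control condition.
#' @return Fold change relative to the control.
#' @export
ddct_fold_change <- function(ct_target, ct_housekeeping,
                             ct_target_control, ct_housekeeping_control) {
  cts <- list(ct_target, ct_housekeeping, ct_target_control,
              ct_housekeeping_control)
  if (any(vapply(cts, function(x) any(!is.finite(x)) || any(x <= 0), logical(1)))) {
    stopf("all Ct values must be positive and finite")
  }
  d_sample <- mean(ct_target) - mean(ct_housekeeping)
  d_control <- mean(ct_target_control) - mean(ct_housekeeping_control)
  2^-(d_sample - d_control)
}

#' ChIP-qPCR percent input
#'
#' The input Ct is first adjusted for the fraction of chromatin it
#' represents (`Ct_input - log2(1 / input_fraction)`), then the
#' immunoprecipitated signal is expressed as a percentage of that
#' dilution-adjusted input: `100 * 2^(adjusted_input - Ct_IP)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample (replicates averaged).
#' @param ct_input Ct of the input aliquot.
#' @param input_fraction Fraction of chromatin used as input (0 < f <= 1).
#' @return Percent input.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stopf("input_fraction must be in (0, 1]")
  }
  adjusted <- mean(ct_input) - log2(1 / input_fraction)
  100 * 2^(adjusted - mean(ct_ip))
}
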