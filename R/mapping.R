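#' Biophysical interpretation of the model parameters
#'
#' The dimensionless model maps onto biophysical voltages once a spike
#' threshold is assumed: with threshold `V_thresh`, the resting potential is
#' `V_thresh - (l1 + l2 + w^2)/2` (the threshold sits half the total
#' self-decrement above rest), the post-spike reset is
#' `V_thresh - l2 - w^2`, and the postsynaptic-potential amplitude is `w^2`.
#' With the standard operating point (threshold -55 mV, no L1 cost, L2 cost
#' 8.5 mV, weight 1.2) this gives a rest of about -60 mV, a reset of about
#' -65 mV and PSPs of about 1.4 mV.
#'
#' @param spike_threshold_mv Assumed biophysical spike threshold (mV).
#' @param l1_cost,l2_cost Spike costs (mV scale).
#' @param weight Readout weight (mV^1/2 scale).
#' @return Tibble with columns `rest_mv`, `reset_mv`, `psp_mv`.
#' @examples
#' biophysical_mapping()
#' @export
biophysical_mapping <- function(spike_threshold_mv = -55, l1_cost = 0,
                                l2_cost = 8.5, weight = 1.2) {
  tibble(
    rest_mv = spike_threshold_mv - 0.5 * (l1_cost + l2_cost + weight^2),
    reset_mv = spike_threshold_mv - l2_cost - weight^2,
    psp_mv = weight^2
  )
}
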