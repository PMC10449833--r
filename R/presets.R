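#' Default evoked-input lattice for the four-population microcircuit
#'
#' Axis vectors spanning the region of evoked modulations where the model's
#' populations respond gradedly under the default baseline drive: the
#' excitatory axis starts above the excitatory firing onset, the PV axis
#' covers suppression through strong recruitment, and the SST axis reaches
#' the drive levels at which SST cells overcome PV inhibition. A 5 x 5 x 5
#' lattice keeps a full sweep tractable on one CPU; pass denser axes to
#' [sweep_tf()] for production maps.
#'
#' @return A named list with numeric vectors `ax_E`, `ax_P`, `ax_S` (Hz).
#' @export
epsv_grid_axes <- function() {
  list(ax_E = c(16, 22, 28, 34, 40),
       ax_P = c(-30, -15, 0, 15, 30),
       ax_S = c(0, 15, 30, 45, 60))
}

#' Stored operating-regime presets of the default microcircuit
#'
#' Mean-input operating points for the PV-dominated, SST-dominated and mixed
#' inhibitory regimes of the default network, located once by
#' [find_regime_presets()] on a transfer-function grid measured over
#' [epsv_grid_axes()] (default network seed 1, two repetitions per node,
#' excitatory-rate match tolerance 0.35). Stored so that downstream
#' analyses do not need to re-run the multi-minute grid sweep; re-derive
#' with [sweep_tf()] + [find_regime_presets()] after changing the network.
#'
#' @return A tibble with columns `regime`, `dlambda_E`, `dlambda_P`,
#'   `dlambda_S`.
#' @export
epsv_presets <- function() {
  tibble::tribble(
    ~regime,         ~dlambda_E, ~dlambda_P, ~dlambda_S,
    "PV-dominated",          40,          0,         30,
    "SST-dominated",         40,        -30,         60,
    "mixed",                 28,        -15,         60)
}
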