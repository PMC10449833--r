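#' Neuron parameter table for the cortical microcircuit populations
#'
#' Returns the per-population constants of the adaptive exponential
#' integrate-and-fire (AdEx) neuron with conductance-based exponential
#' synapses, one row per population. The default table covers the four
#' populations of the EPSV microcircuit: excitatory pyramidal cells (`PC`)
#' and the parvalbumin- (`PV`), somatostatin- (`SST`) and VIP-expressing
#' (`VIP`) interneuron classes. PV cells carry no adaptation and no
#' exponential spike-initiation term (`a`, `b`, `Delta_T`, `tau_w` are `NA`),
#' i.e. they are plain leaky integrate-and-fire neurons with a hard
#' threshold.
#'
#' Columns and units: `C_m` membrane capacitance (pF); `E_L` leak reversal
#' (mV); `g_L` leak conductance (nS); `V_th` spike-initiation threshold
#' (mV); `V_r` reset potential (mV); `Delta_T` slope factor (mV); `a`
#' subthreshold adaptation (nS); `b` spike-triggered adaptation (pA);
#' `tau_w` adaptation time constant (ms); `t_r` refractory period (ms);
#' `E_e`, `E_i` excitatory/inhibitory reversal potentials (mV); `tau_e`,
#' `tau_i` synaptic decay constants (ms); `I_e` constant injected current
#' (pA).
#'
#' @param populations Character vector of population names to include.
#' @param C_m Membrane capacitance in pF, shared by all populations.
#' @return A tibble with one row per population, class `neuron_params`.
#' @examples
#' neuron_params()
#' neuron_params("PC")
#' @export
neuron_params <- function(populations = c("PC", "PV", "SST", "VIP"),
                          C_m = 200) {
  tab <- tibble::tribble(
    ~pop,  ~V_r,  ~E_L, ~g_L, ~V_th,   ~a,  ~b, ~Delta_T, ~tau_w, ~tau_e, ~tau_i,
    "PC", -66.4, -70.0, 20.3, -41.5,  2.0, 4.0,      2.0,  120.0,   0.20,   25.0,
    "PV", -67.4, -70.0, 77.1, -41.6,   NA,  NA,       NA,     NA,   0.20,    5.5,
    "SST", -59.9, -70.0, 21.4, -41.8, 2.0, 4.0,      2.0,  120.0,   0.20,   99.1,
    "VIP", -65.7, -70.0, 26.6, -43.7, -1.0, 19.0,    2.0,  120.0,   0.28,   12.2
  )
  miss <- setdiff(populations, tab$pop)
  if (length(miss) > 0) {
    rlang::abort(paste0("unknown population(s): ", paste(miss, collapse = ", ")),
                 class = "spikevar_bad_population")
  }
  out <- tab[match(populations, tab$pop), ]
  out$C_m <- C_m
  out$t_r <- 2.0
  out$E_e <- 0.0
  out$E_i <- -85.0
  out$I_e <- 0.0
  out <- validate_neuron_params(out)
  class(out) <- c("neuron_params", class(out))
  out
}

#' Validate a neuron parameter table
#'
#' Checks positivity of `C_m`, `g_L`, `tau_e`, `tau_i`, that `V_r < V_th`,
#' and that the adaptation block (`a`, `b`, `Delta_T`, `tau_w`) is either
#' fully present or fully absent per population.
#'
#' @param params A tibble as returned by [neuron_params()].
#' @return The validated tibble, invisibly modified only by validation.
#' @export
validate_neuron_params <- function(params) {
  stopifnot(is.data.frame(params))
  need <- c("pop", "C_m", "E_L", "g_L", "V_th", "V_r", "Delta_T", "a", "b",
            "tau_w", "t_r", "E_e", "E_i", "tau_e", "tau_i", "I_e")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing parameter column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "spikevar_bad_params")
  }
  bad <- function(msg) rlang::abort(msg, class = "spikevar_bad_params")
  if (any(params$C_m <= 0)) bad("C_m must be positive")
  if (any(params$g_L <= 0)) bad("g_L must be positive")
  if (any(params$tau_e <= 0) || any(params$tau_i <= 0)) {
    bad("synaptic time constants must be positive")
  }
  if (any(params$V_r >= params$V_th)) bad("V_r must be below V_th")
  adapt <- cbind(params$a, params$b, params$Delta_T, params$tau_w)
  n_na <- rowSums(is.na(adapt))
  if (any(!n_na %in% c(0L, 4L))) {
    bad("adaptation parameters (a, b, Delta_T, tau_w) must be all present or all absent")
  }
  params
}

#' Does a population carry adaptation / an exponential spike-initiation term?
#' @param params_row One row of a [neuron_params()] table.
#' @return Logical scalar.
#' @keywords internal
has_adaptation <- function(params_row) {
  !is.na(params_row$Delta_T)
}

#' Numerical spike-detection ceiling for a population
#'
#' AdEx populations (with a slope factor) detect a spike when the membrane
#' potential reaches `V_th + 5 * Delta_T`, the conventional surrogate for the
#' divergence of the exponential upswing; hard-threshold populations detect
#' at `V_th` itself.
#'
#' @param params_row One row of a [neuron_params()] table.
#' @return Detection ceiling in mV.
#' @export
detection_ceiling <- function(params_row) {
  if (has_adaptation(params_row)) {
    params_row$V_th + 5 * params_row$Delta_T
  } else {
    params_row$V_th
  }
}

#' Subthreshold membrane and adaptation derivatives
#'
#' Evaluates the AdEx right-hand side
#' \deqn{C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_{th})/\Delta_T}
#'       - g_e (V - E_e) - g_i (V - E_i) - w + I_e}
#' \deqn{\tau_w \dot w = a (V - E_L) - w}
#' For populations without adaptation (PV) the exponential term and the
#' `w` dynamics are omitted entirely.
#'
#' @param V Membrane potential (mV). Vectorised.
#' @param w Adaptation current (pA).
#' @param g_e,g_i Excitatory / inhibitory conductances (nS), non-negative.
#' @param params_row One row of a [neuron_params()] table.
#' @return A tibble with columns `dV_dt` (mV/ms) and `dw_dt` (pA/ms).
#' @examples
#' pv <- neuron_params("PV")
#' membrane_derivatives(V = -70, w = 0, g_e = 0, g_i = 0, params_row = pv)
#' @export
membrane_derivatives <- function(V, w, g_e, g_i, params_row) {
  p <- validate_neuron_params(params_row)
  if (nrow(p) != 1) rlang::abort("params_row must be a single row")
  if (any(!is.finite(V)) || any(!is.finite(w)) ||
      any(!is.finite(g_e)) || any(!is.finite(g_i))) {
    rlang::abort("non-finite state", class = "spikevar_bad_state")
  }
  if (any(g_e < 0) || any(g_i < 0)) {
    rlang::abort("conductances must be non-negative", class = "spikevar_bad_state")
  }
  ceiling_mV <- detection_ceiling(p)
  if (any(V > ceiling_mV)) {
    rlang::abort("V above spike-detection ceiling", class = "spikevar_bad_state")
  }
  I_exp <- 0
  if (has_adaptation(p)) {
    I_exp <- p$g_L * p$Delta_T * exp((V - p$V_th) / p$Delta_T)
    dw_dt <- (p$a * (V - p$E_L) - w) / p$tau_w
  } else {
    dw_dt <- rep(0, length(V))
  }
  dV_dt <- (-p$g_L * (V - p$E_L) + I_exp -
              g_e * (V - p$E_e) - g_i * (V - p$E_i) -
              w + p$I_e) / p$C_m
  tibble::tibble(dV_dt = dV_dt, dw_dt = dw_dt)
}

#' Exponential decay of a synaptic conductance
#'
#' The synaptic kernel is a single decaying exponential: each incoming spike
#' adds its peak conductance instantaneously and the total decays with time
#' constant `tau`. Contributions of multiple spikes superpose additively.
#'
#' @param g Conductance (nS).
#' @param dt Elapsed time (ms), non-negative.
#' @param tau Decay time constant (ms), positive.
#' @return `g * exp(-dt / tau)` (nS).
#' @examples
#' decay_conductance(1, dt = 5, tau = 5)  # 1/e
#' @export
decay_conductance <- function(g, dt, tau) {
  if (any(dt < 0)) rlang::abort("dt must be non-negative", class = "spikevar_bad_dt")
  if (any(tau <= 0)) rlang::abort("tau must be positive", class = "spikevar_bad_dt")
  g * exp(-dt / tau)
}

#' Peak postsynaptic-potential deflection of a single synaptic event
#'
#' Simulates the subthreshold membrane response of a neuron held at `V_hold`
#' (leak anchored at the holding potential; adaptation and the exponential
#' spike-initiation term disabled) to one presynaptic spike of peak
#' conductance `g_peak` decaying with `tau_syn` towards reversal `E_rev`,
#' and returns the peak deflection from `V_hold`. The sign of the deflection
#' follows the driving force `E_rev - V_hold`. Used to express synaptic
#' weights as PSP amplitudes for the weight-capping rule.
#'
#' @param g_peak Peak conductance of the event (nS), non-negative.
#' @param tau_syn Synaptic decay constant (ms).
#' @param E_rev Synaptic reversal potential (mV).
#' @param params_row One row of a [neuron_params()] table (supplies `C_m`,
#'   `g_L`).
#' @param V_hold Holding potential (mV).
#' @return Peak deflection (mV), signed.
#' @examples
#' pc <- neuron_params("PC")
#' psp_peak(0.2, tau_syn = pc$tau_e, E_rev = pc$E_e, params_row = pc,
#'          V_hold = -55)
#' @export
psp_peak <- function(g_peak, tau_syn, E_rev, params_row, V_hold = -55) {
  p <- validate_neuron_params(params_row)
  if (g_peak < 0) rlang::abort("g_peak must be non-negative")
  if (g_peak == 0 || E_rev == V_hold) return(0)
  t_end <- max(10 * tau_syn, 10 * p$C_m / p$g_L)
  times <- seq(0, t_end, length.out = 4000)
  rhs <- function(t, y, parms) {
    g <- g_peak * exp(-t / tau_syn)
    dV <- (-p$g_L * (y[1] - V_hold) - g * (y[1] - E_rev)) / p$C_m
    list(dV)
  }
  sol <- deSolve::lsoda(c(V = V_hold), times, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  defl <- sol[, "V"] - V_hold
  defl[which.max(abs(defl))]
}
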