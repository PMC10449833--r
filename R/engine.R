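#' Trial protocol windows
#'
#' A trial of `total_ms` splits into a preparation window (discarded;
#' reaching the operating point from the cold start), a post-stimulus
#' settling window, and the steady-state measurement window. The stimulus
#' (switch from baseline to evoked input rates) occurs at `onset_ms`, the
#' end of preparation. Defaults: 1000 ms total, 250 ms preparation, 250 ms
#' settling, last 500 ms measured.
#'
#' @param total_ms Trial duration (ms).
#' @param prep_ms Preparation window (ms).
#' @param settle_ms Post-stimulus settling window (ms).
#' @param measure_ms Steady-state measurement window (ms).
#' @return A list of class `trial_protocol` with the windows plus derived
#'   `onset_ms` and `measure_from_ms`.
#' @export
trial_protocol <- function(total_ms = 1000, prep_ms = 250, settle_ms = 250,
                           measure_ms = 500) {
  if (prep_ms + settle_ms + measure_ms != total_ms) {
    rlang::abort("windows must partition the trial", class = "spikevar_bad_protocol")
  }
  structure(list(total_ms = total_ms, prep_ms = prep_ms,
                 settle_ms = settle_ms, measure_ms = measure_ms,
                 onset_ms = prep_ms,
                 measure_from_ms = total_ms - measure_ms),
            class = "trial_protocol")
}

# channel (E/P/S) -> population name mapping for evoked modulations
channel_to_pop <- c(E = "PC", P = "PV", S = "SST")

# Accept delta in channel (E/P/S) or population (PC/PV/SST) naming;
# return population naming.
normalize_delta <- function(delta) {
  if (length(delta) == 0) return(numeric())
  nm <- names(delta)
  if (is.null(nm)) rlang::abort("delta must be named")
  chan <- nm %in% names(channel_to_pop)
  nm[chan] <- channel_to_pop[nm[chan]]
  stats::setNames(as.numeric(delta), nm)
}

#' Clip an evoked modulation to keep final rates non-negative
#'
#' Trial-cloud draws can push a final input rate below zero; those
#' modulations are clipped at `-base` (final rate 0) and the number of
#' clipped channels recorded in the `n_clipped` attribute.
#'
#' @param spec An [input_spec()].
#' @param delta Named modulation vector (channel or population names).
#' @return Clipped modulation vector (population names) with attribute
#'   `n_clipped`.
#' @export
clip_delta <- function(spec, delta) {
  d <- normalize_delta(delta)
  base <- spec$base_rates[names(d)]
  low <- d < -base
  d[low] <- -base[low]
  attr(d, "n_clipped") <- sum(low)
  d
}

# Build the per-population parameter matrix the C++ core expects.
params_matrix <- function(params, pops) {
  cols <- c("C_m", "E_L", "g_L", "V_th", "V_r", "Delta_T", "a", "b", "tau_w",
            "t_r", "E_e", "E_i", "tau_e", "tau_i", "I_e")
  p <- params[match(pops, params$pop), ]
  m <- as.matrix(p[, cols])
  adapt <- as.numeric(!is.na(p$Delta_T))
  m[is.na(m)] <- 0
  cbind(m, has_adapt = adapt)
}

#' Simulate one trial of a built network
#'
#' Advances every neuron with the AdEx update rules at a fixed step,
#' delivering recurrent spikes after the conduction delay and external
#' Poisson drive through excitatory synapses. External rates switch from
#' baseline to baseline-plus-modulation at the protocol's stimulus onset;
#' state is carried across the switch. Deterministic given `seed`.
#'
#' @param net A [build_network()] result.
#' @param spec An [input_spec()]; per-neuron drive is the superposition of
#'   `spec$n_sources` independent sources.
#' @param delta Named evoked modulation (Hz per source), channel (`E`, `P`,
#'   `S`) or population names; default none (baseline throughout).
#' @param protocol A [trial_protocol()].
#' @param dt Integration step (ms).
#' @param seed Integer seed for the input-spike stream.
#' @param clip If `TRUE`, clip modulations that would push a final rate
#'   negative (trial-cloud convention); if `FALSE`, such modulations error.
#' @return A `spike_record`: list with `spikes` (tibble `neuron_id`,
#'   `time_ms`), `neurons`, `protocol`, `dt`, `duration_ms`, `onset_ms`,
#'   `seed`, `n_clipped`.
#' @examples
#' \donttest{
#' net <- build_network(one_pop_config(n = 50), seed = 1)
#' rec <- run_trial(net, input_spec(base_rates = c(PC = 16)), seed = 1)
#' population_rate(rec, "PC", 250, 1000)
#' }
#' @export
run_trial <- function(net, spec, delta = numeric(),
                      protocol = trial_protocol(), dt = 0.1, seed = 1L,
                      clip = FALSE) {
  stopifnot(inherits(net, "spikevar_network"))
  pops <- names(net$config$sizes)
  if (!all(names(spec$base_rates) %in% pops) ||
      !all(pops %in% names(spec$base_rates))) {
    rlang::abort("input spec populations must match the network",
                 class = "spikevar_bad_config")
  }
  n_clipped <- 0L
  if (clip) {
    delta <- clip_delta(spec, delta)
    n_clipped <- attr(delta, "n_clipped")
    attributes(delta) <- list(names = names(delta))
    rates1 <- evoked_rates(spec, delta)
  } else {
    rates1 <- evoked_rates(spec, normalize_delta(delta))
  }
  rates0 <- spec$base_rates
  pop_idx <- match(net$neurons$pop, pops)
  pm <- params_matrix(net$config$params, pops)
  res <- sim_network_cpp(
    pop_id = pop_idx - 1L,
    pars = pm,
    edge_src = as.integer(net$edges$source_id - 1L),
    edge_tgt = as.integer(net$edges$target_id - 1L),
    edge_w = net$edges$conductance_nS,
    edge_inh = as.integer(net$edges$sign == "inh"),
    delay_ms = net$config$delay_ms,
    ext_rate0 = spec$n_sources * rates0[pop_idx],
    ext_rate1 = spec$n_sources * rates1[pop_idx],
    onset_ms = protocol$onset_ms,
    duration_ms = protocol$total_ms,
    dt = dt,
    w_ext = spec$weight_nS,
    seed = derive_seed(seed, "input-spikes"))
  structure(list(
    spikes = tibble::tibble(neuron_id = res$neuron_id, time_ms = res$time_ms),
    neurons = net$neurons,
    protocol = protocol,
    dt = dt,
    duration_ms = protocol$total_ms,
    onset_ms = protocol$onset_ms,
    seed = seed,
    n_clipped = n_clipped),
    class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("<spike_record>", nrow(x$spikes), "spikes from", nrow(x$neurons),
      "neurons over", x$duration_ms, "ms\n")
  invisible(x)
}

#' Mean population firing rate in a time window
#'
#' Total spikes of the population's members in `[t0, t1)` divided by member
#' count and window length.
#'
#' @param rec A `spike_record`.
#' @param population Population name.
#' @param t0,t1 Window bounds (ms), `t0 < t1`, within the trial.
#' @return Rate in Hz.
#' @export
population_rate <- function(rec, population, t0, t1) {
  if (t0 >= t1) rlang::abort("t0 must be below t1")
  members <- rec$neurons$id[rec$neurons$pop == population]
  if (length(members) == 0) {
    rlang::abort(paste0("empty population: ", population),
                 class = "spikevar_bad_population")
  }
  n_spk <- sum(rec$spikes$neuron_id %in% members &
                 rec$spikes$time_ms >= t0 & rec$spikes$time_ms < t1)
  n_spk / (length(members) * (t1 - t0) / 1000)
}

#' Mean firing rate of every population in a window
#'
#' @inheritParams population_rate
#' @param t0,t1 Window bounds (ms); defaults to the record's steady-state
#'   measurement window.
#' @return A tibble with columns `pop`, `rate_Hz`.
#' @export
population_rates <- function(rec, t0 = rec$protocol$measure_from_ms,
                             t1 = rec$duration_ms) {
  pops <- unique(rec$neurons$pop)
  tibble::tibble(
    pop = pops,
    rate_Hz = vapply(pops, function(p) population_rate(rec, p, t0, t1),
                     numeric(1)))
}

#' Peristimulus time histogram over trials
#'
#' Bins each trial's population spikes into rate traces and averages over
#' trials.
#'
#' @param records A list of `spike_record`s sharing duration and step.
#' @param population Population name.
#' @param binsize_ms Bin width (ms); must be a multiple of the integration
#'   step. The trace bin width is not pinned by the trial protocol; 10 ms is
#'   the package default.
#' @return A list of class `psth` with `trace` (tibble `trial`, `bin_start_ms`,
#'   `rate_Hz`) and `average` (tibble `bin_start_ms`, `rate_Hz`).
#' @export
psth <- function(records, population, binsize_ms = 10) {
  if (inherits(records, "spike_record")) records <- list(records)
  durs <- vapply(records, function(r) r$duration_ms, numeric(1))
  dts <- vapply(records, function(r) r$dt, numeric(1))
  if (length(unique(durs)) != 1 || length(unique(dts)) != 1) {
    rlang::abort("records must share duration and dt", class = "spikevar_bad_protocol")
  }
  if (abs(binsize_ms / dts[1] - round(binsize_ms / dts[1])) > 1e-9) {
    rlang::abort("binsize must be a multiple of dt", class = "spikevar_bad_protocol")
  }
  edges <- seq(0, durs[1], by = binsize_ms)
  traces <- purrr::imap_dfr(records, function(r, k) {
    members <- r$neurons$id[r$neurons$pop == population]
    tms <- r$spikes$time_ms[r$spikes$neuron_id %in% members]
    # right = FALSE bins [a, b); include.lowest keeps spikes stamped exactly
    # at the trial end in the last bin
    counts <- graphics::hist(tms, breaks = edges, plot = FALSE,
                             right = FALSE, include.lowest = TRUE)$counts
    tibble::tibble(trial = k,
                   bin_start_ms = edges[-length(edges)],
                   rate_Hz = counts / (length(members) * binsize_ms / 1000))
  })
  avg <- traces |>
    dplyr::group_by(.data$bin_start_ms) |>
    dplyr::summarise(rate_Hz = mean(.data$rate_Hz), .groups = "drop")
  structure(list(trace = traces, average = avg, population = population,
                 binsize_ms = binsize_ms, n_members = NA_integer_),
            class = "psth")
}

#' Write spikes as a two-column CSV
#' @param rec A `spike_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec$spikes), path, row.names = FALSE)
  invisible(path)
}
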