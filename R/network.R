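#' Configuration of the four-population microcircuit network
#'
#' Assembles the connectivity blueprint of the EPSV microcircuit: population
#' sizes, the pairwise connection-probability and base-conductance matrices
#' (rows = source population, columns = target population), log-normal
#' weight-scale parameters, PSP caps, and the uniform conduction delay.
#'
#' Default sizes are 3600 PC, 480 PV, 360 SST, 360 VIP. Pairs with no
#' connection (PC/PV onto VIP from PC and PV sources, SST/VIP onto PV) have
#' `NA` probability and produce no edges. The SST->SST and VIP->VIP base
#' conductances are not independently specified by the connectivity table the
#' circuit is built from; they default to 0.07 nS, the same-row inhibitory
#' conductance onto the other interneuron class, and can be overridden via
#' `conductance`.
#'
#' Each sampled weight is `base_g * LogNormal(meanlog = 0, sdlog = 1)`,
#' then clipped so that the peak PSP at a -55 mV holding potential does not
#' exceed `epsp_cap_mV` (excitatory) or `ipsp_cap_mV` in magnitude
#' (inhibitory). All synapses share a 2 ms conduction delay.
#'
#' @param sizes Named integer vector of population sizes.
#' @param conn_prob Square matrix of connection probabilities, rows = source,
#'   columns = target, `NA` = no connection.
#' @param conductance Square matrix of base conductances (nS), same layout.
#' @param params A [neuron_params()] table covering all populations in
#'   `sizes`.
#' @param excitatory Character vector of excitatory population names; all
#'   others are inhibitory.
#' @param delay_ms Conduction delay (ms), uniform across synapses.
#' @param weight_sdlog Log-normal sdlog of the weight scale factor.
#' @param epsp_cap_mV,ipsp_cap_mV PSP magnitude caps (mV) at `V_hold_mV`.
#' @param V_hold_mV Holding potential for the capping rule (mV).
#' @return A list of class `network_config`.
#' @examples
#' cfg <- network_config()
#' cfg$sizes
#' @export
network_config <- function(sizes = c(PC = 3600, PV = 480, SST = 360, VIP = 360),
                           conn_prob = NULL,
                           conductance = NULL,
                           params = neuron_params(names(sizes)),
                           excitatory = "PC",
                           delay_ms = 2,
                           weight_sdlog = 1,
                           epsp_cap_mV = 0.5,
                           ipsp_cap_mV = 2.0,
                           V_hold_mV = -55) {
  pops <- names(sizes)
  if (is.null(pops) || any(pops == "")) {
    rlang::abort("sizes must be a named vector", class = "spikevar_bad_config")
  }
  if (is.null(conn_prob)) conn_prob <- default_conn_prob()[pops, pops, drop = FALSE]
  if (is.null(conductance)) conductance <- default_conductance()[pops, pops, drop = FALSE]
  cfg <- structure(
    list(sizes = sizes, conn_prob = conn_prob, conductance = conductance,
         params = params, excitatory = excitatory, delay_ms = delay_ms,
         weight_sdlog = weight_sdlog, epsp_cap_mV = epsp_cap_mV,
         ipsp_cap_mV = ipsp_cap_mV, V_hold_mV = V_hold_mV),
    class = "network_config")
  validate_network_config(cfg)
}

default_conn_prob <- function() {
  m <- matrix(c(
    0.10, 0.60, 0.55,   NA,
    0.45, 0.50, 0.60,   NA,
    0.35,   NA, 0.50, 0.50,
    0.10,   NA, 0.45, 0.60), nrow = 4, byrow = TRUE,
    dimnames = list(c("PC", "PV", "SST", "VIP"), c("PC", "PV", "SST", "VIP")))
  m
}

default_conductance <- function() {
  # SST->SST and VIP->VIP base conductances default to the same-row
  # inhibitory value onto the other interneuron class (0.07 nS).
  m <- matrix(c(
    0.20, 0.08, 0.16,   NA,
    0.27, 0.46, 0.45,   NA,
    0.21,   NA, 0.07, 0.07,
    0.78,   NA, 0.07, 0.07), nrow = 4, byrow = TRUE,
    dimnames = list(c("PC", "PV", "SST", "VIP"), c("PC", "PV", "SST", "VIP")))
  m
}

#' Validate a network configuration
#'
#' Rejects probabilities outside `[0, 1]`, negative conductances,
#' non-positive delays, and connected pairs (p > 0) lacking a base
#' conductance.
#'
#' @param cfg A `network_config`.
#' @return `cfg`, invisibly unchanged, or an error of class
#'   `spikevar_bad_config`.
#' @export
validate_network_config <- function(cfg) {
  bad <- function(msg) rlang::abort(msg, class = "spikevar_bad_config")
  pops <- names(cfg$sizes)
  if (any(cfg$sizes <= 0)) bad("population sizes must be positive")
  p <- cfg$conn_prob
  g <- cfg$conductance
  if (!identical(dim(p), dim(g)) || !identical(rownames(p), pops) ||
      !identical(colnames(p), pops)) {
    bad("conn_prob and conductance must be square matrices over the populations")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) bad("connection probabilities must lie in [0, 1]")
  if (any(g < 0, na.rm = TRUE)) bad("conductances must be non-negative")
  if (cfg$delay_ms <= 0) bad("delay must be positive")
  orphan <- !is.na(p) & p > 0 & is.na(g)
  if (any(orphan)) {
    idx <- which(orphan, arr.ind = TRUE)
    bad(paste0("connected pair(s) without a base conductance: ",
               paste(paste0(pops[idx[, 1]], "->", pops[idx[, 2]]), collapse = ", ")))
  }
  if (!all(pops %in% cfg$params$pop)) bad("params must cover every population")
  invisible(cfg)
}

#' Single-population degenerate configuration
#'
#' One excitatory population with weak recurrent connections, used to expose
#' the monotone one-dimensional transfer-function of an unopposed excitatory
#' circuit. Runs through the same engine as the full microcircuit.
#'
#' @param n Number of neurons.
#' @param p Recurrent connection probability.
#' @param g_nS Recurrent base conductance (nS); weak by default so recurrence
#'   perturbs rather than dominates the drive.
#' @return A `network_config`.
#' @export
one_pop_config <- function(n = 400, p = 0.1, g_nS = 0.05) {
  network_config(
    sizes = c(PC = n),
    conn_prob = matrix(p, 1, 1, dimnames = list("PC", "PC")),
    conductance = matrix(g_nS, 1, 1, dimnames = list("PC", "PC")),
    params = neuron_params("PC"))
}

#' Two-population excitatory-inhibitory degenerate configuration
#'
#' An excitatory population recurrently coupled to one fast (PV-like)
#' inhibitory population; block probabilities and conductances mirror the
#' corresponding entries of the full microcircuit.
#'
#' @param n_e,n_i Population sizes.
#' @return A `network_config`.
#' @export
ei_config <- function(n_e = 400, n_i = 100) {
  pops <- c("PC", "PV")
  network_config(
    sizes = c(PC = n_e, PV = n_i),
    conn_prob = matrix(c(0.10, 0.60,
                         0.45, 0.50), 2, byrow = TRUE,
                       dimnames = list(pops, pops)),
    conductance = matrix(c(0.20, 0.08,
                           0.27, 0.46), 2, byrow = TRUE,
                         dimnames = list(pops, pops)),
    params = neuron_params(pops))
}

#' Draw a random directed edge set between two populations
#'
#' Each ordered (source, target) pair is included independently with
#' probability `p`; self-pairs are excluded when the source and target
#' population are the same. Uses the current RNG state.
#'
#' @param n_src,n_tgt Population sizes.
#' @param p Connection probability in `[0, 1]`.
#' @param same_population If `TRUE`, `n_src` and `n_tgt` index the same
#'   neurons and autapses (src == tgt) are excluded.
#' @return A tibble with integer columns `src`, `tgt` (1-based, local to each
#'   population).
#' @export
draw_connections <- function(n_src, n_tgt, p, same_population = FALSE) {
  if (p < 0 || p > 1) {
    rlang::abort("p must lie in [0, 1]", class = "spikevar_bad_config")
  }
  if (same_population && n_src != n_tgt) {
    rlang::abort("same_population requires n_src == n_tgt")
  }
  n_pairs <- if (same_population) n_src * (n_tgt - 1) else n_src * n_tgt
  if (n_pairs == 0 || p == 0) {
    return(tibble::tibble(src = integer(), tgt = integer()))
  }
  k <- stats::rbinom(1, n_pairs, p)
  idx <- if (k == n_pairs) seq_len(n_pairs) else sort(sample.int(n_pairs, k))
  idx0 <- idx - 1
  if (same_population) {
    src <- idx0 %/% (n_tgt - 1)
    off <- idx0 %% (n_tgt - 1)
    tgt <- off + (off >= src)
  } else {
    src <- idx0 %/% n_tgt
    tgt <- idx0 %% n_tgt
  }
  tibble::tibble(src = as.integer(src + 1L), tgt = as.integer(tgt + 1L))
}

#' Sample log-normally scaled synaptic conductances with a PSP cap
#'
#' Each weight is `base_g` times a log-normal scale factor (meanlog 0), then
#' clipped at `g_cap`, the conductance whose single-event PSP reaches the
#' capping amplitude on the target population.
#'
#' @param base_g Base conductance (nS).
#' @param n_edges Number of weights to draw.
#' @param g_cap Conductance ceiling (nS); `Inf` disables capping.
#' @param sdlog Log-normal sdlog.
#' @return Numeric vector of conductances (nS).
#' @export
sample_weights <- function(base_g, n_edges, g_cap = Inf, sdlog = 1) {
  if (base_g < 0) rlang::abort("base_g must be non-negative")
  pmin(base_g * stats::rlnorm(n_edges, meanlog = 0, sdlog = sdlog), g_cap)
}

#' Conductance ceiling realizing a PSP amplitude cap
#'
#' Inverts [psp_peak()] for a synapse onto the given target population:
#' returns the peak conductance whose single-event PSP at `V_hold` has
#' magnitude `cap_mV`.
#'
#' @param cap_mV PSP magnitude cap (mV), positive.
#' @param sign `"exc"` or `"inh"`; selects the reversal potential and decay
#'   constant of the target.
#' @param target_params One row of a [neuron_params()] table.
#' @param V_hold Holding potential (mV).
#' @return Conductance (nS).
#' @export
conductance_cap <- function(cap_mV, sign, target_params, V_hold = -55) {
  stopifnot(cap_mV > 0, sign %in% c("exc", "inh"))
  tau <- if (sign == "exc") target_params$tau_e else target_params$tau_i
  E_rev <- if (sign == "exc") target_params$E_e else target_params$E_i
  f <- function(g) abs(psp_peak(g, tau, E_rev, target_params, V_hold)) - cap_mV
  # linear small-signal estimate brackets the root
  g0 <- cap_mV / abs(psp_peak(0.1, tau, E_rev, target_params, V_hold)) * 0.1
  stats::uniroot(f, lower = g0 / 50, upper = g0 * 50, extendInt = "upX",
                 tol = 1e-6)$root
}

#' Build a microcircuit network realization
#'
#' Draws the full directed edge list from a [network_config()]: Bernoulli
#' connectivity per population pair, log-normally scaled conductances
#' clipped at the PSP caps, uniform conduction delays, and edge signs set by
#' the source population. Connectivity and weight randomness use separate
#' named RNG streams derived from `seed`, so each layer is independently
#' reproducible; rebuilding with the same seed yields an identical edge
#' list.
#'
#' @param config A `network_config`.
#' @param seed Integer seed.
#' @return A list of class `spikevar_network` with elements `neurons` (tibble
#'   `id`, `pop`), `edges` (tibble `source_id`, `target_id`,
#'   `conductance_nS`, `delay_ms`, `sign`), `config`, `g_caps`, and `seed`.
#' @examples
#' \donttest{
#' net <- build_network(network_config(), seed = 1)
#' dplyr::count(net$edges, sign)
#' }
#' @export
build_network <- function(config, seed = 1L) {
  validate_network_config(config)
  pops <- names(config$sizes)
  offsets <- c(0, cumsum(config$sizes))[seq_along(pops)]
  names(offsets) <- pops
  neurons <- tibble::tibble(
    id = seq_len(sum(config$sizes)),
    pop = rep(pops, times = config$sizes))

  pop_sign <- ifelse(pops %in% config$excitatory, "exc", "inh")
  names(pop_sign) <- pops

  # PSP-cap conductances per (target population, sign)
  g_caps <- list()
  for (tp in pops) {
    trow <- config$params[config$params$pop == tp, ]
    g_caps[[tp]] <- c(
      exc = conductance_cap(config$epsp_cap_mV, "exc", trow, config$V_hold_mV),
      inh = conductance_cap(config$ipsp_cap_mV, "inh", trow, config$V_hold_mV))
  }

  conn_seed <- derive_seed(seed, "connectivity")
  weight_seed <- derive_seed(seed, "weights")
  blocks <- list()
  for (sp in pops) {
    for (tp in pops) {
      p <- config$conn_prob[sp, tp]
      if (is.na(p) || p == 0) next
      pair_seed <- derive_seed(conn_seed, paste0(sp, ">", tp))
      idx <- with_seed(pair_seed,
        draw_connections(config$sizes[[sp]], config$sizes[[tp]], p,
                         same_population = sp == tp))
      if (nrow(idx) == 0) next
      sgn <- pop_sign[[sp]]
      cap <- g_caps[[tp]][[sgn]]
      w_seed <- derive_seed(weight_seed, paste0(sp, ">", tp))
      w <- with_seed(w_seed,
        sample_weights(config$conductance[sp, tp], nrow(idx), g_cap = cap,
                       sdlog = config$weight_sdlog))
      blocks[[paste0(sp, ">", tp)]] <- tibble::tibble(
        source_id = idx$src + offsets[[sp]],
        target_id = idx$tgt + offsets[[tp]],
        conductance_nS = w,
        delay_ms = config$delay_ms,
        sign = sgn)
    }
  }
  empty <- tibble::tibble(source_id = integer(), target_id = integer(),
                          conductance_nS = numeric(), delay_ms = numeric(),
                          sign = character())
  edges <- dplyr::bind_rows(c(list(empty), blocks))
  structure(list(neurons = neurons, edges = edges, config = config,
                 g_caps = g_caps, seed = seed),
            class = "spikevar_network")
}

#' @export
print.spikevar_network <- function(x, ...) {
  cat("<spikevar_network>\n")
  cat("  neurons:", nrow(x$neurons), "in",
      length(unique(x$neurons$pop)), "population(s)\n")
  cat("  edges:  ", nrow(x$edges), "\n")
  sz <- table(factor(x$neurons$pop, levels = names(x$config$sizes)))
  cat("  sizes:  ", paste(names(sz), sz, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a network edge list as CSV
#'
#' Columns `source_id`, `target_id`, `conductance_nS`, `delay_ms`, `sign`.
#'
#' @param net A `spikevar_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  utils::write.csv(as.data.frame(net$edges), path, row.names = FALSE)
  invisible(path)
}

#' Write a network configuration as JSON
#'
#' Mirrors the two connectivity matrices (probability and conductance),
#' population sizes, caps, and the neuron parameter table.
#'
#' @param config A `network_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  x <- list(
    sizes = as.list(config$sizes),
    conn_prob = config$conn_prob,
    conductance = config$conductance,
    delay_ms = config$delay_ms,
    weight_sdlog = config$weight_sdlog,
    epsp_cap_mV = config$epsp_cap_mV,
    ipsp_cap_mV = config$ipsp_cap_mV,
    V_hold_mV = config$V_hold_mV,
    excitatory = config$excitatory,
    params = as.data.frame(config$params))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}
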