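#' Propagate a trial-to-trial input distribution through the transfer-function
#'
#' Samples a per-trial input cloud from the three-dimensional normal
#' distribution, maps every point through the trilinearly interpolated
#' transfer-function, and summarises the across-trial output statistics: the
#' full output covariance over the (E, P, S) population rates and the
#' excitatory output variance as the primary scalar.
#'
#' Cloud points that would push a final input rate below zero are clipped
#' to the zero-rate boundary (and counted). If more than `max_drop_frac` of
#' the cloud falls outside the lattice hull the mapping aborts (the
#' distribution is too wide for the grid); points outside the hull below
#' that fraction are dropped and counted.
#'
#' @param grid A [tf_grid()].
#' @param dist An [input_distribution()].
#' @param spec The [input_spec()] defining the zero-rate clipping boundary.
#' @param n Cloud size (default 10000).
#' @param seed Integer seed for the cloud stream.
#' @param max_drop_frac Maximal tolerated out-of-hull fraction.
#' @return A list of class `tf_mapping` with `samples` (tibble of per-trial
#'   modulations and mapped rates), `cov` (3x3 output covariance over E, P,
#'   S), `var_E`, `n_clipped`, `n_dropped`, `dist`.
#' @export
map_through_tf <- function(grid, dist, spec = input_spec(), n = 10000,
                           seed = 1L, max_drop_frac = 0.05) {
  cloud <- sample_cloud(dist, n, seed = seed)
  # clip to the zero-final-rate boundary per channel
  n_clipped <- 0L
  for (ch in c("E", "P", "S")) {
    pop <- channel_to_pop[[ch]]
    if (!pop %in% names(spec$base_rates)) next
    col <- paste0("dlambda_", ch)
    low <- cloud[[col]] < -spec$base_rates[[pop]]
    n_clipped <- n_clipped + sum(low)
    cloud[[col]][low] <- -spec$base_rates[[pop]]
  }
  inside <- rep(TRUE, nrow(cloud))
  hull <- list(E = range(grid$ax_E), P = range(grid$ax_P), S = range(grid$ax_S))
  for (ch in c("E", "P", "S")) {
    x <- cloud[[paste0("dlambda_", ch)]]
    inside <- inside & x >= hull[[ch]][1] - 1e-9 & x <= hull[[ch]][2] + 1e-9
  }
  n_dropped <- sum(!inside)
  if (n_dropped > max_drop_frac * n) {
    rlang::abort(sprintf(
      "%d of %d cloud points fall outside the lattice hull (> %.0f%%): distribution too wide for the grid",
      n_dropped, n, 100 * max_drop_frac),
      class = "spikevar_out_of_hull")
  }
  cloud <- cloud[inside, ]
  rates <- interpolate_tf(grid, cloud[, c("dlambda_E", "dlambda_P", "dlambda_S")])
  samples <- dplyr::bind_cols(cloud, rates)
  out_pops <- intersect(c(unname(channel_to_pop)), names(grid$rates))
  have <- paste0("rate_", out_pops)
  m <- as.matrix(samples[, have])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  colnames(m) <- names(channel_to_pop)[match(out_pops, channel_to_pop)]
  cv <- stats::cov(m)
  e_name <- names(channel_to_pop)[channel_to_pop == grid$excitatory]
  var_E <- if (length(e_name) == 1 && e_name %in% colnames(cv)) {
    cv[e_name, e_name]
  } else {
    stats::var(m[, 1])
  }
  structure(list(samples = samples, cov = cv, var_E = var_E,
                 n_clipped = n_clipped, n_dropped = n_dropped, dist = dist,
                 n = n, seed = seed),
            class = "tf_mapping")
}

#' @export
print.tf_mapping <- function(x, ...) {
  cat("<tf_mapping>", nrow(x$samples), "mapped trials; var_E =",
      signif(x$var_E, 4), "Hz^2\n")
  invisible(x)
}

#' Across-trial output covariance from full network simulation
#'
#' Draws one input-cloud point per trial, runs the full trial protocol for
#' each (baseline before stimulus onset, baseline plus that trial's
#' modulation after), measures each population's steady-state rate over the
#' measurement window, and returns the sample covariance of the (E, P, S)
#' rates across trials. Any aborted trial invalidates the whole covariance.
#'
#' @param net A [build_network()] result.
#' @param spec An [input_spec()].
#' @param dist An [input_distribution()].
#' @param n_trials Number of trials (>= 2); 100 in the full protocol.
#' @param protocol A [trial_protocol()].
#' @param dt Integration step (ms).
#' @param seed Integer seed; per-trial input-noise seeds and the cloud
#'   stream are derived from it.
#' @return A list of class `trial_covariance` with `cov` (3x3 over E, P, S),
#'   `var_E`, `rates` (per-trial steady-state rates), `cloud`, `n_trials`.
#' @export
simulate_trial_covariance <- function(net, spec, dist, n_trials = 100,
                                      protocol = trial_protocol(), dt = 0.1,
                                      seed = 1L) {
  if (n_trials < 2) rlang::abort("n_trials must be at least 2")
  cloud <- sample_cloud(dist, n_trials, seed = seed)
  pops <- intersect(unname(channel_to_pop), names(net$config$sizes))
  chans <- names(channel_to_pop)[match(pops, channel_to_pop)]
  rates <- matrix(NA_real_, n_trials, length(pops),
                  dimnames = list(NULL, chans))
  for (i in seq_len(n_trials)) {
    delta <- c(E = cloud$dlambda_E[i], P = cloud$dlambda_P[i],
               S = cloud$dlambda_S[i])
    delta <- delta[channel_to_pop[names(delta)] %in% pops]
    rec <- run_trial(net, spec, delta = delta, protocol = protocol, dt = dt,
                     seed = derive_seed(seed, paste0("trial-", i)),
                     clip = TRUE)
    rates[i, ] <- vapply(pops, function(p)
      population_rate(rec, p, protocol$measure_from_ms, protocol$total_ms),
      numeric(1))
  }
  cv <- stats::cov(rates)
  e_name <- names(channel_to_pop)[channel_to_pop == net$config$excitatory[1]]
  structure(list(cov = cv,
                 var_E = cv[e_name, e_name],
                 rates = tibble::as_tibble(cbind(trial = seq_len(n_trials),
                                                 as.data.frame(rates))),
                 cloud = cloud, n_trials = n_trials, dist = dist,
                 protocol = protocol, seed = seed),
            class = "trial_covariance")
}

#' @export
print.trial_covariance <- function(x, ...) {
  cat("<trial_covariance> over", x$n_trials, "trials; var_E =",
      signif(x$var_E, 4), "Hz^2\n")
  print(signif(x$cov, 4))
  invisible(x)
}

#' Output variability across a lattice of input means
#'
#' Maps the same input-distribution shape (default: uncorrelated unit
#' variances) through the transfer-function at every mean on a lattice and
#' records the excitatory output variance per cell. Cells whose cloud falls
#' outside the lattice hull are masked.
#'
#' @param grid A [tf_grid()].
#' @param means A data frame with columns `dlambda_E`, `dlambda_P`,
#'   `dlambda_S` (one row per lattice cell).
#' @param sigma Fixed covariance shape (3x3), default `diag(3)` Hz^2.
#' @param spec An [input_spec()].
#' @param n Cloud size per cell.
#' @param seed Integer seed.
#' @return A `variability_map`: tibble `means` plus columns `var_E`, `sd_E`,
#'   `masked`.
#' @export
sweep_mean_variability <- function(grid, means, sigma = diag(3),
                                   spec = input_spec(), n = 2000, seed = 1L) {
  dimnames(sigma) <- list(c("E", "P", "S"), c("E", "P", "S"))
  res <- purrr::pmap_dfr(means, function(dlambda_E, dlambda_P, dlambda_S, ...) {
    dist <- input_distribution(
      mean = c(E = dlambda_E, P = dlambda_P, S = dlambda_S), sigma = sigma)
    v <- tryCatch(
      map_through_tf(grid, dist, spec = spec, n = n,
                     seed = derive_seed(seed, paste(dlambda_E, dlambda_P,
                                                    dlambda_S)))$var_E,
      spikevar_out_of_hull = function(e) NA_real_)
    tibble::tibble(dlambda_E = dlambda_E, dlambda_P = dlambda_P,
                   dlambda_S = dlambda_S,
                   var_E = v, sd_E = sqrt(v), masked = is.na(v))
  })
  class(res) <- c("variability_map", class(res))
  res
}

#' Output variability across trial-covariance or trial-balance factors
#'
#' Sweeps two factor axes of the input distribution at a fixed mean and
#' maps each resulting covariance through the transfer-function. For
#' `factor = "covariance"` the axes are two pairwise covariances with the
#' variances held fixed; for `factor = "balance"` the axes are two signed
#' balance ratios under a fixed total variance, with covariance magnitudes
#' held fixed. Cells whose assembled covariance matrix is not positive
#' semidefinite are rejected and masked (carrying no value), the map
#' analogue of blank cells in a factor-sweep heat map.
#'
#' @param grid A [tf_grid()].
#' @param mean Named mean modulation vector `c(E, P, S)` (Hz).
#' @param factor `"covariance"` or `"balance"`.
#' @param pair1,pair2 Which factor each axis sweeps: two of `"EP"`, `"ES"`,
#'   `"PS"` (balance sweeps must cover `EP` and `ES`).
#' @param axis1,axis2 Numeric vectors of swept factor values.
#' @param variances Fixed variances `c(EE, PP, SS)` for covariance sweeps.
#' @param total_var Fixed total variance for balance sweeps.
#' @param cov_mag Fixed covariance magnitude (Hz^2) for balance sweeps.
#' @param fixed Covariances held fixed in a covariance sweep (values for the
#'   pair not being swept).
#' @param spec An [input_spec()].
#' @param n Cloud size per cell.
#' @param seed Integer seed.
#' @return A `variability_map` tibble with columns `f1`, `f2` (factor
#'   values), `var_E`, `sd_E`, `masked`, and attributes `factor`, `axes`.
#' @export
sweep_factor_variability <- function(grid, mean = c(E = 0, P = 0, S = 0),
                                     factor = c("covariance", "balance"),
                                     pair1 = "EP", pair2 = "ES",
                                     axis1, axis2,
                                     variances = c(1.8, 0.6, 0.6),
                                     total_var = 3, cov_mag = 0.5,
                                     fixed = c(EP = 0, ES = 0, PS = 0),
                                     spec = input_spec(), n = 2000,
                                     seed = 1L) {
  factor <- match.arg(factor)
  stopifnot(pair1 %in% c("EP", "ES", "PS"), pair2 %in% c("EP", "ES", "PS"),
            pair1 != pair2)
  if (factor == "balance" && !setequal(c(pair1, pair2), c("EP", "ES"))) {
    rlang::abort("balance sweeps must cover the EP and ES ratios")
  }
  grid_cells <- tidyr::expand_grid(f1 = unname(axis1), f2 = unname(axis2))
  res <- purrr::pmap_dfr(grid_cells, function(f1, f2) {
    sigma <- if (factor == "covariance") {
      cv <- fixed
      cv[[pair1]] <- f1
      cv[[pair2]] <- f2
      build_covariance(variances = variances, covariances = cv)
    } else {
      bal <- c(EP = NA_real_, ES = NA_real_)
      bal[[pair1]] <- f1
      bal[[pair2]] <- f2
      build_covariance(total_var = total_var, balance = bal,
                       covariances = c(EP = cov_mag, ES = cov_mag, PS = cov_mag))
    }
    if (is.null(sigma)) {
      return(tibble::tibble(f1 = f1, f2 = f2, var_E = NA_real_,
                            sd_E = NA_real_, masked = TRUE))
    }
    dist <- input_distribution(mean = mean, sigma = sigma)
    v <- tryCatch(
      map_through_tf(grid, dist, spec = spec, n = n,
                     seed = derive_seed(seed, paste(factor, f1, f2)))$var_E,
      spikevar_out_of_hull = function(e) NA_real_)
    tibble::tibble(f1 = f1, f2 = f2, var_E = v, sd_E = sqrt(v),
                   masked = is.na(v))
  })
  if (all(res$masked)) rlang::warn("all sweep cells are masked")
  attr(res, "factor") <- factor
  attr(res, "axes") <- c(pair1, pair2)
  class(res) <- c("variability_map", class(res))
  res
}
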