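#' External input specification
#'
#' Describes the feedforward excitatory drive each neuron receives: baseline
#' Poisson rates per population, the number of independent Poisson sources
#' per neuron, and the external synaptic weight. Defaults are the baseline
#' operating point of the EPSV circuit: per-source rates
#' (16.0, 90.0, 9.3, 12.0) Hz onto (PC, PV, SST, VIP), 20 sources per
#' neuron, 50 nS synapses, tuned so the network fires near in-vivo
#' spontaneous rates.
#'
#' @param base_rates Named numeric vector of per-source baseline rates (Hz).
#' @param n_sources Independent Poisson sources per neuron.
#' @param weight_nS External synaptic peak conductance (nS).
#' @return A list of class `input_spec`.
#' @export
input_spec <- function(base_rates = c(PC = 16.0, PV = 90.0, SST = 9.3, VIP = 12.0),
                       n_sources = 20,
                       weight_nS = 50) {
  if (any(base_rates < 0)) {
    rlang::abort("baseline rates must be non-negative", class = "spikevar_bad_rate")
  }
  structure(list(base_rates = base_rates, n_sources = n_sources,
                 weight_nS = weight_nS),
            class = "input_spec")
}

#' Generate homogeneous Poisson spike trains
#'
#' `n_sources` independent homogeneous Poisson processes at a common rate,
#' returned in tidy long format. Uses the current RNG state.
#'
#' @param rate Rate per source (Hz), non-negative.
#' @param n_sources Number of independent sources.
#' @param duration Duration (ms).
#' @return A tibble with columns `source` (integer) and `time_ms`, sorted
#'   within source.
#' @examples
#' set.seed(1)
#' trains <- poisson_trains(16, n_sources = 20, duration = 1000)
#' nrow(trains) / 20 # about 16 spikes per source
#' @export
poisson_trains <- function(rate, n_sources, duration) {
  if (rate < 0) rlang::abort("rate must be non-negative", class = "spikevar_bad_rate")
  counts <- stats::rpois(n_sources, rate * duration / 1000)
  tibble::tibble(
    source = rep(seq_len(n_sources), counts),
    time_ms = unlist(lapply(counts, function(k) sort(stats::runif(k, 0, duration))),
                     use.names = FALSE))
}

#' Final evoked input rates
#'
#' Adds an evoked modulation to the baseline per-source rates. The VIP
#' modulation is fixed at zero (the input space is three-dimensional over
#' the PC, PV and SST channels). Negative modulations are allowed as long as
#' every final rate stays non-negative.
#'
#' @param spec An [input_spec()].
#' @param delta Named numeric vector of rate modulations (Hz); names must be
#'   populations of `spec`; omitted populations get 0.
#' @return Named numeric vector of final per-source rates (Hz).
#' @examples
#' evoked_rates(input_spec(), c(PC = 2, PV = -1))
#' @export
evoked_rates <- function(spec, delta = numeric()) {
  rates <- spec$base_rates
  d <- stats::setNames(numeric(length(rates)), names(rates))
  if (length(delta) > 0) {
    unknown <- setdiff(names(delta), names(rates))
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown population(s) in delta: ",
                          paste(unknown, collapse = ", ")),
                   class = "spikevar_bad_rate")
    }
    d[names(delta)] <- delta
  }
  if ("VIP" %in% names(d)) d[["VIP"]] <- 0
  out <- rates + d
  if (any(out < 0)) {
    rlang::abort(paste0("negative final input rate for: ",
                        paste(names(out)[out < 0], collapse = ", ")),
                 class = "spikevar_negative_rate")
  }
  out
}

#' Test positive semidefiniteness of a symmetric matrix
#'
#' A matrix is accepted when its smallest eigenvalue is no smaller than
#' `-tol` times its largest (floating-point symmetry noise allowance).
#'
#' @param m Symmetric numeric matrix.
#' @param tol Relative eigenvalue tolerance.
#' @return Logical scalar.
#' @export
is_psd <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(max(ev), .Machine$double.eps)
}

#' Assemble a trial-to-trial input covariance matrix
#'
#' Builds the 3x3 across-trial covariance of the (E, P, S) input-rate
#' modulations, either directly from variances, or from a fixed total
#' variance split according to signed balance factors (the one-factor-at-a-
#' time sweeps hold the total `sigma_EE + sigma_PP + sigma_SS` constant).
#' The balance factor of a pair is the signed ratio of its variances: the
#' magnitude is `var_X / var_Y` and the sign is positive when the pair's
#' trial-wise inputs are correlated, negative when anti-correlated. A
#' negative balance is realized by flipping the sign of the corresponding
#' covariance entry.
#'
#' The matrix is returned only when positive semidefinite; otherwise `NULL`
#' (the rejection marker that renders as masked cells in sweep maps).
#'
#' @param variances Numeric vector `c(EE, PP, SS)` of variances (Hz^2), or
#'   `NULL` when building from `total_var` + `balance`.
#' @param covariances Numeric vector `c(EP, ES, PS)` of covariances (Hz^2);
#'   magnitudes are kept, signs may be overridden by negative balances.
#' @param total_var Total variance `EE + PP + SS` (Hz^2), used with
#'   `balance`.
#' @param balance Named vector with `EP = sigma_E/P` and `ES = sigma_E/S`
#'   signed variance ratios (and optionally `PS`, whose sign applies to the
#'   PS covariance; its magnitude is implied by the other two).
#' @return A 3x3 symmetric matrix with dimnames `E`, `P`, `S`, or `NULL`
#'   when not positive semidefinite.
#' @examples
#' build_covariance(variances = c(1.8, 0.6, 0.6))
#' build_covariance(variances = c(1, 1, 1),
#'                  covariances = c(EP = 1.2, ES = 0, PS = 0)) # NULL
#' @export
build_covariance <- function(variances = NULL,
                             covariances = c(EP = 0, ES = 0, PS = 0),
                             total_var = NULL,
                             balance = NULL) {
  cv <- c(EP = 0, ES = 0, PS = 0)
  cv[names(covariances)] <- covariances
  if (is.null(variances)) {
    if (is.null(total_var) || is.null(balance)) {
      rlang::abort("supply either variances, or total_var with balance",
                   class = "spikevar_bad_covariance")
    }
    if (total_var <= 0) rlang::abort("total_var must be positive",
                                     class = "spikevar_bad_covariance")
    b_EP <- balance[["EP"]]
    b_ES <- balance[["ES"]]
    if (b_EP == 0 || b_ES == 0) {
      rlang::abort("balance ratios must be nonzero",
                   class = "spikevar_bad_covariance")
    }
    v_E <- total_var / (1 + 1 / abs(b_EP) + 1 / abs(b_ES))
    variances <- c(v_E, v_E / abs(b_EP), v_E / abs(b_ES))
    cv[["EP"]] <- sign(b_EP) * abs(cv[["EP"]])
    cv[["ES"]] <- sign(b_ES) * abs(cv[["ES"]])
    if ("PS" %in% names(balance)) {
      cv[["PS"]] <- sign(balance[["PS"]]) * abs(cv[["PS"]])
    }
  }
  if (any(variances < 0)) {
    rlang::abort("variances must be non-negative", class = "spikevar_bad_covariance")
  }
  m <- matrix(c(variances[1], cv[["EP"]], cv[["ES"]],
                cv[["EP"]], variances[2], cv[["PS"]],
                cv[["ES"]], cv[["PS"]], variances[3]),
              nrow = 3, dimnames = list(c("E", "P", "S"), c("E", "P", "S")))
  if (!isSymmetric(m)) {
    rlang::abort("covariance must be symmetric", class = "spikevar_bad_covariance")
  }
  if (!is_psd(m)) return(NULL)
  m
}

#' Signed balance factors of a covariance matrix
#'
#' For each pair of input channels, the signed ratio of their across-trial
#' variances: magnitude `var_X / var_Y`, sign taken from the pair's
#' covariance (positive when correlated or uncorrelated, negative when
#' anti-correlated).
#'
#' @param sigma 3x3 covariance matrix with dimnames `E`, `P`, `S`.
#' @return Named numeric vector `c(EP, ES, PS)`.
#' @export
balance_factors <- function(sigma) {
  sgn <- function(x) if (x < 0) -1 else 1
  c(EP = sgn(sigma["E", "P"]) * sigma["E", "E"] / sigma["P", "P"],
    ES = sgn(sigma["E", "S"]) * sigma["E", "E"] / sigma["S", "S"],
    PS = sgn(sigma["P", "S"]) * sigma["P", "P"] / sigma["S", "S"])
}

#' Trial-to-trial input distribution
#'
#' Bundles the mean modulation vector and accepted covariance matrix of the
#' three-dimensional normal distribution from which per-trial input-rate
#' modulations are drawn.
#'
#' @param mean Named numeric vector `c(E, P, S)` of mean modulations (Hz).
#' @param sigma 3x3 positive-semidefinite covariance matrix (Hz^2), e.g.
#'   from [build_covariance()].
#' @return A list of class `input_distribution` with elements `mean`,
#'   `sigma`, `balance`.
#' @export
input_distribution <- function(mean = c(E = 0, P = 0, S = 0),
                               sigma = build_covariance(variances = c(1.8, 0.6, 0.6))) {
  if (is.null(sigma)) {
    rlang::abort("sigma was rejected (not positive semidefinite)",
                 class = "spikevar_bad_covariance")
  }
  m <- c(E = 0, P = 0, S = 0)
  m[names(mean)] <- mean
  dimnames(sigma) <- list(c("E", "P", "S"), c("E", "P", "S"))
  if (!is_psd(sigma) || !isSymmetric(unname(sigma))) {
    rlang::abort("sigma must be symmetric positive semidefinite",
                 class = "spikevar_bad_covariance")
  }
  structure(list(mean = m, sigma = sigma, balance = balance_factors(sigma)),
            class = "input_distribution")
}

#' Sample a trial-wise input cloud
#'
#' Draws `n` per-trial modulation vectors from the three-dimensional normal
#' input distribution. Deterministic given `(dist, n, seed)`.
#'
#' @param dist An [input_distribution()].
#' @param n Number of trials/points (10000 for transfer-function mapping,
#'   100 for simulated trial protocols).
#' @param seed Integer seed (a dedicated cloud stream is derived from it).
#' @return A tibble with columns `trial`, `dlambda_E`, `dlambda_P`,
#'   `dlambda_S` (Hz).
#' @examples
#' cloud <- sample_cloud(input_distribution(), n = 100, seed = 1)
#' @export
sample_cloud <- function(dist, n, seed = 1L) {
  stopifnot(inherits(dist, "input_distribution"))
  x <- with_seed(derive_seed(seed, "cloud"),
                 MASS::mvrnorm(n, mu = dist$mean, Sigma = dist$sigma))
  if (n == 1) x <- matrix(x, nrow = 1)
  tibble::tibble(trial = seq_len(n),
                 dlambda_E = x[, 1], dlambda_P = x[, 2], dlambda_S = x[, 3])
}

#' Write an input cloud as CSV
#' @param cloud A tibble from [sample_cloud()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE)
  invisible(path)
}

#' Write an input distribution as JSON
#' @param dist An [input_distribution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution_json <- function(dist, path) {
  jsonlite::write_json(
    list(mean = as.list(dist$mean), sigma = dist$sigma,
         balance = as.list(dist$balance)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
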