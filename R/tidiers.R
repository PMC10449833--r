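#' @importFrom generics tidy glance
NULL

#' Tidy an across-trial output covariance
#'
#' One row per covariance entry of the (E, P, S) steady-state rates.
#'
#' @param x A `trial_covariance` or `tf_mapping`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `covariance`.
#' @export
tidy.trial_covariance <- function(x, ...) {
  cv <- x$cov
  tidyr::expand_grid(row = rownames(cv), col = colnames(cv)) |>
    dplyr::mutate(covariance = as.vector(t(cv)))
}

#' @rdname tidy.trial_covariance
#' @export
tidy.tf_mapping <- function(x, ...) {
  cv <- x$cov
  tidyr::expand_grid(row = rownames(cv), col = colnames(cv)) |>
    dplyr::mutate(covariance = as.vector(t(cv)))
}

#' One-row summary of an across-trial covariance estimate
#'
#' @param x A `trial_covariance`.
#' @param ... Unused.
#' @return A one-row tibble with `var_E`, `sd_E`, `n_trials`.
#' @export
glance.trial_covariance <- function(x, ...) {
  tibble::tibble(var_E = x$var_E, sd_E = sqrt(x$var_E), n_trials = x$n_trials)
}

#' One-row summary of a transfer-function mapping
#'
#' @param x A `tf_mapping`.
#' @param ... Unused.
#' @return A one-row tibble with `var_E`, `sd_E`, `n`, `n_clipped`,
#'   `n_dropped`.
#' @export
glance.tf_mapping <- function(x, ...) {
  tibble::tibble(var_E = x$var_E, sd_E = sqrt(x$var_E), n = x$n,
                 n_clipped = x$n_clipped, n_dropped = x$n_dropped)
}

#' Tidy a spike record
#'
#' @param x A `spike_record`.
#' @param ... Unused.
#' @return A tibble with `neuron_id`, `pop`, `time_ms`.
#' @export
tidy.spike_record <- function(x, ...) {
  dplyr::left_join(x$spikes, x$neurons, by = c(neuron_id = "id"))
}

#' One-row summary of a spike record
#'
#' Steady-state rates per population, spread as one column each.
#'
#' @param x A `spike_record`.
#' @param ... Unused.
#' @return A one-row tibble with `duration_ms`, `n_spikes`, and one
#'   `rate_<pop>` column per population.
#' @export
glance.spike_record <- function(x, ...) {
  pr <- population_rates(x)
  out <- tibble::tibble(duration_ms = x$duration_ms,
                        n_spikes = nrow(x$spikes))
  for (i in seq_len(nrow(pr))) out[[paste0("rate_", pr$pop[i])]] <- pr$rate_Hz[i]
  out
}
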