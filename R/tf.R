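#' Transfer-function grid container
#'
#' Holds the measured steady-state output rates of each population on a
#' three-dimensional lattice of evoked input-rate modulations
#' `(dlambda_E, dlambda_P, dlambda_S)` (the VIP modulation is fixed at 0).
#' Node values are averages over the steady-state measurement window;
#' lattice nodes whose final input rates would be negative carry `NA`.
#'
#' @param ax_E,ax_P,ax_S Strictly increasing axis vectors (Hz); singleton
#'   axes are allowed (degenerate lower-dimensional grids).
#' @param rates Named list of numeric arrays, one per population, each of
#'   dimension `c(length(ax_E), length(ax_P), length(ax_S))`, in Hz.
#' @param excitatory Name of the excitatory (output) population.
#' @param meta Optional list of estimation metadata (seeds, repetitions).
#' @return A list of class `tf_grid`.
#' @export
tf_grid <- function(ax_E, ax_P, ax_S, rates, excitatory = "PC", meta = list()) {
  dims <- c(length(ax_E), length(ax_P), length(ax_S))
  for (ax in list(ax_E, ax_P, ax_S)) {
    if (length(ax) > 1 && any(diff(ax) <= 0)) {
      rlang::abort("axes must be strictly increasing", class = "spikevar_bad_grid")
    }
  }
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (!identical(dim(r), as.integer(dims))) {
      rlang::abort(paste0("rates[['", nm, "']] has wrong dimensions"),
                   class = "spikevar_bad_grid")
    }
    if (any(r < 0, na.rm = TRUE)) {
      rlang::abort("output rates must be non-negative", class = "spikevar_bad_grid")
    }
  }
  if (!excitatory %in% names(rates)) {
    rlang::abort("excitatory population missing from rates", class = "spikevar_bad_grid")
  }
  structure(list(ax_E = ax_E, ax_P = ax_P, ax_S = ax_S, rates = rates,
                 excitatory = excitatory, meta = meta),
            class = "tf_grid")
}

#' @export
print.tf_grid <- function(x, ...) {
  cat("<tf_grid>", length(x$ax_E), "x", length(x$ax_P), "x", length(x$ax_S),
      "lattice;", length(x$rates), "population(s):",
      paste(names(x$rates), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a transfer-function grid
#'
#' @param x A `tf_grid`.
#' @param ... Unused.
#' @return A tibble with columns `dlambda_E`, `dlambda_P`, `dlambda_S` and
#'   one `rate_<pop>` column per population.
#' @export
as_tibble.tf_grid <- function(x, ...) {
  out <- tidyr::expand_grid(dlambda_S = x$ax_S, dlambda_P = x$ax_P,
                            dlambda_E = x$ax_E)[, c("dlambda_E", "dlambda_P", "dlambda_S")]
  for (nm in names(x$rates)) {
    out[[paste0("rate_", nm)]] <- as.vector(x$rates[[nm]])
  }
  out
}

#' Measure the transfer-function on a lattice of evoked inputs
#'
#' Runs the trial protocol at every lattice node of evoked modulations and
#' records the steady-state rate of every population, averaged over
#' `repetitions` independent input-noise seeds. Nodes whose final input
#' rates would be negative are carried as `NA` (invalid), never silently
#' zeroed.
#'
#' @param net A [build_network()] result.
#' @param spec An [input_spec()].
#' @param ax_E,ax_P,ax_S Axis vectors of evoked modulations (Hz).
#' @param protocol A [trial_protocol()].
#' @param repetitions Independent repetitions averaged per node.
#' @param dt Integration step (ms).
#' @param seed Integer seed.
#' @return A `tf_grid` with one rate volume per population.
#' @export
sweep_tf <- function(net, spec, ax_E, ax_P = 0, ax_S = 0,
                     protocol = trial_protocol(), repetitions = 3,
                     dt = 0.1, seed = 1L) {
  pops <- names(net$config$sizes)
  dims <- c(length(ax_E), length(ax_P), length(ax_S))
  rates <- lapply(stats::setNames(pops, pops), function(p) array(NA_real_, dims))
  for (k in seq_along(ax_S)) for (j in seq_along(ax_P)) for (i in seq_along(ax_E)) {
    delta <- c(E = ax_E[i], P = ax_P[j], S = ax_S[k])
    delta <- delta[channel_to_pop[names(delta)] %in% pops]
    final <- tryCatch(evoked_rates(spec, normalize_delta(delta)),
                      spikevar_negative_rate = function(e) NULL)
    if (is.null(final)) next
    node_rates <- matrix(0, repetitions, length(pops))
    for (r in seq_len(repetitions)) {
      rec <- run_trial(net, spec, delta = delta, protocol = protocol, dt = dt,
                       seed = derive_seed(seed, sprintf("tf-%d-%d-%d-%d", i, j, k, r)))
      node_rates[r, ] <- vapply(pops, function(p)
        population_rate(rec, p, protocol$measure_from_ms, protocol$total_ms),
        numeric(1))
    }
    for (pi in seq_along(pops)) {
      rates[[pops[pi]]][i, j, k] <- mean(node_rates[, pi])
    }
  }
  tf_grid(ax_E, ax_P, ax_S, rates,
          excitatory = net$config$excitatory[1],
          meta = list(seed = seed, repetitions = repetitions, dt = dt))
}

# per-axis interpolation bookkeeping: lower index, upper index, fraction
axis_coords <- function(ax, x, label) {
  n <- length(ax)
  eps <- 1e-9
  if (n == 1) {
    if (any(abs(x - ax) > eps)) {
      rlang::abort(paste0("query outside lattice hull on axis ", label),
                   class = "spikevar_out_of_hull")
    }
    return(list(i0 = rep(1L, length(x)), i1 = rep(1L, length(x)),
                f = rep(0, length(x))))
  }
  if (any(x < ax[1] - eps | x > ax[n] + eps)) {
    rlang::abort(paste0("query outside lattice hull on axis ", label),
                 class = "spikevar_out_of_hull")
  }
  i0 <- pmin(pmax(findInterval(x, ax), 1L), n - 1L)
  f <- (x - ax[i0]) / (ax[i0 + 1L] - ax[i0])
  f <- pmin(pmax(f, 0), 1)
  list(i0 = i0, i1 = i0 + 1L, f = f)
}

#' Trilinear interpolation of the transfer-function
#'
#' Interpolates each population's rate volume independently with a
#' trilinear (piecewise multilinear) scheme: exact at lattice nodes,
#' continuous across cell boundaries. Queries outside the lattice hull
#' raise an error of class `spikevar_out_of_hull`; there is no
#' extrapolation.
#'
#' @param grid A [tf_grid()].
#' @param query A data frame with columns `dlambda_E`, `dlambda_P`,
#'   `dlambda_S`, or a numeric vector of length 3, or a 3-column matrix.
#' @return A tibble with one `rate_<pop>` column per population and one row
#'   per query.
#' @export
interpolate_tf <- function(grid, query) {
  if (is.numeric(query) && is.null(dim(query))) query <- matrix(query, nrow = 1)
  if (is.matrix(query)) {
    query <- tibble::tibble(dlambda_E = query[, 1], dlambda_P = query[, 2],
                            dlambda_S = query[, 3])
  }
  cE <- axis_coords(grid$ax_E, query$dlambda_E, "E")
  cP <- axis_coords(grid$ax_P, query$dlambda_P, "P")
  cS <- axis_coords(grid$ax_S, query$dlambda_S, "S")
  dims <- c(length(grid$ax_E), length(grid$ax_P), length(grid$ax_S))
  corner <- function(arr, iE, iP, iS) arr[cbind(iE, iP, iS)]
  out <- tibble::tibble(.rows = nrow(query))
  for (nm in names(grid$rates)) {
    arr <- grid$rates[[nm]]
    v <- (1 - cE$f) * (1 - cP$f) * (1 - cS$f) * corner(arr, cE$i0, cP$i0, cS$i0) +
      cE$f * (1 - cP$f) * (1 - cS$f) * corner(arr, cE$i1, cP$i0, cS$i0) +
      (1 - cE$f) * cP$f * (1 - cS$f) * corner(arr, cE$i0, cP$i1, cS$i0) +
      cE$f * cP$f * (1 - cS$f) * corner(arr, cE$i1, cP$i1, cS$i0) +
      (1 - cE$f) * (1 - cP$f) * cS$f * corner(arr, cE$i0, cP$i0, cS$i1) +
      cE$f * (1 - cP$f) * cS$f * corner(arr, cE$i1, cP$i0, cS$i1) +
      (1 - cE$f) * cP$f * cS$f * corner(arr, cE$i0, cP$i1, cS$i1) +
      cE$f * cP$f * cS$f * corner(arr, cE$i1, cP$i1, cS$i1)
    out[[paste0("rate_", nm)]] <- v
  }
  out
}

#' Iso-firing-rate point set
#'
#' Densely samples the lattice hull on a regular refinement and returns the
#' points whose interpolated output rate of the chosen population lies
#' within `tol` of `level` (the point-set analogue of an iso-firing-rate
#' surface; with one axis held singleton it yields 2-D iso-rate contours).
#'
#' @param grid A [tf_grid()].
#' @param population Population whose rate defines the surface.
#' @param level Target rate (Hz).
#' @param tol Acceptance half-width (Hz).
#' @param n_per_axis Refinement points per (non-singleton) axis.
#' @return A tibble of accepted points with their interpolated rate; empty
#'   (with a warning) when `level` lies outside the grid's observed range.
#' @export
iso_rate_set <- function(grid, population, level, tol = 0.25, n_per_axis = 25) {
  arr <- grid$rates[[population]]
  rng <- range(arr, na.rm = TRUE)
  if (level < rng[1] || level > rng[2]) {
    rlang::warn("level outside the grid's observed rate range; empty set")
    return(tibble::tibble(dlambda_E = numeric(), dlambda_P = numeric(),
                          dlambda_S = numeric(), rate = numeric()))
  }
  refine <- function(ax) {
    if (length(ax) == 1) ax else seq(ax[1], ax[length(ax)], length.out = n_per_axis)
  }
  pts <- tidyr::expand_grid(dlambda_E = refine(grid$ax_E),
                            dlambda_P = refine(grid$ax_P),
                            dlambda_S = refine(grid$ax_S))
  r <- interpolate_tf(grid, pts)[[paste0("rate_", population)]]
  keep <- !is.na(r) & abs(r - level) <= tol
  out <- pts[keep, ]
  out$rate <- r[keep]
  out
}

#' Locate matched-rate operating-regime presets on a transfer-function grid
#'
#' Scans the lattice for three mean-input operating points with
#' approximately equal excitatory output rate but different inhibitory
#' composition: PV-dominated (high PV, low SST rate), SST-dominated (high
#' SST, low PV), and mixed (both intermediate). Rates are compared after
#' normalizing each interneuron volume to its own maximum; the excitatory
#' rates of the returned presets match the PV-dominated anchor within
#' `rate_match`.
#'
#' @param grid A `tf_grid` containing `PV` and `SST` rate volumes.
#' @param rate_match Relative excitatory-rate matching tolerance.
#' @param min_rate_E Minimum excitatory rate (Hz) for a node to qualify as an
#'   operating point; keeps the search off the silent floor of the grid.
#' @return A tibble with columns `regime`, `dlambda_E`, `dlambda_P`,
#'   `dlambda_S`, `rate_E`, `rate_PV`, `rate_SST`.
#' @export
find_regime_presets <- function(grid, rate_match = 0.2, min_rate_E = 1) {
  need <- c(grid$excitatory, "PV", "SST")
  if (!all(need %in% names(grid$rates))) {
    rlang::abort("grid must contain excitatory, PV and SST rate volumes",
                 class = "spikevar_bad_grid")
  }
  tb <- as_tibble.tf_grid(grid)
  e_col <- paste0("rate_", grid$excitatory)
  tb <- tb[stats::complete.cases(tb), ]
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  p <- norm(tb$rate_PV)
  s <- norm(tb$rate_SST)
  active <- tb[[e_col]] >= min_rate_E
  if (!any(active)) {
    rlang::abort("no lattice node reaches min_rate_E", class = "spikevar_bad_grid")
  }
  pick <- function(score, ok) {
    score[!ok] <- -Inf
    which.max(score)
  }
  pv_i <- pick(p - s, active)
  e_ref <- tb[[e_col]][pv_i]
  matched <- active & abs(tb[[e_col]] - e_ref) <= rate_match * max(e_ref, 1e-12)
  sst_i <- pick(s - p, matched)
  # mixed regime: both interneuron classes substantially active and balanced
  mix_i <- pick(pmin(p, s) - 0.5 * abs(p - s), matched)
  idx <- c(pv_i, sst_i, mix_i)
  tibble::tibble(
    regime = c("PV-dominated", "SST-dominated", "mixed"),
    dlambda_E = tb$dlambda_E[idx],
    dlambda_P = tb$dlambda_P[idx],
    dlambda_S = tb$dlambda_S[idx],
    rate_E = tb[[e_col]][idx],
    rate_PV = tb$rate_PV[idx],
    rate_SST = tb$rate_SST[idx])
}

#' Write a transfer-function grid in long CSV format
#'
#' Columns `dlambda_E`, `dlambda_P`, `dlambda_S` plus one rate column per
#' population.
#'
#' @param grid A `tf_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tf_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(as_tibble.tf_grid(grid)), path,
                   row.names = FALSE)
  invisible(path)
}
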