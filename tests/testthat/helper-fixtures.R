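# Shared fixtures built in code: small networks and synthetic
# transfer-function grids with known analytic structure.

tiny_unconnected <- function(pop = "PC", n = 50) {
  network_config(
    sizes = stats::setNames(n, pop),
    conn_prob = matrix(0, 1, 1, dimnames = list(pop, pop)),
    conductance = matrix(0, 1, 1, dimnames = list(pop, pop)),
    params = neuron_params(pop),
    excitatory = pop)
}

# linear transfer-function grid: rate = pmax(base + aE*dE - aP*dP - aS*dS, 0)
linear_tf_grid <- function(ax_E = seq(-4, 4, by = 2),
                           ax_P = seq(-4, 4, by = 2),
                           ax_S = seq(-4, 4, by = 2),
                           base = 10, aE = 1, aP = 0.5, aS = 0.25) {
  f <- function(dE, dP, dS) pmax(base + aE * dE - aP * dP - aS * dS, 0)
  arr <- array(0, c(length(ax_E), length(ax_P), length(ax_S)))
  for (k in seq_along(ax_S)) for (j in seq_along(ax_P)) for (i in seq_along(ax_E)) {
    arr[i, j, k] <- f(ax_E[i], ax_P[j], ax_S[k])
  }
  tf_grid(ax_E, ax_P, ax_S, rates = list(PC = arr), excitatory = "PC")
}

# smooth nonlinear grid over a fine lattice (for delta-method comparisons)
smooth_tf_grid <- function(n_per_axis = 9, half_width = 3) {
  ax <- seq(-half_width, half_width, length.out = n_per_axis)
  f <- function(dE, dP, dS) {
    14 + 2.0 * dE - 1.2 * dP - 0.6 * dS + 0.15 * dE * dP + 0.05 * dE^2
  }
  arr <- array(0, c(n_per_axis, n_per_axis, n_per_axis))
  for (k in seq_len(n_per_axis)) for (j in seq_len(n_per_axis)) for (i in seq_len(n_per_axis)) {
    arr[i, j, k] <- f(ax[i], ax[j], ax[k])
  }
  stopifnot(all(arr > 0))
  tf_grid(ax, ax, ax, rates = list(PC = arr), excitatory = "PC")
}

# independent trilinear oracle, written as the closed-form weight formula
trilinear_oracle <- function(ax_E, ax_P, ax_S, arr, q) {
  loc <- function(ax, x) {
    i <- max(which(ax <= x + 1e-12))
    i <- min(i, length(ax) - 1)
    list(i = i, f = (x - ax[i]) / (ax[i + 1] - ax[i]))
  }
  lE <- loc(ax_E, q[1]); lP <- loc(ax_P, q[2]); lS <- loc(ax_S, q[3])
  v <- 0
  for (dE in 0:1) for (dP in 0:1) for (dS in 0:1) {
    wt <- (if (dE) lE$f else 1 - lE$f) *
      (if (dP) lP$f else 1 - lP$f) *
      (if (dS) lS$f else 1 - lS$f)
    v <- v + wt * arr[lE$i + dE, lP$i + dP, lS$i + dS]
  }
  v
}
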