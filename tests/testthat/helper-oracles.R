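# Independent oracles, deliberately avoiding the package's code paths.

# Direct-summation Shannon entropy in bits
entropy_oracle <- function(p) {
  acc <- 0
  for (pi in p) if (pi > 0) acc <- acc - pi * (log(pi) / log(2))
  acc
}

# Fixed-step classical RK4 on the coupled-trait system, built on the exported
# R right-hand side (the adaptive path under test integrates compiled code)
rk4_integrate <- function(params, init, times, h = 1e-3) {
  y <- c(N = init$N0, P = init$P0, E_stress = init$E0)
  t <- init$t0
  out <- matrix(NA_real_, length(times), 3L,
                dimnames = list(NULL, names(y)))
  for (k in seq_along(times)) {
    while (t < times[k] - 1e-12) {
      step <- min(h, times[k] - t)
      k1 <- ecto_rhs(t, y, params, t0 = init$t0)
      k2 <- ecto_rhs(t + step / 2, y + step / 2 * k1, params, t0 = init$t0)
      k3 <- ecto_rhs(t + step / 2, y + step / 2 * k2, params, t0 = init$t0)
      k4 <- ecto_rhs(t + step, y + step * k3, params, t0 = init$t0)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      names(y) <- c("N", "P", "E_stress")
      t <- t + step
    }
    out[k, ] <- y
  }
  out
}

# Exhaustive minimization over all monotone boundary-matched warping paths
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
  }
  rec(1L, 1L, 0)
  best
}

# Reference parameterization of the qualitative demonstration system
set3_params <- function() {
  ecto_params(mu = 0.00001, alpha = 0.098, beta = 0.17117, gamma = 0.03,
              c1 = 2.0, c2 = 0.21, c3 = 0, K = 0.5, G = 1)
}

set3_init <- function() ecto_init(N0 = 0.9, P0 = 0.93, E0 = 0.01, t0 = 0)

# Synthetic study conditions shared by recovery / contrast experiments
recovery_spec <- function() {
  ecto_spec(free = c("alpha", "beta", "gamma"),
            fixed = c(mu = 0.1, c1 = 0.5, c2 = 0.2, c3 = 1.0,
                      K = 0.5, G = 1, E0 = 0.05))
}
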