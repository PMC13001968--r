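#' ECTO model parameters
#'
#' Constructs the full coefficient set of the three-state coupled-trait ODE
#' system. The states are `N` (primary trait-like state), `P` (secondary
#' coupled state) and `E_stress` (latent environmental stress):
#' \deqn{dN/dt = \mu N - (\alpha N + \beta^2 P)\,N}
#' \deqn{dP/dt = \mu P - \beta P\,(c_1 P + c_2 N + c_3 E)/G}
#' \deqn{dE/dt = \gamma E\, N/(N + K)}
#' With forcing enabled, `E` inside the metabolic-cost aggregate is replaced
#' by `E + A sin(omega (t - t0))`; the `E_stress` ODE itself is unforced.
#'
#' @param mu Baseline influx/persistence rate shared by `N` and `P`
#'   (per year).
#' @param alpha Self-limitation coefficient of `N`.
#' @param beta Cross-coupling coefficient; squared in the `N` equation so the
#'   coupling damps regardless of sign.
#' @param gamma Stress amplification rate (per year).
#' @param c1,c2,c3 Metabolic-cost weights on `P`, `N` and `E_stress`.
#' @param K Positive saturation constant of the stress kernel `N/(N+K)`.
#' @param G Positive capacity normalization constant (default 1).
#' @param A,omega Sinusoidal forcing amplitude (dimensionless) and angular
#'   frequency (radians per year); inert unless `forcing = TRUE`.
#' @param forcing Logical; add `A sin(omega (t - t0))` to the stress term
#'   inside the metabolic cost.
#' @param coupled Logical; `FALSE` selects the uncoupled null model, which
#'   zeroes every `N`–`P` pathway (`beta`, `c2`, `c3`) so `N` follows a pure
#'   logistic law and `P` pure exponential persistence.
#' @return A list of class `"ecto_params"`.
#' @examples
#' p <- ecto_params(mu = 1e-5, alpha = 0.098, beta = 0.17117, gamma = 0.03,
#'                  c1 = 2, c2 = 0.21, K = 0.5)
#' @export
ecto_params <- function(mu = 0, alpha = 0, beta = 0, gamma = 0,
                        c1 = 0, c2 = 0, c3 = 0, K = 0.5, G = 1,
                        A = 1, omega = 1, forcing = FALSE, coupled = TRUE) {
  p <- list(mu = mu, alpha = alpha, beta = beta, gamma = gamma,
            c1 = c1, c2 = c2, c3 = c3, K = K, G = G, A = A, omega = omega,
            forcing = isTRUE(forcing), coupled = isTRUE(coupled))
  num <- unlist(p[ecto_param_names()])
  if (anyNA(num) || any(!is.finite(num))) {
    stop("all ECTO parameters must be finite", call. = FALSE)
  }
  if (p$K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (p$G <= 0) stop("`G` must be > 0", call. = FALSE)
  if (!p$coupled) {
    p$beta <- 0; p$c2 <- 0; p$c3 <- 0
  }
  class(p) <- "ecto_params"
  p
}

ecto_param_names <- function() {
  c("mu", "alpha", "beta", "gamma", "c1", "c2", "c3", "K", "G", "A", "omega")
}

#' @export
print.ecto_params <- function(x, ...) {
  cat("ECTO parameters (", if (x$coupled) "coupled" else "uncoupled",
      if (x$forcing) ", sinusoidal forcing" else "", ")\n", sep = "")
  v <- unlist(x[ecto_param_names()])
  print(signif(v, 6))
  invisible(x)
}

#' Initial condition of the ECTO system
#'
#' The primary state is initialized from data: `N0` is set to the pooled (or
#' item-level) normalized entropy at the first observed wave; `P0` and `E0`
#' are small positive constants or fitted baselines.
#'
#' @param N0,P0,E0 Nonnegative starting values of the three states.
#' @param t0 Time of the first wave, in years (internal model time is
#'   `t - t0`).
#' @return A list of class `"ecto_init"`.
#' @export
ecto_init <- function(N0, P0 = 0.01, E0 = 0.01, t0 = 0) {
  v <- c(N0 = N0, P0 = P0, E0 = E0, t0 = t0)
  if (anyNA(v) || any(!is.finite(v))) stop("initial condition must be finite", call. = FALSE)
  if (any(v[c("N0", "P0", "E0")] < 0)) {
    stop("initial states must be nonnegative", call. = FALSE)
  }
  structure(list(N0 = N0, P0 = P0, E0 = E0, t0 = t0), class = "ecto_init")
}

#' Selection pressure term
#'
#' The constraint `s(N, P) = alpha * N + beta^2 * P` damping the growth of
#' the primary state. The square on `beta` makes the cross-coupling a
#' nonnegative damping contribution for either sign of `beta`.
#'
#' @param N,P State values.
#' @param params An [ecto_params()] object.
#' @return The selection pressure (a rate).
#' @export
selection_pressure <- function(N, P, params) {
  stopifnot(inherits(params, "ecto_params"))
  if (!all(is.finite(c(N, P)))) stop("non-finite state", call. = FALSE)
  params$alpha * N + params$beta^2 * P
}

#' Metabolic cost aggregate
#'
#' The accounting variable `c1*P + c2*N + c3*E_stress` that damps the
#' secondary state. With forcing enabled the stress component is augmented by
#' `A sin(omega (t - t0))` before weighting by `c3`.
#'
#' @param state Named numeric vector or list with `N`, `P`, `E_stress`.
#' @param params An [ecto_params()] object.
#' @param t Time in years (only relevant under forcing).
#' @param t0 Time origin for the forcing phase.
#' @return The metabolic cost level.
#' @export
metabolic_cost <- function(state, params, t = 0, t0 = 0) {
  stopifnot(inherits(params, "ecto_params"))
  s <- as.list(state)
  E <- s$E_stress
  if (!all(is.finite(c(s$N, s$P, E, t)))) stop("non-finite state", call. = FALSE)
  if (params$forcing) E <- E + params$A * sin(params$omega * (t - t0))
  params$c1 * s$P + params$c2 * s$N + params$c3 * E
}

#' Right-hand side of the ECTO ODE system
#'
#' Evaluates the derivative of the state `(N, P, E_stress)` at time `t`. This
#' is the reference R implementation; [ecto_simulate()] integrates an
#' equivalent compiled version.
#'
#' @param t Time in years.
#' @param state Named numeric vector or list with `N`, `P`, `E_stress`.
#' @param params An [ecto_params()] object.
#' @param t0 Time origin for the forcing phase.
#' @return Named numeric vector `(dN, dP, dE_stress)`.
#' @export
ecto_rhs <- function(t, state, params, t0 = 0) {
  stopifnot(inherits(params, "ecto_params"))
  s <- as.list(state)
  if (!all(is.finite(c(s$N, s$P, s$E_stress)))) {
    stop(sprintf("non-finite state at t = %g", t), call. = FALSE)
  }
  dN <- params$mu * s$N - selection_pressure(s$N, s$P, params) * s$N
  dP <- params$mu * s$P -
    params$beta * s$P * metabolic_cost(s, params, t, t0) / params$G
  dE <- params$gamma * s$E_stress * s$N / (s$N + params$K)
  c(dN = dN, dP = dP, dE_stress = dE)
}

#' Integrate the ECTO system
#'
#' Simulates the autonomous system forward from an initial condition with an
#' adaptive explicit Runge--Kutta scheme (Dormand--Prince 4(5) via deSolve;
#' relative tolerance 1e-8, absolute 1e-10), evaluated at the requested
#' times. A blow-up guard converts numerical overflow (any |state| above
#' 1e12, or solver failure) into a structured error of class
#' `"ecto_simulation_error"`.
#'
#' @param params An [ecto_params()] object.
#' @param init An [ecto_init()] object; `times[1]` must be `>= init$t0`.
#' @param times Strictly increasing evaluation times in years.
#' @param rtol,atol Integration tolerances.
#' @return Data frame of class `"ecto_trajectory"` with columns `time`, `N`,
#'   `P`, `E_stress`; attributes `params` and `init` record the inputs.
#' @examples
#' p <- ecto_params(alpha = 0.5)
#' tr <- ecto_simulate(p, ecto_init(N0 = 1, P0 = 0, E0 = 0), times = c(0, 2))
#' tr$N[2]  # closed form: 1 / (1 + 0.5 * 2)
#' @export
ecto_simulate <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ecto_params"), inherits(init, "ecto_init"))
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("`times` must be non-empty and strictly increasing", call. = FALSE)
  }
  if (times[1L] < init$t0 - 1e-12) {
    stop("`times` must start at or after `init$t0`", call. = FALSE)
  }
  y0 <- c(N = init$N0, P = init$P0, E_stress = init$E0)
  solve_times <- times
  prepend <- FALSE
  if (times[1L] > init$t0 + 1e-12) {
    solve_times <- c(init$t0, times)  # integration always starts at t0
    prepend <- TRUE
  }
  if (length(solve_times) == 1L) {
    out <- data.frame(time = solve_times, N = init$N0, P = init$P0,
                      E_stress = init$E0)
  } else {
    parms <- c(unlist(params[ecto_param_names()]),
               t0 = init$t0, forcing = as.numeric(params$forcing))
    sol <- try(suppressWarnings(
      deSolve::ode(y = y0, times = solve_times, parms = parms,
                   func = "ecto_derivs", dllname = "ecto",
                   initfunc = "ecto_initmod", method = "ode45",
                   rtol = rtol, atol = atol, maxsteps = 5000)),
      silent = TRUE)
    fail <- inherits(sol, "try-error") || nrow(sol) < length(solve_times) ||
      anyNA(sol) || any(!is.finite(sol)) || any(abs(sol[, -1L]) > 1e12)
    if (fail) {
      stop(structure(class = c("ecto_simulation_error", "error", "condition"),
                     list(message = paste0(
                       "ECTO integration failed or blew up (|state| > 1e12); ",
                       "last good time ",
                       if (inherits(sol, "try-error")) "unknown"
                       else format(max(sol[is.finite(rowSums(sol)), 1L]))),
                       call = sys.call(-1L))))
    }
    out <- as.data.frame(unclass(sol))
    names(out) <- c("time", "N", "P", "E_stress")
    if (prepend) out <- out[-1L, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "params") <- params
  attr(out, "init") <- init
  class(out) <- c("ecto_trajectory", "data.frame")
  out
}

#' @export
print.ecto_trajectory <- function(x, ...) {
  cat("ECTO trajectory:", nrow(x), "time points over [",
      format(x$time[1L]), ",", format(x$time[nrow(x)]), "] years\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
plot.ecto_trajectory <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$N, x$P, x$E_stress), type = "l", lty = 1,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "time (years)", ylab = "state", ...)
  graphics::legend("topright", legend = c("N", "P", "E_stress"), lty = 1,
                   col = c("black", "firebrick", "steelblue"), bty = "n")
  invisible(x)
}
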