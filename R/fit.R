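#' Observed two-trait entropy trajectories
#'
#' Bundles the wave times and the two entropy series mapped to the model
#' states `N` and `P` (typically normalized entropies on `[0, 1]`).
#'
#' @param wave_times Strictly increasing observation times (years).
#' @param n_obs,p_obs Observed values for the `N`- and `P`-mapped traits.
#' @return Data frame of class `"ecto_observed"` with columns `wave_time`,
#'   `n_obs`, `p_obs`.
#' @export
ecto_observed <- function(wave_times, n_obs, p_obs) {
  if (length(wave_times) != length(n_obs) || length(n_obs) != length(p_obs)) {
    stop("`wave_times`, `n_obs`, `p_obs` must have equal lengths", call. = FALSE)
  }
  if (any(diff(wave_times) <= 0)) {
    stop("`wave_times` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(c(wave_times, n_obs, p_obs))) stop("missing values", call. = FALSE)
  out <- data.frame(wave_time = wave_times, n_obs = n_obs, p_obs = p_obs)
  class(out) <- c("ecto_observed", "data.frame")
  out
}

#' Map two items of an entropy table to observed model trajectories
#'
#' Selects the two items to be modeled, picks the fitting scale, and returns
#' an [ecto_observed()] object.
#'
#' @param entropy An `"ecto_entropy"` data frame from [likert_entropy()] or
#'   [dental_entropy()].
#' @param n_item,p_item Item ids mapped to the `N` and `P` states.
#' @param scale `"norm"` fits normalized entropies in `[0, 1]` (default);
#'   `"bits"` fits raw entropies.
#' @return An `"ecto_observed"` object with attribute `scale`.
#' @export
entropy_to_observed <- function(entropy, n_item, p_item,
                                scale = c("norm", "bits")) {
  scale <- match.arg(scale)
  col <- if (scale == "norm") "entropy_norm" else "entropy_bits"
  pick <- function(item) {
    d <- entropy[entropy$item_id == item, , drop = FALSE]
    if (nrow(d) == 0) stop("item not found: ", item, call. = FALSE)
    d[order(d$wave_time), , drop = FALSE]
  }
  dn <- pick(n_item); dp <- pick(p_item)
  if (!isTRUE(all.equal(dn$wave_time, dp$wave_time))) {
    stop("the two items are not on a common wave grid", call. = FALSE)
  }
  out <- ecto_observed(dn$wave_time, dn[[col]], dp[[col]])
  attr(out, "scale") <- scale
  attr(out, "items") <- c(n = n_item, p = p_item)
  out
}

#' Sum-of-squared-errors objective
#'
#' Simulates the model at the observation times and returns
#' \eqn{\sum_k (N(t_k)-n_k)^2 + \sum_k (P(t_k)-p_k)^2}. A failed or
#' blown-up simulation maps to a large finite penalty (1e6) so bounded
#' optimizers can continue past pathological trial points.
#'
#' @param params An [ecto_params()] object.
#' @param init An [ecto_init()] object.
#' @param obs An [ecto_observed()] object.
#' @param penalty Value returned when simulation fails.
#' @return Nonnegative squared error (or `penalty`).
#' @export
sse_objective <- function(params, init, obs, penalty = 1e6) {
  stopifnot(inherits(obs, "ecto_observed"))
  tr <- tryCatch(ecto_simulate(params, init, obs$wave_time),
                 error = function(e) NULL)
  if (is.null(tr)) return(penalty)
  sum((tr$N - obs$n_obs)^2) + sum((tr$P - obs$p_obs)^2)
}

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Resolve the (N0, P0) initialization policies against the data and return
# the working parameter table (spec rows + possibly overridden values/freedom)
resolve_spec <- function(spec, obs, n0_policy, p0_policy,
                         n0_value = NULL, p0_value = NULL) {
  s <- as.data.frame(spec)
  set_policy <- function(s, par, policy, value, data_value) {
    switch(policy,
      data = { s[par, "free"] <- FALSE; s[par, "value"] <- data_value },
      free = { s[par, "free"] <- TRUE },
      constant = {
        if (is.null(value)) stop("policy 'constant' needs a value for ", par,
                                 call. = FALSE)
        s[par, "free"] <- FALSE; s[par, "value"] <- value
      })
    s
  }
  s <- set_policy(s, "N0", n0_policy, n0_value, obs$n_obs[1L])
  s <- set_policy(s, "P0", p0_policy, p0_value, obs$p_obs[1L])
  s$value[s$free] <- pmin(pmax(s$value[s$free], s$lower[s$free]), s$upper[s$free])
  attr(s, "forcing") <- attr(spec, "forcing")
  attr(s, "coupled") <- attr(spec, "coupled")
  s
}

# Build ecto_params + ecto_init from a full named parameter vector
assemble_model <- function(values, forcing, coupled, t0) {
  p <- ecto_params(mu = values[["mu"]], alpha = values[["alpha"]],
                   beta = values[["beta"]], gamma = values[["gamma"]],
                   c1 = values[["c1"]], c2 = values[["c2"]],
                   c3 = values[["c3"]], K = values[["K"]], G = values[["G"]],
                   A = values[["A"]], omega = values[["omega"]],
                   forcing = forcing, coupled = coupled)
  list(params = p,
       init = ecto_init(N0 = values[["N0"]], P0 = values[["P0"]],
                        E0 = values[["E0"]], t0 = t0))
}

make_objective <- function(s, obs, t0, penalty = 1e6) {
  free_names <- rownames(s)[s$free]
  values <- stats::setNames(s$value, rownames(s))
  forcing <- isTRUE(attr(s, "forcing"))
  coupled <- isTRUE(attr(s, "coupled"))
  function(theta) {
    v <- values
    v[free_names] <- theta
    m <- tryCatch(assemble_model(v, forcing, coupled, t0),
                  error = function(e) NULL)
    if (is.null(m)) return(penalty)
    sse_objective(m$params, m$init, obs, penalty = penalty)
  }
}

fit_one_start <- function(objective, start, lower, upper, control) {
  res <- tryCatch(
    stats::optim(par = start, fn = objective, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = control),
    error = function(e) NULL)
  if (is.null(res)) {
    f0 <- objective(start)
    return(list(par = start, value = f0, convergence = 1L, failed = TRUE))
  }
  res$failed <- FALSE
  res
}

#' Fit the ECTO model by bounded multistart least squares
#'
#' Estimates the free parameters of the coupled-trait ODE system by
#' minimizing the summed squared error between the simulated `(N, P)`
#' trajectories and the two observed entropy series, using `L-BFGS-B` within
#' box bounds, restarted from `n_starts` uniform-in-bounds random
#' initializations (seeded, reproducible).
#'
#' The primary state is initialized from data: by default `N0` is pinned to
#' the first observed `N`-trait value and `P0` to the first observed
#' `P`-trait value; either can instead be declared `"free"` (estimated
#' within `[0, 1]`-type bounds, used e.g. when the first wave is held out)
#' or `"constant"`.
#'
#' @param obs An [ecto_observed()] object (see [entropy_to_observed()]).
#' @param spec An [ecto_spec()] describing free/fixed parameters and bounds;
#'   defaults to the fully free specification.
#' @param n_starts Number of random multistart initializations (>= 1).
#' @param seed Integer seed governing the start draws.
#' @param n0_policy,p0_policy Initialization policy for `N0`/`P0`: `"data"`
#'   (pin to first observed value), `"free"`, or `"constant"`.
#' @param n0_value,p0_value Values used under the `"constant"` policy.
#' @param t0 Time origin of the simulation; defaults to the first wave time.
#' @param control Passed to [stats::optim()] (merged over defaults
#'   `maxit = 300`, `factr = 1e7`, and a finite-difference step `ndeps` of
#'   1e-6 per free parameter).
#' @param penalty Objective value substituted on simulation failure.
#' @return Object of class `"ecto_fit"`: a list with the best `params` and
#'   `init`, estimated free-parameter vector `par`, `sse`, per-trait
#'   `metrics`, multistart SSE distribution (`sse_starts`, `start_stats`),
#'   convergence codes, and the inputs needed to re-simulate.
#' @examples
#' obs <- entropy_to_observed(dental_entropy(), "supp", "time")
#' fit <- ecto_fit(obs, ecto_spec_reduced(), n_starts = 4, seed = 1)
#' coef(fit)
#' @export
ecto_fit <- function(obs, spec = ecto_spec_full(), n_starts = 32,
                     seed = 20260319,
                     n0_policy = c("data", "free", "constant"),
                     p0_policy = c("data", "free", "constant"),
                     n0_value = NULL, p0_value = NULL,
                     t0 = NULL, control = list(), penalty = 1e6) {
  stopifnot(inherits(obs, "ecto_observed"), inherits(spec, "ecto_spec"))
  n0_policy <- match.arg(n0_policy)
  p0_policy <- match.arg(p0_policy)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  if (is.null(t0)) t0 <- obs$wave_time[1L]
  s <- resolve_spec(spec, obs, n0_policy, p0_policy, n0_value, p0_value)
  free_names <- rownames(s)[s$free]
  objective <- make_objective(s, obs, t0, penalty)
  if (length(free_names) == 0) {
    # nothing to estimate: evaluate the fully fixed model
    return(finish_fit(list(par = numeric(0), value = objective(numeric(0)),
                           convergence = 0L, failed = FALSE),
                      character(0), s, obs, t0, penalty,
                      n_starts = 0L, seed = NA_integer_,
                      sse_starts = numeric(0), control = control))
  }
  lower <- s[free_names, "lower"]; upper <- s[free_names, "upper"]
  ctrl <- utils::modifyList(
    list(maxit = 300, factr = 1e7, ndeps = rep(1e-6, length(free_names))),
    control)

  # Draw uniform-in-bounds random starts sequentially from the seeded
  # stream; candidates already sitting at the blow-up penalty give the
  # optimizer no gradient, so they are redrawn (up to 20 draws per start,
  # after which the penalized candidate is kept). Sequential draws keep the
  # accepted-start sequence prefix-stable when `n_starts` is extended.
  starts <- with_seed(seed, {
    out <- matrix(NA_real_, n_starts, length(free_names))
    for (i in seq_len(n_starts)) {
      for (try in seq_len(20L)) {
        cand <- lower + stats::runif(length(free_names)) * (upper - lower)
        if (objective(cand) < penalty) break
      }
      out[i, ] <- cand
    }
    out
  })
  runs <- lapply(seq_len(n_starts), function(i) {
    fit_one_start(objective, starts[i, ], lower, upper, ctrl)
  })
  if (all(vapply(runs, `[[`, logical(1), "failed"))) {
    stop("all multistart optimizations failed", call. = FALSE)
  }
  sse_starts <- vapply(runs, `[[`, numeric(1), "value")
  best_i <- which.min(sse_starts)
  finish_fit(runs[[best_i]], free_names, s, obs, t0, penalty,
             n_starts = n_starts, seed = seed, sse_starts = sse_starts,
             control = ctrl, best_start = best_i)
}

# Assemble the "ecto_fit" object from the winning optimizer run
finish_fit <- function(best, free_names, s, obs, t0, penalty,
                       n_starts, seed, sse_starts, control,
                       best_start = 1L) {
  par <- stats::setNames(best$par, free_names)
  values <- stats::setNames(s$value, rownames(s))
  values[free_names] <- par
  model <- assemble_model(values, isTRUE(attr(s, "forcing")),
                          isTRUE(attr(s, "coupled")), t0)
  traj <- tryCatch(ecto_simulate(model$params, model$init, obs$wave_time),
                   error = function(e) NULL)
  metrics <- if (is.null(traj)) list(n = NULL, p = NULL) else list(
    n = tryCatch(fit_metrics(obs$n_obs, traj$N), error = function(e) NULL),
    p = tryCatch(fit_metrics(obs$p_obs, traj$P), error = function(e) NULL))
  if (length(sse_starts) == 0L) sse_starts <- best$value
  out <- list(par = par, values = values, params = model$params,
              init = model$init, spec = s, obs = obs, t0 = t0,
              sse = best$value, fitted_waves = traj, metrics = metrics,
              convergence = best$convergence,
              converged = !best$failed && best$convergence == 0L &&
                !is.null(traj) && best$value < penalty,
              n_starts = n_starts, seed = seed, sse_starts = sse_starts,
              start_stats = c(mean = mean(sse_starts),
                              sd = if (length(sse_starts) > 1L)
                                stats::sd(sse_starts) else 0,
                              min = min(sse_starts), max = max(sse_starts)),
              best_start = best_start, control = control, penalty = penalty,
              scale = attr(obs, "scale"))
  class(out) <- "ecto_fit"
  out
}

#' Fit from a single given start (no multistart)
#'
#' Deterministic single-start variant of [ecto_fit()]: runs one bounded
#' `L-BFGS-B` descent from `start` (a named vector over the free
#' parameters; defaults to the spec's start values).
#'
#' @inheritParams ecto_fit
#' @param start Named numeric vector of starting values for the free
#'   parameters; must lie within bounds.
#' @return An `"ecto_fit"` object with `n_starts = 1`.
#' @export
ecto_fit_single <- function(obs, spec = ecto_spec_full(), start = NULL,
                            n0_policy = c("data", "free", "constant"),
                            p0_policy = c("data", "free", "constant"),
                            n0_value = NULL, p0_value = NULL,
                            t0 = NULL, control = list(), penalty = 1e6) {
  stopifnot(inherits(obs, "ecto_observed"), inherits(spec, "ecto_spec"))
  n0_policy <- match.arg(n0_policy)
  p0_policy <- match.arg(p0_policy)
  if (is.null(t0)) t0 <- obs$wave_time[1L]
  s <- resolve_spec(spec, obs, n0_policy, p0_policy, n0_value, p0_value)
  free_names <- rownames(s)[s$free]
  if (length(free_names) == 0) {
    objective <- make_objective(s, obs, t0, penalty)
    return(finish_fit(list(par = numeric(0), value = objective(numeric(0)),
                           convergence = 0L, failed = FALSE),
                      character(0), s, obs, t0, penalty,
                      n_starts = 0L, seed = NA_integer_,
                      sse_starts = numeric(0), control = control))
  }
  lower <- s[free_names, "lower"]; upper <- s[free_names, "upper"]
  if (is.null(start)) {
    start <- stats::setNames(s[free_names, "value"], free_names)
  } else {
    if (!all(free_names %in% names(start))) {
      stop("`start` must name every free parameter", call. = FALSE)
    }
    start <- start[free_names]
  }
  if (any(start < lower - 1e-12) || any(start > upper + 1e-12)) {
    stop("start value outside bounds", call. = FALSE)
  }
  objective <- make_objective(s, obs, t0, penalty)
  ctrl <- utils::modifyList(
    list(maxit = 300, factr = 1e7, ndeps = rep(1e-6, length(free_names))),
    control)
  best <- fit_one_start(objective, as.numeric(start), lower, upper, ctrl)
  finish_fit(best, free_names, s, obs, t0, penalty,
             n_starts = 1L, seed = NA_integer_, sse_starts = best$value,
             control = ctrl)
}

#' @export
print.ecto_fit <- function(x, digits = 4, ...) {
  cat("ECTO model fit (", if (attr(x$spec, "coupled")) "coupled" else "uncoupled",
      "; ", length(x$par), " free parameters; ", x$n_starts, " start",
      if (x$n_starts > 1) "s", ")\n", sep = "")
  cat("  SSE:", format(x$sse, digits = digits), "\n")
  if (!is.null(x$metrics$n)) {
    cat(sprintf("  N trait: RMSE %.4f, R^2 %.4f\n",
                x$metrics$n["rmse"], x$metrics$n["r_squared"]))
  }
  if (!is.null(x$metrics$p)) {
    cat(sprintf("  P trait: RMSE %.4f, R^2 %.4f\n",
                x$metrics$p["rmse"], x$metrics$p["r_squared"]))
  }
  cat("  Estimates:\n")
  print(signif(x$par, digits))
  invisible(x)
}

#' @export
summary.ecto_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ecto_fit")
}

#' @export
print.summary.ecto_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("  Initial condition: N0 =", format(f$init$N0, digits = digits),
      ", P0 =", format(f$init$P0, digits = digits),
      ", E0 =", format(f$init$E0, digits = digits),
      " (t0 =", format(f$t0), ")\n")
  if (f$n_starts > 1) {
    cat("  Multistart SSE: mean", format(f$start_stats["mean"], digits = digits),
        "sd", format(f$start_stats["sd"], digits = 2),
        "min", format(f$start_stats["min"], digits = digits),
        "max", format(f$start_stats["max"], digits = digits), "\n")
  }
  cat("  Converged:", f$converged, "(optim code", f$convergence, ")\n")
  invisible(x)
}

#' @export
coef.ecto_fit <- function(object, all = FALSE, ...) {
  if (all) object$values else object$par
}

#' Simulate the fitted system at new times
#'
#' @param object An `"ecto_fit"`.
#' @param times Evaluation times (years); defaults to the observation waves.
#' @param ... Unused.
#' @return An `"ecto_trajectory"` data frame.
#' @export
predict.ecto_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$obs$wave_time
  ecto_simulate(object$params, object$init, times)
}

#' @export
fitted.ecto_fit <- function(object, ...) {
  if (is.null(object$fitted_waves)) {
    stop("fit did not produce a valid trajectory (all starts penalized)",
         call. = FALSE)
  }
  data.frame(wave_time = object$obs$wave_time,
             n_fit = object$fitted_waves$N,
             p_fit = object$fitted_waves$P)
}

#' @export
residuals.ecto_fit <- function(object, ...) {
  if (is.null(object$fitted_waves)) {
    stop("fit did not produce a valid trajectory (all starts penalized)",
         call. = FALSE)
  }
  data.frame(wave_time = object$obs$wave_time,
             n_resid = object$obs$n_obs - object$fitted_waves$N,
             p_resid = object$obs$p_obs - object$fitted_waves$P)
}

#' @export
plot.ecto_fit <- function(x, n_grid = 200, ...) {
  tt <- seq(x$t0, max(x$obs$wave_time), length.out = n_grid)
  tr <- predict(x, times = tt)
  ylim <- range(x$obs$n_obs, x$obs$p_obs, tr$N, tr$P)
  graphics::plot(x$obs$wave_time, x$obs$n_obs, pch = 16, ylim = ylim,
                 xlab = "time (years)", ylab = "entropy index",
                 col = "black", ...)
  graphics::points(x$obs$wave_time, x$obs$p_obs, pch = 17, col = "firebrick")
  graphics::lines(tr$time, tr$N, col = "black")
  graphics::lines(tr$time, tr$P, col = "firebrick")
  graphics::legend("bottomright", legend = c("N (obs/fit)", "P (obs/fit)"),
                   col = c("black", "firebrick"), pch = c(16, 17), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Simulate new observation sets from a fitted model
#'
#' Draws `nsim` replicate observation sets: the fitted trajectory at the
#' observation waves plus iid Gaussian noise with the residual standard
#' deviation (pooled over both traits), mirroring the generative model used
#' for parameter-recovery experiments.
#'
#' @param object An `"ecto_fit"`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [ecto_observed()] objects.
#' @export
simulate.ecto_fit <- function(object, nsim = 1, seed = NULL, ...) {
  r <- residuals(object)
  sdhat <- stats::sd(c(r$n_resid, r$p_resid))
  gen <- function() {
    ecto_observed(object$obs$wave_time,
                  object$fitted_waves$N + stats::rnorm(nrow(r), 0, sdhat),
                  object$fitted_waves$P + stats::rnorm(nrow(r), 0, sdhat))
  }
  if (is.null(seed)) replicate(nsim, gen(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
}
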