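#' Leave-one-wave-out forecast validation
#'
#' For each wave, refits the model on the remaining waves and predicts the
#' held-out wave by forward simulation over the full time span. When the
#' first wave is held out, the data-pinned initial conditions `N0`/`P0`
#' become free parameters (the data-based initialization is undefined
#' without wave 1); the time origin stays at the first wave.
#'
#' @param obs An [ecto_observed()] object with at least 3 waves.
#' @param spec An [ecto_spec()].
#' @param n_starts,seed Multistart settings for each fold's refit.
#' @param ... Further arguments passed to [ecto_fit()] (e.g. `control`).
#' @return Object of class `"ecto_loo"`: a list with `folds` (data frame of
#'   per-fold observed/predicted values and failure flags) and `rmse`
#'   (aggregate held-out RMSE per trait, pooling squared residuals across
#'   folds before the root).
#' @export
loo_validate <- function(obs, spec = ecto_spec_full(), n_starts = 8,
                         seed = 20260319, ...) {
  stopifnot(inherits(obs, "ecto_observed"))
  W <- nrow(obs)
  if (W < 3L) stop("need at least 3 waves for leave-one-wave-out", call. = FALSE)
  t0 <- obs$wave_time[1L]
  folds <- lapply(seq_len(W), function(w) {
    train <- obs[-w, , drop = FALSE]
    class(train) <- c("ecto_observed", "data.frame")
    first_held <- w == 1L
    fit <- tryCatch(
      ecto_fit(train, spec, n_starts = n_starts, seed = seed + w,
               n0_policy = if (first_held) "free" else "data",
               p0_policy = if (first_held) "free" else "data",
               t0 = t0, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(wave_time = obs$wave_time[w],
                        n_obs = obs$n_obs[w], p_obs = obs$p_obs[w],
                        n_pred = NA_real_, p_pred = NA_real_, failed = TRUE))
    }
    pred <- tryCatch(predict(fit, times = obs$wave_time),
                     error = function(e) NULL)
    if (is.null(pred)) {
      return(data.frame(wave_time = obs$wave_time[w],
                        n_obs = obs$n_obs[w], p_obs = obs$p_obs[w],
                        n_pred = NA_real_, p_pred = NA_real_, failed = TRUE))
    }
    data.frame(wave_time = obs$wave_time[w],
               n_obs = obs$n_obs[w], p_obs = obs$p_obs[w],
               n_pred = pred$N[w], p_pred = pred$P[w], failed = FALSE)
  })
  folds <- do.call(rbind, folds)
  ok <- !folds$failed
  if (any(folds$failed)) {
    warning(sum(folds$failed), " fold(s) failed; aggregate RMSE uses the ",
            sum(ok), " successful fold(s)", call. = FALSE)
  }
  if (!any(ok)) stop("all leave-one-wave-out folds failed", call. = FALSE)
  rmse <- c(n = sqrt(mean((folds$n_obs[ok] - folds$n_pred[ok])^2)),
            p = sqrt(mean((folds$p_obs[ok] - folds$p_pred[ok])^2)))
  structure(list(folds = folds, rmse = rmse, n_starts = n_starts,
                 seed = seed), class = "ecto_loo")
}

#' @export
print.ecto_loo <- function(x, digits = 4, ...) {
  cat("Leave-one-wave-out validation (", nrow(x$folds), " folds)\n", sep = "")
  f <- x$folds
  f$n_pred <- signif(f$n_pred, digits)
  f$p_pred <- signif(f$p_pred, digits)
  print.data.frame(f)
  cat(sprintf("Aggregate LOO RMSE: N %.4f, P %.4f\n",
              x$rmse["n"], x$rmse["p"]))
  invisible(x)
}
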