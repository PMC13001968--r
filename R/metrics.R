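#' Basic fit-quality metrics
#'
#' Root-mean-square error, coefficient of determination
#' `R^2 = 1 - SSE/SStot` (about the observed mean; may be negative for fits
#' worse than the mean), and Pearson correlation with a two-sided t-test
#' p-value on `n - 2` degrees of freedom.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Named numeric vector `rmse`, `r_squared`, `pearson_r`,
#'   `pearson_p`.
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal lengths", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least two points", call. = FALSE)
  resid <- observed - predicted
  rmse <- sqrt(mean(resid^2))
  sstot <- sum((observed - mean(observed))^2)
  if (sstot <= 0) {
    stop("observed vector is constant; R^2 and Pearson r are undefined ",
         sprintf("(rmse = %g)", rmse), call. = FALSE)
  }
  r2 <- 1 - sum(resid^2) / sstot
  if (stats::sd(predicted) == 0) {
    r <- NA_real_; p <- NA_real_
  } else if (length(observed) < 3L) {
    # r is determined (+-1) by two points; the t test needs n - 2 > 0
    r <- stats::cor(observed, predicted); p <- NA_real_
  } else {
    ct <- stats::cor.test(observed, predicted, alternative = "two.sided",
                          method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  c(rmse = rmse, r_squared = r2, pearson_r = r, pearson_p = p)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with local cost `|a_i - b_j|`, full
#' (unconstrained) window, boundary-matched endpoints, and no path-length
#' normalization. Symmetric in its arguments.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Nonnegative warping distance; 0 iff the two sequences are
#'   identical after collapsing consecutive duplicates.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: repeats absorbed by warping
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("inputs must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("inputs must not contain NA", call. = FALSE)
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    cost_i <- abs(a[i] - b)
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost_i[j] +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}
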