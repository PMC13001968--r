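#' Convert Likert category counts to a probability distribution
#'
#' Divides each category count by the row total. This is the first step in
#' summarizing a wave's categorical response distribution by its Shannon
#' entropy.
#'
#' @param counts Integer (or integer-valued numeric) vector of nonnegative
#'   response counts, one per Likert category.
#' @param item_id,wave_label Optional labels used only to make error messages
#'   traceable to the offending table row.
#' @return Numeric vector of the same length as `counts`, summing to 1.
#' @examples
#' counts_to_probabilities(c(10, 10, 10, 10, 10))
#' counts_to_probabilities(c(3, 1, 0, 0, 0))
#' @export
counts_to_probabilities <- function(counts, item_id = NULL, wave_label = NULL) {
  where <- if (!is.null(item_id) || !is.null(wave_label)) {
    sprintf(" (item %s, wave %s)",
            if (is.null(item_id)) "?" else item_id,
            if (is.null(wave_label)) "?" else wave_label)
  } else ""
  if (!is.numeric(counts) || length(counts) == 0L) {
    stop("`counts` must be a non-empty numeric vector", where, call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("negative or missing category counts", where, call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("all category counts are zero", where, call. = FALSE)
  }
  counts / total
}

#' Shannon entropy of a categorical distribution, in bits
#'
#' Computes \eqn{H = -\sum_i p_i \log_2 p_i}, omitting zero-probability
#' categories (their limit contribution is 0). The maximum over distributions
#' of length `n` is `log2(n)`, attained by the uniform distribution.
#'
#' @param probs Probability vector; must be nonnegative and sum to 1 within
#'   `tol`.
#' @param tol Tolerance on the sum-to-one check. Probabilities derived from
#'   counts are exact up to float round-off, so the default only guards
#'   round-trips.
#' @return Entropy in bits, in `[0, log2(length(probs))]`.
#' @examples
#' shannon_entropy(rep(0.2, 5))        # log2(5)
#' shannon_entropy(c(1, 0, 0, 0, 0))   # 0
#' @export
shannon_entropy <- function(probs, tol = 1e-9) {
  if (!is.numeric(probs) || length(probs) == 0L || anyNA(probs)) {
    stop("`probs` must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  if (any(probs < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(probs) - 1) > tol) {
    stop(sprintf("probabilities sum to %.12g, not 1 (tolerance %g)",
                 sum(probs), tol), call. = FALSE)
  }
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

#' Normalize an entropy value by its theoretical maximum
#'
#' Maps an entropy in bits to `[0, 1]` by dividing by `log2(n_categories)`,
#' so that items with different numbers of valid response categories become
#' comparable.
#'
#' @param h Entropy in bits.
#' @param n_categories Number of response categories (>= 2).
#' @return Dimensionless normalized entropy in `[0, 1]`.
#' @export
normalize_entropy <- function(h, n_categories) {
  if (length(n_categories) != 1L || !is.numeric(n_categories) ||
      n_categories < 2 || n_categories != round(n_categories)) {
    stop("`n_categories` must be a single integer >= 2", call. = FALSE)
  }
  hmax <- log2(n_categories)
  if (any(h < -1e-9) || any(h > hmax + 1e-9)) {
    stop(sprintf("entropy outside [0, log2(%d)] beyond tolerance", n_categories),
         call. = FALSE)
  }
  pmin(pmax(h / hmax, 0), 1)
}

#' Per-item entropy trajectories from a Likert wave table
#'
#' Computes, for every (item, wave) row of a long-format count table, the
#' Shannon entropy in bits and its normalized value. Category counts are the
#' columns named `cat_1 ... cat_k`; items may differ in their number of valid
#' categories (trailing all-`NA` category columns are dropped per item).
#'
#' @param table Data frame with columns `item_id`, `wave_label` (optional),
#'   `wave_time`, and `cat_1 ... cat_k`, as produced by [read_likert_csv()] or
#'   [generate_likert_waves()].
#' @return Data frame of class `"ecto_entropy"` with columns `item_id`,
#'   `wave_time`, `n_categories`, `entropy_bits`, `entropy_norm`, ordered by
#'   item and wave time.
#' @seealso [pooled_entropy()] for the cohort-level index.
#' @export
likert_entropy <- function(table) {
  table <- validate_likert_table(table)
  cat_cols <- grep("^cat_", names(table), value = TRUE)
  out <- lapply(split(table, table$item_id), function(d) {
    d <- d[order(d$wave_time), , drop = FALSE]
    counts <- as.matrix(d[, cat_cols, drop = FALSE])
    keep <- colSums(!is.na(counts)) > 0
    counts <- counts[, keep, drop = FALSE]
    counts[is.na(counts)] <- 0
    k <- ncol(counts)
    h <- vapply(seq_len(nrow(counts)), function(i) {
      p <- counts_to_probabilities(counts[i, ], item_id = d$item_id[[i]],
                                   wave_label = wave_label_of(d, i))
      shannon_entropy(p)
    }, numeric(1))
    data.frame(item_id = d$item_id, wave_time = d$wave_time,
               n_categories = k, entropy_bits = h,
               entropy_norm = normalize_entropy(h, k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ecto_entropy", "data.frame")
  res
}

wave_label_of <- function(d, i) {
  if ("wave_label" %in% names(d)) d$wave_label[[i]] else as.character(d$wave_time[[i]])
}

#' Pooled cohort entropy index
#'
#' Averages normalized item entropies across items at each wave, giving a
#' single dimensionless heterogeneity summary `h_star(t)` on `[0, 1]` per
#' wave. All items must be observed on an identical wave-time grid.
#'
#' @param entropy An `"ecto_entropy"` data frame from [likert_entropy()], or
#'   any data frame with columns `item_id`, `wave_time`, `entropy_norm`.
#' @return Data frame with columns `wave_time`, `h_star`, `n_items`.
#' @export
pooled_entropy <- function(entropy) {
  stopifnot(all(c("item_id", "wave_time", "entropy_norm") %in% names(entropy)))
  items <- split(entropy, entropy$item_id)
  grid <- sort(unique(items[[1L]]$wave_time))
  bad <- names(items)[!vapply(items, function(d) {
    identical(sort(d$wave_time), grid)
  }, logical(1))]
  if (length(bad) > 0) {
    stop("items not on the common wave grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mat <- vapply(items, function(d) d$entropy_norm[order(d$wave_time)],
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  data.frame(wave_time = grid, h_star = rowMeans(mat), n_items = length(items))
}

validate_likert_table <- function(table) {
  if (!is.data.frame(table)) stop("expected a data frame", call. = FALSE)
  need <- c("item_id", "wave_time")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cat_cols <- grep("^cat_", names(table), value = TRUE)
  if (length(cat_cols) < 2) {
    stop("need at least two `cat_` count columns", call. = FALSE)
  }
  key <- paste(table$item_id, table$wave_time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (item, wave) rows at row(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cnt <- as.matrix(table[, cat_cols, drop = FALSE])
  if (any(cnt < 0, na.rm = TRUE)) {
    bad <- which(apply(cnt < 0, 1L, any, na.rm = TRUE))
    stop("negative counts at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  table
}
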