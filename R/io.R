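#' Read and write long-format Likert count tables
#'
#' The CSV schema is one row per (item, wave): columns `item_id`,
#' `wave_label` (optional), `wave_time` (years), and category counts in
#' columns named `cat_1 ... cat_k`. UTF-8, comma-separated, header required,
#' `.` decimal. Validation rejects missing columns, negative counts and
#' duplicate (item, wave) rows, naming the offending rows.
#'
#' @param path CSV file path.
#' @return [read_likert_csv()]: a validated data frame;
#'   [write_likert_csv()]: invisibly, `path`.
#' @export
read_likert_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_likert_table(raw)
}

#' @rdname read_likert_csv
#' @param table A Likert wave table (validated on write).
#' @export
write_likert_csv <- function(table, path) {
  table <- validate_likert_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write entropy tables to CSV
#'
#' `write_entropy_csv()` writes the per-item series (`item_id, wave_time,
#' entropy_bits, entropy_norm`); `write_pooled_csv()` writes the pooled
#' index (`wave_time, h_star, n_items`).
#'
#' @param entropy An `"ecto_entropy"` data frame.
#' @param pooled A pooled-index data frame from [pooled_entropy()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_entropy_csv <- function(entropy, path) {
  cols <- c("item_id", "wave_time", "entropy_bits", "entropy_norm")
  stopifnot(all(cols %in% names(entropy)))
  utils::write.csv(entropy[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_entropy_csv
#' @export
write_pooled_csv <- function(pooled, path) {
  stopifnot(all(c("wave_time", "h_star", "n_items") %in% names(pooled)))
  utils::write.csv(pooled, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns `time, N, P, E_stress`.
#'
#' @param trajectory An `"ecto_trajectory"`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(all(c("time", "N", "P", "E_stress") %in% names(trajectory)))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

fit_to_list <- function(fit) {
  list(par = as.list(fit$par),
       values = as.list(fit$values),
       sse = fit$sse,
       metrics = lapply(fit$metrics, function(m) if (is.null(m)) NULL else as.list(m)),
       converged = fit$converged,
       n_starts = fit$n_starts,
       seed = fit$seed,
       start_stats = as.list(fit$start_stats),
       scale = if (is.null(fit$scale)) NA else fit$scale,
       t0 = fit$t0,
       coupled = isTRUE(attr(fit$spec, "coupled")),
       forcing = isTRUE(attr(fit$spec, "forcing")))
}

#' Run the full analysis pipeline
#'
#' Executes entropy extraction, model fitting and fit metrics (optionally
#' leave-one-wave-out validation and a sensitivity scan) from a single
#' configuration, writing all artifacts plus a machine-readable provenance
#' record to an output directory. Reruns with an identical configuration
#' produce byte-identical JSON reports.
#'
#' @param config A list (or path to a YAML/JSON file encoding one) with
#'   fields:
#'   \describe{
#'     \item{likert_csv}{Path to a long-format count table, or `NULL` to use
#'       the bundled dental entropy fixture.}
#'     \item{n_item, p_item}{Item ids mapped to the `N` and `P` states.}
#'     \item{scale}{`"norm"` (default) or `"bits"`.}
#'     \item{spec}{Path to a YAML/JSON parameter spec, or `NULL` for the
#'       fully free spec; `"reduced"` selects [ecto_spec_reduced()].}
#'     \item{n_starts, seed}{Multistart settings (defaults 32, 20260319).}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{loo, sensitivity}{Logical switches (default `FALSE`).}
#'   }
#' @return Invisibly, a list with the fit and report paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(likert_csv = NULL, n_item = "supp", p_item = "time",
         scale = "norm", spec = NULL, n_starts = 32L, seed = 20260319L,
         out_dir = ".", loo = FALSE, sensitivity = FALSE), config)
  if (!is.null(cfg$likert_csv) && !file.exists(cfg$likert_csv)) {
    stop("input file not found: ", cfg$likert_csv, call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)

  entropy <- if (is.null(cfg$likert_csv)) {
    dental_entropy()
  } else {
    likert_entropy(read_likert_csv(cfg$likert_csv))
  }
  write_entropy_csv(entropy, path("entropy.csv"))
  pooled <- pooled_entropy(entropy)
  write_pooled_csv(pooled, path("pooled.csv"))

  spec <- if (is.null(cfg$spec)) {
    ecto_spec_full()
  } else if (identical(cfg$spec, "reduced")) {
    ecto_spec_reduced()
  } else {
    read_ecto_spec(cfg$spec)
  }
  obs <- entropy_to_observed(entropy, cfg$n_item, cfg$p_item, scale = cfg$scale)
  fit <- ecto_fit(obs, spec, n_starts = cfg$n_starts, seed = cfg$seed)
  report <- fit_to_list(fit)
  jsonlite::write_json(report, path("fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  write_trajectory_csv(
    predict(fit, seq(fit$t0, max(obs$wave_time), length.out = 101L)),
    path("trajectory.csv"))

  paths <- list(fit = path("fit.json"), entropy = path("entropy.csv"),
                pooled = path("pooled.csv"), trajectory = path("trajectory.csv"))
  if (isTRUE(cfg$loo)) {
    loo <- loo_validate(obs, spec, n_starts = max(4L, cfg$n_starts %/% 4L),
                        seed = cfg$seed)
    jsonlite::write_json(list(folds = loo$folds, rmse = as.list(loo$rmse)),
                         path("loo.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "rows")
    paths$loo <- path("loo.json")
  }
  if (isTRUE(cfg$sensitivity)) {
    sens <- sensitivity_scan(fit)
    utils::write.csv(as.data.frame(sens), path("sensitivity.csv"),
                     row.names = FALSE, quote = FALSE)
    paths$sensitivity <- path("sensitivity.csv")
  }
  provenance <- list(
    config = cfg[order(names(cfg))],
    seed = cfg$seed,
    scale = cfg$scale,
    package_version = as.character(utils::packageVersion("ecto")),
    spec = lapply(seq_len(nrow(fit$spec)), function(i) {
      as.list(fit$spec[i, c("free", "value", "lower", "upper")])
    }))
  names(provenance$spec) <- rownames(fit$spec)
  jsonlite::write_json(provenance, path("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths$provenance <- path("provenance.json")
  invisible(list(fit = fit, paths = paths))
}
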