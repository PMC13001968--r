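ecto_fit_param_names <- function() {
  c(ecto_param_names(), "N0", "P0", "E0")
}

ecto_default_bounds <- function() {
  # brackets every parameter value used in practice with ample margin
  list(mu    = c(0, 1),
       alpha = c(0, 5),
       beta  = c(-2, 2),
       gamma = c(0, 1),
       c1    = c(0, 20),
       c2    = c(0, 20),
       c3    = c(0, 20),
       K     = c(1e-3, 10),
       G     = c(1e-3, 10),
       A     = c(0, 5),
       omega = c(0, 2 * pi),
       N0    = c(0, 1),
       P0    = c(1e-4, 1),
       E0    = c(1e-4, 1))
}

ecto_default_values <- function() {
  c(mu = 0, alpha = 0, beta = 0, gamma = 0, c1 = 0, c2 = 0, c3 = 0,
    K = 0.5, G = 1, A = 1, omega = 1, N0 = 0.5, P0 = 0.01, E0 = 0.01)
}

#' Parameter specification for ECTO model fitting
#'
#' Declares, for every model coefficient and fittable initial condition,
#' whether it is free or fixed, its fixed value or starting point, and its
#' box bounds. The managed parameters are `mu, alpha, beta, gamma, c1, c2,
#' c3, K, G, A, omega` plus the initial states `N0, P0, E0` (`N0` and `P0`
#' are usually pinned to data by the fitting policy; see [ecto_fit()]).
#'
#' @param free Character vector of parameter names to estimate.
#' @param fixed Named numeric vector/list overriding default fixed values
#'   (or starting values, for free parameters).
#' @param lower,upper Named numeric vectors overriding the default bounds.
#' @param forcing Logical; enable the sinusoidal forcing term (`A`, `omega`
#'   become meaningful).
#' @param coupled Logical; `FALSE` builds the uncoupled null model, forcing
#'   `beta = c2 = c3 = 0` (they are removed from the free set).
#' @return Data frame of class `"ecto_spec"` with one row per parameter and
#'   columns `free`, `value`, `lower`, `upper`.
#' @seealso [ecto_spec_full()], [ecto_spec_reduced()]
#' @export
ecto_spec <- function(free = character(), fixed = NULL,
                      lower = NULL, upper = NULL,
                      forcing = FALSE, coupled = TRUE) {
  pn <- ecto_fit_param_names()
  bounds <- ecto_default_bounds()
  s <- data.frame(free = pn %in% free,
                  value = unname(ecto_default_values()[pn]),
                  lower = vapply(bounds[pn], `[`, numeric(1), 1L),
                  upper = vapply(bounds[pn], `[`, numeric(1), 2L),
                  row.names = pn)
  bad <- setdiff(free, pn)
  if (length(bad) > 0) {
    stop("unknown parameter(s) in `free`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  apply_named <- function(col, vals) {
    if (is.null(vals)) return()
    vals <- unlist(vals)
    unknown <- setdiff(names(vals), pn)
    if (length(unknown) > 0) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    s[names(vals), col] <<- unname(vals)
  }
  apply_named("value", fixed)
  apply_named("lower", lower)
  apply_named("upper", upper)
  if (!coupled) {
    s[c("beta", "c2", "c3"), "value"] <- 0
    s[c("beta", "c2", "c3"), "free"] <- FALSE
  }
  if (any(s[c("K", "G"), "lower"] <= 0)) {
    stop("bounds for `K` and `G` must be strictly positive", call. = FALSE)
  }
  # free parameters start in-bounds; fixed ones may sit anywhere
  s$value[s$free] <- pmin(pmax(s$value[s$free], s$lower[s$free]),
                          s$upper[s$free])
  viol <- s$free & (s$lower > s$value | s$value > s$upper)
  if (any(viol)) {
    stop("start value outside bounds for: ",
         paste(rownames(s)[viol], collapse = ", "), call. = FALSE)
  }
  if (any(s$lower > s$upper)) stop("lower bound above upper bound", call. = FALSE)
  attr(s, "forcing") <- isTRUE(forcing)
  attr(s, "coupled") <- isTRUE(coupled)
  class(s) <- c("ecto_spec", "data.frame")
  s
}

#' Fully free parameter specification
#'
#' Frees every model coefficient plus `E0` (and `A`, `omega` when forcing is
#' enabled). `N0` and `P0` stay policy-controlled; see [ecto_fit()].
#'
#' @inheritParams ecto_spec
#' @param ... Passed on to [ecto_spec()].
#' @return An `"ecto_spec"` object.
#' @export
ecto_spec_full <- function(forcing = FALSE, ...) {
  free <- c("mu", "alpha", "beta", "gamma", "c1", "c2", "c3", "K", "G", "E0")
  if (forcing) free <- c(free, "A", "omega")
  ecto_spec(free = free, forcing = forcing, ...)
}

#' Reduced parameter specification
#'
#' Frees only `(mu, alpha, gamma, E0, beta, c1)`; the remaining coefficients
#' are held at reference values (`c2 = 0.21`, `c3 = 0`, `K = 0.5`, `G = 1`).
#'
#' @param ... Passed on to [ecto_spec()].
#' @return An `"ecto_spec"` object.
#' @export
ecto_spec_reduced <- function(...) {
  ecto_spec(free = c("mu", "alpha", "gamma", "E0", "beta", "c1"),
            fixed = c(c2 = 0.21, c3 = 0, K = 0.5, G = 1), ...)
}

#' @export
print.ecto_spec <- function(x, ...) {
  cat("ECTO parameter spec (", sum(x$free), " free, ",
      if (attr(x, "coupled")) "coupled" else "uncoupled",
      if (attr(x, "forcing")) ", forcing" else "", ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write a parameter spec as YAML/JSON
#'
#' The on-disk format maps each parameter name to
#' `{value, free, lower, upper}`, plus top-level `forcing`/`coupled` flags.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return [read_ecto_spec()] returns an `"ecto_spec"`;
#'   [write_ecto_spec()] invisibly returns `path`.
#' @export
read_ecto_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  flags <- list(forcing = isTRUE(raw$forcing), coupled = !isFALSE(raw$coupled))
  raw$forcing <- NULL; raw$coupled <- NULL
  free <- names(raw)[vapply(raw, function(p) isTRUE(p$free), logical(1))]
  getf <- function(field) {
    v <- unlist(lapply(raw, function(p) p[[field]]))
    if (is.null(v)) NULL else v
  }
  ecto_spec(free = free, fixed = getf("value"),
            lower = getf("lower"), upper = getf("upper"),
            forcing = flags$forcing, coupled = flags$coupled)
}

#' @rdname read_ecto_spec
#' @param spec An `"ecto_spec"` object.
#' @export
write_ecto_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ecto_spec"))
  out <- lapply(rownames(spec), function(p) {
    list(value = spec[p, "value"], free = spec[p, "free"],
         lower = spec[p, "lower"], upper = spec[p, "upper"])
  })
  names(out) <- rownames(spec)
  out$forcing <- attr(spec, "forcing")
  out$coupled <- attr(spec, "coupled")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
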