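#' Distribution specification
#'
#' A lightweight description of a univariate distribution used for exposure
#' factors and concentrations: one of `point`, `normal`, `lognormal`,
#' `gamma`, `weibull`, `triangular`, `uniform`. Parameters follow the base-R
#' conventions (`mean`/`sd`, `meanlog`/`sdlog`, `shape`/`rate`,
#' `shape`/`scale`); `triangular` takes `min`, `mode`, `max`; `uniform`
#' `min`/`max`; `point` a single `value`.
#'
#' @param family distribution family name.
#' @param ... named parameters for the family.
#' @return object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("lognormal", meanlog = 0, sdlog = 1)
#' dist_spec("point", value = 70)
dist_spec <- function(family, ...) {
  family <- match.arg(family, c("point", "normal", "lognormal", "gamma",
                                "weibull", "triangular", "uniform"))
  pars <- list(...)
  need <- switch(family,
    point = "value", normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"), gamma = c("shape", "rate"),
    weibull = c("shape", "scale"), triangular = c("min", "mode", "max"),
    uniform = c("min", "max"))
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop(sprintf("family '%s' requires parameter(s): %s", family,
                 paste(missing, collapse = ", ")))
  if (family == "triangular" &&
      !(pars$min <= pars$mode && pars$mode <= pars$max))
    stop("triangular requires min <= mode <= max")
  if (family == "uniform" && pars$min > pars$max)
    stop("uniform requires min <= max")
  structure(c(list(family = family), pars[need]), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- unlist(x[-1L])
  cat(sprintf("dist_spec %s(%s)\n", x$family,
              paste(names(pars), signif(pars, 6), sep = "=", collapse = ", ")))
  invisible(x)
}

rtriangular <- function(n, min, mode, max) {
  # inverse-CDF sampler
  u <- runif(n)
  fc <- if (max > min) (mode - min) / (max - min) else 0
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Draw from a distribution specification
#'
#' Samples `n` values from a [dist_spec()]. For physically nonnegative
#' quantities, draws below `lower` are resampled (truncation by rejection);
#' the number of rejected draws is available as attribute `"resampled"`.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param lower truncation bound (default 0; use `-Inf` to disable).
#' @return numeric vector of length `n`.
#' @export
r_dist <- function(spec, n, lower = 0) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  draw <- function(k) switch(spec$family,
    point = rep(spec$value, k),
    normal = rnorm(k, spec$mean, spec$sd),
    lognormal = rlnorm(k, spec$meanlog, spec$sdlog),
    gamma = rgamma(k, shape = spec$shape, rate = spec$rate),
    weibull = rweibull(k, shape = spec$shape, scale = spec$scale),
    triangular = rtriangular(k, spec$min, spec$mode, spec$max),
    uniform = runif(k, spec$min, spec$max))
  if (spec$family == "point" && spec$value < lower)
    stop("point mass below the truncation bound")
  x <- draw(n)
  resampled <- 0L
  while (any(bad <- x < lower)) {
    resampled <- resampled + sum(bad)
    x[bad] <- draw(sum(bad))
    if (resampled > 1e6)
      stop("truncation rejected more than 1e6 draws; check the specification")
  }
  attr(x, "resampled") <- resampled
  x
}

dist_mean <- function(spec) {
  switch(spec$family,
    point = spec$value,
    normal = spec$mean,
    lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
    gamma = spec$shape / spec$rate,
    weibull = spec$scale * gamma(1 + 1 / spec$shape),
    triangular = (spec$min + spec$mode + spec$max) / 3,
    uniform = (spec$min + spec$max) / 2)
}

#' Lognormal specification matching a mean and standard deviation
#'
#' Converts an arithmetic mean and SD into the `meanlog`/`sdlog`
#' parameterisation by moment matching, the default way concentration
#' distributions are built from literature summary tables.
#'
#' @param mean arithmetic mean (> 0).
#' @param sd arithmetic standard deviation (>= 0); `sd = 0` yields a point
#'   mass.
#' @return a [dist_spec()].
#' @export
lognormal_from_mean_sd <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(dist_spec("point", value = mean))
  s2 <- log(1 + (sd / mean)^2)
  dist_spec("lognormal", meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
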