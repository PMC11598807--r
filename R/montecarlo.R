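ad_statistic <- function(x, pfun) {
  # Anderson-Darling statistic against a fitted continuous CDF
  x <- sort(x)
  n <- length(x)
  u <- pmin(pmax(pfun(x), 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

chisq_gof <- function(x, qfun, n_par) {
  # equal-probability bins, k = ceiling(1 + log2(n))
  n <- length(x)
  k <- ceiling(1 + log2(n))
  edges <- qfun(seq(0, 1, length.out = k + 1))
  edges[1] <- -Inf; edges[k + 1] <- Inf
  obs <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = k)
  expd <- n / k
  stat <- sum((obs - expd)^2 / expd)
  df <- max(k - 1 - n_par, 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Select the best-fitting distribution for a sample
#'
#' Fits each candidate family by maximum likelihood (via
#' \pkg{fitdistrplus}) and selects the family with the smallest
#' Anderson-Darling statistic; a chi-square goodness-of-fit on
#' equal-probability bins (`k = ceiling(1 + log2(n))`) is reported as a
#' secondary diagnostic but never arbitrates. Families requiring positive
#' support are skipped with a warning when the sample contains nonpositive
#' values; a constant sample short-circuits to a point mass.
#'
#' @param samples numeric vector, `n >= 20`.
#' @param candidates subset of `"normal"`, `"lognormal"`, `"gamma"`,
#'   `"weibull"`, `"uniform"`.
#' @return list of class `fitted_dist`: `family`, `spec` (a [dist_spec()]),
#'   and `gof` (per-candidate AD statistic, chi-square statistic, df, p).
#' @export
fit_best_distribution <- function(samples,
                                  candidates = c("normal", "lognormal",
                                                 "gamma", "weibull")) {
  x <- as.numeric(samples)
  if (anyNA(x) || any(!is.finite(x))) stop("samples must be finite")
  if (length(unique(x)) == 1L) {
    return(structure(list(family = "point",
                          spec = dist_spec("point", value = x[1]),
                          gof = NULL),
                     class = "fitted_dist"))
  }
  if (length(x) < 20L)
    stop("distribution fitting requires at least 20 samples")
  candidates <- match.arg(candidates,
                          c("normal", "lognormal", "gamma", "weibull",
                            "uniform"), several.ok = TRUE)
  positive_only <- c("lognormal", "gamma", "weibull")
  rows <- list(); specs <- list()
  for (fam in candidates) {
    if (fam %in% positive_only && any(x <= 0)) {
      warning("nonpositive samples: skipping family '", fam, "'")
      next
    }
    fit <- tryCatch(fit_one_family(x, fam), error = function(e) NULL)
    if (is.null(fit)) next
    ad <- ad_statistic(x, fit$pfun)
    cs <- chisq_gof(x, fit$qfun, fit$n_par)
    rows[[fam]] <- data.frame(family = fam, ad = ad, chisq = cs$stat,
                              chisq_df = cs$df, chisq_p = cs$p)
    specs[[fam]] <- fit$spec
  }
  if (!length(rows))
    stop("no candidate family could be fitted to the sample")
  gof <- do.call(rbind, rows)
  rownames(gof) <- NULL
  best <- gof$family[which.min(gof$ad)]
  structure(list(family = best, spec = specs[[best]], gof = gof),
            class = "fitted_dist")
}

fit_one_family <- function(x, fam) {
  if (fam == "uniform") {
    a <- min(x); b <- max(x)
    return(list(spec = dist_spec("uniform", min = a, max = b),
                pfun = function(q) punif(q, a, b),
                qfun = function(p) qunif(p, a, b), n_par = 2L))
  }
  distr <- switch(fam, normal = "norm", lognormal = "lnorm",
                  gamma = "gamma", weibull = "weibull")
  # optimizer exploration can warn (NaN log-likelihoods off-support)
  est <- suppressWarnings(
    fitdistrplus::fitdist(x, distr, method = "mle")$estimate)
  switch(fam,
    normal = list(
      spec = dist_spec("normal", mean = est[["mean"]], sd = est[["sd"]]),
      pfun = function(q) pnorm(q, est[["mean"]], est[["sd"]]),
      qfun = function(p) qnorm(p, est[["mean"]], est[["sd"]]), n_par = 2L),
    lognormal = list(
      spec = dist_spec("lognormal", meanlog = est[["meanlog"]],
                       sdlog = est[["sdlog"]]),
      pfun = function(q) plnorm(q, est[["meanlog"]], est[["sdlog"]]),
      qfun = function(p) qlnorm(p, est[["meanlog"]], est[["sdlog"]]),
      n_par = 2L),
    gamma = list(
      spec = dist_spec("gamma", shape = est[["shape"]], rate = est[["rate"]]),
      pfun = function(q) pgamma(q, est[["shape"]], est[["rate"]]),
      qfun = function(p) qgamma(p, est[["shape"]], est[["rate"]]),
      n_par = 2L),
    weibull = list(
      spec = dist_spec("weibull", shape = est[["shape"]],
                       scale = est[["scale"]]),
      pfun = function(q) pweibull(q, est[["shape"]], est[["scale"]]),
      qfun = function(p) qweibull(p, est[["shape"]], est[["scale"]]),
      n_par = 2L))
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat("fitted_dist: "); print(x$spec)
  invisible(x)
}

#' Default concentration distributions from a summary table
#'
#' Lognormal per congener, moment-matched to the summary mean and SD
#' (converted from ng g^-1 to mg kg^-1), the default when raw per-sample
#' concentrations are unavailable. A zero SD degrades to a point mass.
#'
#' @param summary a table with congener names (`compound` or `congener`)
#'   and `mean_ng_g`/`sd_ng_g` (or `mean`/`sd`, ng g^-1) columns, e.g.
#'   [reference_concentrations()] or [summarize_concentrations()].
#' @return named list of [dist_spec()] objects (mg kg^-1 scale).
#' @export
default_concentration_dists <- function(summary = reference_concentrations()) {
  nm <- if ("compound" %in% names(summary)) summary$compound
        else summary$congener
  mu <- if ("mean_ng_g" %in% names(summary)) summary$mean_ng_g
        else summary$mean
  sdv <- if ("sd_ng_g" %in% names(summary)) summary$sd_ng_g else summary$sd
  out <- Map(function(m, s) lognormal_from_mean_sd(m * 1e-3, s * 1e-3),
             mu, sdv)
  names(out) <- nm
  out
}

#' Default exposure-factor distributions
#'
#' Variability models around a point parameter set: body weight normal
#' (mean `bw`, SD 10 kg, truncated at 0); time in vehicle, ingestion rate,
#' inhalation rate and exposure frequency triangular around their point
#' values (+/- 50%, frequency capped at 365 days); duration, skin area,
#' adherence and emission factor held at their point values.
#'
#' @param params an [exposure_params()].
#' @return named list of [dist_spec()] objects.
#' @export
default_param_dists <- function(params = default_exposure_params()) {
  tri <- function(v, cap = Inf)
    dist_spec("triangular", min = 0.5 * v, mode = v, max = min(1.5 * v, cap))
  list(
    r_ing = tri(params$r_ing),
    r_inh = tri(params$r_inh),
    et = tri(params$et, cap = 1),
    ef = dist_spec("triangular", min = 250, mode = params$ef, max = 365),
    ed = dist_spec("point", value = params$ed),
    sa = dist_spec("point", value = params$sa),
    da = dist_spec("point", value = params$da),
    pef = dist_spec("point", value = params$pef),
    bw = dist_spec("normal", mean = params$bw, sd = 10)
  )
}

#' Monte Carlo propagation of exposure and risk
#'
#' Draws all inputs independently per iteration — congener concentrations
#' from `conc_dists`, exposure factors from `param_dists` — evaluates the
#' three-route dose equations, and accumulates the hazard index (congeners
#' with an RfD) and total carcinogenic risk (congeners with an SF).
#' Physically negative draws are resampled at 0. The averaging time follows
#' the drawn duration (`at = ed * 365`; lifetime 70 * 365 for CR). With
#' every input a point mass the draws reproduce the deterministic pipeline
#' exactly. Bit-reproducible for a given seed.
#'
#' @param conc_dists named list of [dist_spec()] per congener (mg kg^-1),
#'   e.g. [default_concentration_dists()].
#' @param param_dists named list of [dist_spec()] per exposure factor, e.g.
#'   [default_param_dists()]; any factor of [exposure_params()] except
#'   `population`, `at`, `at_cancer` and the conversion constants may be
#'   given.
#' @param panel congener panel (RfD, SF, dermal fractions).
#' @param params base [exposure_params()] supplying the population label
#'   and any factor not listed in `param_dists`.
#' @param n_iter iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `risk_distribution`: `draws` (data.frame with
#'   `hi`, `cr`), `inputs` (per-iteration input draws, for sensitivity),
#'   `n_iter`, `seed`, `population`.
#' @export
monte_carlo_risk <- function(conc_dists, param_dists = list(),
                             panel = default_panel(),
                             params = default_exposure_params(),
                             n_iter = 10000L, seed = 1L) {
  stopifnot(n_iter >= 1)
  if (is.null(names(conc_dists)) || any(names(conc_dists) == ""))
    stop("conc_dists must be named by congener")
  missing_pan <- setdiff(names(conc_dists), panel$name)
  if (length(missing_pan))
    stop("congener(s) not in panel: ", paste(missing_pan, collapse = ", "))
  drawable <- c("r_ing", "r_inh", "et", "ef", "ed", "sa", "da", "pef", "bw")
  unknown <- setdiff(names(param_dists), drawable)
  if (length(unknown))
    stop("not a drawable exposure factor: ",
         paste(unknown, collapse = ", "))
  for (nm in names(param_dists))
    if (!inherits(param_dists[[nm]], "dist_spec"))
      stop("missing or invalid distribution for input '", nm, "'")
  set.seed(as.integer(seed))
  # fixed draw order: exposure factors (alphabetical), then congeners
  pd <- params
  for (nm in sort(names(param_dists)))
    pd[[nm]] <- as.numeric(r_dist(param_dists[[nm]], n_iter, lower = 0))
  pd$at <- pd$ed * 365
  conc <- matrix(NA_real_, n_iter, length(conc_dists),
                 dimnames = list(NULL, names(conc_dists)))
  for (nm in names(conc_dists)) {
    if (!inherits(conc_dists[[nm]], "dist_spec"))
      stop("missing or invalid distribution for input '", nm, "'")
    conc[, nm] <- as.numeric(r_dist(conc_dists[[nm]], n_iter, lower = 0))
  }
  pan <- panel[match(colnames(conc), panel$name), , drop = FALSE]
  hq_cols <- list(); cr_cols <- list()
  for (j in seq_len(ncol(conc))) {
    tot <- add_ingestion(conc[, j], pd) + add_inhalation(conc[, j], pd) +
      add_dermal(conc[, j], pd, pan$dermal_abs[j])
    if (!is.na(pan$rfd[j]))
      hq_cols[[length(hq_cols) + 1L]] <- tot / pan$rfd[j]
    if (!is.na(pan$sf[j]))
      cr_cols[[length(cr_cols) + 1L]] <-
        tot * pd$at / pd$at_cancer * pan$sf[j]
  }
  # rowSums accumulates like sum(), keeping the point-mass case bit-equal
  # to the deterministic hazard_index / cr_table path
  hi <- if (length(hq_cols)) rowSums(do.call(cbind, hq_cols))
        else numeric(n_iter)
  cr <- if (length(cr_cols)) rowSums(do.call(cbind, cr_cols))
        else numeric(n_iter)
  inputs <- as.data.frame(conc)
  drawn <- intersect(sort(names(param_dists)), drawable)
  if (length(drawn))
    inputs <- data.frame(pd[drawn], inputs, check.names = FALSE)
  structure(list(draws = data.frame(hi = hi, cr = cr), inputs = inputs,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 population = params$population),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  q <- percentile_summary(x)
  cat(sprintf("risk_distribution (%s, %d iterations)\n", x$population,
              x$n_iter))
  print(q)
  invisible(x)
}

#' Percentile summary of a risk distribution
#'
#' Empirical quantiles of the HI and CR draws using the standard
#' linear-interpolation convention (R quantile type 7).
#'
#' @param r a `risk_distribution` (or numeric vector of draws).
#' @param levels percentile levels in \[0, 100\].
#' @return data.frame with one row per level.
#' @export
percentile_summary <- function(r, levels = c(10, 50, 90)) {
  if (any(levels < 0 | levels > 100))
    stop("percentile levels must lie in [0, 100]")
  if (is.numeric(r)) {
    if (!length(r)) stop("no draws")
    return(data.frame(level = levels,
                      value = unname(quantile(r, levels / 100, type = 7))))
  }
  stopifnot(inherits(r, "risk_distribution"))
  if (!nrow(r$draws)) stop("no draws")
  data.frame(level = levels,
             hi = unname(quantile(r$draws$hi, levels / 100, type = 7)),
             cr = unname(quantile(r$draws$cr, levels / 100, type = 7)))
}

#' Contribution-to-variance sensitivity analysis
#'
#' Spearman rank correlation between each input and the output across Monte
#' Carlo iterations, converted to signed percentage contributions:
#' `contribution_v = sign(rho_v) * rho_v^2 / sum_w rho_w^2 * 100`. A
#' positive sign means the input drives the risk up; inputs in a
#' denominator (body weight) come out negative. Rank-based, hence invariant
#' to monotone rescaling of any input. Constant inputs contribute 0 with a
#' warning.
#'
#' @param inputs data.frame of input draws (one column per input), or a
#'   `risk_distribution` (its stored inputs are used).
#' @param output numeric vector of output draws, or for a
#'   `risk_distribution` the name `"hi"` or `"cr"`.
#' @return data.frame of class `sensitivity_report`: `input`, `rho`,
#'   `contribution` (signed %, absolute values summing to 100).
#' @export
sensitivity_contributions <- function(inputs, output = "hi") {
  if (inherits(inputs, "risk_distribution")) {
    output <- inputs$draws[[match.arg(output, c("hi", "cr"))]]
    inputs <- inputs$inputs
  }
  inputs <- as.data.frame(inputs)
  stopifnot(is.numeric(output), nrow(inputs) == length(output))
  if (length(output) < 100)
    stop("sensitivity analysis requires at least 100 iterations")
  rho <- vapply(inputs, function(v) {
    if (sd(v) == 0 || sd(output) == 0) NA_real_
    else cor(v, output, method = "spearman")
  }, numeric(1))
  if (anyNA(rho))
    warning("constant input(s), contribution set to 0: ",
            paste(names(inputs)[is.na(rho)], collapse = ", "))
  rho0 <- ifelse(is.na(rho), 0, rho)
  denom <- sum(rho0^2)
  contrib <- if (denom == 0) rep(0, length(rho0))
             else sign(rho0) * rho0^2 / denom * 100
  out <- data.frame(input = names(inputs), rho = rho0,
                    contribution = contrib, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$contribution), decreasing = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", class(out))
  out
}
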