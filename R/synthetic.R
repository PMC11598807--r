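#' Planted nonnegative source structure
#'
#' Describes the ground truth for the synthetic concentration generator: `p`
#' nonnegative source profiles over `m` congeners (rows normalised to sum to
#' 1, the convention used for fitted profiles) and a per-factor distribution
#' for the sample contributions.
#'
#' @param profiles p x m nonnegative matrix of source profiles; rows are
#'   rescaled to sum to 1.
#' @param g_dist list of `p` [dist_spec()] objects for the per-sample factor
#'   contributions, or a single spec recycled to all factors. Defaults to
#'   heavy-tailed lognormal contributions typical of dust concentrations.
#' @param noise_cv relative (coefficient-of-variation) scale of the
#'   multiplicative noise; >= 0.
#' @return object of class `planted_sources`.
#' @export
planted_sources <- function(profiles,
                            g_dist = dist_spec("lognormal", meanlog = log(1e3),
                                               sdlog = 1),
                            noise_cv = 0.1) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("profiles must be nonnegative")
  rs <- rowSums(profiles)
  if (any(rs <= 0)) stop("each profile row must have positive mass")
  profiles <- profiles / rs
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (inherits(g_dist, "dist_spec")) g_dist <- rep(list(g_dist), nrow(profiles))
  if (length(g_dist) != nrow(profiles))
    stop("g_dist must supply one distribution per factor")
  structure(list(f_true = profiles, g_dist = g_dist, noise_cv = noise_cv),
            class = "planted_sources")
}

#' Generate synthetic concentration matrices with known sources
#'
#' Draws sample contributions G from the planted per-factor distributions,
#' forms X = G F under multiplicative noise, censors cells that fall below
#' the congener MDL, and returns both the data and the ground truth. Noise is
#' multiplicative lognormal by default — `X = GF * exp(N(-s^2/2, s^2))` with
#' `s^2 = log(1 + noise_cv^2)`, mean 1 — matching the heavy right tails of
#' dust concentrations that span several orders of magnitude; additive
#' Gaussian noise (truncated at 0) is available as an option.
#'
#' @param n number of samples (>= 1).
#' @param sources a [planted_sources()].
#' @param panel congener panel supplying MDLs; must have as many rows as the
#'   profiles have columns.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @param noise one of `"lognormal"`, `"additive"`.
#' @return list with `data` (a [conc_matrix()], censored cells already
#'   flagged but not substituted), `g_true` (n x p), `f_true` (p x m). The
#'   ground truth is never written into the data file.
#' @export
gen_concentrations <- function(n, sources, panel = default_panel(),
                               seed = 1L, noise = c("lognormal", "additive")) {
  stopifnot(inherits(sources, "planted_sources"), n >= 1)
  noise <- match.arg(noise)
  f <- sources$f_true
  p <- nrow(f); m <- ncol(f)
  if (nrow(panel) != m)
    stop(sprintf("panel has %d congeners but profiles have %d columns",
                 nrow(panel), m))
  set.seed(as.integer(seed))
  g <- vapply(seq_len(p), function(k) r_dist(sources$g_dist[[k]], n),
              numeric(n))
  g <- matrix(g, nrow = n, ncol = p)
  x0 <- g %*% f
  cv <- sources$noise_cv
  if (cv > 0) {
    if (noise == "lognormal") {
      s2 <- log(1 + cv^2)
      x <- x0 * matrix(rlnorm(n * m, -s2 / 2, sqrt(s2)), n, m)
    } else {
      x <- pmax(x0 + matrix(rnorm(n * m, 0, cv * mean(x0)), n, m), 0)
    }
  } else {
    x <- x0
  }
  colnames(x) <- panel$name
  censored <- sweep(x, 2L, panel$mdl, "<")
  list(data = conc_matrix(x, censored, panel),
       g_true = g, f_true = f)
}

#' Generate a population of exposure-factor draws
#'
#' Samples `n_draws` joint realisations of the exposure factors of a
#' population specification — each factor an independent [dist_spec()] — for
#' use in Monte Carlo risk propagation or as synthetic survey data. All draws
#' are positive (truncation at 0 by resampling).
#'
#' @param spec named list of [dist_spec()] objects, one per exposure factor.
#' @param n_draws number of rows (>= 1).
#' @param seed integer seed.
#' @return data.frame with one column per factor, `n_draws` rows.
#' @export
gen_exposure_population <- function(spec, n_draws, seed = 1L) {
  stopifnot(is.list(spec), length(spec) >= 1, n_draws >= 1)
  if (is.null(names(spec)) || any(names(spec) == ""))
    stop("every exposure factor must be named")
  bad <- !vapply(spec, inherits, logical(1), "dist_spec")
  if (any(bad))
    stop("not a dist_spec: ", paste(names(spec)[bad], collapse = ", "))
  set.seed(as.integer(seed))
  out <- lapply(spec, function(s) as.numeric(r_dist(s, n_draws, lower = 0)))
  as.data.frame(out, optional = TRUE)
}
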