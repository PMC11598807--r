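#' Measurement-uncertainty matrix for PMF
#'
#' Builds the per-cell uncertainty sigma used to weight the factorization
#' objective. For a concentration at or below the congener MDL the
#' uncertainty is a fixed fraction of the MDL, `sigma = (5/6) MDL`; above the
#' MDL it combines the relative error with half the MDL,
#' `sigma = sqrt((error_fraction * C)^2 + (0.5 * MDL)^2)`. The rule is
#' deliberately discontinuous at C = MDL (the below-MDL branch applies at
#' equality), the receptor-modelling convention.
#'
#' @param m a [conc_matrix()] (values already substituted or raw; the branch
#'   is chosen by comparing the stored value with the MDL).
#' @param error_fraction relative measurement error in (0, 1); 0.1 is the
#'   conventional choice.
#' @return list of class `uncertainty_matrix` with `sigma` (n x m) and
#'   `error_fraction`.
#' @export
build_uncertainty <- function(m, error_fraction = 0.1) {
  stopifnot(inherits(m, "conc_matrix"))
  if (!(error_fraction > 0 && error_fraction < 1))
    stop("error_fraction must be in (0, 1)")
  mdl <- m$panel$mdl
  if (any(!is.finite(mdl)) || any(mdl <= 0))
    stop("every congener needs a positive MDL")
  x <- m$values
  mdlm <- matrix(mdl, nrow(x), ncol(x), byrow = TRUE)
  below <- x <= mdlm | m$censored
  sigma <- sqrt((error_fraction * x)^2 + (0.5 * mdlm)^2)
  sigma[below] <- (5 / 6) * mdlm[below]
  dimnames(sigma) <- dimnames(x)
  structure(list(sigma = sigma, error_fraction = error_fraction),
            class = "uncertainty_matrix")
}

#' PMF objective Q
#'
#' Uncertainty-weighted sum of squared residuals,
#' `Q = sum(((x - g f) / sigma)^2)`.
#'
#' @param x n x m data matrix.
#' @param g n x p contributions.
#' @param f p x m profiles.
#' @param sigma n x m positive uncertainties.
#' @return scalar Q >= 0.
#' @export
pmf_q <- function(x, g, f, sigma) {
  x <- as.matrix(x); g <- as.matrix(g); f <- as.matrix(f)
  sigma <- as.matrix(sigma)
  if (!identical(dim(x), dim(sigma)))
    stop("x and sigma must have the same shape")
  if (ncol(g) != nrow(f) || nrow(g) != nrow(x) || ncol(f) != ncol(x))
    stop("nonconforming factor shapes")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  sum(((x - g %*% f) / sigma)^2)
}

#' Fit a positive matrix factorization
#'
#' Weighted nonnegative factorization X ~ G F minimising the
#' uncertainty-weighted least-squares objective [pmf_q()] under G, F >= 0,
#' via multiplicative update rules with 1/sigma^2 weights (the weighted
#' Lee-Seung scheme, monotone nonincreasing in Q). Multiple random restarts
#' are run from strictly positive initialisations scaled to the column
#' means, with per-restart seeds drawn from a seeded master stream; the
#' restart with the lowest Q wins. For reporting, rows of F are normalised
#' to sum to 1 with G absorbing the scale, which removes the diagonal
#' rescaling ambiguity of the factorization.
#'
#' @param x n x m nonnegative data matrix (or [conc_matrix()], substituted).
#' @param sigma n x m uncertainties (or an `uncertainty_matrix`).
#' @param p number of factors, 1 <= p <= min(n, m).
#' @param restarts number of random restarts (default 20).
#' @param seed integer master seed; results are deterministic given it.
#' @param max_iter maximum update sweeps per restart.
#' @param tol convergence threshold on the relative change of Q.
#' @return list of class `pmf_result`: `g`, `f`, `q`, `e` (residuals
#'   X - G F), `q_trace` (per-iteration Q of the winning restart),
#'   `q_restarts`, `converged`, `restarts`, `seed`.
#' @export
fit_pmf <- function(x, sigma, p, restarts = 20L, seed = 1L,
                    max_iter = 5000L, tol = 1e-8) {
  if (inherits(x, "conc_matrix")) x <- x$values
  if (inherits(sigma, "uncertainty_matrix")) sigma <- sigma$sigma
  x <- as.matrix(x); sigma <- as.matrix(sigma)
  n <- nrow(x); m <- ncol(x)
  if (p < 1 || p > min(n, m))
    stop("p must satisfy 1 <= p <= min(n, m)")
  if (restarts < 1) stop("restarts must be >= 1")
  if (any(x < 0)) stop("x must be nonnegative")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  zerocol <- colSums(x) == 0
  if (any(zerocol))
    stop("column(s) with no signal (all zero): ",
         paste(colnames(x)[zerocol], collapse = ", "),
         "; exclude them before fitting")
  w <- 1 / sigma^2
  wx <- w * x
  eps <- .Machine$double.eps
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max, restarts)
  colmean <- colMeans(x)
  best <- NULL
  q_restarts <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    # strictly positive init scaled to column means
    g <- matrix(runif(n * p, 0.1, 1), n, p)
    f <- matrix(runif(p * m, 0.1, 1), p, m)
    f <- f * rep(colmean / (colMeans(g %*% f) + eps), each = p)
    q <- pmf_q(x, g, f, sigma)
    q_trace <- q
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      gf <- g %*% f
      f <- f * (crossprod(g, wx) / pmax(crossprod(g, w * gf), eps))
      gf <- g %*% f
      g <- g * (tcrossprod(wx, f) / pmax((w * gf) %*% t(f), eps))
      q_new <- pmf_q(x, g, f, sigma)
      q_trace <- c(q_trace, q_new)
      if (is.finite(q) && abs(q - q_new) <= tol * max(q, eps)) {
        q <- q_new
        converged <- TRUE
        break
      }
      q <- q_new
    }
    q_restarts[r] <- q
    if (is.null(best) || q < best$q)
      best <- list(g = g, f = f, q = q, q_trace = q_trace,
                   converged = converged)
  }
  # normalise profiles: rows of f sum to 1, g absorbs the scale
  s <- rowSums(best$f)
  f <- best$f / s
  g <- best$g * rep(s, each = n)
  dimnames(f) <- list(paste0("Factor", seq_len(p)), colnames(x))
  dimnames(g) <- list(rownames(x), paste0("Factor", seq_len(p)))
  structure(list(g = g, f = f, q = best$q, e = x - g %*% f,
                 q_trace = best$q_trace, q_restarts = q_restarts,
                 converged = best$converged, restarts = restarts,
                 seed = as.integer(seed)),
            class = "pmf_result")
}

#' @export
print.pmf_result <- function(x, ...) {
  cat(sprintf("pmf_result: %d factors, Q = %.4g (%d restarts%s)\n",
              nrow(x$f), x$q, x$restarts,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Per-congener factor contribution percentages
#'
#' For each congener, the share of its total modelled mass attributed to
#' each factor: `100 * sum_i g_ik f_kj / sum_k sum_i g_ik f_kj`. Rows sum to
#' 100; congeners with zero modelled mass are reported as `NA` with a
#' warning.
#'
#' @param r a `pmf_result`.
#' @return m x p matrix of percentages.
#' @export
species_contributions <- function(r) {
  stopifnot(inherits(r, "pmf_result"))
  mass <- t(r$f * colSums(r$g))           # m x p: sum_i g_ik f_kj
  tot <- rowSums(mass)
  zero <- tot == 0
  if (any(zero))
    warning("congener(s) with zero modelled mass: ",
            paste(rownames(mass)[zero], collapse = ", "))
  out <- 100 * mass / ifelse(tot == 0, NA, tot)
  out
}

#' Match estimated factors to reference profiles
#'
#' One-to-one assignment between estimated and reference profile rows
#' maximising the total cosine similarity, by exhaustive search over
#' permutations (practical for p <= 8). Cosine similarity is
#' scale-invariant, so profile normalisation conventions do not matter.
#'
#' @param f_est p x m estimated profiles.
#' @param f_true p x m reference profiles.
#' @return list with `perm` (index into rows of `f_true` for each row of
#'   `f_est`), `similarity` (per matched pair), `mean_similarity`.
#' @export
match_factors <- function(f_est, f_true) {
  f_est <- as.matrix(f_est); f_true <- as.matrix(f_true)
  if (!identical(dim(f_est), dim(f_true)))
    stop("profile matrices must have identical shape")
  p <- nrow(f_est)
  if (p > 8) stop("exhaustive matching supports at most 8 factors")
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(p), seq_len(p),
               Vectorize(function(i, j) cosine(f_est[i, ], f_true[j, ])))
  perms <- permutations_of(p)
  scores <- vapply(perms, function(pr) sum(sim[cbind(seq_len(p), pr)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  s <- sim[cbind(seq_len(p), best)]
  list(perm = best, similarity = s, mean_similarity = mean(s))
}

permutations_of <- function(p) {
  # all permutations of 1..p, by inserting p into each (p-1)-permutation
  if (p == 1L) return(list(1L))
  sub <- permutations_of(p - 1L)
  out <- vector("list", p * length(sub))
  i <- 0L
  for (s in sub) for (pos in 0:(p - 1L)) {
    i <- i + 1L
    out[[i]] <- append(s, p, after = pos)
  }
  out
}
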