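#' Per-congener normality screen
#'
#' Shapiro-Wilk test per congener. Environmental concentration data are
#' typically heavy-tailed, and a failed screen motivates rank-based
#' (Spearman) correlation downstream; the result carries a `weak_adherence`
#' flag set when any congener rejects normality at the 5% level.
#'
#' @param m a [conc_matrix()] (substituted).
#' @return data.frame with `congener`, `statistic`, `p`; attribute
#'   `weak_adherence`.
#' @export
normality_screen <- function(m) {
  stopifnot(inherits(m, "conc_matrix"))
  if (nrow(m$values) < 3L)
    stop("normality screen requires at least 3 samples per congener")
  res <- lapply(seq_len(ncol(m$values)), function(j) {
    x <- m$values[, j]
    if (sd(x) == 0)
      stop("constant column: ", colnames(m$values)[j])
    t <- shapiro.test(x)
    c(statistic = unname(t$statistic), p = t$p.value)
  })
  out <- data.frame(congener = colnames(m$values),
                    do.call(rbind, res), row.names = NULL)
  attr(out, "weak_adherence") <- any(out$p < 0.05)
  out
}

#' Spearman correlation matrix with p-values
#'
#' Rank correlation between all congener pairs (average ranks for ties);
#' two-sided p-values from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom. Constant columns
#' yield `NA` correlations with a warning.
#'
#' @param m a [conc_matrix()] or numeric matrix (columns = variables).
#' @return list of class `correlation_result` with elements `r`, `p`, `n`.
#' @export
spearman_matrix <- function(m) {
  x <- if (inherits(m, "conc_matrix")) m$values else as.matrix(m)
  n <- nrow(x)
  if (n < 3L) stop("Spearman correlation requires at least 3 samples")
  const <- apply(x, 2L, sd) == 0
  if (any(const)) {
    warning("constant column(s), correlations reported as NA: ",
            paste(colnames(x)[const], collapse = ", "))
  }
  r <- suppressWarnings(cor(x, method = "spearman"))
  r[const, ] <- NA; r[, const] <- NA; diag(r) <- ifelse(const, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  structure(list(r = r, p = p, n = n), class = "correlation_result")
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO computed from the anti-image (partial) correlations:
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries, where
#' `q_ij = -s_ij / sqrt(s_ii s_jj)` and S is the inverse of the correlation
#' matrix. Values above 0.6 are conventionally required before factor
#' analysis; low-communality variables can be dropped to raise it.
#'
#' @param r correlation matrix (symmetric, unit diagonal).
#' @return scalar in \[0, 1\].
#' @export
kmo_statistic <- function(r) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r))
  inv <- tryCatch(solve(r), error = function(e)
    stop("correlation matrix is singular; consider removing congeners ",
         "with low common factor variance"))
  q <- -inv / sqrt(tcrossprod(diag(inv)))
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2m + 5)/6) log det(R)` on `m(m-1)/2` degrees of
#' freedom.
#'
#' @param r correlation matrix.
#' @param n number of samples behind `r` (must exceed the number of
#'   variables).
#' @return list with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(r, n) {
  r <- as.matrix(r)
  m <- ncol(r)
  if (n <= m) stop("Bartlett's test requires n > number of variables")
  d <- det(r)
  if (d <= 0) stop("det(R) <= 0: correlation matrix not positive definite")
  chi2 <- -(n - 1 - (2 * m + 5) / 6) * log(d)
  df <- m * (m - 1) / 2
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' PCA on the correlation matrix with varimax rotation
#'
#' Columns are standardised internally; the correlation matrix is
#' eigen-decomposed, the top `k` loadings (`lambda = v sqrt(e)`) are rotated
#' with normalised-Kaiser varimax, and per-factor variance explained is
#' reported as the rotated sum of squared loadings over the number of
#' variables. Communalities are invariant under the orthogonal rotation. The
#' sign of each rotated factor is fixed so its largest-magnitude loading is
#' positive. `k` is caller-specified; the eigenvalue-at-least-1 count is
#' returned as `suggested_k` for reference, since substantive source
#' interpretation can justify retaining a factor slightly below that
#' threshold.
#'
#' @param m a [conc_matrix()] or numeric matrix.
#' @param k number of factors to retain (<= number of variables).
#' @param exclude character vector of congener columns to drop before
#'   analysis (e.g. variables with low communalities that depress the KMO).
#' @return list of class `factor_model`: `loadings` (m x k, rotated),
#'   `eigenvalues`, `variance_explained` (%), `cumulative` (%),
#'   `communalities`, `kmo`, `bartlett`, `suggested_k`.
#' @export
pca_varimax <- function(m, k, exclude = character()) {
  x <- if (inherits(m, "conc_matrix")) m$values else as.matrix(m)
  if (length(exclude)) {
    unknown <- setdiff(exclude, colnames(x))
    if (length(unknown))
      stop("exclude names not in data: ", paste(unknown, collapse = ", "))
    x <- x[, setdiff(colnames(x), exclude), drop = FALSE]
  }
  if (any(!is.finite(x))) stop("non-finite values in input")
  nvar <- ncol(x); n <- nrow(x)
  if (k > nvar) stop("k must not exceed the number of variables")
  r <- cor(x)
  eig <- eigen(r, symmetric = TRUE)
  ev <- eig$values
  lambda <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(k)], 0)), k)
  rownames(lambda) <- colnames(x)
  rot <- if (k > 1L) {
    vr <- varimax(lambda, normalize = TRUE, eps = 1e-10)
    unclass(vr$loadings)
  } else lambda
  # sign convention: dominant loading of each factor positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  colnames(rot) <- paste0("Factor", seq_len(k))
  ssl <- colSums(rot^2)
  ord <- order(ssl, decreasing = TRUE)
  rot <- rot[, ord, drop = FALSE]
  colnames(rot) <- paste0("Factor", seq_len(k))
  ssl <- ssl[ord]
  ve <- ssl / nvar * 100
  structure(list(
    loadings = rot,
    eigenvalues = ev,
    variance_explained = ve,
    cumulative = cumsum(ve),
    communalities = rowSums(rot^2),
    kmo = kmo_statistic(r),
    bartlett = bartlett_sphericity(r, n),
    suggested_k = sum(ev >= 1),
    k = k
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d factors, %.2f%% cumulative variance\n",
              x$k, x$cumulative[x$k]))
  cat(sprintf("KMO %.3f; Bartlett chi2 %.1f (df %d, p %.3g)\n",
              x$kmo, x$bartlett$chi2, x$bartlett$df, x$bartlett$p))
  invisible(x)
}
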