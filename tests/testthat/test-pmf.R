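test_that("uncertainty rules evaluate their closed forms", {
  pan <- default_panel("TnBP")          # MDL 0.05
  below <- conc_matrix(matrix(0.01, 1, 1, dimnames = list(NULL, "TnBP")),
                       panel = pan)
  expect_equal(unname(drop(build_uncertainty(below, 0.1)$sigma)), 5 / 6 * 0.05)
  expect_equal(unname(drop(build_uncertainty(below, 0.1)$sigma)), 0.0416667,
               tolerance = 1e-5)
  above <- conc_matrix(matrix(10, 1, 1, dimnames = list(NULL, "TnBP")),
                       panel = pan)
  expect_equal(unname(drop(build_uncertainty(above, 0.1)$sigma)),
               sqrt((0.1 * 10)^2 + (0.5 * 0.05)^2))
  expect_equal(unname(drop(build_uncertainty(above, 0.1)$sigma)), 1.000312,
               tolerance = 1e-6)
  # equality goes to the below-MDL branch
  at_mdl <- conc_matrix(matrix(0.05, 1, 1, dimnames = list(NULL, "TnBP")),
                        panel = pan)
  expect_equal(unname(drop(build_uncertainty(at_mdl, 0.1)$sigma)), 5 / 6 * 0.05)
  expect_error(build_uncertainty(above, 0), "error_fraction")
  expect_error(build_uncertainty(above, 1), "error_fraction")
})

test_that("the uncertainty rule is discontinuous at C = MDL by a known jump", {
  mdl <- 0.05; ef <- 0.1
  at <- 5 / 6 * mdl
  just_above <- sqrt((ef * mdl)^2 + (0.5 * mdl)^2)
  expect_equal(at - just_above, mdl * (5 / 6 - sqrt(ef^2 + 0.25)))
  expect_gt(at, just_above)   # the below-MDL branch is the larger of the two
})

test_that("Q matches a brute-force double loop and its invariances", {
  set.seed(12)
  x <- matrix(rlnorm(20), 5, 4)
  g <- matrix(runif(10), 5, 2)
  f <- matrix(runif(8), 2, 4)
  sigma <- matrix(runif(20, 0.5, 2), 5, 4)
  q_oracle <- 0
  gf <- g %*% f
  for (i in 1:5) for (j in 1:4)
    q_oracle <- q_oracle + ((x[i, j] - gf[i, j]) / sigma[i, j])^2
  expect_equal(pmf_q(x, g, f, sigma), q_oracle, tolerance = 1e-12)
  expect_equal(pmf_q(gf, g, f, sigma), 0)
  expect_equal(pmf_q(matrix(3), matrix(1), matrix(1), matrix(1)), 4)
  # diagonal rescaling ambiguity leaves Q unchanged
  d <- c(0.3, 7)
  expect_equal(pmf_q(x, g %*% diag(d), diag(1 / d) %*% f, sigma),
               pmf_q(x, g, f, sigma), tolerance = 1e-10)
  expect_error(pmf_q(x, g, f, sigma * 0), "positive")
  expect_error(pmf_q(x, g, matrix(1, 3, 4), sigma), "nonconforming")
})

test_that("noise-free planted data factorize to near-zero Q", {
  set.seed(2)
  g <- matrix(rlnorm(40 * 3), 40, 3)
  f <- random_profiles(3, 6, 3); f <- f / rowSums(f)
  x <- g %*% f
  sigma <- matrix(0.1 * mean(x), 40, 6)
  fit <- fit_pmf(x, sigma, p = 3, restarts = 5, seed = 1)
  expect_lte(fit$q, 1e-6 * 40 * 6)
  expect_true(all(fit$g >= 0) && all(fit$f >= 0))
  expect_equal(fit$e, x - fit$g %*% fit$f)
  expect_equal(fit$q, pmf_q(x, fit$g, fit$f, sigma), tolerance = 1e-8)
  expect_equal(unname(rowSums(fit$f)), rep(1, 3))   # reporting normalisation
})

test_that("updates are monotone and the best restart is returned", {
  sim <- planted_sim(n = 60, p = 2, noise_cv = 0.15, seed = 19)
  m <- substitute_below_mdl(sim$data)
  sigma <- build_uncertainty(m, 0.1)
  fit <- fit_pmf(m, sigma, p = 2, restarts = 6, seed = 7)
  # within the winning restart Q never increases (up to convergence slack)
  expect_true(all(diff(fit$q_trace) <=
                    1e-8 * pmax(head(fit$q_trace, -1), 1)))
  expect_equal(fit$q, min(fit$q_restarts))
  expect_lte(fit$q, fit$q_trace[length(fit$q_trace)] + 1e-9)
  # more restarts never worse at a fixed master seed
  q1 <- fit_pmf(m, sigma, p = 2, restarts = 1, seed = 7)$q
  expect_lte(fit$q, q1 + 1e-12)
  # determinism
  fit2 <- fit_pmf(m, sigma, p = 2, restarts = 6, seed = 7)
  expect_identical(fit$q, fit2$q)
  expect_identical(fit$f, fit2$f)
})

test_that("fit_pmf validates its inputs", {
  x <- matrix(1, 4, 3); s <- matrix(1, 4, 3)
  expect_error(fit_pmf(x, s, p = 4), "1 <= p")
  expect_error(fit_pmf(x, s, p = 2, restarts = 0), "restarts")
  x0 <- x; x0[, 2] <- 0
  colnames(x0) <- colnames(s) <- c("a", "b", "c")
  expect_error(fit_pmf(x0, s, p = 2), "exclude")
})

test_that("species contributions are normalised shares of modelled mass", {
  sim <- planted_sim(n = 80, p = 2, noise_cv = 0.1, seed = 23)
  m <- substitute_below_mdl(sim$data)
  fit <- fit_pmf(m, build_uncertainty(m, 0.1), p = 2, restarts = 8,
                 seed = 2)
  sc <- species_contributions(fit)
  expect_equal(unname(rowSums(sc)), rep(100, ncol(m$values)),
               tolerance = 1e-8)
  one <- fit_pmf(m, build_uncertainty(m, 0.1), p = 1, restarts = 2,
                 seed = 2)
  expect_equal(unname(species_contributions(one)[, 1]),
               rep(100, ncol(m$values)))
})

test_that("a congener fed by a single factor is attributed to it", {
  # factor 1 alone generates congener 1
  f <- rbind(c(0.6, 0.2, 0.1, 0.1, 0, 0),
             c(0,   0.1, 0.2, 0.2, 0.3, 0.2))
  pan <- default_panel()[1:6, ]
  src <- planted_sources(f, noise_cv = 0.05)
  sim <- gen_concentrations(150, src, pan, seed = 6)
  m <- substitute_below_mdl(sim$data)
  fit <- fit_pmf(m, build_uncertainty(m, 0.1), p = 2, restarts = 10,
                 seed = 4)
  mt <- match_factors(fit$f, sim$f_true)
  est_factor1 <- which(mt$perm == 1)
  sc <- species_contributions(fit)
  expect_gte(sc[1, est_factor1], 95)
})

test_that("factor matching recovers permutations and ignores scale", {
  f <- random_profiles(3, 8, 41)
  perm <- c(3, 1, 2)
  mt <- match_factors(f[perm, ], f)
  expect_equal(mt$perm, perm)
  expect_equal(mt$similarity, rep(1, 3), tolerance = 1e-12)
  mt2 <- match_factors(f * c(10, 0.1, 3), f)   # row rescaling
  expect_equal(mt2$perm, 1:3)
  expect_equal(mt2$mean_similarity, 1, tolerance = 1e-12)
})

test_that("matching equals an explicit brute force over assignments", {
  f_est <- random_profiles(3, 8, 51)
  f_true <- random_profiles(3, 8, 52)
  mt <- match_factors(f_est, f_true)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  scores <- vapply(perms, function(pr)
    sum(vapply(1:3, function(i) cosine(f_est[i, ], f_true[pr[i], ]),
               numeric(1))), numeric(1))
  expect_equal(sum(mt$similarity), max(scores), tolerance = 1e-12)
  expect_error(match_factors(matrix(1, 9, 10), matrix(1, 9, 10)),
               "at most 8")
})
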