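test_that("distribution selection identifies a lognormal sample", {
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    fit_best_distribution(rlnorm(1000, 0, 1))$family
  }, character(1))
  expect_gte(mean(picks == "lognormal"), 0.95)
})

test_that("distribution fitting handles degenerate and invalid input", {
  f <- fit_best_distribution(rep(7, 30))
  expect_equal(f$family, "point")
  expect_equal(f$spec$value, 7)
  expect_error(fit_best_distribution(c(1, 2, 3, 4, 5)), "at least 20")
  set.seed(1)
  x <- c(rnorm(50), -1)   # nonpositive: positive-support families skipped
  w <- capture_warnings(f2 <- fit_best_distribution(x))
  expect_match(w, "skipping", all = TRUE)
  expect_length(w, 3)
  expect_equal(f2$family, "normal")
  expect_true(all(c("ad", "chisq", "chisq_p") %in% names(f2$gof)))
})

test_that("moment-matched lognormal reproduces mean and SD", {
  spec <- lognormal_from_mean_sd(43.4, 104)
  expect_equal(exp(spec$meanlog + spec$sdlog^2 / 2), 43.4)
  v <- (exp(spec$sdlog^2) - 1) * exp(2 * spec$meanlog + spec$sdlog^2)
  expect_equal(sqrt(v), 104)
  expect_equal(lognormal_from_mean_sd(5, 0)$family, "point")
})

test_that("percentile summary follows the linear-interpolation convention", {
  expect_equal(percentile_summary(as.numeric(1:100), 50)$value, 50.5)
  draws <- rep(3.3, 50)
  p <- percentile_summary(draws, c(10, 50, 90))
  expect_equal(p$value, rep(3.3, 3))
  expect_error(percentile_summary(draws, 120), "\\[0, 100\\]")
  expect_error(percentile_summary(numeric(0)), "no draws")
})

test_that("point-mass Monte Carlo reproduces the deterministic pipeline exactly", {
  ref <- reference_concentrations()
  panel <- default_panel()
  prm <- default_exposure_params("occupational")
  conc <- setNames(ref$mean_ng_g * 1e-3, ref$compound)
  at <- add_table(conc, panel, prm)
  hi_det <- attr(suppressWarnings(hq_table(at, panel)), "hi")
  cr_det <- attr(suppressWarnings(cr_table(at, panel, prm)), "cr_total")
  cd <- lapply(conc, function(v) dist_spec("point", value = v))
  rd <- monte_carlo_risk(cd, list(), panel, prm, n_iter = 50, seed = 1)
  expect_identical(unique(rd$draws$hi), hi_det)
  expect_identical(unique(rd$draws$cr), cr_det)
  p <- percentile_summary(rd)
  expect_equal(p$hi, rep(hi_det, 3))
})

test_that("Monte Carlo draws are seed-reproducible and homogeneous in C", {
  cd <- default_concentration_dists()
  prm <- default_exposure_params("occupational")
  pdists <- default_param_dists(prm)
  a <- monte_carlo_risk(cd, pdists, params = prm, n_iter = 500, seed = 3)
  b <- monte_carlo_risk(cd, pdists, params = prm, n_iter = 500, seed = 3)
  expect_identical(a$draws, b$draws)
  expect_identical(a$inputs, b$inputs)
  d <- monte_carlo_risk(cd, pdists, params = prm, n_iter = 500, seed = 4)
  expect_false(identical(a$draws$hi, d$draws$hi))
  # scaling all concentration distributions x10 scales HI draws x10
  cd10 <- lapply(cd, function(s) {
    s$meanlog <- s$meanlog + log(10); s
  })
  a10 <- monte_carlo_risk(cd10, pdists, params = prm, n_iter = 500, seed = 3)
  expect_equal(a10$draws$hi, 10 * a$draws$hi, tolerance = 1e-10)
})

test_that("percentile error shrinks like one over the square root of n", {
  ref <- reference_concentrations()
  cd <- setNames(lapply(ref$mean_ng_g * 1e-3,
                        function(m) lognormal_from_mean_sd(m, 0.5 * m)),
                 ref$compound)
  prm <- default_exposure_params("occupational")
  pdists <- default_param_dists(prm)
  n_grid <- c(100, 1000, 10000)
  sds <- vapply(n_grid, function(nit) {
    p90 <- vapply(1:10, function(s)
      percentile_summary(monte_carlo_risk(cd, pdists, params = prm,
                                          n_iter = nit,
                                          seed = 100 + s))$hi[3],
      numeric(1))
    sd(p90)
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(n_grid)))[2]
  expect_lt(abs(slope - (-0.5)), 0.3 * 0.5)
})

test_that("monte_carlo_risk validates missing distributions by name", {
  cd <- default_concentration_dists()
  expect_error(monte_carlo_risk(cd, list(bw = 70)), "bw")
  expect_error(monte_carlo_risk(cd, list(foo = dist_spec("point", value = 1))),
               "foo")
  cd$TnBP <- NULL; cd$bogus <- dist_spec("point", value = 1)
  expect_error(monte_carlo_risk(cd), "bogus")
})

test_that("sensitivity contributions isolate a single varying input", {
  set.seed(9)
  x <- data.frame(a = runif(2000), b = rep(1, 2000))
  out <- x$a * 3
  expect_warning(s <- sensitivity_contributions(x, out), "constant")
  expect_equal(s$contribution[s$input == "a"], 100)
  expect_equal(s$contribution[s$input == "b"], 0)
})

test_that("symmetric independent inputs split the contribution evenly", {
  set.seed(17)
  x <- data.frame(a = rnorm(10000, 10, 1), b = rnorm(10000, 10, 1))
  s <- sensitivity_contributions(x, x$a + x$b)
  expect_equal(s$contribution[s$input == "a"], 50, tolerance = 0.1)
  expect_equal(s$contribution[s$input == "b"], 50, tolerance = 0.1)
  expect_equal(sum(abs(s$contribution)), 100, tolerance = 1e-6)
})

test_that("sensitivity is rank-based and signed", {
  set.seed(23)
  x <- data.frame(a = runif(1000, 1, 2), b = runif(1000, 1, 2))
  out <- x$a / x$b            # b enters in the denominator
  s1 <- sensitivity_contributions(x, out)
  expect_lt(s1$contribution[s1$input == "b"], 0)
  expect_gt(s1$contribution[s1$input == "a"], 0)
  # invariance under strictly monotone rescaling of an input
  x2 <- x; x2$a <- log(x2$a)
  s2 <- sensitivity_contributions(x2, out)
  expect_equal(s1$contribution, s2$contribution, tolerance = 1e-12)
  expect_error(sensitivity_contributions(x[1:50, ], out[1:50]),
               "at least 100")
})

test_that("body weight contributes negatively in the risk simulation", {
  prm <- default_exposure_params("occupational")
  rd <- monte_carlo_risk(default_concentration_dists(),
                         default_param_dists(prm), params = prm,
                         n_iter = 3000, seed = 11)
  s <- suppressWarnings(sensitivity_contributions(rd, "hi"))
  expect_lt(s$contribution[s$input == "bw"], 0)
  expect_gt(s$contribution[s$input == "et"], 0)
})
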