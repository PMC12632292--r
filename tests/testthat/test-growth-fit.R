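test_that("noiseless data is fit exactly and ties break to the linear model", {
  set.seed(10)
  x <- runif(40, 22, 32)
  f <- fit_growth_model(x, 1 + 2 * x)
  expect_identical(f$degree, 1L)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-10)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-10)
  expect_true(all(f$inlier_mask))
  # equality with ordinary least squares under zero outliers / zero noise
  ols <- coef(lm(y ~ x, data.frame(x = x, y = 1 + 2 * x)))
  expect_equal(unname(coef(f)), unname(ols), tolerance = 1e-9)
})

test_that("an exact parabola selects the quadratic by AIC", {
  set.seed(11)
  x <- runif(50, 22, 32)
  y <- 3 - 0.5 * x + 0.08 * x^2
  f <- fit_growth_model(x, y)
  expect_identical(f$degree, 2L)
  expect_lt(f$aic_quadratic, f$aic_linear)
  expect_equal(unname(coef(f)), c(3, -0.5, 0.08), tolerance = 1e-8)
})

test_that("gross outliers are excluded and the slope survives them", {
  set.seed(12)
  x <- runif(68, 22, 32)
  mu <- 1 + 2 * x
  sig <- 0.4
  y <- mu + rnorm(68, 0, sig)
  bad <- sample.int(68, 13)               # ~19% contamination
  y[bad] <- mu[bad] + sample(c(-1, 1), 13, TRUE) * runif(13, 5, 8) * sig
  f <- fit_growth_model(x, y, degrees = 1L)
  expect_true(all(!f$inlier_mask[bad]))
  expect_lt(abs(coef(f)["slope"] - 2) / 2, 0.02)
  # oracle: least squares on the clean subset agrees closely
  clean <- coef(lm(y[-bad] ~ x[-bad]))[2]
  expect_lt(abs(coef(f)["slope"] - clean) / 2, 0.02)
})

test_that("consensus below minimum inclusion falls back with a flag", {
  set.seed(13)
  x <- runif(20, 22, 32)
  y <- rnorm(20) # no structure; threshold from scatter keeps most points
  f <- fit_growth_model(x, y)
  expect_true(sum(f$inlier_mask) >= ceiling(0.75 * 20) || f$fallback)
  # constant covariate: degenerate design handled as intercept-only
  fc <- fit_growth_model(rep(5, 15), rnorm(15))
  expect_true(fc$degenerate_x)
  expect_equal(unname(coef(fc)["slope"]), 0)
})

test_that("fits are deterministic, seed-isolated, and serializable", {
  set.seed(14)
  x <- runif(30, 22, 32)
  y <- 2 + 0.3 * x + rnorm(30, 0, 0.3)
  f1 <- fit_growth_model(x, y)
  f2 <- fit_growth_model(x, y)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$inlier_mask, f2$inlier_mask)
  # the fixed internal seed must not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(fit_growth_model(x, y)); b <- runif(1)
  expect_identical(a, b)
  js <- jsonlite::fromJSON(growth_fit_json(f1))
  expect_equal(js$degree, f1$degree)
  expect_equal(unlist(js$coefficients), coef(f1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(js$inlier_indices, which(f1$inlier_mask))
})

test_that("breakdown: slope error is small below 25% contamination and grows", {
  errs <- vapply(c(0.05, 0.15, 0.23, 0.35, 0.45), function(frac) {
    e <- vapply(1:12, function(s) {
      set.seed(1000 + s)
      x <- runif(80, 22, 32)
      mu <- 1 + 2 * x
      sig <- 0.3
      y <- mu + rnorm(80, 0, sig)
      k <- round(frac * 80)
      bad <- sample.int(80, k)
      y[bad] <- mu[bad] + runif(k, 5, 8) * sig   # one-sided gross deviates
      abs(coef(fit_growth_model(x, y, degrees = 1L))["slope"] - 2) / 2
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_lt(errs[1], 0.02)
  expect_lt(errs[2], 0.02)
  expect_lt(errs[3], 0.02)
  expect_gt(errs[5], errs[3])  # degrades beyond the design contamination
})

test_that("model methods: predict, fitted, simulate, summary, plot", {
  set.seed(15)
  x <- runif(30, 22, 32)
  f <- fit_growth_model(x, 5 + x + rnorm(30, 0, 0.1), degrees = 1L)
  expect_equal(predict(f, 27), unname(coef(f)[1] + coef(f)[2] * 27))
  expect_equal(fitted(f), predict(f))
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(30L, 3L))
  expect_identical(sim, simulate(f, nsim = 3, seed = 1))
  s <- summary(f)
  expect_s3_class(s, "summary.sp_growth_fit")
  expect_gt(s$r_squared, 0.95)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
  expect_output(print(f), "Robust growth fit")
})

test_that("input contracts are enforced", {
  expect_error(fit_growth_model(1:5, 1:5), "at least 10")
  expect_error(fit_growth_model(1:10, 1:9), "lengths differ")
  expect_error(fit_growth_model(c(1:9, NA), 1:10), "missing")
})
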