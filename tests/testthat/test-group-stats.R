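test_that("trimester assignment uses a strict boundary at 27 weeks", {
  expect_identical(as.character(assign_trimester_group(c(22, 27, 27.1, 32))),
                   c("late2", "late2", "early3", "early3"))
  expect_error(assign_trimester_group(21.5), "outside")
  expect_error(assign_trimester_group(33), "outside")
})

test_that("percent change arithmetic, degenerate cases, and CI shape", {
  pc <- percent_change(rep(100, 10), rep(150, 10))
  expect_equal(pc$pc, 50)
  expect_equal(pc$se, 0)
  eq <- percent_change(c(9, 10, 11), c(10, 9, 11))
  expect_equal(eq$pc, 0)
  expect_true(eq$ci95[1] < 0 && eq$ci95[2] > 0)
  expect_equal(mean(eq$ci95), eq$pc)                 # CI symmetric about pc
  bad <- percent_change(c(-2, 0, 2), c(1, 2, 3))
  expect_false(bad$defined)
  expect_true(is.na(bad$pc))
  expect_error(percent_change(1:2, 1:5), "at least 3")
})

test_that("delta-method SE matches a parametric bootstrap oracle", {
  m1 <- 100; se1 <- 2; m2 <- 150; se2 <- 3
  n <- 30
  sd1 <- se1 * sqrt(n); sd2 <- se2 * sqrt(n)
  # closed form under test, on synthetic groups with those moments
  g1 <- scale(rnorm(n)) * sd1 + m1
  g2 <- scale(rnorm(n)) * sd2 + m2
  pc <- percent_change(as.numeric(g1), as.numeric(g2))
  set.seed(31)
  boot <- replicate(1e5, {
    b1 <- m1 + rnorm(1, 0, se1)
    b2 <- m2 + rnorm(1, 0, se2)
    100 * (b2 - b1) / b1
  })
  expect_equal(pc$se, sd(boot), tolerance = 0.05 * sd(boot))
  expect_equal(pc$pc, mean(boot), tolerance = 0.3)
})

test_that("homotopic growth z-test arithmetic and antisymmetry", {
  pcL <- list(pc = 30, se = 3); pcR <- list(pc = 40, se = 4)
  zt <- homotopic_growth_ztest(pcL, pcR)
  expect_equal(zt$z, 2)                         # 10 / sqrt(9 + 16)
  expect_equal(zt$p, 2 * pnorm(-2))
  expect_equal(homotopic_growth_ztest(pcR, pcL)$z, -2)
  same <- homotopic_growth_ztest(pcL, pcL)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  expect_error(homotopic_growth_ztest(list(pc = 1, se = 0),
                                      list(pc = 1, se = 0)), "zero")
})

test_that("asymmetry index formula, bounds, and antisymmetry", {
  expect_equal(asymmetry_index(100, 100), 0)
  expect_equal(asymmetry_index(90, 110), 20)
  expect_equal(asymmetry_index(110, 90), -20)
  expect_equal(asymmetry_index(3, 6), 200 / 3)
  expect_true(is.na(asymmetry_index(0, 0)))
  set.seed(32)
  l <- runif(100, 1, 5); r <- runif(100, 1, 5)
  expect_equal(asymmetry_index(l, r), -asymmetry_index(r, l))
  expect_true(all(abs(asymmetry_index(l, r)) <= 200))
})

test_that("lateralization t-test and its degenerate contract", {
  z <- lateralization_test(rep(0, 10))
  expect_equal(z$t_stat, 0); expect_equal(z$p, 1)
  d <- lateralization_test(rep(3, 10))
  expect_true(d$degenerate); expect_equal(d$p, 0)
  set.seed(33)
  ai <- rnorm(30, 20, 10)
  lt <- lateralization_test(ai)
  tt <- t.test(ai)
  expect_equal(lt$t_stat, unname(tt$statistic))
  expect_equal(lt$p, tt$p.value)
  expect_equal(lt$cohens_d, mean(ai) / sd(ai))
})

test_that("paired homotopic test equals one-sample t on differences", {
  set.seed(34)
  L <- rnorm(25, 10); R <- L + rnorm(25, 0.5, 0.3)
  pt <- paired_homotopic_test(L, R)
  tt <- t.test(R - L)
  expect_equal(pt$t_stat, unname(tt$statistic))
  expect_equal(pt$p, tt$p.value)
  expect_equal(pt$cohens_d, mean(R - L) / sd(R - L))
  # constant difference d with zero spread: closed-form degenerate
  same <- paired_homotopic_test(L, L)
  expect_equal(same$t_stat, 0)
  # constant difference, nonzero spread: t = d sqrt(n) / s
  dfix <- c(rep(1, 12), rep(2, 12))
  t_expected <- mean(dfix) * sqrt(24) / sd(dfix)
  expect_equal(paired_homotopic_test(rep(0, 24), dfix)$t_stat, t_expected)
})

test_that("AI-change z-test arithmetic and null behavior", {
  set.seed(35)
  a1 <- rnorm(29, 0, 5); a2 <- rnorm(39, 5, 5)
  zt <- ai_change_ztest(a1, a2)
  se <- sqrt(var(a1) / 29 + var(a2) / 39)
  expect_equal(zt$z, (mean(a2) - mean(a1)) / se)
  expect_equal(zt$delta_ai, mean(a2) - mean(a1))
  ident <- ai_change_ztest(a1, a1)
  expect_equal(ident$z, 0)
  expect_equal(ai_change_ztest(a2, a1)$z, -zt$z)
})

test_that("BH FDR equals the exhaustive brute-force step-up (length <= 8)", {
  pool <- c(0.001, 0.008, 0.02, 0.04, 0.05, 0.2, 0.5, 0.77, 1)
  set.seed(36)
  for (n in 1:8) {
    for (rep in 1:40) {
      p <- sample(pool, n, replace = TRUE)
      got <- bh_fdr(p)
      oq <- bh_stepup_oracle(p)
      expect_equal(got$q, oq, tolerance = 1e-12)
      off_boundary <- abs(oq - 0.05) > 1e-9   # float order can flip exact ties
      expect_identical(got$rejected[off_boundary], (oq <= 0.05)[off_boundary])
    }
  }
  # printed examples
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))$rejected))
  expect_false(any(bh_fdr(rep(1, 6))$rejected))
  expect_true(bh_fdr(0.05)$rejected)
  expect_false(bh_fdr(0.051)$rejected)
  expect_error(bh_fdr(c(0.2, 1.2)), "outside")
})

test_that("BH keeps the familywise null error near alpha across regions", {
  set.seed(37)
  n_sim <- 500
  any_false <- replicate(n_sim, {
    ai <- matrix(rnorm(30 * 17), 30)
    p <- apply(ai, 2, function(v) t.test(v)$p.value)
    any(bh_fdr(p)$rejected)
  })
  rate <- mean(any_false)
  tol <- 2 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(rate, 0.05 + tol + 0.02)
})

test_that("lateralization suite applies one FDR family across regions", {
  set.seed(38)
  tab <- data.frame(region = rep(c("a", "b", "c"), each = 20),
                    ai = c(rnorm(20, 25, 5), rnorm(20, 0, 5), rnorm(20, -25, 5)))
  out <- lateralization_suite(tab)
  expect_identical(out$direction[out$region == "a"], "right")
  expect_identical(out$direction[out$region == "c"], "left")
  expect_equal(out$q, bh_stepup_oracle(out$p))
})
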