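test_that("growth profile of a linear model has a constant closed-form rate", {
  set.seed(50)
  x <- runif(30, 22, 32)
  fit <- fit_growth_model(x, 2 + 0.3 * x)
  pr <- growth_profile(fit)
  expect_length(pr$grid, 101)
  expect_length(pr$rate, 100)
  expect_equal(pr$midpoints[1], 22.05)
  expect_equal(pr$midpoints[100], 31.95)
  v22 <- 2 + 0.3 * 22
  expect_equal(pr$baseline, v22, tolerance = 1e-8)
  expect_equal(pr$rate, rep(100 * 0.3 / v22, 100), tolerance = 1e-6)
})

test_that("nonpositive baselines are rejected", {
  set.seed(51)
  x <- runif(30, 22, 32)
  fit <- fit_growth_model(x, -50 + 2 * x)   # negative at 22 weeks
  expect_error(growth_profile(fit), "baseline")
})

test_that("trajectory metrics: arithmetic, tie rule, telescoping identity", {
  mid <- seq(22.05, 31.95, by = 0.1)
  cm <- cluster_metrics(rep(3, 100), mid)
  expect_equal(cm$auc, 30)
  expect_equal(cm$growth_density, 0)
  expect_equal(cm$peak_time, 22.05)          # earliest tie wins
  z <- cluster_metrics(rep(0, 100), mid)
  expect_equal(z$peak_rate, 0); expect_equal(z$auc, 0)
  expect_equal(z$peak_time, 22.05)

  # AUC telescopes exactly to cumulative growth for any fitted profile
  set.seed(52)
  for (i in 1:20) {
    x <- runif(25, 22, 32)
    y <- runif(1, 1, 5) * (1 + runif(1, 0.02, 0.2) * (x - 22)) +
      rnorm(25, 0, 0.05)
    pr <- growth_profile(fit_growth_model(x, y))
    cm <- cluster_metrics(pr$rate, pr$midpoints)
    expect_equal(cm$auc,
                 100 * (pr$values[101] - pr$values[1]) / pr$values[1],
                 tolerance = 1e-9)
  }
  expect_error(cluster_metrics(numeric(0)), "empty")
})

test_that("rate curves are invariant under rescaling of the measure", {
  set.seed(53)
  x <- runif(40, 22, 32)
  y <- 2 * (1 + 0.1 * (x - 22)) + rnorm(40, 0, 0.02)
  p1 <- growth_profile(fit_growth_model(x, y))
  p2 <- growth_profile(fit_growth_model(x, 7.3 * y))
  expect_equal(p2$rate, p1$rate, tolerance = 1e-6)
})

test_that("Ward clustering recovers planted archetypes and selects k = 3", {
  prof <- make_rate_profiles(n_per = 6, noise_sd = 0.4, seed = 54)
  cl <- ward_cluster(prof, k_candidates = 2:6)
  expect_identical(cl$k, 3L)
  expect_equal(ari(cl$labels, attr(prof, "truth")), 1)
  sil <- cl$silhouette_by_k
  expect_gt(sil["3"], sil["2"])
  expect_gt(sil["3"], sil["4"])
  # override honors a forced k
  cl4 <- ward_cluster(prof, k_candidates = 2:6, override_k = 4)
  expect_identical(cl4$k, 4L)
})

test_that("identical profiles are a flagged degenerate solution with k = 1", {
  prof <- matrix(rep(1:100, 6), nrow = 6, byrow = TRUE)
  rownames(prof) <- paste0("p", 1:6)
  cl <- ward_cluster(prof)
  expect_true(cl$degenerate)
  expect_identical(cl$k, 1L)
  expect_true(all(cl$labels == 1))
  expect_error(ward_cluster(prof[1:3, ]), "at least 4")
  prof2 <- make_rate_profiles(seed = 55)
  expect_error(ward_cluster(prof2, k_candidates = c(1, 2)), "k_candidates")
})

test_that("bilateral symmetry matrix matches brute-force enumeration", {
  regs <- sp_region_names()
  # perfectly mirrored labels: identity-like matrix
  mirror <- data.frame(region = rep(regs, 2),
                       hemisphere = rep(c("L", "R"), each = 17),
                       cluster = rep(rep(1:3, length.out = 17), 2))
  M <- bilateral_symmetry(mirror)
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(sum(M) - sum(diag(M)), 0)

  # all left in c1, all right in c2
  split <- data.frame(region = rep(regs, 2),
                      hemisphere = rep(c("L", "R"), each = 17),
                      cluster = rep(1:2, each = 17))
  M2 <- bilateral_symmetry(split)
  expect_equal(M2["1", "2"], 1)
  expect_equal(unname(diag(M2)), c(0, 0))

  # mixed toy labeling vs oracle
  toy <- data.frame(region = rep(c("a", "b", "c", "d"), 2),
                    hemisphere = rep(c("L", "R"), each = 4),
                    cluster = c(1, 1, 2, 2, 1, 2, 2, 1))
  expect_equal(bilateral_symmetry(toy), symmetry_oracle(toy))
  expect_error(bilateral_symmetry(toy[-1, ]), "missing hemisphere")
})

test_that("cluster solutions print and plot", {
  prof <- make_rate_profiles(seed = 56)
  cl <- ward_cluster(prof)
  expect_output(print(cl), "sp_clusters")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(cl))
})
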