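test_that("cohort generation is a deterministic function of the config", {
  c1 <- generate_cohort(cohort_config(seed = 5))
  c2 <- generate_cohort(cohort_config(seed = 5))
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$measures, c2$measures)
  c3 <- generate_cohort(cohort_config(seed = 6))
  expect_false(identical(c1$measures$value, c3$measures$value))
})

test_that("zero noise, zero outliers, zero AI gives exact mirror symmetry", {
  cfg <- cohort_config(seed = 2, noise_cv = c(thickness = 0, area = 0,
                                              volume = 0, depth = 0),
                       bv_noise_cv = 0, outlier_fraction = 0,
                       asymmetry_offsets = matrix(
                         0, 17, 4, dimnames = list(sp_region_names(),
                                                   c("thickness", "area",
                                                     "volume", "depth"))))
  co <- generate_cohort(cfg)
  wide <- reshape(co$measures[, c("subject_id", "region", "hemisphere",
                                  "metric", "value")],
                  idvar = c("subject_id", "region", "metric"),
                  timevar = "hemisphere", direction = "wide")
  expect_equal(wide$value.L, wide$value.R)
  # noiseless values equal the closed-form law exactly
  ga <- co$subjects$ga_weeks[match(wide$subject_id, co$subjects$subject_id)]
  expected <- vapply(seq_len(nrow(wide)), function(i)
    true_measure(cfg, ga[i], wide$region[i], wide$metric[i], "L"), numeric(1))
  expect_equal(wide$value.L, expected, tolerance = 1e-10)
})

test_that("planted asymmetry appears at the planted magnitude", {
  offs <- matrix(
    0, 17, 4, dimnames = list(sp_region_names(),
                              c("thickness", "area", "volume", "depth")))
  offs["precentral", "volume"] <- 20
  cfg <- cohort_config(seed = 3, asymmetry_offsets = offs,
                       outlier_fraction = 0)
  co <- generate_cohort(cfg)
  m <- co$measures[co$measures$region == "precentral" &
                     co$measures$metric == "volume", ]
  L <- m$value[m$hemisphere == "L"]
  R <- m$value[m$hemisphere == "R"]
  ai <- mean(asymmetry_index(L, R))
  # sampling error of the mean AI is ~ 100*sqrt(2)*cv/sqrt(n) ~ 1.7
  expect_equal(ai, 20, tolerance = 5)
  expect_equal(co$truth$ai_true[co$truth$region == "precentral" &
                                  co$truth$metric == "volume"], 20)
})

test_that("ground-truth percent change matches numerical integration", {
  cfg <- cohort_config()
  gt <- cohort_ground_truth(cfg)
  for (i in sample.int(nrow(gt), 8)) {
    f <- function(g) 1 + gt$b1[i] * (g - 22) + gt$b2[i] * (g - 22)^2
    m1 <- integrate(f, 22, 27)$value / 5
    m2 <- integrate(f, 27, 32)$value / 5
    expect_equal(gt$pc_true[i], 100 * (m2 - m1) / m1, tolerance = 1e-9)
  }
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_subjects = 5), ">= 10")
  expect_error(cohort_config(outlier_fraction = 0.3), "0.25")
  expect_error(cohort_config(ga_range = c(20, 32)), "within")
  expect_error(cohort_config(regions = letters[1:5]), "17 unique")
})

test_that("outlier rows are gross deviates and flagged", {
  cfg <- cohort_config(seed = 9, outlier_fraction = 0.1, bv_noise_cv = 0)
  co <- generate_cohort(cfg)
  frac <- mean(co$measures$outlier)
  expect_gt(frac, 0.07); expect_lt(frac, 0.13)
  # outlier rows sit at least ~4.5 noise SDs from the noiseless law
  mm <- co$measures[co$measures$metric == "volume" & co$measures$outlier, ]
  ga <- co$subjects$ga_weeks[match(mm$subject_id, co$subjects$subject_id)]
  laws <- vapply(seq_len(nrow(mm)), function(i)
    true_measure(cfg, ga[i], mm$region[i], mm$metric[i], mm$hemisphere[i]),
    numeric(1))
  base <- laws / ifelse(mm$hemisphere == "R",
                        1 + cfg$asymmetry_offsets[cbind(mm$region, mm$metric)] / 200,
                        1 - cfg$asymmetry_offsets[cbind(mm$region, mm$metric)] / 200)
  rel <- abs(mm$value - laws) / (0.1 * base)
  expect_true(all(rel > 4.99))
})

test_that("cohort CSV round trip preserves the tables", {
  co <- generate_cohort(cohort_config(seed = 4, n_subjects = 12))
  dir <- file.path(tempdir(), "cohort_csv")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects$ga_weeks, co$subjects$ga_weeks, tolerance = 1e-12)
  expect_equal(back$measures$value, co$measures$value, tolerance = 1e-12)
  expect_identical(names(back$measures),
                   c("subject_id", "region", "hemisphere", "metric", "value"))
})
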