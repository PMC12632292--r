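#' Canonical region vocabulary
#'
#' The 17 bilateral cerebral regions retained by the analysis (frontal,
#' central, parietal, occipital, and temporal gyri), in a fixed canonical
#' order.
#'
#' @return character vector of length 17.
#' @export
sp_region_names <- function() {
  c("superior_frontal", "middle_frontal", "inferior_frontal",
    "precentral", "postcentral", "paracentral",
    "superior_parietal", "inferior_parietal", "supramarginal",
    "precuneus", "cuneus", "lingual", "lateral_occipital", "fusiform",
    "superior_temporal", "middle_temporal", "inferior_temporal")
}

sp_metrics <- function() c("thickness", "area", "volume", "depth")

# growth archetypes per metric: f(t) = 1 + b1 t + b2 t^2 on t = GA - 22,
# f(0) = 1. Coefficients chosen so that uniform-GA group means reproduce
# field-typical trimester percent changes (thickness ~ 28-49%, area ~ 64%,
# volume ~ 65-95%) with early-peaking, steady, and late-peaking shapes.
sp_archetypes <- function() {
  list(
    thickness = list(early  = c(b1 = 0.20,   b2 = -0.00577),
                     late   = c(b1 = 0.02,   b2 =  0.00407),
                     steady = c(b1 = 0.10,   b2 =  0)),
    area      = list(early  = c(b1 = 0.26,   b2 = -0.005463),
                     late   = c(b1 = 0.10,   b2 =  0.006716),
                     steady = c(b1 = 0.1882, b2 =  0)),
    volume    = list(early  = c(b1 = 0.40,   b2 = -0.002376),
                     late   = c(b1 = 0.12,   b2 =  0.005495),
                     steady = c(b1 = 0.2723, b2 =  0)),
    depth     = list(early  = c(b1 = 0.08,   b2 = 0),
                     late   = c(b1 = 0.08,   b2 = 0),
                     steady = c(b1 = 0.08,   b2 = 0))
  )
}

default_cluster_assignment <- function(regions) {
  early <- c("precentral", "postcentral", "paracentral", "cuneus", "lingual",
             "superior_frontal")
  late <- c("superior_parietal", "inferior_parietal", "supramarginal",
            "superior_temporal", "middle_temporal", "inferior_temporal")
  stats::setNames(ifelse(regions %in% early, "early",
                         ifelse(regions %in% late, "late", "steady")), regions)
}

default_asymmetry_offsets <- function(regions) {
  m <- matrix(0, length(regions), 4,
              dimnames = list(regions, sp_metrics()))
  m["inferior_frontal", "thickness"] <- 16
  m["precuneus", "thickness"] <- -18
  m["superior_temporal", "thickness"] <- -8
  m["postcentral", "thickness"] <- 6
  m["middle_frontal", "area"] <- 15
  m["supramarginal", "area"] <- -16
  m["superior_temporal", "area"] <- 5
  m["precentral", "volume"] <- -17
  m["postcentral", "volume"] <- 15
  m["lingual", "volume"] <- 8
  m["precuneus", "volume"] <- -15
  m
}

#' Synthetic cohort configuration
#'
#' Describes the simulated study: cohort size and gestational-age window,
#' per-region growth laws (three archetype shapes per metric: early-peaking
#' decelerating quadratic, steady linear, late-peaking accelerating
#' quadratic), baseline sizes, planted hemispheric asymmetries, measurement
#' noise, and gross-outlier contamination. All downstream estimands (percent
#' change, asymmetry index, cluster membership) are derivable in closed form
#' from this object.
#'
#' @param n_subjects cohort size (>= 10; default 68).
#' @param ga_range gestational-age window in weeks, within [22, 32].
#' @param regions 17 unique region names.
#' @param cluster_assignment named character vector mapping each region to an
#'   archetype (`"early"`, `"late"`, `"steady"`).
#' @param asymmetry_offsets regions x metrics matrix of planted asymmetry
#'   indices (%); positive is rightward.
#' @param noise_cv named per-metric Gaussian noise, as a coefficient of
#'   variation relative to the noiseless value (default 0.10 for each
#'   metric).
#' @param bv_noise_cv lognormal coefficient of variation of brain volume
#'   about its gestational-age law (default 0.05).
#' @param outlier_fraction expected fraction of measure rows replaced by
#'   gross deviates at >= 5 noise SDs (must be < 0.25 so the RANSAC
#'   75%-inclusion contract can hold; default 0.05).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 68L, ga_range = c(22, 32),
                          regions = sp_region_names(),
                          cluster_assignment = default_cluster_assignment(regions),
                          asymmetry_offsets = default_asymmetry_offsets(regions),
                          noise_cv = c(thickness = 0.10, area = 0.10,
                                       volume = 0.10, depth = 0.10),
                          bv_noise_cv = 0.05,
                          outlier_fraction = 0.05,
                          seed = 1L) {
  if (n_subjects < 10L) stop("n_subjects must be >= 10 (group statistics undefined below)")
  if (ga_range[1] < 22 || ga_range[2] > 32 || ga_range[1] >= ga_range[2])
    stop("ga_range must be an increasing interval within [22, 32]")
  if (length(regions) != 17L || anyDuplicated(regions))
    stop("regions must be 17 unique names")
  if (outlier_fraction < 0 || outlier_fraction >= 0.25)
    stop("outlier_fraction must lie in [0, 0.25) for RANSAC minimum-inclusion compatibility")
  if (!all(regions %in% names(cluster_assignment)))
    stop("cluster_assignment must cover every region")
  if (!all(cluster_assignment[regions] %in% c("early", "late", "steady")))
    stop("archetypes must be early/late/steady")
  asymmetry_offsets <- as.matrix(asymmetry_offsets)[regions, sp_metrics(), drop = FALSE]
  if (any(abs(asymmetry_offsets) >= 200)) stop("planted AI must lie in (-200, 200)")
  noise_cv <- noise_cv[sp_metrics()]
  if (anyNA(noise_cv) || any(noise_cv < 0)) stop("noise_cv must name all four metrics, >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects), ga_range = ga_range,
    regions = regions,
    cluster_assignment = cluster_assignment[regions],
    asymmetry_offsets = asymmetry_offsets,
    noise_cv = noise_cv, bv_noise_cv = bv_noise_cv,
    outlier_fraction = outlier_fraction,
    # baseline sizes at 22 w (mm / mm^2 / mm^3) and per-region multipliers
    metric_base = c(thickness = 2.2, area = 250, volume = 600, depth = 2.5),
    region_multiplier = stats::setNames(seq(0.7, 1.3, length.out = 17), regions),
    # brain-volume law (monotone quadratic, ~4.25x over the window) and
    # per-metric allometric exponents
    bv_base = 60000, bv_b1 = 0.2, bv_b2 = 0.0125,
    size_exponent = c(thickness = 1 / 3, area = 2 / 3, volume = 1, depth = 1 / 3),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d subjects, GA %.1f-%.1f w, noise CV %s, outliers %.0f%%, seed %d\n",
              x$n_subjects, x$ga_range[1], x$ga_range[2],
              paste(sprintf("%s %.2f", names(x$noise_cv), x$noise_cv), collapse = "/"),
              100 * x$outlier_fraction, x$seed))
  invisible(x)
}

archetype_value <- function(coef, t) 1 + coef["b1"] * t + coef["b2"] * t^2

bv_law <- function(config, ga) {
  t <- ga - 22
  config$bv_base * (1 + config$bv_b1 * t + config$bv_b2 * t^2)
}

#' Noiseless expected measure for given subjects
#'
#' Closed-form value of the generator's growth law at given gestational ages:
#' baseline x archetype curve x hemisphere asymmetry factor (brain-size
#' scaling is identically 1 on the noiseless law). Used as the exact oracle
#' for planted-truth tests.
#'
#' @param config a [cohort_config()].
#' @param ga gestational ages (weeks).
#' @param region region name.
#' @param metric one of `thickness`, `area`, `volume`, `depth`.
#' @param hemisphere `"L"` or `"R"`.
#' @return numeric vector of noiseless values.
#' @export
true_measure <- function(config, ga, region, metric, hemisphere) {
  arch <- sp_archetypes()[[metric]][[config$cluster_assignment[[region]]]]
  base <- config$metric_base[[metric]] * config$region_multiplier[[region]]
  ai <- config$asymmetry_offsets[region, metric]
  hf <- if (hemisphere == "R") 1 + ai / 200 else 1 - ai / 200
  base * archetype_value(arch, ga - 22) * hf
}

# population percent change of the archetype curve between uniform-GA groups
archetype_pc <- function(coef, ga_range = c(22, 32), boundary = 27) {
  mean_f <- function(lo, hi) {
    t1 <- lo - 22; t2 <- hi - 22
    m1 <- (t1 + t2) / 2
    m2 <- (t2^3 - t1^3) / (3 * (t2 - t1))
    1 + coef["b1"] * m1 + coef["b2"] * m2
  }
  m1 <- mean_f(ga_range[1], boundary)
  m2 <- mean_f(boundary, ga_range[2])
  unname(100 * (m2 - m1) / m1)
}

#' Ground truth for a cohort configuration
#'
#' Closed-form estimands implied by the generator: per region x metric the
#' archetype and its coefficients, the population trimester percent change
#' (uniform-GA group means of the growth law), the planted asymmetry index,
#' and the planted cluster label.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per region x metric.
#' @export
cohort_ground_truth <- function(config) {
  grid <- expand.grid(region = config$regions, metric = sp_metrics(),
                      stringsAsFactors = FALSE)
  arch <- sp_archetypes()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$region[i]; m <- grid$metric[i]
    a <- config$cluster_assignment[[r]]
    cf <- arch[[m]][[a]]
    data.frame(region = r, metric = m, archetype = a,
               b1 = unname(cf["b1"]), b2 = unname(cf["b2"]),
               baseline = config$metric_base[[m]] * config$region_multiplier[[r]],
               pc_true = archetype_pc(cf, config$ga_range),
               ai_true = config$asymmetry_offsets[r, m])
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of `n_subjects` fetuses: gestational age uniform on the
#' configured window, sex, supratentorial brain volume following a monotone
#' exponential GA law with lognormal noise, and a long-format measure table
#' (subject x region x hemisphere x metric). Each measure is
#' `baseline x archetype(GA) x size-scaling x (1 +/- AI/200)` plus Gaussian
#' noise at the configured CV; a configured fraction of rows is replaced by
#' gross deviates 5-8 noise SDs from the noiseless value. Deterministic given
#' the configuration (including its seed).
#'
#' @param config a [cohort_config()].
#' @return object of class `sp_cohort`: `subjects` (data.frame
#'   `subject_id, ga_weeks, sex, brain_volume_mm3`), `measures` (data.frame
#'   `subject_id, region, hemisphere, metric, value, outlier`), `truth`
#'   ([cohort_ground_truth()] plus the configuration), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ga <- stats::runif(n, config$ga_range[1], config$ga_range[2])
  sex <- sample(c("M", "F", "unknown"), n, replace = TRUE,
                prob = c(0.50, 0.47, 0.03))
  bv <- bv_law(config, ga) * exp(stats::rnorm(n, 0, config$bv_noise_cv))
  subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         ga_weeks = ga, sex = sex, brain_volume_mm3 = bv)

  grid <- expand.grid(subject = seq_len(n), hemisphere = c("L", "R"),
                      region = config$regions, metric = sp_metrics(),
                      stringsAsFactors = FALSE)
  t <- ga[grid$subject] - 22
  arch_tab <- sp_archetypes()
  b1 <- numeric(nrow(grid)); b2 <- numeric(nrow(grid))
  for (m in sp_metrics()) for (a in c("early", "late", "steady")) {
    sel <- grid$metric == m & config$cluster_assignment[grid$region] == a
    b1[sel] <- arch_tab[[m]][[a]]["b1"]
    b2[sel] <- arch_tab[[m]][[a]]["b2"]
  }
  f <- 1 + b1 * t + b2 * t^2
  base <- config$metric_base[grid$metric] * config$region_multiplier[grid$region]
  ai <- config$asymmetry_offsets[cbind(grid$region, grid$metric)]
  hf <- ifelse(grid$hemisphere == "R", 1 + ai / 200, 1 - ai / 200)
  scaling <- (bv[grid$subject] / bv_law(config, ga[grid$subject]))^
    config$size_exponent[grid$metric]
  mu <- base * f * scaling * hf
  sd_noise <- config$noise_cv[grid$metric] * base * f
  value <- mu + stats::rnorm(nrow(grid), 0, sd_noise)
  is_outlier <- stats::runif(nrow(grid)) < config$outlier_fraction
  dev <- sample(c(-1, 1), nrow(grid), replace = TRUE) *
    stats::runif(nrow(grid), 5, 8) * sd_noise
  value[is_outlier] <- mu[is_outlier] + dev[is_outlier]

  measures <- data.frame(subject_id = subjects$subject_id[grid$subject],
                         region = grid$region, hemisphere = grid$hemisphere,
                         metric = grid$metric, value = value,
                         outlier = is_outlier)
  truth <- cohort_ground_truth(config)
  structure(list(subjects = subjects, measures = measures, truth = truth,
                 config = config),
            class = "sp_cohort")
}

#' @export
print.sp_cohort <- function(x, ...) {
  cat(sprintf("sp_cohort: %d subjects (GA %.1f-%.1f w), %d measure rows (%d outliers)\n",
              nrow(x$subjects), min(x$subjects$ga_weeks), max(x$subjects$ga_weeks),
              nrow(x$measures), sum(x$measures$outlier)))
  invisible(x)
}

#' Write / read a cohort as CSV tables
#'
#' `subjects.csv` holds `subject_id, ga_weeks, sex, brain_volume_mm3`;
#' `measures.csv` holds `subject_id, region, hemisphere, metric, value`.
#'
#' @param cohort an [generate_cohort()] result (or a list with `subjects` and
#'   `measures` data.frames).
#' @param dir output directory (created if needed).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a list
#'   with `subjects` and `measures`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  meas <- cohort$measures[, c("subject_id", "region", "hemisphere", "metric", "value")]
  utils::write.csv(meas, file.path(dir, "measures.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(subjects = utils::read.csv(file.path(dir, "subjects.csv")),
       measures = utils::read.csv(file.path(dir, "measures.csv")))
}
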