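# numerically-constant guards: floating-point jitter in noiseless synthetic
# data must behave like exact constancy
zero_tol <- function(x) 1e-8 * max(1, abs(mean(x)))
near_constant <- function(x) {
  s <- stats::sd(x)
  s == 0 || s / sqrt(length(x)) < 1e-10 * max(1, abs(mean(x)))
}

#' Trimester group assignment
#'
#' Splits gestational ages at the boundary (27.0 weeks by default):
#' `ga <= boundary` is the late-second trimester group (`late2`),
#' `ga > boundary` the early-third (`early3`).
#'
#' @param ga gestational age (weeks), each in [22, 32].
#' @param boundary group boundary in weeks (inclusive on the left).
#' @return factor with levels `late2`, `early3`.
#' @export
assign_trimester_group <- function(ga, boundary = 27) {
  if (any(ga < 22 | ga > 32)) stop("gestational age outside [22, 32] weeks")
  factor(ifelse(ga <= boundary, "late2", "early3"), levels = c("late2", "early3"))
}

#' Percent change between trimester group means
#'
#' `pc = 100 * (m2 - m1) / m1` for group means `m1` (late 2nd) and `m2`
#' (early 3rd). The standard error propagates the two group-mean standard
#' errors by the delta method,
#' `se^2 = (100 / m1)^2 * (se2^2 + se1^2 * (m2 / m1)^2)`,
#' and the 95% interval is `pc +/- 1.96 * se`. Inputs are expected to be
#' covariate-adjusted values (see [residualize()]); group means then equal
#' raw means while the SEs reflect the residual spread.
#'
#' @param values_late2,values_early3 numeric vectors of adjusted values for
#'   the two groups (each of length >= 3).
#' @param z_crit critical value for the confidence interval (default 1.96).
#' @return list with `pc`, `se`, `ci95` (length 2), `m1`, `m2`, `group_ns`,
#'   and `defined` (FALSE, with `pc = NA`, when a group mean is not positive).
#' @export
percent_change <- function(values_late2, values_early3, z_crit = 1.96) {
  n1 <- length(values_late2); n2 <- length(values_early3)
  if (n1 < 3L || n2 < 3L) stop("each group needs at least 3 observations")
  m1 <- mean(values_late2); m2 <- mean(values_early3)
  if (m1 <= 0 || m2 <= 0)
    return(list(pc = NA_real_, se = NA_real_, ci95 = c(NA_real_, NA_real_),
                m1 = m1, m2 = m2, group_ns = c(n1, n2), defined = FALSE))
  se1 <- stats::sd(values_late2) / sqrt(n1)
  se2 <- stats::sd(values_early3) / sqrt(n2)
  pc <- 100 * (m2 - m1) / m1
  se <- sqrt((100 / m1)^2 * (se2^2 + se1^2 * (m2 / m1)^2))
  list(pc = pc, se = se, ci95 = c(pc - z_crit * se, pc + z_crit * se),
       m1 = m1, m2 = m2, group_ns = c(n1, n2), defined = TRUE)
}

#' Z-test on homotopic percent-change difference
#'
#' Compares relative growth between the left and right instances of the same
#' region: `z = (pc_R - pc_L) / sqrt(se_L^2 + se_R^2)` with a two-sided
#' normal p-value.
#'
#' @param pc_left,pc_right [percent_change()] results for the two hemispheres.
#' @return list with `z` and `p`.
#' @export
homotopic_growth_ztest <- function(pc_left, pc_right) {
  se <- sqrt(pc_left$se^2 + pc_right$se^2)
  if (!is.finite(se) || se == 0) stop("pooled standard error is zero or undefined")
  z <- (pc_right$pc - pc_left$pc) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Asymmetry index
#'
#' `AI = (right - left) * 100 / (0.5 * (right + left))`, in percent; positive
#' values indicate rightward asymmetry. Bounded in [-200, 200] for
#' non-negative inputs; undefined (NA) when `right + left <= 0`.
#'
#' @param left,right numeric values (vectorized).
#' @return numeric AI values (%).
#' @export
asymmetry_index <- function(left, right) {
  s <- right + left
  ai <- ifelse(s > 0, (right - left) * 100 / (0.5 * s), NA_real_)
  unname(ai)
}

#' One-sample lateralization test for a single region
#'
#' Tests per-subject asymmetry indices against zero. A degenerate
#' zero-variance sample is flagged and given `p = 0` when the mean is nonzero
#' (`p = 1` otherwise).
#'
#' @param ais per-subject AI values for one region and metric (n >= 3).
#' @return list with `mean_ai`, `t_stat`, `p`, `cohens_d`, `n`, `degenerate`.
#' @export
lateralization_test <- function(ais) {
  ais <- ais[is.finite(ais)]
  n <- length(ais)
  if (n < 3L) stop("need at least 3 asymmetry indices")
  s <- stats::sd(ais)
  if (near_constant(ais)) {
    m <- mean(ais)
    z <- abs(m) <= zero_tol(ais)
    return(list(mean_ai = m, t_stat = if (z) 0 else Inf * sign(m),
                p = if (z) 1 else 0, cohens_d = NA_real_, n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(ais, mu = 0)
  list(mean_ai = mean(ais), t_stat = unname(tt$statistic), p = tt$p.value,
       cohens_d = mean(ais) / s, n = n, degenerate = FALSE)
}

#' Paired homotopic t-test
#'
#' Paired t-test on right-minus-left differences of subject-matched values;
#' equivalent to a one-sample t-test on the differences. Cohen's d is the
#' mean difference divided by the SD of the differences.
#'
#' @param left_values,right_values subject-paired numeric vectors (n >= 3).
#' @return list with `t_stat`, `p`, `cohens_d`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
paired_homotopic_test <- function(left_values, right_values) {
  if (length(left_values) != length(right_values)) stop("values must be paired")
  d <- right_values - left_values
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3L) stop("need at least 3 pairs")
  s <- stats::sd(d)
  if (near_constant(d)) {
    m <- mean(d)
    z <- abs(m) <= zero_tol(d)
    return(list(t_stat = if (z) 0 else Inf * sign(m),
                p = if (z) 1 else 0, cohens_d = NA_real_,
                mean_diff = m, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t_stat = unname(tt$statistic), p = tt$p.value, cohens_d = mean(d) / s,
       mean_diff = mean(d), n = n, degenerate = FALSE)
}

#' Z-test on the change in mean asymmetry index between groups
#'
#' `delta = mean(early3 AI) - mean(late2 AI)`, tested with a pooled standard
#' error `sqrt(se1^2 + se2^2)` from the two independent group SEs.
#'
#' @param ais_late2,ais_early3 per-subject AI values in the two groups.
#' @return list with `delta_ai`, `z`, `p`, `degenerate`.
#' @export
ai_change_ztest <- function(ais_late2, ais_early3) {
  a1 <- ais_late2[is.finite(ais_late2)]
  a2 <- ais_early3[is.finite(ais_early3)]
  if (length(a1) < 3L || length(a2) < 3L) stop("each group needs >= 3 values")
  se <- sqrt(stats::var(a1) / length(a1) + stats::var(a2) / length(a2))
  delta <- mean(a2) - mean(a1)
  if (se <= zero_tol(c(a1, a2))) {
    z <- abs(delta) <= zero_tol(c(a1, a2))
    return(list(delta_ai = delta, z = if (z) 0 else Inf * sign(delta),
                p = if (z) 1 else 0, degenerate = TRUE))
  }
  z <- delta / se
  list(delta_ai = delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR adjustment of a p-value family (one family per metric across
#' regions in the pipeline). Adjusted q-values are monotone in the ordered
#' p-values; `rejected` marks `q <= alpha`.
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param alpha FDR level for the rejection flags (default 0.05).
#' @return list with `q` (adjusted values) and `rejected` (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= alpha)
}

#' Lateralization suite across regions
#'
#' Runs [lateralization_test()] per region on a long table of per-subject
#' asymmetry indices and applies [bh_fdr()] across the regions (one family).
#' The lateralization `direction` is `right`/`left` only when `q < alpha`.
#'
#' @param ai_table data.frame with columns `region` and `ai`.
#' @param alpha FDR level.
#' @return data.frame, one row per region: `region`, `n`, `mean_ai`,
#'   `t_stat`, `p`, `q`, `cohens_d`, `direction`.
#' @export
lateralization_suite <- function(ai_table, alpha = 0.05) {
  stopifnot(all(c("region", "ai") %in% names(ai_table)))
  regs <- unique(as.character(ai_table$region))
  rows <- lapply(regs, function(r) {
    lt <- lateralization_test(ai_table$ai[ai_table$region == r])
    data.frame(region = r, n = lt$n, mean_ai = lt$mean_ai, t_stat = lt$t_stat,
               p = lt$p, cohens_d = lt$cohens_d)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, alpha)
  out$q <- fdr$q
  out$direction <- ifelse(!fdr$rejected, "none",
                          ifelse(out$mean_ai > 0, "right", "left"))
  out
}
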