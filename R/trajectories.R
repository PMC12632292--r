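#' Continuous growth profile from a fitted growth model
#'
#' Samples the fitted trajectory every 0.1 weeks on the 22-32 week grid (101
#' points) and converts it to a baseline-normalized relative growth-rate
#' curve by finite differences:
#' `rate_i = 100 * (v_{i+1} - v_i) / (0.1 * baseline)` (%/week), assigned to
#' the interval midpoints 22.05, 22.15, ..., 31.95 (100 values). The baseline
#' is the fitted value at 22.0 weeks, so the Riemann sum of the rate curve
#' telescopes exactly to the cumulative growth
#' `100 * (v(32) - v(22)) / v(22)`.
#'
#' @param model an [fit_growth_model()] result (or any object with a
#'   `predict(model, x)` method returning trajectory values).
#' @param ga_range trajectory limits in weeks (default `c(22, 32)`).
#' @param step sampling interval in weeks (default 0.1).
#' @return object of class `growth_profile`: `grid`, `values`, `baseline`,
#'   `midpoints`, `rate`.
#' @export
growth_profile <- function(model, ga_range = c(22, 32), step = 0.1) {
  grid <- seq(ga_range[1], ga_range[2], by = step)
  values <- if (inherits(model, "sp_growth_fit")) predict(model, grid)
            else stats::predict(model, grid)
  baseline <- values[1]
  if (!is.finite(baseline) || baseline <= 0)
    stop("nonpositive baseline: fitted trajectory must be positive at ",
         ga_range[1], " weeks")
  rate <- 100 * diff(values) / (step * baseline)
  structure(list(grid = grid, values = values, baseline = baseline,
                 midpoints = grid[-length(grid)] + step / 2, rate = rate),
            class = "growth_profile")
}

#' @export
print.growth_profile <- function(x, ...) {
  cat(sprintf("growth_profile: %d samples on [%.1f, %.1f] w, baseline %.4g, AUC %.2f%%\n",
              length(x$grid), min(x$grid), max(x$grid), x$baseline,
              sum(x$rate) * diff(x$grid[1:2])))
  invisible(x)
}

#' Trajectory metrics of a relative growth-rate curve
#'
#' Peak growth rate and its gestational age (ties broken toward the earliest
#' midpoint), cumulative growth as the Riemann sum of the rate curve (AUC, in
#' percent), and growth density, the standard deviation of the
#' moving-average-smoothed rate curve (temporal concentration of growth).
#' Smoothing uses a centered window of `smoothing_window` weeks (5 samples at
#' the default grid), truncated at the curve edges.
#'
#' @param rate numeric rate curve (%/week) on interval midpoints.
#' @param midpoints midpoint gestational ages (weeks).
#' @param smoothing_window moving-average window (weeks, default 0.5).
#' @return list with `peak_rate`, `peak_time`, `auc`, `growth_density`.
#' @export
cluster_metrics <- function(rate, midpoints = seq(22.05, by = 0.1,
                                                  length.out = length(rate)),
                            smoothing_window = 0.5) {
  if (length(rate) == 0L) stop("empty rate curve")
  if (length(rate) != length(midpoints)) stop("rate and midpoints lengths differ")
  step <- if (length(midpoints) > 1) midpoints[2] - midpoints[1] else 0.1
  i <- which.max(rate)                    # which.max takes the earliest tie
  half <- max(0L, floor(round(smoothing_window / step) / 2))
  sm <- vapply(seq_along(rate), function(k) {
    mean(rate[max(1, k - half):min(length(rate), k + half)])
  }, numeric(1))
  list(peak_rate = rate[i], peak_time = midpoints[i],
       auc = sum(rate) * step,
       growth_density = if (length(sm) > 1) stats::sd(sm) else 0)
}

#' Ward clustering of growth-rate profiles with silhouette selection
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances between rate
#' curves). For every candidate number of clusters the mean silhouette width
#' is computed; the chosen `k` maximizes the silhouette unless `override_k`
#' is supplied (mirroring selection aided by dendrogram inspection). When all
#' profiles are identical the solution is degenerate: `k` is forced to 1 and
#' flagged.
#'
#' @param profiles numeric matrix, one row per profile (rate curves on a
#'   common grid); row names identify the profiles.
#' @param k_candidates candidate cluster counts (default `2:8`), each within
#'   `[2, nrow - 1]`.
#' @param override_k optional fixed cluster count.
#' @param midpoints midpoint grid for per-cluster metrics.
#' @return object of class `sp_clusters`: `k`, `labels`, `silhouette_by_k`,
#'   `hclust`, `mean_curves` (k x p), `cluster_metrics` (per-cluster list of
#'   [cluster_metrics()]), `degenerate`.
#' @export
ward_cluster <- function(profiles, k_candidates = 2:8, override_k = NULL,
                         midpoints = seq(22.05, by = 0.1,
                                         length.out = ncol(profiles))) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 4L) stop("need at least 4 profiles to cluster")
  d <- stats::dist(profiles)
  if (max(d) < .Machine$double.eps^0.5) {
    labels <- stats::setNames(rep(1L, n), rownames(profiles))
    mc <- colMeans(profiles)
    return(structure(list(k = 1L, labels = labels,
                          silhouette_by_k = stats::setNames(numeric(0), NULL),
                          hclust = NULL,
                          mean_curves = matrix(mc, 1,
                                               dimnames = list("1", NULL)),
                          cluster_metrics = list(`1` = cluster_metrics(mc, midpoints)),
                          degenerate = TRUE),
                     class = "sp_clusters"))
  }
  k_candidates <- as.integer(k_candidates)
  if (any(k_candidates < 2L | k_candidates > n - 1L))
    stop("k_candidates must lie in [2, n-1]")
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_candidates, function(k) {
    lab <- stats::cutree(hc, k = k)
    sw <- cluster::silhouette(lab, d)[, "sil_width"]
    mean(ifelse(is.finite(sw), sw, 0))  # duplicate profiles give 0/0 widths
  }, numeric(1))
  names(sil) <- k_candidates
  k <- if (!is.null(override_k)) as.integer(override_k)
       else k_candidates[which.max(sil)]
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(profiles)
  mean_curves <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(profiles[labels == c, , drop = FALSE])))
  rownames(mean_curves) <- seq_len(k)
  cm <- lapply(seq_len(k), function(c) cluster_metrics(mean_curves[c, ], midpoints))
  names(cm) <- seq_len(k)
  structure(list(k = k, labels = labels, silhouette_by_k = sil, hclust = hc,
                 mean_curves = mean_curves, cluster_metrics = cm,
                 degenerate = FALSE),
            class = "sp_clusters")
}

#' @export
print.sp_clusters <- function(x, ...) {
  if (x$degenerate) {
    cat("sp_clusters: degenerate (all profiles identical), k = 1\n")
    return(invisible(x))
  }
  cat(sprintf("sp_clusters: k = %d (silhouette %.3f)\n",
              x$k, x$silhouette_by_k[as.character(x$k)]))
  cat("silhouette by k:",
      paste(sprintf("%s: %.3f", names(x$silhouette_by_k), x$silhouette_by_k),
            collapse = ", "), "\n")
  tab <- do.call(rbind, lapply(x$cluster_metrics, as.data.frame))
  tab <- cbind(cluster = rownames(tab), n = as.vector(table(x$labels)), tab)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.sp_clusters <- function(x, midpoints = seq(22.05, by = 0.1,
                                                length.out = ncol(x$mean_curves)),
                             ...) {
  cols <- grDevices::hcl.colors(max(2, x$k), "Dark 3")
  graphics::matplot(midpoints, t(x$mean_curves), type = "l", lty = 1, lwd = 2,
                    col = cols[seq_len(x$k)],
                    xlab = "gestational age (weeks)",
                    ylab = "relative growth rate (%/week)", ...)
  graphics::legend("topright", legend = paste("cluster", seq_len(x$k)),
                   col = cols[seq_len(x$k)], lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Bilateral symmetry matrix of cluster assignments
#'
#' Cell `(i, j)` is the number of region names whose left-hemisphere profile
#' sits in cluster `i` and right-hemisphere profile in cluster `j`, divided
#' by the number of unique region names with either hemisphere in cluster `i`
#' or `j` (for the diagonal: in cluster `i`). Diagonal cells measure
#' homotopic consistency of each cluster.
#'
#' @param labels data.frame with columns `region`, `hemisphere` (`"L"`/`"R"`),
#'   `cluster`; every region must appear with both hemispheres.
#' @return `k x k` numeric matrix with entries in [0, 1].
#' @export
bilateral_symmetry <- function(labels) {
  stopifnot(all(c("region", "hemisphere", "cluster") %in% names(labels)))
  regs <- unique(as.character(labels$region))
  getlab <- function(r, h) {
    v <- labels$cluster[labels$region == r & labels$hemisphere == h]
    if (length(v) != 1L) stop("region ", r, " is missing hemisphere ", h)
    v
  }
  L <- vapply(regs, getlab, numeric(1), h = "L")
  R <- vapply(regs, getlab, numeric(1), h = "R")
  ks <- sort(unique(c(L, R)))
  M <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  for (a in seq_along(ks)) for (b in seq_along(ks)) {
    i <- ks[a]; j <- ks[b]
    num <- sum(L == i & R == j)
    denom <- length(unique(regs[L == i | R == i | L == j | R == j]))
    M[a, b] <- if (denom == 0) 0 else num / denom
  }
  M
}
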