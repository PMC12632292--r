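#' Robust polynomial growth model (RANSAC consensus + AIC degree selection)
#'
#' Fits degree-1 and degree-2 polynomial models of `y` on `x` (gestational age
#' in weeks) by random sample consensus and returns the degree with the lower
#' Akaike Information Criterion. For each degree, minimal vertex sets are
#' drawn, a candidate model is fit, and the consensus set collects the
#' observations whose absolute residual falls below a fixed threshold
#' (2.0 x 1.4826 x MAD of the residuals of an initial full-sample
#' least-squares fit; the threshold is shared across trials so that trials
#' anchored on outliers cannot inflate their own inlier count). The final
#' coefficients come from an ordinary least-squares refit on the winning
#' consensus set; AIC is evaluated on the full sample under Gaussian
#' residuals with `k = degree + 2` parameters (coefficients plus the noise
#' variance). The polynomial basis is centered at the covariate mean
#' internally (about 27 weeks for a gestational-age covariate) to
#' decorrelate the terms; reported coefficients are in the raw basis
#' `(intercept, slope[, curvature])`.
#'
#' With zero noise the initial residuals are zero, the threshold collapses to
#' zero, every observation is a consensus inlier, and the fit equals ordinary
#' least squares exactly. If the best consensus holds fewer than
#' `min_inclusion` of the sample, the fit falls back to full-sample least
#' squares and is flagged (`fallback = TRUE`).
#'
#' @param x numeric predictor (weeks), typically gestational age in [22, 32].
#' @param y numeric response, same length as `x`, `n >= 10`.
#' @param seed integer seed controlling the RANSAC draws (default 42).
#' @param min_inclusion minimum consensus fraction (default 0.75).
#' @param n_trials number of random minimal-sample trials per degree.
#' @param threshold_scale multiplier on the robust residual scale
#'   (default 2.0).
#' @param degrees candidate polynomial degrees (subset of `c(1, 2)`).
#' @return An object of class `sp_growth_fit` with elements `degree`,
#'   `coefficients` (raw basis), `inlier_mask`, `aic_linear`, `aic_quadratic`,
#'   `sigma` (inlier residual SD), `fallback`, `seed`, and the training data.
#' @seealso [residualize()], [growth_profile()]
#' @examples
#' ga <- seq(22, 32, length.out = 40)
#' fit <- fit_growth_model(ga, 1 + 0.2 * ga)
#' coef(fit)
#' @export
fit_growth_model <- function(x, y, seed = 42L, min_inclusion = 0.75,
                             n_trials = 100L, threshold_scale = 2.0,
                             degrees = c(1L, 2L)) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations to fit a growth model")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  # center the polynomial basis at the covariate mean to decorrelate the
  # linear and quadratic terms (~27 for a gestational-age covariate);
  # reported coefficients are converted back to the raw basis
  center <- mean(x)
  degenerate_x <- stats::sd(x) < 1e-10

  fits <- list()
  for (d in degrees) {
    fits[[as.character(d)]] <-
      if (degenerate_x) intercept_fit(x, y, d, center)
      else ransac_degree(x, y, d, center, seed, n_trials, min_inclusion,
                         threshold_scale)
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  # parsimony tie-break: pick the lower degree on (numerically) equal AIC,
  # including the all-interpolating zero-noise case where both RSS vanish
  best <- names(fits)[1]
  for (nm in names(fits)[-1])
    if (aics[[nm]] < aics[[best]] - 1e-10) best <- nm
  f <- fits[[best]]

  structure(list(
    degree = as.integer(best),
    coefficients = f$coef_raw,
    inlier_mask = f$inliers,
    aic_linear = if ("1" %in% names(fits)) fits[["1"]]$aic else NA_real_,
    aic_quadratic = if ("2" %in% names(fits)) fits[["2"]]$aic else NA_real_,
    sigma = f$sigma,
    fallback = f$fallback,
    degenerate_x = degenerate_x,
    threshold = f$threshold,
    seed = as.integer(seed),
    center = center,
    x = x, y = y
  ), class = "sp_growth_fit")
}

poly_basis <- function(x, degree, center) {
  xc <- x - center
  X <- cbind(1, xc)
  if (degree == 2L) X <- cbind(X, xc^2)
  X
}

# centered-basis coefficients -> raw polynomial coefficients
uncenter_coef <- function(beta, degree, center) {
  beta <- unname(beta)
  if (degree == 1L) {
    c(intercept = beta[1] - beta[2] * center, slope = beta[2])
  } else {
    c(intercept = beta[1] - beta[2] * center + beta[3] * center^2,
      slope = beta[2] - 2 * beta[3] * center,
      curvature = beta[3])
  }
}

ls_solve <- function(X, y) qr.coef(qr(X), y)

gauss_aic <- function(rss, n, k) {
  rss <- max(rss, n * 1e-24)   # guard the log for interpolating fits
  n * log(rss / n) + 2 * k
}

intercept_fit <- function(x, y, degree, center) {
  mu <- mean(y)
  rss <- sum((y - mu)^2)
  beta <- c(mu, 0, if (degree == 2L) 0)
  list(coef_raw = uncenter_coef(beta, degree, center),
       inliers = rep(TRUE, length(y)),
       aic = gauss_aic(rss, length(y), degree + 2),
       sigma = stats::sd(y), fallback = TRUE, threshold = NA_real_)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_fixed_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ransac_degree <- function(x, y, degree, center, seed, n_trials, min_inclusion,
                          threshold_scale) {
  n <- length(y)
  X <- poly_basis(x, degree, center)
  p <- ncol(X)
  beta0 <- ls_solve(X, y)
  r0 <- y - drop(X %*% beta0)
  thr <- threshold_scale * 1.4826 * stats::median(abs(r0 - stats::median(r0)))

  trial_idx <- with_fixed_seed(seed,
    replicate(n_trials, sample.int(n, p), simplify = FALSE))
  best_inl <- NULL; best_n <- -1L; best_rss <- Inf
  for (t in seq_len(n_trials)) {
    idx <- trial_idx[[t]]
    Xi <- X[idx, , drop = FALSE]
    b <- tryCatch(solve(Xi, y[idx]), error = function(e) NULL)
    if (is.null(b) || anyNA(b)) next
    ares <- abs(y - drop(X %*% b))
    inl <- ares <= thr
    ni <- sum(inl)
    if (ni < p) next
    rss <- sum(ares[inl]^2)
    if (ni > best_n || (ni == best_n && rss < best_rss)) {
      best_inl <- inl; best_n <- ni; best_rss <- rss
    }
  }
  # consensus refinement to a fixed point: refit on the inlier set and
  # re-threshold until the set stabilizes. This removes the dependence of
  # the final inlier set on which random trial happened to win (a variance
  # source), while gross outliers beyond the threshold stay excluded.
  if (!is.null(best_inl)) {
    for (it in 1:25) {
      beta <- ls_solve(X[best_inl, , drop = FALSE], y[best_inl])
      new_inl <- abs(y - drop(X %*% beta)) <= thr
      if (sum(new_inl) < p) break
      if (identical(new_inl, best_inl)) break
      best_inl <- new_inl
    }
    best_n <- sum(best_inl)
  }
  fallback <- FALSE
  if (is.null(best_inl) || best_n < ceiling(min_inclusion * n)) {
    best_inl <- rep(TRUE, n)
    fallback <- TRUE
  }
  beta <- ls_solve(X[best_inl, , drop = FALSE], y[best_inl])
  pred <- drop(X %*% beta)
  rss_full <- sum((y - pred)^2)
  res_in <- (y - pred)[best_inl]
  list(coef_raw = uncenter_coef(beta, degree, center),
       inliers = best_inl,
       aic = gauss_aic(rss_full, n, degree + 2),
       sigma = stats::sd(res_in),
       fallback = fallback, threshold = thr)
}

#' @export
coef.sp_growth_fit <- function(object, ...) object$coefficients

#' @export
predict.sp_growth_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x
       else newdata
  b <- object$coefficients
  out <- b[1] + b[2] * x
  if (object$degree == 2L) out <- out + b[3] * x^2
  unname(out)
}

#' @export
fitted.sp_growth_fit <- function(object, ...) predict(object)

#' @export
residuals.sp_growth_fit <- function(object, ...) object$y - predict(object)

#' @export
print.sp_growth_fit <- function(x, ...) {
  cat(sprintf("Robust growth fit: degree %d (AIC %.2f linear / %.2f quadratic)\n",
              x$degree, x$aic_linear, x$aic_quadratic))
  print(round(x$coefficients, 6))
  cat(sprintf("inliers %d/%d%s, sigma %.4g, seed %d\n",
              sum(x$inlier_mask), length(x$inlier_mask),
              if (x$fallback) " [fallback: full-sample LS]" else "",
              x$sigma, x$seed))
  invisible(x)
}

#' @export
summary.sp_growth_fit <- function(object, ...) {
  out <- list(degree = object$degree,
              coefficients = object$coefficients,
              n = length(object$y),
              n_inliers = sum(object$inlier_mask),
              n_outliers = sum(!object$inlier_mask),
              sigma = object$sigma,
              aic = c(linear = object$aic_linear, quadratic = object$aic_quadratic),
              threshold = object$threshold,
              fallback = object$fallback,
              r_squared = 1 - sum(residuals(object)^2) /
                sum((object$y - mean(object$y))^2))
  class(out) <- "summary.sp_growth_fit"
  out
}

#' @export
print.summary.sp_growth_fit <- function(x, ...) {
  cat(sprintf("Robust growth fit (degree %d)\n", x$degree))
  print(round(x$coefficients, 6))
  cat(sprintf("n = %d, inliers = %d, outliers = %d, sigma = %.4g\n",
              x$n, x$n_inliers, x$n_outliers, x$sigma))
  cat(sprintf("AIC: linear %.2f, quadratic %.2f; full-sample R^2 = %.3f\n",
              x$aic["linear"], x$aic["quadratic"], x$r_squared))
  if (x$fallback) cat("note: consensus below minimum inclusion; full-sample LS used\n")
  invisible(x)
}

#' @export
plot.sp_growth_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = ifelse(x$inlier_mask, 19, 4),
                 col = ifelse(x$inlier_mask, "grey30", "red3"),
                 xlab = "gestational age (weeks)", ylab = "measure", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "steelblue", lwd = 2)
  invisible(x)
}

#' @export
simulate.sp_growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() replicate(nsim, predict(object) +
                                 stats::rnorm(length(object$y), 0, object$sigma))
  out <- as.data.frame(if (is.null(seed)) draw() else with_fixed_seed(seed, draw()))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize a growth fit to JSON
#'
#' Round-trippable plain-JSON record of the fitted model: degree, raw-basis
#' coefficients, seed, and inlier indices.
#'
#' @param fit an [fit_growth_model()] result.
#' @param path optional file to write; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
growth_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "sp_growth_fit"))
  obj <- list(degree = fit$degree,
              coefficients = as.list(fit$coefficients),
              seed = fit$seed,
              inlier_indices = which(fit$inlier_mask),
              aic = list(linear = fit$aic_linear, quadratic = fit$aic_quadratic),
              fallback = fit$fallback)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
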