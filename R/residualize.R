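#' Sequential robust residualization
#'
#' Removes covariate effects from a measure one covariate at a time, in the
#' stated order, each step using the robust RANSAC/AIC growth model
#' ([fit_growth_model()]). Starting from `r0 = y`, step `i` fits
#' `r_{i-1} ~ x_i` and subtracts the prediction. Because each least-squares
#' step produces mean-zero residuals, the group/region means that downstream
#' analyses need would be annihilated by literal residuals; with
#' `keep_mean = TRUE` (the default) each step removes only the centered
#' covariate effect (`pred - mean(pred)`), so the sample mean is invariant
#' under the step while the spread shrinks to the residual spread
#' (covariate-adjusted values).
#'
#' The order of covariates matters when they are correlated; the pipeline
#' convention is gestational age first, then residual brain volume, and for
#' thickness additionally regional SP depth (itself pre-adjusted for GA and
#' residual brain volume).
#'
#' @param y numeric response.
#' @param covariates named list of numeric covariate vectors, applied in
#'   order. An element may also be a list `list(x = , model = )` supplying a
#'   pre-fitted [sp_growth_fit][fit_growth_model()] to use for prediction.
#' @param seed seed forwarded to each internal [fit_growth_model()] call.
#' @param keep_mean remove only the centered covariate effect at each step
#'   (adjusted values) rather than returning mean-zero residuals.
#' @param ref_grid optional named list mapping a covariate name to a grid of
#'   reference covariate values. For such a covariate the value added back is
#'   the mean of the fitted curve over that grid instead of the sample mean,
#'   i.e. the step standardizes the sample's covariate composition to the
#'   grid (used to standardize trimester groups to a uniform
#'   gestational-age window before comparing group means).
#' @param ... further arguments passed to [fit_growth_model()].
#' @return list of class `sp_residualized` with `residuals` (the final
#'   adjusted values), `fits` (one [sp_growth_fit][fit_growth_model()] per
#'   step), and `keep_mean`.
#' @export
residualize <- function(y, covariates, seed = 42L, keep_mean = TRUE,
                        ref_grid = NULL, ...) {
  stopifnot(is.list(covariates), length(covariates) >= 1L)
  r <- y
  fits <- vector("list", length(covariates))
  names(fits) <- names(covariates)
  for (i in seq_along(covariates)) {
    cv <- covariates[[i]]
    if (is.list(cv) && !is.null(cv$model)) {
      x <- cv$x
      if (length(x) != length(r)) stop("covariate length mismatch")
      pred <- predict(cv$model, x)
      fits[[i]] <- cv$model
    } else {
      x <- if (is.list(cv)) cv$x else cv
      if (length(x) != length(r)) stop("covariate length mismatch")
      fit <- fit_growth_model(x, r, seed = seed, ...)
      pred <- predict(fit)
      fits[[i]] <- fit
    }
    nm <- names(covariates)[i]
    m <- if (!is.null(ref_grid) && !is.null(nm) && nm %in% names(ref_grid)) {
      mean(predict(fits[[i]], ref_grid[[nm]]))
    } else if (keep_mean) mean(pred) else 0
    r <- r - pred + m
  }
  structure(list(residuals = r, fits = fits, keep_mean = keep_mean),
            class = "sp_residualized")
}

#' @export
print.sp_residualized <- function(x, ...) {
  cat("sp_residualized:", length(x$residuals), "values adjusted for",
      length(x$fits), "covariate(s)",
      if (x$keep_mean) "(means retained)\n" else "(mean-zero residuals)\n")
  invisible(x)
}

#' Residual brain volume
#'
#' Supratentorial brain volume adjusted for gestational age: the mean-zero
#' residual of the robust GA fit. This is the size covariate used throughout
#' the regional analyses.
#'
#' @param brain_volume supratentorial volume (mm^3) per subject.
#' @param ga gestational age (weeks) per subject.
#' @param seed RANSAC seed.
#' @param ... passed to [fit_growth_model()].
#' @return numeric vector of mean-zero residuals (mm^3).
#' @export
residual_brain_volume <- function(brain_volume, ga, seed = 42L, ...) {
  residualize(brain_volume, list(ga = ga), seed = seed,
              keep_mean = FALSE, ...)$residuals
}
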