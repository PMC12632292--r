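#' ANCOVA with type-III sums of squares and partial eta squared
#'
#' General linear model with effect (sum-to-zero) coding for factors.
#' Marginal (type-III) sums of squares are computed per effect by dropping
#' that effect's model-matrix columns from the full model. Effect size is
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' For repeated-measures designs (`subject` given together with `within`
#' factor names), a univariate split-plot error stratification is used:
#' between-subject effects (those involving no within-subject factor) are
#' tested against the subject stratum (subject-to-subject variation left
#' after the between-subject model), and within-subject effects against the
#' residual stratum (variation left after adding the subject factor and all
#' within effects).
#'
#' @param data data.frame holding the response and all design variables.
#' @param response name of the response column.
#' @param covariates character vector of numeric covariate columns.
#' @param factors character vector of factor columns (effect-coded). Rows
#'   with missing factor levels (e.g. unknown sex) are dropped.
#' @param interactions character vector of interaction terms in formula
#'   notation, e.g. `"ga:sex"` or `"region:hemisphere"`.
#' @param subject optional name of the subject-id column for repeated
#'   measures.
#' @param within names of the within-subject factors (subset of `factors`).
#' @return data.frame of class `sp_ancova`: one row per effect with `effect`,
#'   `df`, `ss`, `F`, `p`, `partial_eta_sq`, `stratum`, plus error-stratum
#'   rows.
#' @export
sp_ancova <- function(data, response, covariates = character(),
                      factors = character(), interactions = character(),
                      subject = NULL, within = character()) {
  terms_all <- c(covariates, factors, interactions)
  if (length(terms_all) == 0L) stop("no effects specified")
  vars_needed <- unique(c(response, covariates, factors, subject,
                          unlist(strsplit(interactions, ":", fixed = TRUE))))
  missing_cols <- setdiff(vars_needed, names(data))
  if (length(missing_cols)) stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  df <- data[stats::complete.cases(data[, vars_needed, drop = FALSE]), , drop = FALSE]
  for (f in unique(c(factors, subject))) df[[f]] <- factor(df[[f]])

  y <- df[[response]]
  n <- length(y)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))

  form <- stats::as.formula(paste("~", paste(terms_all, collapse = " + ")))
  X <- stats::model.matrix(form, df)
  asg <- attr(X, "assign")
  term_labels <- attr(stats::terms(form), "term.labels")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- unique(term_labels[asg[setdiff(seq_len(ncol(X)),
                                              qrX$pivot[seq_len(qrX$rank)])]])
    stop("rank-deficient design; aliased effects: ",
         paste(aliased, collapse = ", "))
  }
  rss_full <- sum(qr.resid(qrX, y)^2)
  df_resid_full <- n - qrX$rank

  marginal_ss <- function(X, y, asg, term_id, rss_full) {
    keep <- asg != term_id
    Xr <- X[, keep, drop = FALSE]
    rss_r <- sum(qr.resid(qr(Xr), y)^2)
    c(ss = rss_r - rss_full, df = sum(!keep))
  }

  involves_within <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    any(parts %in% within)
  }

  repeated <- !is.null(subject) && length(within) > 0L
  if (!repeated) {
    rows <- lapply(seq_along(term_labels), function(i) {
      ms <- marginal_ss(X, y, asg, i, rss_full)
      Fv <- (ms["ss"] / ms["df"]) / (rss_full / df_resid_full)
      data.frame(effect = term_labels[i], df = unname(ms["df"]),
                 ss = unname(ms["ss"]), F = unname(Fv),
                 p = stats::pf(Fv, ms["df"], df_resid_full, lower.tail = FALSE),
                 partial_eta_sq = unname(ms["ss"] / (ms["ss"] + rss_full)),
                 stratum = "residual")
    })
    out <- do.call(rbind, rows)
    out <- rbind(out, data.frame(effect = "Residuals", df = df_resid_full,
                                 ss = rss_full, F = NA, p = NA,
                                 partial_eta_sq = NA, stratum = "residual"))
    class(out) <- c("sp_ancova", "data.frame")
    return(out)
  }

  ## split-plot stratification
  between_terms <- term_labels[!vapply(term_labels, involves_within, logical(1))]
  within_terms <- setdiff(term_labels, between_terms)

  # subject stratum error: subject variation beyond the between model
  form_b <- stats::as.formula(paste("~", paste(c(between_terms, "1"), collapse = " + ")))
  Xb <- stats::model.matrix(form_b, df)
  qb <- qr(Xb)
  rss_b <- sum(qr.resid(qb, y)^2)
  form_bs <- stats::as.formula(paste("~", paste(c(between_terms, subject), collapse = " + ")))
  Xbs <- stats::model.matrix(form_bs, df)
  qbs <- qr(Xbs)
  rss_bs <- sum(qr.resid(qbs, y)^2)
  ss_subj <- rss_b - rss_bs
  df_subj <- qbs$rank - qb$rank
  if (df_subj <= 0) stop("no subject-stratum degrees of freedom; check the design")

  # within stratum: full model + subject factor
  form_w <- stats::as.formula(paste("~", paste(c(term_labels, subject), collapse = " + ")))
  Xw <- stats::model.matrix(form_w, df)
  asg_w <- attr(Xw, "assign")
  labels_w <- attr(stats::terms(form_w), "term.labels")
  qw <- qr(Xw)
  if (qw$rank < ncol(Xw)) {
    aliased <- unique(labels_w[asg_w[setdiff(seq_len(ncol(Xw)),
                                             qw$pivot[seq_len(qw$rank)])]])
    aliased <- setdiff(aliased, subject)
    if (length(aliased))
      stop("rank-deficient design; aliased effects: ", paste(aliased, collapse = ", "))
  }
  rss_w <- sum(qr.resid(qw, y)^2)
  df_w <- n - qw$rank

  rows <- lapply(term_labels, function(tl) {
    if (tl %in% between_terms) {
      i <- match(tl, between_terms)
      asg_b <- attr(Xb, "assign")
      ms <- marginal_ss(Xb, y, asg_b, i, rss_b)
      # marginal between SS computed within the between model, tested vs subject MS
      Fv <- (ms["ss"] / ms["df"]) / (ss_subj / df_subj)
      data.frame(effect = tl, df = unname(ms["df"]), ss = unname(ms["ss"]),
                 F = unname(Fv),
                 p = stats::pf(Fv, ms["df"], df_subj, lower.tail = FALSE),
                 partial_eta_sq = unname(ms["ss"] / (ms["ss"] + ss_subj)),
                 stratum = "between")
    } else {
      i <- match(tl, labels_w)
      ms <- marginal_ss(Xw, y, asg_w, i, rss_w)
      Fv <- (ms["ss"] / ms["df"]) / (rss_w / df_w)
      data.frame(effect = tl, df = unname(ms["df"]), ss = unname(ms["ss"]),
                 F = unname(Fv),
                 p = stats::pf(Fv, ms["df"], df_w, lower.tail = FALSE),
                 partial_eta_sq = unname(ms["ss"] / (ms["ss"] + rss_w)),
                 stratum = "within")
    }
  })
  out <- do.call(rbind, rows)
  out <- rbind(out,
               data.frame(effect = "Subjects", df = df_subj, ss = ss_subj,
                          F = NA, p = NA, partial_eta_sq = NA, stratum = "between-error"),
               data.frame(effect = "Residuals", df = df_w, ss = rss_w,
                          F = NA, p = NA, partial_eta_sq = NA, stratum = "within-error"))
  class(out) <- c("sp_ancova", "data.frame")
  out
}

#' @export
print.sp_ancova <- function(x, ...) {
  cat("ANCOVA (type-III, effect coding)\n")
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, 6)
  y$F <- signif(y$F, 6)
  y$p <- signif(y$p, 4)
  y$partial_eta_sq <- signif(y$partial_eta_sq, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
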