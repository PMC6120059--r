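# Statistical tests of correspondence between the two capacity estimates:
# equality-vs-regression model comparison (F test, BIC difference), Pearson
# correlations, study pooling with z-scoring, ceiling exclusion and the
# fit-quality control analysis.

#' Equality-versus-regression test of the two capacity estimates
#'
#' Compares an equality model (`K_Pm = K_SD`, no free parameters beyond the
#' error SD) with ordinary least-squares regression
#' `K_Pm = beta0 + beta1 * K_SD` across subjects. Significance comes from an
#' F test on the residual sums of squares (equivalent to a likelihood ratio
#' test); BIC is computed for both models as
#' `n * log(RSS / n) + k * log(n)` with `k = 1` and `k = 3` (the error SD
#' counted in both) and `delta_bic = BIC_equality - BIC_regression` (positive
#' values favour the regression model).
#'
#' @param pairs Data frame with columns `k_pm` and `k_sd` (one row per
#'   subject), e.g. from [capacity_pairs()].
#' @return List of class `consistency_result`: `f_stat`, `p_equality`,
#'   `delta_bic`, `beta0`, `beta1`, `r_pearson`, `p_pearson`, `n`,
#'   `degenerate` flag. Degenerate residual configurations (perfect fits)
#'   return limiting p-values and a flag, never an error.
#' @export
equality_vs_regression <- function(pairs) {
  x <- pairs$k_sd
  y <- pairs$k_pm
  n <- length(x)
  if (n < 3) stop("equality_vs_regression(): need at least 3 pairs", call. = FALSE)
  rss0 <- sum((y - x)^2)
  degenerate <- FALSE
  if (stats::var(x) == 0) {
    # regression undefined; slope unidentifiable
    degenerate <- TRUE
    beta0 <- mean(y)
    beta1 <- NA_real_
    rss1 <- sum((y - mean(y))^2)
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
    beta0 <- unname(fit$coefficients[1])
    beta1 <- unname(fit$coefficients[2])
    rss1 <- sum(fit$residuals^2)
  }
  if (rss1 <= 1e-12 * (1 + rss0)) {
    degenerate <- TRUE
    p_eq <- if (rss0 <= 1e-12) 1 else 0     # limits of the F tail
    f_stat <- if (rss0 <= 1e-12) 0 else Inf
  } else {
    f_stat <- ((rss0 - rss1) / 2) / (rss1 / (n - 2))
    f_stat <- max(f_stat, 0)
    p_eq <- stats::pf(f_stat, 2, n - 2, lower.tail = FALSE)
  }
  bic0 <- if (rss0 > 0) n * log(rss0 / n) + 1 * log(n) else -Inf
  bic1 <- if (rss1 > 0) n * log(rss1 / n) + 3 * log(n) else -Inf
  delta_bic <- bic0 - bic1
  if (!is.finite(delta_bic)) degenerate <- TRUE
  ct <- tryCatch(pearson_cor(pairs), error = function(e) list(r = NA_real_, p = NA_real_))
  structure(list(f_stat = f_stat, p_equality = p_eq, delta_bic = delta_bic,
                 beta0 = beta0, beta1 = beta1,
                 r_pearson = ct$r, p_pearson = ct$p, n = n,
                 degenerate = degenerate),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf(
    "equality vs regression (n = %d)\n  F = %.3f, p = %.4g, deltaBIC = %.2f\n  K_Pm = %.3f + %.3f K_SD;  Pearson r = %.3f (p = %.4g)%s\n",
    x$n, x$f_stat, x$p_equality, x$delta_bic, x$beta0,
    ifelse(is.na(x$beta1), NaN, x$beta1), x$r_pearson, x$p_pearson,
    if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Pearson correlation between the two capacity estimates
#'
#' @param pairs Data frame with `k_pm`, `k_sd` columns.
#' @return List with `r` and two-sided `p` (t test).
#' @export
pearson_cor <- function(pairs) {
  x <- pairs$k_sd
  y <- pairs$k_pm
  if (length(x) < 3) stop("pearson_cor(): need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_cor(): zero variance; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pool capacity pairs across studies
#'
#' Concatenates per-study capacity pairs and runs the consistency tests on
#' the pooled set. With `zscore = TRUE` each study's `k_pm` and `k_sd` are
#' independently standardized (mean 0, SD 1) before pooling, which guards the
#' pooled correlation against between-study mean differences (Simpson's
#' paradox); the equality test is only meaningful on the raw scale, so it is
#' reported as `NA` in that case. Studies with fewer than 2 subjects are
#' dropped with a warning.
#'
#' @param pairs Data frame with `study`, `k_pm`, `k_sd` columns.
#' @param zscore Standardize within study before pooling?
#' @return A `consistency_result` (see [equality_vs_regression()]), with the
#'   equality components set to `NA` when `zscore = TRUE`.
#' @export
pooled_analysis <- function(pairs, zscore = FALSE) {
  if (!"study" %in% names(pairs)) stop("pooled_analysis(): need a study column",
                                       call. = FALSE)
  keep <- ave(rep(1, nrow(pairs)), pairs$study, FUN = length) >= 2
  if (any(!keep)) {
    warning(sprintf("dropping %d pair(s) from studies with < 2 subjects",
                    sum(!keep)))
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (length(unique(pairs$study)) < 1 || nrow(pairs) < 3) {
    stop("pooled_analysis(): not enough data after exclusions", call. = FALSE)
  }
  if (zscore) {
    z <- function(v, g) ave(v, g, FUN = function(u) (u - mean(u)) / stats::sd(u))
    zp <- pairs
    zp$k_pm <- z(pairs$k_pm, pairs$study)
    zp$k_sd <- z(pairs$k_sd, pairs$study)
    ct <- pearson_cor(zp)
    res <- structure(list(f_stat = NA_real_, p_equality = NA_real_,
                          delta_bic = NA_real_, beta0 = NA_real_,
                          beta1 = NA_real_, r_pearson = ct$r,
                          p_pearson = ct$p, n = nrow(zp), degenerate = FALSE),
                     class = "consistency_result")
    return(res)
  }
  equality_vs_regression(pairs)
}

#' Exclude subjects whose estimates sit at the ceiling
#'
#' Removes subjects whose `k_pm` equals the maximum set size tested (within
#' 1e-6) or whose `k_sd` reaches or exceeds it (the plateau optimizer is
#' allowed above the maximum set size): such estimates are censored and can
#' inflate the apparent correspondence.
#'
#' @param pairs Data frame with `k_pm`, `k_sd` and `max_set_size` columns.
#' @return The retained rows.
#' @export
exclude_at_ceiling <- function(pairs) {
  stopifnot("max_set_size" %in% names(pairs))
  at_ceiling <- abs(pairs$k_pm - pairs$max_set_size) <= 1e-6 |
    pairs$k_sd >= pairs$max_set_size - 1e-6
  pairs[!at_ceiling, , drop = FALSE]
}

#' Does estimate disagreement track plateau-fit quality?
#'
#' Correlates the absolute difference between the two capacity estimates with
#' the root-mean-square error of the plateau fit. A null correlation says the
#' lack of correspondence is not explained by poor plateau fits.
#'
#' @param pairs Data frame with `k_pm`, `k_sd`, `rmse_sd_fit` columns.
#' @return List with `r`, `p`.
#' @export
fit_quality_check <- function(pairs) {
  d <- abs(pairs$k_pm - pairs$k_sd)
  if (length(d) < 3) stop("fit_quality_check(): need at least 3 pairs", call. = FALSE)
  if (stats::var(pairs$rmse_sd_fit) == 0 || stats::var(d) == 0) {
    stop("fit_quality_check(): zero variance; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(d, pairs$rmse_sd_fit, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Study-level consistency from subject-averaged profiles
#'
#' Averages `Pm(N)` and `SD(N)` across the subjects of each study, computes
#' one capacity pair per study from the averaged profile, and runs the
#' equality-versus-regression test across studies.
#'
#' @param fit_table Output of [fit_all_cells()] with a `study` column.
#' @inheritParams capacity_pair
#' @return List with `pairs` (one row per study) and `result`
#'   (a `consistency_result`).
#' @export
group_mean_analysis <- function(fit_table, k_pm_method = "max_npm",
                                k_sd_method = "plateau") {
  stopifnot("study" %in% names(fit_table))
  studies <- unique(fit_table$study)
  if (length(studies) < 3) {
    stop("group_mean_analysis(): need at least 3 studies", call. = FALSE)
  }
  rows <- lapply(studies, function(s) {
    d <- fit_table[fit_table$study == s, , drop = FALSE]
    pm_bar <- tapply(d$pm, d$set_size, mean)
    sd_bar <- tapply(d$sd_deg, d$set_size, mean)
    ns <- as.numeric(names(pm_bar))
    fits <- data.frame(set_size = ns, pm = as.numeric(pm_bar),
                       sd_deg = as.numeric(sd_bar))
    pair <- capacity_pair(fits, k_pm_method = k_pm_method,
                          k_sd_method = k_sd_method)
    pair$study <- s
    pair
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(pairs = pairs, result = equality_vs_regression(pairs))
}
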