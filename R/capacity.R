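# Capacity estimation from mixture-fit profiles: K_Pm from guessing
# frequency (max over N of N * Pm(N)) and K_SD from the plateau in recall
# variability, plus the two bilinear alternatives. Capacities are continuous,
# never rounded to integers.

#' Per-subject set-size profile
#'
#' Validated container for the fitted `Pm(N)` and `SD(N)` of one subject.
#' The inclusion rule requires at least four distinct set sizes including
#' set size one.
#'
#' @param set_sizes Distinct positive integer set sizes.
#' @param pm Memory probabilities per set size, in `[0, 1]`.
#' @param sd_deg Fitted recall SDs per set size, degrees, `> 0`.
#' @return List of class `set_size_profile`, sorted by set size.
#' @export
set_size_profile <- function(set_sizes, pm, sd_deg) {
  stopifnot(length(set_sizes) == length(pm), length(pm) == length(sd_deg))
  if (anyDuplicated(set_sizes)) stop("duplicate set sizes", call. = FALSE)
  if (length(set_sizes) < 4 || !(1 %in% set_sizes)) {
    stop("profile needs >= 4 distinct set sizes including set size 1",
         call. = FALSE)
  }
  if (any(set_sizes < 1) || any(set_sizes != round(set_sizes))) {
    stop("set sizes must be positive integers", call. = FALSE)
  }
  if (any(pm < 0 | pm > 1)) stop("Pm must be in [0, 1]", call. = FALSE)
  if (any(sd_deg <= 0)) stop("SD must be > 0", call. = FALSE)
  o <- order(set_sizes)
  structure(list(set_sizes = as.numeric(set_sizes[o]), pm = pm[o],
                 sd_deg = sd_deg[o]),
            class = "set_size_profile")
}

#' Capacity from guessing frequency
#'
#' `K_Pm = max over N of N * Pm(N)`: the largest estimated number of items
#' in memory across set sizes.
#'
#' @param profile A [set_size_profile()].
#' @return Scalar capacity estimate (items, possibly non-integer).
#' @export
k_from_pm <- function(profile) {
  stopifnot(inherits(profile, "set_size_profile"))
  max(profile$set_sizes * profile$pm)
}

# Breakpoint parameterization: K is searched on (0.5, max(N) + 1) through a
# logistic transform, so the simplex runs unconstrained.
k_transform <- function(t, maxn) 0.5 + (maxn + 0.5) * stats::plogis(t)
k_transform_inv <- function(k, maxn) {
  stats::qlogis(min(max((k - 0.5) / (maxn + 0.5), 1e-6), 1 - 1e-6))
}

#' Capacity from the variability plateau
#'
#' Least-squares fit of `SD(N) = sigma1 * sqrt(min(N, K))` to the fitted
#' recall SDs: below capacity, an item held in `K/N` slots is recalled with
#' the SD of an average of that many samples; at and above capacity a single
#' sample is available and the SD plateaus. The squared error is minimized
#' with Nelder-Mead simplex search over `(sigma1, K)` from a range of
#' starting values (`K0 = 1, ..., max(N)`, `sigma1_0 = SD(1)`), with `K`
#' constrained to `(0.5, max(N) + 1)` by a logistic transform; the best
#' start by squared error wins. On profiles where the squared-error surface
#' is flat in `K` (e.g. no plateau within the tested range) the returned
#' breakpoint depends on where the simplex terminates -- that spread is part
#' of the estimator's sampling behavior.
#'
#' @param profile A [set_size_profile()].
#' @return List of class `plateau_fit` with `sigma1` (degrees), `k_sd`
#'   (items), `rmse` (degrees), `sse`.
#' @export
k_from_sd_plateau <- function(profile) {
  stopifnot(inherits(profile, "set_size_profile"))
  n <- profile$set_sizes
  y <- profile$sd_deg
  maxn <- max(n)
  sse <- function(par) {
    pred <- par[1] * sqrt(pmin(n, k_transform(par[2], maxn)))
    sum((y - pred)^2)
  }
  best <- NULL
  for (k0 in seq_len(maxn)) {
    o <- stats::optim(c(y[1], k_transform_inv(k0, maxn)), sse,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(sigma1 = best$par[1],
                 k_sd = k_transform(best$par[2], maxn),
                 rmse = sqrt(best$value / length(n)), sse = best$value),
            class = "plateau_fit")
}

# Shared machinery for the two bilinear fits y = a + b * min(N, K): simplex
# over (a, b, K-transform) started from ordinary least squares at each K0.
bilinear_fit <- function(n, y) {
  maxn <- max(n)
  sse <- function(par) {
    pred <- par[1] + par[2] * pmin(n, k_transform(par[3], maxn))
    sum((y - pred)^2)
  }
  best <- NULL
  for (k0 in seq_len(maxn)) {
    x0 <- pmin(n, k0)
    coefs <- stats::lm.fit(cbind(1, x0), y)$coefficients
    if (!is.finite(coefs[2])) coefs[2] <- 0      # K0 below all set sizes
    o <- stats::optim(c(coefs[1], coefs[2], k_transform_inv(k0, maxn)), sse,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  a <- unname(best$par[1])
  b <- unname(best$par[2])
  k <- unname(k_transform(best$par[3], maxn))
  degenerate <- FALSE
  if (!is.finite(b) || abs(b) < 1e-8 * (1 + abs(a))) {
    # flat profile: breakpoint unidentifiable; deterministic tie-break
    degenerate <- TRUE
    b <- if (is.finite(b)) b else 0
    k <- maxn
  }
  structure(list(a = unname(a), b = unname(b), k = k,
                 rmse = sqrt(best$value / length(n)), sse = best$value,
                 degenerate = degenerate),
            class = "bilinear_fit")
}

#' Bilinear fit to the recall-SD profile
#'
#' Alternative plateau estimator: `SD(N) = a + b * min(N, K)`.
#'
#' @param profile A [set_size_profile()].
#' @return List of class `bilinear_fit` with `a`, `b`, `k` (the breakpoint,
#'   items), `rmse`, `degenerate` (`TRUE` when `b` is indistinguishable from
#'   zero, in which case `k` is reported as the maximum set size).
#' @export
bilinear_sd <- function(profile) {
  stopifnot(inherits(profile, "set_size_profile"))
  bilinear_fit(profile$set_sizes, profile$sd_deg)
}

#' Bilinear fit to the estimated number of items in memory
#'
#' `N * Pm(N) = a + b * min(N, K)`; the breakpoint `K` is the alternative
#' guessing-based capacity estimate.
#'
#' @param profile A [set_size_profile()].
#' @return A `bilinear_fit` (see [bilinear_sd()]).
#' @export
bilinear_npm <- function(profile) {
  stopifnot(inherits(profile, "set_size_profile"))
  bilinear_fit(profile$set_sizes, profile$set_sizes * profile$pm)
}

#' Both capacity estimates for one subject
#'
#' Assembles a [set_size_profile()] from per-set-size mixture fits and
#' applies the configured estimator for each capacity.
#'
#' @param fits Data frame with one row per set size for a single subject:
#'   columns `set_size`, `pm`, `sd_deg` (as produced by [fit_all_cells()]).
#' @param k_pm_method `"max_npm"` (default, `max N * Pm`) or
#'   `"bilinear"` (breakpoint of [bilinear_npm()]).
#' @param k_sd_method `"plateau"` (default, [k_from_sd_plateau()]) or
#'   `"bilinear"` ([bilinear_sd()]).
#' @return One-row data frame of class `capacity_pair`: `k_pm`, `k_sd`,
#'   `sigma1` (degrees, SD fit at set size one), `rmse_sd_fit` (degrees),
#'   `k_pm_method`, `k_sd_method`, `max_set_size`.
#' @export
capacity_pair <- function(fits, k_pm_method = c("max_npm", "bilinear"),
                          k_sd_method = c("plateau", "bilinear")) {
  k_pm_method <- match.arg(k_pm_method)
  k_sd_method <- match.arg(k_sd_method)
  profile <- set_size_profile(fits$set_size, fits$pm, fits$sd_deg)
  k_pm <- if (k_pm_method == "max_npm") {
    k_from_pm(profile)
  } else {
    bilinear_npm(profile)$k
  }
  if (k_sd_method == "plateau") {
    sdfit <- k_from_sd_plateau(profile)
    k_sd <- sdfit$k_sd
    sigma1 <- sdfit$sigma1
    rmse <- sdfit$rmse
  } else {
    sdfit <- bilinear_sd(profile)
    k_sd <- sdfit$k
    sigma1 <- sdfit$a + sdfit$b          # fitted SD at set size one
    rmse <- sdfit$rmse
  }
  out <- data.frame(k_pm = k_pm, k_sd = k_sd, sigma1 = sigma1,
                    rmse_sd_fit = rmse,
                    k_pm_method = k_pm_method, k_sd_method = k_sd_method,
                    max_set_size = max(profile$set_sizes),
                    stringsAsFactors = FALSE)
  class(out) <- c("capacity_pair", "data.frame")
  out
}

#' Capacity pairs for every subject in a fit table
#'
#' @param fit_table Output of [fit_all_cells()].
#' @inheritParams capacity_pair
#' @return Data frame with one row per subject (`study` carried through when
#'   present) and the [capacity_pair()] columns.
#' @export
capacity_pairs <- function(fit_table, k_pm_method = "max_npm",
                           k_sd_method = "plateau") {
  has_study <- "study" %in% names(fit_table)
  key <- if (has_study) {
    interaction(fit_table$study, fit_table$subject, drop = TRUE)
  } else {
    factor(fit_table$subject)
  }
  rows <- lapply(split(fit_table, key), function(d) {
    pair <- capacity_pair(d, k_pm_method = k_pm_method,
                          k_sd_method = k_sd_method)
    pair$subject <- d$subject[1]
    if (has_study) pair$study <- d$study[1]
    pair
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  front <- intersect(c("study", "subject"), names(out))
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}
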