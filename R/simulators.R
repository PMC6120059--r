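# Generative models of continuous-report performance and the self-consistency
# Monte Carlo. The slot model ("slots + averaging"): a whole number of slots
# is available on each trial; storing an item in S slots shrinks its recall
# SD by sqrt(S); unstored items are pure guesses. The hybrid model adds
# doubly stochastic precision: each occupied slot carries an independent
# Gamma-distributed precision, and precisions add under precision-weighted
# averaging.

# von Mises sampling with a per-trial concentration vector (Best-Fisher with
# element-wise rejection masks).
vm_sample_vec <- function(mu, kappa) {
  n <- length(kappa)
  stopifnot(length(mu) %in% c(1L, n))
  if (length(mu) == 1L) mu <- rep(mu, n)
  out <- numeric(n)
  unif <- kappa <= 1e-10
  if (any(unif)) out[unif] <- stats::runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo) > 0) {
    k <- pmin(kappa[todo], KAPPA_MAX)
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    rr <- (1 + rho^2) / (2 * rho)
    pending <- seq_along(todo)
    theta <- numeric(length(todo))
    while (length(pending) > 0) {
      m <- length(pending)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + rr[pending] * z) / (rr[pending] + z)
      ccf <- k[pending] * (rr[pending] - f)
      ok <- (ccf * (2 - ccf) - u2 > 0) | (log(ccf / u2) + 1 - ccf >= 0)
      acc <- pending[ok]
      theta[acc] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      pending <- pending[!ok]
    }
    out[todo] <- theta
  }
  wrap_angle(out + mu)
}

#' Simulation design and population configuration
#'
#' Defaults reproduce the reference Monte Carlo design: 10 subjects, 250
#' trials at each of set sizes 1, 2, 3 and 6, and a subject population with
#' capacity `K = 3.74 +/- 1.3` items, set-size-one SD
#' `sigma1 = 17.4 +/- 5.3` degrees and a K-sigma1 correlation of -0.38; the
#' hybrid model's Gamma shape defaults to `tau = 4.4`.
#'
#' @param n_subjects Subjects per simulated experiment.
#' @param set_sizes Distinct positive integers, at least four including 1.
#' @param trials_per_set_size Trials per subject per set size.
#' @param model `"slot"` or `"hybrid"`.
#' @param tau Gamma shape of per-slot precision (hybrid only), `> 0`.
#' @param mean_k,sd_k Population mean and SD of capacity (items).
#' @param mean_sigma1,sd_sigma1 Population mean and SD of `sigma1` (degrees).
#' @param corr_k_sigma1 Population correlation between `K` and `sigma1`.
#' @param n_reps Monte Carlo replicates.
#' @param seed RNG seed used by [run_monte_carlo()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, set_sizes = c(1, 2, 3, 6),
                       trials_per_set_size = 250,
                       model = c("slot", "hybrid"), tau = 4.4,
                       mean_k = 3.74, sd_k = 1.3,
                       mean_sigma1 = 17.4, sd_sigma1 = 5.3,
                       corr_k_sigma1 = -0.38,
                       n_reps = 300, seed = 1L) {
  model <- match.arg(model)
  set_sizes <- sort(unique(as.numeric(set_sizes)))
  if (length(set_sizes) < 4 || !(1 %in% set_sizes) ||
      any(set_sizes != round(set_sizes)) || any(set_sizes < 1)) {
    stop("sim_config(): set_sizes must be >= 4 distinct positive integers including 1",
         call. = FALSE)
  }
  if (model == "hybrid" && (!is.finite(tau) || tau <= 0)) {
    stop("sim_config(): tau must be > 0 for the hybrid model", call. = FALSE)
  }
  stopifnot(n_subjects >= 1, trials_per_set_size >= 1, n_reps >= 1,
            sd_k >= 0, sd_sigma1 >= 0, abs(corr_k_sigma1) <= 1)
  structure(list(n_subjects = n_subjects, set_sizes = set_sizes,
                 trials_per_set_size = trials_per_set_size, model = model,
                 tau = tau, mean_k = mean_k, sd_k = sd_k,
                 mean_sigma1 = mean_sigma1, sd_sigma1 = sd_sigma1,
                 corr_k_sigma1 = corr_k_sigma1, n_reps = n_reps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw subject parameters from the population
#'
#' `(K, sigma1)` pairs from a bivariate normal with the configured moments,
#' rejection-resampled into the admissible region `K > 0.25`,
#' `sigma1 > 1` degree.
#'
#' @param config A [sim_config()].
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @return Data frame with columns `subject`, `k`, `sigma1`.
#' @export
sample_population <- function(config, n = config$n_subjects) {
  mu <- c(config$mean_k, config$mean_sigma1)
  sds <- c(config$sd_k, config$sd_sigma1)
  rho <- config$corr_k_sigma1
  k <- numeric(0)
  s1 <- numeric(0)
  rejected <- 0L
  while (length(k) < n) {
    m <- max(n - length(k), 32L)
    z1 <- stats::rnorm(m)
    z2 <- stats::rnorm(m)
    kk <- mu[1] + sds[1] * z1
    ss <- mu[2] + sds[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
    ok <- kk > 0.25 & ss > 1
    if (!any(ok)) {
      rejected <- rejected + m
      if (rejected > 1e4) {
        stop("sample_population(): admissible region has negligible mass under this configuration",
             call. = FALSE)
      }
    } else {
      rejected <- 0L
    }
    k <- c(k, kk[ok])
    s1 <- c(s1, ss[ok])
  }
  data.frame(subject = seq_len(n), k = k[seq_len(n)], sigma1 = s1[seq_len(n)])
}

# Per-trial slot bookkeeping shared by both generative models. Returns the
# realized capacity K_t, the number of slots S on the probed item (0 when the
# probed item is not stored) for each trial.
slot_allocation <- function(k, n_items, n_trials) {
  k0 <- floor(k)
  kt <- k0 + (stats::runif(n_trials) < (k - k0))
  s <- integer(n_trials)
  over <- n_items <= kt          # more slots than items: averaging regime
  if (any(over)) {
    base <- kt[over] %/% n_items
    rem <- kt[over] %% n_items
    s[over] <- base + (stats::runif(sum(over)) < rem / n_items)
  }
  if (any(!over)) {
    # K_t distinct items stored with one slot each; probed uniformly
    s[!over] <- as.integer(stats::runif(sum(!over)) < kt[!over] / n_items)
  }
  list(kt = kt, s = s)
}

#' Simulate continuous-report trials from the slot model
#'
#' Capacity is realized per trial as `floor(K)` plus a Bernoulli draw of the
#' fractional part. With `N` items and `K_t` slots: when `N <= K_t` slots are
#' divided as evenly as possible (remainder to uniformly chosen distinct
#' items) and an item held in `S` slots is recalled with
#' `SD = sigma1 * sqrt(K / S)` (so the expected set-size-one SD is `sigma1`);
#' when `N > K_t`, `K_t` distinct items hold one slot each and an unstored
#' probed item yields a uniform guess. Targets and the probed item are
#' uniform.
#'
#' @param params One-row data frame or list with `k` (items) and `sigma1`
#'   (degrees), as from [sample_population()].
#' @param set_sizes Set sizes to simulate.
#' @param trials Trials per set size.
#' @param subject Subject label stored in the output.
#' @return Trial table: `subject`, `set_size`, `target`, `response` (radians).
#' @export
simulate_slot_trials <- function(params, set_sizes = c(1, 2, 3, 6),
                                 trials = 250, subject = 1L) {
  k <- params$k
  sigma1 <- deg2rad(params$sigma1)
  stopifnot(is.finite(k), k > 0, is.finite(sigma1), sigma1 > 0)
  rows <- lapply(set_sizes, function(n_items) {
    alloc <- slot_allocation(k, n_items, trials)
    target <- stats::runif(trials, -pi, pi)
    kappa <- numeric(trials)
    stored <- alloc$s >= 1
    # few distinct slot counts per cell: solve kappa once per count
    s_levels <- sort(unique(alloc$s[stored]))
    kappa_by_s <- sd_to_kappa(sigma1 * sqrt(k / s_levels))
    kappa[stored] <- kappa_by_s[match(alloc$s[stored], s_levels)]
    resp <- numeric(trials)
    resp[stored] <- vm_sample_vec(target[stored], kappa[stored])
    resp[!stored] <- stats::runif(sum(!stored), -pi, pi)
    data.frame(subject = subject, set_size = n_items, target = target,
               response = wrap_angle(resp))
  })
  do.call(rbind, rows)
}

# von Mises concentration for a trial with total precision j (precision in
# 1/radian^2; SD = 1/sqrt(j)), capped at the overflow guard
kappa_from_precision <- function(j) {
  sd2 <- 1 / pmax(j, 1e-12)
  pmin(a1inv(exp(-sd2 / 2)), KAPPA_MAX)
}

#' Calibrate the hybrid model's per-slot mean precision
#'
#' The hybrid model identifies precision with inverse squared circular SD:
#' a slot sample with precision `J` has `SD = 1/sqrt(J)`, and the
#' precision-weighted average of an item's `S` slot samples has precision
#' `J_1 + ... + J_S` -- the same averaging rule as the slot model, which is
#' the `tau -> Inf` limit. Per-slot precision is
#' `J ~ Gamma(shape tau, mean jbar)` with a single `jbar`, chosen so that at
#' set size one the expected mean resultant length of the recall
#' distribution equals that of a von Mises with circular SD `sigma1` -- the
#' quantity the mixture fit estimates -- anchoring both simulators to the
#' same `sigma1`.
#'
#' @param k Capacity (items).
#' @param sigma1_rad Set-size-one SD, radians.
#' @param tau Gamma shape, `> 0`.
#' @return Per-slot mean precision `jbar` (1/radian^2).
#' @export
calibrate_hybrid_jbar <- function(k, sigma1_rad, tau) {
  stopifnot(tau > 0, k > 0, sigma1_rad > 0)
  # precisions above the overflow guard are not representable; the sharpest
  # attainable recall SD is kappa_to_sd(KAPPA_MAX) (~2.2 degrees)
  r_target <- min(exp(-sigma1_rad^2 / 2), a1(KAPPA_MAX * 0.98))
  k0 <- floor(k)
  frac <- k - k0
  kts <- c(k0, k0 + 1)
  w <- c(1 - frac, frac)
  keep <- kts >= 1 & w > 0
  kts <- kts[keep]
  w <- w[keep] / sum(w[keep])
  expected_r <- function(jbar) {
    vals <- vapply(kts, function(kt) {
      shape <- kt * tau
      scale <- jbar / tau
      q_hi <- stats::qgamma(1 - 1e-9, shape = shape, scale = scale)
      stats::integrate(function(x) a1(kappa_from_precision(x)) *
                         stats::dgamma(x, shape = shape, scale = scale),
                       lower = 0, upper = q_hi, rel.tol = 1e-8,
                       subdivisions = 400L)$value
    }, numeric(1))
    sum(w * vals)
  }
  f <- function(j) expected_r(j) - r_target
  # expected resultant is monotone in jbar; expand the bracket geometrically
  mid <- 1 / (sigma1_rad^2 * sum(w * kts))   # tau -> Inf (slot-model) value
  lo <- mid
  hi <- mid
  while (f(lo) > 0 && lo > 1e-8) lo <- lo / 4
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 4
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibrate_hybrid_jbar(): could not bracket the calibration root",
         call. = FALSE)
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Simulate trials from the doubly stochastic hybrid model
#'
#' Slot bookkeeping as in [simulate_slot_trials()], but each occupied slot
#' carries an independent precision `J ~ Gamma(shape tau, mean jbar)`
#' (precision = inverse squared circular SD) and an item stored in `S` slots
#' is recalled with `SD = 1/sqrt(J_1 + ... + J_S)` (precision-weighted
#' averaging). `jbar` comes from [calibrate_hybrid_jbar()] so the expected
#' set-size-one recall SD is `sigma1`. As `tau` grows the Gamma degenerates
#' to its mean and the model converges to [simulate_slot_trials()].
#'
#' @inheritParams simulate_slot_trials
#' @param tau Gamma shape parameter, `> 0`.
#' @return Trial table: `subject`, `set_size`, `target`, `response` (radians).
#' @export
simulate_hybrid_trials <- function(params, tau = 4.4,
                                   set_sizes = c(1, 2, 3, 6),
                                   trials = 250, subject = 1L) {
  k <- params$k
  sigma1 <- deg2rad(params$sigma1)
  stopifnot(is.finite(k), k > 0, is.finite(sigma1), sigma1 > 0, tau > 0)
  jbar <- calibrate_hybrid_jbar(k, sigma1, tau)
  rows <- lapply(set_sizes, function(n_items) {
    alloc <- slot_allocation(k, n_items, trials)
    target <- stats::runif(trials, -pi, pi)
    resp <- numeric(trials)
    stored <- alloc$s >= 1
    if (any(stored)) {
      # sum of S iid Gamma(tau, scale jbar/tau) is Gamma(S * tau, same scale)
      j_tot <- stats::rgamma(sum(stored), shape = alloc$s[stored] * tau,
                             scale = jbar / tau)
      resp[stored] <- vm_sample_vec(target[stored], kappa_from_precision(j_tot))
    }
    resp[!stored] <- stats::runif(sum(!stored), -pi, pi)
    data.frame(subject = subject, set_size = n_items, target = target,
               response = wrap_angle(resp))
  })
  do.call(rbind, rows)
}

#' Simulate one full experiment
#'
#' One trial table covering every subject in `params` under the configured
#' generative model.
#'
#' @param params Data frame from [sample_population()].
#' @param config A [sim_config()].
#' @return Trial table with all subjects.
#' @export
simulate_experiment <- function(params, config) {
  rows <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    if (config$model == "slot") {
      simulate_slot_trials(p, set_sizes = config$set_sizes,
                           trials = config$trials_per_set_size,
                           subject = p$subject)
    } else {
      simulate_hybrid_trials(p, tau = config$tau,
                             set_sizes = config$set_sizes,
                             trials = config$trials_per_set_size,
                             subject = p$subject)
    }
  })
  do.call(rbind, rows)
}

#' Self-consistency Monte Carlo
#'
#' Repeatedly simulates an experiment from the configured generative model,
#' runs the mixture fits and both capacity estimators on each simulated
#' subject, and records the across-subject Pearson correlation and
#' equality-test p-value of each replicate. Summaries include the mean
#' correlation and p-value and the frequencies at or below the supplied
#' thresholds (defaults: the reference empirical values `r <= 0.19`,
#' `p <= 0.0148`). Replicates with degenerate statistics (zero variance in
#' either estimate) are dropped and counted.
#'
#' @param config A [sim_config()]; `config$seed` seeds the run.
#' @param r_threshold,p_threshold Threshold values for the frequency
#'   summaries.
#' @param control [em_control()] for the mixture fits.
#' @param progress Print a dot every 50 replicates?
#' @return List of class `monte_carlo_summary`: `mean_r`, `mean_p`,
#'   `freq_r_below`, `freq_p_below`, `freq_joint`, `n_valid`, `n_dropped`,
#'   `per_rep` (data frame of per-replicate `r` and `p`), `config`.
#' @export
run_monte_carlo <- function(config, r_threshold = 0.19, p_threshold = 0.0148,
                            control = em_control(), progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rs <- rep(NA_real_, config$n_reps)
  ps <- rep(NA_real_, config$n_reps)
  for (rep_i in seq_len(config$n_reps)) {
    params <- sample_population(config)
    trials <- simulate_experiment(params, config)
    fits <- fit_all_cells(trials, control = control)
    pairs <- capacity_pairs(fits)
    res <- tryCatch(equality_vs_regression(pairs), error = function(e) NULL)
    if (!is.null(res) && !is.na(res$r_pearson) && !isTRUE(res$degenerate)) {
      rs[rep_i] <- res$r_pearson
      ps[rep_i] <- res$p_equality
    }
    if (progress && rep_i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  valid <- !is.na(rs) & !is.na(ps)
  structure(list(
    mean_r = mean(rs[valid]), mean_p = mean(ps[valid]),
    freq_r_below = mean(rs[valid] <= r_threshold),
    freq_p_below = mean(ps[valid] <= p_threshold),
    freq_joint = mean(rs[valid] <= r_threshold & ps[valid] <= p_threshold),
    r_threshold = r_threshold, p_threshold = p_threshold,
    n_valid = sum(valid), n_dropped = sum(!valid),
    per_rep = data.frame(rep = which(valid), r = rs[valid], p = ps[valid]),
    config = config),
    class = "monte_carlo_summary")
}

#' @export
print.monte_carlo_summary <- function(x, ...) {
  cat(sprintf(
    "%s-model Monte Carlo (%d valid / %d replicates)\n  mean r = %.3f, mean equality p = %.3f\n  freq(r <= %.3g) = %.3f, freq(p <= %.3g) = %.3f, joint = %.3f\n",
    x$config$model, x$n_valid, x$config$n_reps, x$mean_r, x$mean_p,
    x$r_threshold, x$freq_r_below, x$p_threshold, x$freq_p_below,
    x$freq_joint))
  invisible(x)
}
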