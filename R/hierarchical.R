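# Bayesian hierarchical model of the two capacity estimates: per-subject
# latent (K_Pm, K_SD) drawn from a bivariate normal population; the observed
# max_N{N * Pm(N)} and SD(N) profiles are noisy measurements of the latents.
# Posterior inference by MCMC (JAGS); the joint density is also available
# directly as hier_log_posterior().

#' Observations for the hierarchical model
#'
#' @param max_npm Per-subject maximum over set sizes of `N * Pm(N)` (items).
#' @param sd_obs Matrix of fitted recall SDs (degrees), subjects in rows,
#'   set sizes in columns (a shared set-size grid).
#' @param set_sizes Set sizes corresponding to the columns of `sd_obs`.
#' @return List of class `hier_data`.
#' @export
hier_data <- function(max_npm, sd_obs, set_sizes) {
  sd_obs <- as.matrix(sd_obs)
  stopifnot(length(max_npm) == nrow(sd_obs),
            length(set_sizes) == ncol(sd_obs),
            all(is.finite(max_npm)), all(is.finite(sd_obs)),
            all(max_npm > 0), all(sd_obs > 0))
  structure(list(max_npm = as.numeric(max_npm), sd_obs = sd_obs,
                 set_sizes = as.numeric(set_sizes),
                 n_subjects = length(max_npm)),
            class = "hier_data")
}

#' Build hierarchical observations from a mixture-fit table
#'
#' @param fit_table Output of [fit_all_cells()] (single shared set-size
#'   grid across subjects).
#' @return A [hier_data()].
#' @export
hier_data_from_fits <- function(fit_table) {
  ns <- sort(unique(fit_table$set_size))
  subs <- unique(fit_table$subject)
  sd_obs <- matrix(NA_real_, length(subs), length(ns))
  max_npm <- numeric(length(subs))
  for (i in seq_along(subs)) {
    d <- fit_table[fit_table$subject == subs[i], ]
    d <- d[order(d$set_size), ]
    if (!identical(as.numeric(d$set_size), as.numeric(ns))) {
      stop("hier_data_from_fits(): subjects must share one set-size grid",
           call. = FALSE)
    }
    sd_obs[i, ] <- d$sd_deg
    max_npm[i] <- max(d$set_size * d$pm)
  }
  hier_data(max_npm, sd_obs, ns)
}

#' Default priors for the hierarchical model
#'
#' Weakly informative on the scale of the data: population mean capacities
#' normal(4, 4) truncated positive; population and observation SDs
#' half-normal (scale 5 items / 10 degrees); the population correlation
#' uniform on (-1, 1); per-subject `sigma1` half-normal (scale 30 degrees).
#'
#' @return Named list of prior scales.
#' @export
hier_priors <- function() {
  list(mean_loc = 4, mean_scale = 4,     # truncated-positive normal
       sd_scale = 5,                     # half-normal, population SDs (items)
       obs_pm_scale = 5,                 # half-normal, sigma_Pm (items)
       obs_sd_scale = 10,                # half-normal, sigma_SD (degrees)
       sigma1_scale = 30)                # half-normal, per-subject sigma1 (deg)
}

# log density of a half-normal with scale s at x > 0
log_halfnorm <- function(x, s) {
  if (any(x <= 0)) return(-Inf)
  sum(stats::dnorm(x, 0, s, log = TRUE) + log(2))
}

# log density of normal(loc, scale) truncated to (0, Inf)
log_truncnorm_pos <- function(x, loc, scale) {
  if (any(x <= 0)) return(-Inf)
  sum(stats::dnorm(x, loc, scale, log = TRUE) -
        stats::pnorm(0, loc, scale, lower.tail = FALSE, log.p = TRUE))
}

# Latent K_SD enters the SD-profile mean through sqrt(min(N, K)); values are
# floored at this constant to keep the mean defined for the (rare) negative
# excursions of the bivariate normal.
K_SD_FLOOR <- 0.01

#' Log posterior of the hierarchical model
#'
#' Sum of (i) the bivariate normal log density of each subject's latent
#' `(K_Pm, K_SD)` given the population mean vector and covariance, (ii) the
#' normal log density of the observed `max N * Pm` given latent `K_Pm` and
#' observation SD `sigma_pm_obs`, (iii) the normal log density of each
#' observed `SD(N)` given `sigma1_i * sqrt(min(N, K_SD_i))` and
#' `sigma_sd_obs`, and (iv) the log priors of [hier_priors()]. Returns
#' `-Inf` outside the support (non-positive SDs, `|rho| >= 1`, non-positive
#' `sigma1`).
#'
#' @param params Named list: `kbar_pm`, `kbar_sd`, `sigma_k_pm`,
#'   `sigma_k_sd`, `rho`, `sigma_pm_obs`, `sigma_sd_obs`, and per-subject
#'   vectors `k_pm`, `k_sd`, `sigma1`.
#' @param data A [hier_data()].
#' @param priors Prior scales, see [hier_priors()].
#' @return Scalar log posterior density (unnormalized).
#' @export
hier_log_posterior <- function(params, data, priors = hier_priors()) {
  p <- params
  if (!all(is.finite(unlist(p)))) return(-Inf)
  if (p$sigma_k_pm <= 0 || p$sigma_k_sd <= 0 || abs(p$rho) >= 1 ||
      p$sigma_pm_obs <= 0 || p$sigma_sd_obs <= 0 || any(p$sigma1 <= 0)) {
    return(-Inf)
  }
  s <- data$n_subjects
  stopifnot(length(p$k_pm) == s, length(p$k_sd) == s, length(p$sigma1) == s)
  # (i) bivariate normal population
  det_fac <- (1 - p$rho^2)
  z1 <- (p$k_pm - p$kbar_pm) / p$sigma_k_pm
  z2 <- (p$k_sd - p$kbar_sd) / p$sigma_k_sd
  lp_pop <- sum(-log(2 * pi) - log(p$sigma_k_pm) - log(p$sigma_k_sd) -
                  0.5 * log(det_fac) -
                  (z1^2 - 2 * p$rho * z1 * z2 + z2^2) / (2 * det_fac))
  # (ii) guessing-frequency observations
  lp_pm <- sum(stats::dnorm(data$max_npm, p$k_pm, p$sigma_pm_obs, log = TRUE))
  # (iii) SD-profile observations
  k_eff <- pmax(p$k_sd, K_SD_FLOOR)
  mu_sd <- outer(seq_len(s), seq_along(data$set_sizes),
                 function(i, j) p$sigma1[i] * sqrt(pmin(data$set_sizes[j], k_eff[i])))
  lp_sd <- sum(stats::dnorm(data$sd_obs, mu_sd, p$sigma_sd_obs, log = TRUE))
  # (iv) priors
  lp_prior <-
    log_truncnorm_pos(p$kbar_pm, priors$mean_loc, priors$mean_scale) +
    log_truncnorm_pos(p$kbar_sd, priors$mean_loc, priors$mean_scale) +
    log_halfnorm(p$sigma_k_pm, priors$sd_scale) +
    log_halfnorm(p$sigma_k_sd, priors$sd_scale) +
    log(0.5) +                                   # rho ~ uniform(-1, 1)
    log_halfnorm(p$sigma_pm_obs, priors$obs_pm_scale) +
    log_halfnorm(p$sigma_sd_obs, priors$obs_sd_scale) +
    log_halfnorm(p$sigma1, priors$sigma1_scale)
  lp_pop + lp_pm + lp_sd + lp_prior
}

hier_jags_model <- "
model {
  for (i in 1:S) {
    K[i, 1:2] ~ dmnorm(mu[1:2], Omega[1:2, 1:2])
    maxnpm[i] ~ dnorm(K[i, 1], tau_pm)
    sigma1[i] ~ dnorm(0, tau_s1) T(0,)
    for (j in 1:J) {
      sdobs[i, j] ~ dnorm(sigma1[i] * sqrt(min(N[j], max(K[i, 2], kfloor))), tau_sd)
    }
  }
  kbar_pm ~ dnorm(mean_loc, 1 / (mean_scale^2)) T(0,)
  kbar_sd ~ dnorm(mean_loc, 1 / (mean_scale^2)) T(0,)
  sigma_k_pm ~ dnorm(0, 1 / (sd_scale^2)) T(0,)
  sigma_k_sd ~ dnorm(0, 1 / (sd_scale^2)) T(0,)
  rho ~ dunif(-1, 1)
  sigma_pm_obs ~ dnorm(0, 1 / (obs_pm_scale^2)) T(0,)
  sigma_sd_obs ~ dnorm(0, 1 / (obs_sd_scale^2)) T(0,)
  mu[1] <- kbar_pm
  mu[2] <- kbar_sd
  Sigma[1, 1] <- sigma_k_pm^2
  Sigma[2, 2] <- sigma_k_sd^2
  Sigma[1, 2] <- rho * sigma_k_pm * sigma_k_sd
  Sigma[2, 1] <- Sigma[1, 2]
  Omega[1:2, 1:2] <- inverse(Sigma[1:2, 1:2])
  tau_pm <- 1 / (sigma_pm_obs^2)
  tau_sd <- 1 / (sigma_sd_obs^2)
  tau_s1 <- 1 / (sigma1_scale^2)
}
"

#' Narrowest 95% (or other mass) highest-density interval
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass of the interval.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  # interval x[i] .. x[i + m - 1] holds m draws; take the narrowest
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

# Split-Rhat: each chain halved, then the usual between/within variance ratio.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    n <- floor(length(ch) / 2)
    list(ch[1:n], ch[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the hierarchical model by MCMC
#'
#' Samples the posterior with JAGS (4 chains by default), returning posterior
#' means, SDs, narrowest 95% highest-density intervals, split-Rhat and
#' effective sample sizes for the population parameters. A warning is
#' attached when any split-Rhat exceeds 1.05.
#'
#' @param data A [hier_data()] (or [fit_all_cells()] table via
#'   [hier_data_from_fits()]).
#' @param n_chains Number of chains (>= 4 recommended).
#' @param n_adapt,n_burn,n_iter Adaptation, burn-in and retained iterations
#'   per chain.
#' @param priors Prior scales, see [hier_priors()].
#' @param seed Integer seed for the JAGS RNGs.
#' @param quiet Suppress JAGS progress output?
#' @return List of class `hier_fit`: `summary` (data frame with `mean`,
#'   `sd`, `hdi_lo`, `hdi_hi`, `rhat`, `ess` per population parameter),
#'   `draws` (matrix of pooled draws), `converged`, `n_chains`, `n_iter`.
#' @export
fit_hierarchical <- function(data, n_chains = 4, n_adapt = 500,
                             n_burn = 1000, n_iter = 1500,
                             priors = hier_priors(), seed = 1L,
                             quiet = TRUE) {
  if (inherits(data, "data.frame")) data <- hier_data_from_fits(data)
  stopifnot(inherits(data, "hier_data"))
  if (data$n_subjects < 2) {
    stop("fit_hierarchical(): need at least 2 subjects (5+ recommended)",
         call. = FALSE)
  }
  jd <- list(S = data$n_subjects, J = length(data$set_sizes),
             N = data$set_sizes, maxnpm = data$max_npm, sdobs = data$sd_obs,
             kfloor = K_SD_FLOOR,
             mean_loc = priors$mean_loc, mean_scale = priors$mean_scale,
             sd_scale = priors$sd_scale, obs_pm_scale = priors$obs_pm_scale,
             obs_sd_scale = priors$obs_sd_scale,
             sigma1_scale = priors$sigma1_scale)
  inits <- lapply(seq_len(n_chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) * 1000L + i)
  })
  monitors <- c("kbar_pm", "kbar_sd", "sigma_k_pm", "sigma_k_sd", "rho",
                "sigma_pm_obs", "sigma_sd_obs")
  run <- function(n_adapt, n_burn, n_iter) {
    jm <- rjags::jags.model(textConnection(hier_jags_model), data = jd,
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_adapt, quiet = quiet)
    update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = n_iter,
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run(n_adapt, n_burn, n_iter)) else run(n_adapt, n_burn, n_iter)
  draws_by_chain <- lapply(samp, as.matrix)
  pooled <- do.call(rbind, draws_by_chain)
  summ <- do.call(rbind, lapply(monitors, function(par) {
    chains <- lapply(draws_by_chain, function(m) m[, par])
    h <- hdi(pooled[, par])
    data.frame(param = par, mean = mean(pooled[, par]),
               sd = stats::sd(pooled[, par]), hdi_lo = h[1], hdi_hi = h[2],
               rhat = split_rhat(chains),
               ess = unname(coda::effectiveSize(samp[, par])),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  converged <- all(summ$rhat < 1.05)
  if (!converged) {
    warning(sprintf("fit_hierarchical(): split-Rhat > 1.05 for: %s",
                    paste(summ$param[summ$rhat >= 1.05], collapse = ", ")))
  }
  structure(list(summary = summ, draws = pooled, converged = converged,
                 n_chains = n_chains, n_iter = n_iter),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("hierarchical model fit (%d chains x %d draws%s)\n",
              x$n_chains, x$n_iter,
              if (x$converged) "" else "; CONVERGENCE WARNING"))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
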