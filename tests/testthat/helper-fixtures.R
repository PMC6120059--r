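# Shared fixture builders. Everything is generated in code at test time.

# errors from the two-component mixture: pm von Mises (sd_deg) + uniform
mixture_errors <- function(n, pm, sd_deg) {
  from_vm <- stats::runif(n) < pm
  e <- numeric(n)
  e[from_vm] <- vm_sample(sum(from_vm), 0, sd_to_kappa(deg2rad_t(sd_deg)))
  e[!from_vm] <- stats::runif(sum(!from_vm), -pi, pi)
  e
}

deg2rad_t <- function(x) x * pi / 180
rad2deg_t <- function(x) x * 180 / pi

# independent modified-Bessel-series oracle, sum_{k} (x/2)^(2k+nu) / (k! (k+nu)!)
bessel_series <- function(x, nu = 0, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k + nu) / (factorial(k) * factorial(k + nu)))
}

# grid-search maximum likelihood oracle for the mixture
grid_ml_loglik <- function(errors, pm_grid = seq(0.005, 0.995, length.out = 100),
                           sd_grid_deg = seq(2, 80, length.out = 100)) {
  u <- 1 / (2 * pi)
  best <- -Inf
  for (sdd in sd_grid_deg) {
    f <- vm_pdf(errors, sd_to_kappa(deg2rad_t(sdd)))
    for (pm in pm_grid) {
      ll <- sum(log(pm * f + (1 - pm) * u))
      if (ll > best) best <- ll
    }
  }
  best
}

# draw a data set directly from the hierarchical generative model
hier_sim <- function(n_subj, rho, seed, sigma_pm = 0.3, sigma_sd = 1.5,
                     means = c(3.6, 3.4), sds = c(1, 1)) {
  set.seed(seed)
  ns <- c(1, 2, 3, 6)
  z1 <- stats::rnorm(n_subj)
  z2 <- stats::rnorm(n_subj)
  k_pm <- pmax(means[1] + sds[1] * z1, 0.3)
  k_sd <- pmax(means[2] + sds[2] * (rho * z1 + sqrt(1 - rho^2) * z2), 0.3)
  sigma1 <- pmax(stats::rnorm(n_subj, 17, 3), 2)
  max_npm <- pmax(k_pm + stats::rnorm(n_subj, 0, sigma_pm), 0.05)
  sd_obs <- t(vapply(seq_len(n_subj), function(i) {
    pmax(sigma1[i] * sqrt(pmin(ns, k_sd[i])) + stats::rnorm(4, 0, sigma_sd), 0.5)
  }, numeric(4)))
  list(data = hier_data(max_npm, sd_obs, ns),
       truth = list(k_pm = k_pm, k_sd = k_sd, sigma1 = sigma1, rho = rho))
}

# minimal trial table on the full circle
make_trials <- function(subject, set_sizes, n_per_cell, pm_fun, sd_fun) {
  rows <- lapply(set_sizes, function(N) {
    target <- stats::runif(n_per_cell, -pi, pi)
    e <- mixture_errors(n_per_cell, pm_fun(N), sd_fun(N))
    data.frame(subject = subject, set_size = N, target = target,
               response = wrap_angle(target + e))
  })
  do.call(rbind, rows)
}
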