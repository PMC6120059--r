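profile_from <- function(ns, pm, sd) set_size_profile(ns, pm, sd)

test_that("k_from_pm takes the maximum estimated number of items in memory", {
  ns <- c(1, 2, 4, 8)
  expect_equal(k_from_pm(profile_from(ns, c(1, 1, 0.75, 0.375), rep(20, 4))), 3)
  expect_equal(k_from_pm(profile_from(ns, c(1, 1, 1, 1), rep(20, 4))), 8)
  expect_equal(k_from_pm(profile_from(ns, c(0.9, 0.8, 0.5, 0.2), rep(20, 4))), 2)
  # never exceeds the largest set size; increasing Pm weakly increases K_Pm
  set.seed(20)
  for (i in 1:25) {
    pm <- stats::runif(4)
    p1 <- profile_from(ns, pm, rep(20, 4))
    p2 <- profile_from(ns, pmin(pm + stats::runif(4, 0, 0.2), 1), rep(20, 4))
    expect_lte(k_from_pm(p1), max(ns))
    expect_gte(k_from_pm(p2), k_from_pm(p1))
  }
})

test_that("set_size_profile enforces the inclusion rule", {
  expect_error(set_size_profile(c(2, 3, 4, 6), rep(1, 4), rep(10, 4)), "set size 1")
  expect_error(set_size_profile(c(1, 2, 3), rep(1, 3), rep(10, 3)), ">= 4")
  expect_error(set_size_profile(c(1, 1, 2, 3), rep(1, 4), rep(10, 4)), "duplicate")
  expect_error(set_size_profile(c(1, 2, 3, 6), c(1, 1, 1, 1.2), rep(10, 4)), "Pm")
})

test_that("plateau fit recovers noiseless profiles exactly", {
  ns <- c(1, 2, 4, 8)
  f <- k_from_sd_plateau(profile_from(ns, rep(1, 4), 10 * sqrt(pmin(ns, 3))))
  expect_equal(f$k_sd, 3, tolerance = 1e-4)
  expect_equal(f$sigma1, 10, tolerance = 1e-4)
  expect_lt(f$rmse, 1e-4)
  # immediate plateau: flat SD profile
  g <- k_from_sd_plateau(profile_from(ns, rep(1, 4), rep(20, 4)))
  expect_equal(g$k_sd, 1, tolerance = 1e-3)
  expect_equal(g$sigma1, 20, tolerance = 1e-3)
})

test_that("plateau fit is scale invariant", {
  ns <- c(1, 2, 3, 6)
  set.seed(21)
  sd_prof <- 12 * sqrt(pmin(ns, 2.6)) + stats::rnorm(4, 0, 0.8)
  f1 <- k_from_sd_plateau(profile_from(ns, rep(1, 4), sd_prof))
  f2 <- k_from_sd_plateau(profile_from(ns, rep(1, 4), 3 * sd_prof))
  expect_equal(f2$k_sd, f1$k_sd, tolerance = 1e-4)
  expect_equal(f2$sigma1, 3 * f1$sigma1, tolerance = 1e-4)
})

test_that("plateau fit finds the breakpoint under measurement noise", {
  ns <- c(1, 2, 4, 8)
  set.seed(22)
  khat <- replicate(500, {
    y <- 10 * sqrt(pmin(ns, 3)) + stats::rnorm(4, 0, 1)
    k_from_sd_plateau(profile_from(ns, rep(1, 4), pmax(y, 0.5)))$k_sd
  })
  expect_lte(abs(stats::median(khat) - 3), 0.5)
})

test_that("bilinear fits recover noiseless parameters and flag flat profiles", {
  ns <- c(1, 2, 4, 8)
  f <- bilinear_sd(profile_from(ns, rep(1, 4), 5 + 4 * pmin(ns, 3)))
  expect_equal(f$a, 5, tolerance = 1e-3)
  expect_equal(f$b, 4, tolerance = 1e-3)
  expect_equal(f$k, 3, tolerance = 1e-3)
  flat <- bilinear_sd(profile_from(ns, rep(1, 4), rep(20, 4)))
  expect_true(flat$degenerate)
  expect_equal(flat$k, 8)
  expect_lt(abs(flat$b), 1e-6)
  # guessing-based bilinear variant, unit and non-unit slope
  g <- bilinear_npm(profile_from(ns, c(1, 1, 0.75, 0.375), rep(20, 4)))
  expect_equal(g$a, 0, tolerance = 1e-3)
  expect_equal(g$b, 1, tolerance = 1e-3)
  expect_equal(g$k, 3, tolerance = 1e-3)
  pm2 <- (0.2 + 0.6 * pmin(ns, 4)) / ns
  h <- bilinear_npm(profile_from(ns, pm2, rep(20, 4)))
  expect_equal(h$a, 0.2, tolerance = 1e-3)
  expect_equal(h$b, 0.6, tolerance = 1e-3)
  expect_equal(h$k, 4, tolerance = 1e-3)
})

test_that("bilinear breakpoint is recovered under noise", {
  ns <- c(1, 2, 4, 8)
  set.seed(23)
  khat <- replicate(300, {
    y <- 5 + 4 * pmin(ns, 3) + stats::rnorm(4, 0, 0.8)
    bilinear_sd(profile_from(ns, rep(1, 4), pmax(y, 0.5)))$k
  })
  expect_lte(abs(stats::median(khat) - 3), 0.5)
})

test_that("capacity_pair composes the estimators; variants selectable", {
  fits <- data.frame(set_size = c(1, 2, 4, 8),
                     pm = c(1, 1, 0.75, 0.375),
                     sd_deg = 10 * sqrt(pmin(c(1, 2, 4, 8), 3)))
  pair <- capacity_pair(fits)
  expect_equal(pair$k_pm, 3)
  expect_equal(pair$k_sd, 3, tolerance = 1e-4)
  expect_equal(pair$sigma1, 10, tolerance = 1e-4)
  expect_equal(pair$max_set_size, 8)
  pair_b <- capacity_pair(fits, k_pm_method = "bilinear",
                          k_sd_method = "bilinear")
  expect_equal(pair_b$k_pm, 3, tolerance = 1e-3)
  # a bilinear fit to the sqrt profile is exact with a breakpoint where the
  # set-size 1-2 line meets the plateau: (10*sqrt(3) - a) / b with
  # b = 10*(sqrt(2) - 1), a = 10 - b
  b_exact <- 10 * (sqrt(2) - 1)
  k_exact <- (10 * sqrt(3) - (10 - b_exact)) / b_exact
  expect_equal(pair_b$k_sd, k_exact, tolerance = 1e-3)
})

test_that("capacity estimates bracket the truth on simulated slot subjects", {
  set.seed(24)
  n_rep <- 200
  ok_pm <- ok_sd <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- simulate_slot_trials(list(k = 4, sigma1 = 15),
                               set_sizes = c(1, 2, 4, 8), trials = 250)
    pair <- capacity_pairs(fit_all_cells(tr))
    ok_pm[i] <- pair$k_pm >= 3 && pair$k_pm <= 5
    # the plateau estimator's breakpoint spreads above the true capacity on
    # noisy profiles; 7 = next set size below the search bound
    ok_sd[i] <- pair$k_sd >= 2.5 && pair$k_sd <= 7
  }
  expect_gte(mean(ok_pm), 0.9)
  expect_gte(mean(ok_sd), 0.9)
})
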