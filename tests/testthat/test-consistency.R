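make_pairs <- function(k_pm, k_sd, ...) {
  data.frame(k_pm = k_pm, k_sd = k_sd, ...)
}

test_that("equality test keeps its nominal size under the equality null", {
  set.seed(30)
  n_rep <- 500
  p <- replicate(n_rep, {
    k_sd <- stats::rnorm(200, 3.5, 1.2)
    k_pm <- k_sd + stats::rnorm(200, 0, 0.5)
    equality_vs_regression(make_pairs(k_pm, k_sd))$p_equality
  })
  rate <- mean(p <= 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("equality test rejects gross violations and flags degeneracy", {
  set.seed(31)
  k_sd <- stats::runif(50, 1, 6)
  flat <- make_pairs(2 + stats::rnorm(50, 0, 0.1), k_sd)
  expect_lt(equality_vs_regression(flat)$p_equality, 0.001)
  same <- make_pairs(1:10, 1:10)
  res <- equality_vs_regression(same)
  expect_true(res$degenerate)
  expect_error(equality_vs_regression(make_pairs(1:2, 2:1)), "at least 3")
})

test_that("F-test p agrees in ordering with the Gaussian likelihood-ratio p", {
  set.seed(32)
  p_f <- p_lrt <- numeric(20)
  for (i in 1:20) {
    n <- 40
    k_sd <- stats::rnorm(n, 3.5, 1)
    k_pm <- 0.5 + stats::runif(1, 0.5, 1.2) * k_sd + stats::rnorm(n, 0, 0.6)
    pr <- make_pairs(k_pm, k_sd)
    res <- equality_vs_regression(pr)
    p_f[i] <- res$p_equality
    rss0 <- sum((k_pm - k_sd)^2)
    fit <- stats::lm(k_pm ~ k_sd)
    rss1 <- sum(stats::residuals(fit)^2)
    lrt <- n * log(rss0 / rss1)             # sigma profiled out
    p_lrt[i] <- stats::pchisq(lrt, 2, lower.tail = FALSE)
  }
  expect_equal(stats::cor(p_f, p_lrt, method = "spearman"), 1)
})

test_that("equality statistics are invariant to subject order", {
  set.seed(33)
  pr <- make_pairs(stats::rnorm(30, 3.5, 1), stats::rnorm(30, 3.5, 1))
  a <- equality_vs_regression(pr)
  b <- equality_vs_regression(pr[sample.int(30), ])
  expect_equal(a$f_stat, b$f_stat)
  expect_equal(a$delta_bic, b$delta_bic)
})

test_that("pearson_cor matches the closed-form coefficient", {
  x <- c(1.2, 2.1, 2.8, 3.3, 4.0, 4.4, 5.1, 5.9, 6.3, 7.0)
  y <- c(2.0, 1.8, 3.1, 2.9, 4.2, 3.8, 5.5, 5.0, 6.8, 6.1)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_cor(make_pairs(y, x))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(pearson_cor(make_pairs(2 * x + 1, x))$r, 1)
  set.seed(34)
  big <- make_pairs(stats::rnorm(1e4), stats::rnorm(1e4))
  expect_lt(abs(pearson_cor(big)$r), 0.05)
  expect_error(pearson_cor(make_pairs(rep(1, 5), 1:5)), "zero variance")
})

test_that("z-scored pooling undoes between-study mean inflation", {
  set.seed(35)
  n <- 60
  base_x <- stats::rnorm(n)
  base_y <- 0.5 * base_x + sqrt(1 - 0.25) * stats::rnorm(n)
  a <- make_pairs(base_y, base_x, study = "a")
  b <- make_pairs(base_y + 5, base_x + 5, study = "b")
  pooled <- rbind(a, b)
  r_within <- pearson_cor(a)$r
  r_raw <- pooled_analysis(pooled, zscore = FALSE)$r_pearson
  r_z <- pooled_analysis(pooled, zscore = TRUE)$r_pearson
  expect_gt(r_raw, r_within + 0.2)        # Simpson-style inflation
  expect_equal(r_z, r_within, tolerance = 1e-10)
  expect_true(is.na(pooled_analysis(pooled, zscore = TRUE)$p_equality))
  # z-scoring already-standardized data changes nothing
  az <- a
  az$k_pm <- (az$k_pm - mean(az$k_pm)) / stats::sd(az$k_pm)
  az$k_sd <- (az$k_sd - mean(az$k_sd)) / stats::sd(az$k_sd)
  expect_equal(pooled_analysis(az, zscore = TRUE)$r_pearson,
               pearson_cor(az)$r, tolerance = 1e-10)
  # single study: pooled result equals the per-study result
  expect_equal(pooled_analysis(a)$p_equality,
               equality_vs_regression(a)$p_equality)
  # undersized studies are dropped with a warning
  c1 <- make_pairs(1.5, 1.4, study = "c")
  expect_warning(res <- pooled_analysis(rbind(a, c1)), "< 2 subjects")
  expect_equal(res$n, n)
})

test_that("ceiling exclusion removes censored estimates only", {
  pr <- make_pairs(
    k_pm = c(8, 3.9, 4.2, 7.9999999, 5, 2, 3, 6, 4, 1.5),
    k_sd = c(3.2, 3.2, 8.4, 2.0, 4.8, 9, 2.7, 5.5, 3.9, 1.2),
    max_set_size = 8)
  kept <- exclude_at_ceiling(pr)
  # removed: k_pm at 8 (rows 1, 4) and k_sd >= 8 (rows 3, 6)
  expect_equal(nrow(kept), 6)
  expect_true(all(kept$k_pm < 8 - 1e-6))
  expect_true(all(kept$k_sd < 8 - 1e-6))
  expect_true(3.9 %in% kept$k_pm)
})

test_that("fit_quality_check correlates disagreement with fit error", {
  rmse <- seq(0.5, 5, length.out = 20)
  good <- make_pairs(3 + rmse * 0.8, rep(3, 20), rmse_sd_fit = rmse)
  res <- fit_quality_check(good)
  expect_gt(res$r, 0.9)
  set.seed(36)
  indep <- make_pairs(3 + stats::rnorm(200), rep(3, 200),
                      rmse_sd_fit = stats::runif(200, 0.5, 5))
  expect_lt(abs(fit_quality_check(indep)$r), 0.15)
  const <- make_pairs(1:5, 5:1, rmse_sd_fit = rep(1, 5))
  expect_error(fit_quality_check(const), "zero variance")
})

test_that("group_mean_analysis works on subject-averaged profiles", {
  # identical subjects: the study-level pair equals any subject's pair
  ns <- c(1, 2, 4, 8)
  one_subject <- function(subj, study) {
    data.frame(study = study, subject = subj, set_size = ns,
               pm = c(1, 1, 0.75, 0.375),
               sd_deg = 10 * sqrt(pmin(ns, 3)))
  }
  ft <- rbind(one_subject("s1", "A"), one_subject("s2", "A"),
              one_subject("s1", "B"), one_subject("s2", "B"),
              one_subject("s1", "C"), one_subject("s2", "C"))
  res <- group_mean_analysis(ft)
  expect_equal(nrow(res$pairs), 3)
  expect_equal(res$pairs$k_pm, rep(3, 3))
  expect_equal(res$pairs$k_sd, rep(3, 3), tolerance = 1e-4)
  expect_error(group_mean_analysis(ft[ft$study != "C", ]), "3 studies")
})

test_that("study-level equality holds under the slot generative model", {
  set.seed(37)
  ok <- logical(5)
  for (r in 1:5) {
    # eight studies with heterogeneous populations, as in a multi-study
    # comparison; between-study spread anchors the regression
    ft <- do.call(rbind, lapply(1:8, function(st) {
      cfg <- sim_config(n_subjects = 8, trials_per_set_size = 150,
                        mean_k = stats::runif(1, 2.5, 5),
                        mean_sigma1 = stats::runif(1, 12, 22))
      params <- sample_population(cfg)
      f <- fit_all_cells(simulate_experiment(params, cfg))
      f$study <- paste0("S", st)
      f$subject <- paste(f$study, f$subject)
      f
    }))
    ok[r] <- group_mean_analysis(ft)$result$p_equality > 0.05
  }
  expect_gte(sum(ok), 3)
})
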