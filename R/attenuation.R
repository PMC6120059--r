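# Spearman's correction for attenuation, with reliabilities of the two
# capacity estimates obtained by double bootstrap resampling of trials.

#' Correct a correlation for attenuation by measurement error
#'
#' `r' = r_xy / sqrt(r_xx * r_yy)`. If the two observed variables are noisy
#' measurements of latent quantities, the corrected value estimates the
#' latent correlation; it is never smaller in magnitude than the raw
#' correlation when reliabilities are at most 1. Results exceeding `[-1, 1]`
#' are clipped and flagged.
#'
#' @param r_xy Observed correlation.
#' @param r_xx,r_yy Reliabilities of the two measurements, `> 0`.
#' @return List with `r_corrected` and `clipped` flag.
#' @export
correct_attenuation <- function(r_xy, r_xx, r_yy) {
  stopifnot(is.finite(r_xy), is.finite(r_xx), is.finite(r_yy))
  if (r_xx <= 0 || r_yy <= 0) {
    stop("correct_attenuation(): reliabilities must be > 0", call. = FALSE)
  }
  r <- r_xy / sqrt(r_xx * r_yy)
  clipped <- FALSE
  if (abs(r) > 1) {
    r <- sign(r)
    clipped <- TRUE
  }
  list(r_corrected = r, clipped = clipped)
}

#' Bootstrap reliability of a capacity estimator
#'
#' For each bootstrap repetition, every subject's trials are resampled with
#' replacement twice, independently, stratified within set size (each cell
#' resampled to its own trial count, so every profile keeps all set sizes);
#' the estimator is applied to both resamples, giving two parallel measures
#' per subject. The correlation across subjects between the two measures is
#' one reliability draw, and the reported reliability is the mean over
#' repetitions. Repetitions with undefined correlations are dropped and
#' counted.
#'
#' @param trials Trial table (radians; columns `subject`, `set_size`,
#'   `target`, `response`).
#' @param estimator `"k_pm"`, `"k_sd"`, or a function
#'   `f(trials_one_subject)` returning a scalar (useful for test doubles).
#' @param n_reps Number of bootstrap repetitions (default 100).
#' @param control [em_control()] passed to the mixture fits.
#' @return List of class `reliability_estimate`: `reliability`, `per_rep`
#'   (valid per-rep correlations), `n_reps`, `n_dropped`, `estimator`.
#' @export
bootstrap_reliability <- function(trials, estimator = c("k_pm", "k_sd"),
                                  n_reps = 100, control = em_control()) {
  if (is.function(estimator)) {
    est_fun <- estimator
    est_name <- "custom"
  } else {
    est_name <- match.arg(estimator)
    est_fun <- function(tr) {
      fits <- fit_all_cells(tr, control = control)
      pair <- capacity_pair(fits)
      if (est_name == "k_pm") pair$k_pm else pair$k_sd
    }
  }
  subjects <- unique(trials$subject)
  by_subj <- split(seq_len(nrow(trials)), trials$subject)
  per_rep <- rep(NA_real_, n_reps)
  for (rep_i in seq_len(n_reps)) {
    est1 <- numeric(length(subjects))
    est2 <- numeric(length(subjects))
    for (si in seq_along(subjects)) {
      idx <- by_subj[[as.character(subjects[si])]]
      tr <- trials[idx, , drop = FALSE]
      cells <- split(seq_len(nrow(tr)), tr$set_size)
      resample <- function() {
        pick <- unlist(lapply(cells, function(ci) {
          ci[sample.int(length(ci), length(ci), replace = TRUE)]
        }), use.names = FALSE)
        tr[pick, , drop = FALSE]
      }
      est1[si] <- est_fun(resample())
      est2[si] <- est_fun(resample())
    }
    if (stats::sd(est1) > 0 && stats::sd(est2) > 0) {
      per_rep[rep_i] <- stats::cor(est1, est2)
    }
  }
  dropped <- sum(is.na(per_rep))
  if (dropped > 0) {
    warning(sprintf("bootstrap_reliability(): %d of %d repetitions had undefined correlations and were dropped",
                    dropped, n_reps))
  }
  valid <- per_rep[!is.na(per_rep)]
  structure(list(reliability = mean(valid), per_rep = valid,
                 n_reps = n_reps, n_dropped = dropped,
                 estimator = est_name),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("bootstrap reliability of %s: %.3f (%d reps, %d dropped)\n",
              x$estimator, x$reliability, x$n_reps, x$n_dropped))
  invisible(x)
}
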