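# Two-component circular mixture model: von Mises recall (probability Pm,
# width SD) plus uniform guessing. Maximum-likelihood fits by EM with a small
# grid of restarts, per subject per set size.

#' @keywords internal
MIN_TRIALS <- 10

#' EM fitting options
#'
#' @param restarts_pm Initial values for the memory probability `Pm`.
#' @param restarts_sd_deg Initial values for the recall SD, degrees.
#' @param tol Absolute log-likelihood convergence tolerance per iteration.
#' @param max_iter Maximum EM iterations per restart.
#' @return List of class `em_control`.
#' @export
em_control <- function(restarts_pm = c(0.3, 0.6, 0.9),
                       restarts_sd_deg = c(10, 30, 60),
                       tol = 1e-6, max_iter = 500L) {
  stopifnot(all(restarts_pm > 0 & restarts_pm < 1), all(restarts_sd_deg > 0),
            tol > 0, max_iter >= 1)
  structure(list(restarts_pm = restarts_pm,
                 restarts_sd_deg = restarts_sd_deg,
                 tol = tol, max_iter = max_iter),
            class = "em_control")
}

#' Fit the von Mises + uniform mixture to response errors
#'
#' Expectation-maximization fit of the two-component mixture
#' `p(e) = Pm * vm(e; kappa) + (1 - Pm) / (2 * pi)` to a vector of wrapped
#' response errors, restarted from a grid of initial values; the restart with
#' the highest log-likelihood is returned.
#'
#' @param errors Response errors `wrap(report - target)` in radians.
#' @param control An [em_control()] list.
#' @param keep_trace Keep the per-iteration log-likelihood of the best
#'   restart (attribute `"trace"`)?
#' @return An object of class `mixture_fit`: list with `pm`, `sd` (radians),
#'   `sd_deg`, `kappa`, `loglik`, `n_trials`, `converged`,
#'   `n_restarts_agreeing` (restarts within 1e-4 of the best log-likelihood).
#' @export
em_fit <- function(errors, control = em_control(), keep_trace = FALSE) {
  if (!is.numeric(errors) || any(!is.finite(errors))) {
    stop("em_fit(): errors must be finite numeric radians", call. = FALSE)
  }
  n <- length(errors)
  if (n < MIN_TRIALS) {
    stop(sprintf("em_fit(): need at least %d trials, got %d", MIN_TRIALS, n),
         call. = FALSE)
  }
  e <- wrap_angle(errors)
  cos_e <- cos(e)
  kappas0 <- sd_to_kappa(deg2rad(control$restarts_sd_deg))
  best <- .em_fit_cpp(cos_e, control$restarts_pm, kappas0,
                      control$tol, control$max_iter, keep_trace)
  # a von Mises this flat is indistinguishable from the uniform component
  # (the likelihood is a ridge in pm); report the boundary pure-guessing fit
  if (best$kappa < 0.15) {
    best$pm <- 0
    best$kappa <- 0
    best$loglik <- n * log(1 / (2 * pi))
    best$converged <- TRUE
  }
  sd_rad <- kappa_to_sd(best$kappa)
  out <- structure(
    list(pm = best$pm, sd = sd_rad, sd_deg = rad2deg(sd_rad),
         kappa = best$kappa, loglik = best$loglik, n_trials = n,
         converged = best$converged,
         n_restarts_agreeing = sum(best$lls >= best$loglik - 1e-4)),
    class = "mixture_fit")
  if (keep_trace) attr(out, "trace") <- best$trace
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "von Mises + uniform mixture fit (n = %d)\n  Pm = %.3f, SD = %.2f deg (kappa = %.3f)\n  logLik = %.3f, converged = %s, %d restarts agree\n",
    x$n_trials, x$pm, x$sd_deg, x$kappa, x$loglik, x$converged,
    x$n_restarts_agreeing))
  invisible(x)
}

#' Mixture log-likelihood at fixed parameters
#'
#' @param errors Wrapped errors, radians.
#' @param pm Memory probability.
#' @param kappa von Mises concentration.
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(errors, pm, kappa) {
  f <- vm_pdf(errors, kappa)
  sum(log(pm * f + (1 - pm) / (2 * pi)))
}

#' Fit the mixture for one subject at one set size
#'
#' Selects the trials of one `(subject, set_size)` cell from a trial table,
#' forms the wrapped response errors and delegates to [em_fit()].
#'
#' @param trials A trial table (see [read_trials()]): columns `subject`,
#'   `set_size`, `target`, `response` in radians on the full circle.
#' @param subject,set_size Cell selector.
#' @param control An [em_control()] list.
#' @return A `mixture_fit`.
#' @export
fit_subject <- function(trials, subject, set_size, control = em_control()) {
  sel <- trials$subject == subject & trials$set_size == set_size
  if (!any(sel)) {
    stop(sprintf("fit_subject(): no trials for cell (subject = %s, set_size = %s)",
                 subject, set_size), call. = FALSE)
  }
  e <- wrap_angle(trials$response[sel] - trials$target[sel])
  em_fit(e, control = control)
}

#' Fit the mixture in every subject-by-set-size cell
#'
#' @param trials Trial table with radian `target`/`response` columns.
#' @param control An [em_control()] list.
#' @return Data frame with one row per cell: `subject`, `set_size`, `pm`,
#'   `sd_deg`, `kappa`, `loglik`, `n`, `converged`. If the trial table has a
#'   `study` column it is carried through.
#' @export
fit_all_cells <- function(trials, control = em_control()) {
  has_study <- "study" %in% names(trials)
  key <- if (has_study) {
    interaction(trials$study, trials$subject, trials$set_size, drop = TRUE)
  } else {
    interaction(trials$subject, trials$set_size, drop = TRUE)
  }
  cells <- split(seq_len(nrow(trials)), key)
  rows <- lapply(cells, function(idx) {
    e <- wrap_angle(trials$response[idx] - trials$target[idx])
    fit <- em_fit(e, control = control)
    data.frame(
      study = if (has_study) trials$study[idx[1]] else NA_character_,
      subject = trials$subject[idx[1]],
      set_size = trials$set_size[idx[1]],
      pm = fit$pm, sd_deg = fit$sd_deg, kappa = fit$kappa,
      loglik = fit$loglik, n = fit$n_trials, converged = fit$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$study, out$subject, out$set_size), , drop = FALSE]
  if (!has_study) out$study <- NULL
  rownames(out) <- NULL
  out
}
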