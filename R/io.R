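# Trial-table I/O and the end-to-end pipeline. Files hold degrees; all
# internal computation is in radians on the full circle. Orientation
# (180-degree periodic) data are doubled onto the full circle at read and
# fitted SDs halved at report.

#' Read a trial table from a delimited text file
#'
#' Expects a header with (configurably named) columns for subject, set size,
#' target and response, plus optionally study and feature space. Angles are
#' degrees in the file; `orientation180` rows are doubled onto the full
#' circle. The returned table is in radians and carries the doubling
#' provenance as the `halve_sd` attribute (`TRUE` when reported SDs must be
#' halved).
#'
#' @param path Path to a CSV/TSV file.
#' @param columns Named mapping from the canonical names (`subject`,
#'   `set_size`, `target`, `response`, and optionally `study`,
#'   `feature_space`) to the file's column names.
#' @param feature_space Default feature space when the file has no such
#'   column: `"circular360"` or `"orientation180"`.
#' @param sep Field separator (`","` default; `"\t"` for TSV).
#' @return Data frame of class `trial_table` with columns `study` (if
#'   present), `subject`, `set_size`, `target`, `response` (radians,
#'   wrapped), `feature_space`.
#' @export
read_trials <- function(path,
                        columns = c(subject = "subject", set_size = "set_size",
                                    target = "target", response = "response"),
                        feature_space = c("circular360", "orientation180"),
                        sep = ",") {
  feature_space <- match.arg(feature_space)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("subject", "set_size", "target", "response")
  missing_map <- setdiff(required, names(columns))
  if (length(missing_map) > 0) {
    stop("read_trials(): column mapping must name ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  missing_col <- columns[!columns %in% names(raw)]
  if (length(missing_col) > 0) {
    stop("read_trials(): file lacks column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    subject = raw[[columns[["subject"]]]],
    set_size = raw[[columns[["set_size"]]]],
    target = raw[[columns[["target"]]]],
    response = raw[[columns[["response"]]]],
    stringsAsFactors = FALSE)
  if ("study" %in% names(columns) && columns[["study"]] %in% names(raw)) {
    out$study <- raw[[columns[["study"]]]]
  }
  fs <- if ("feature_space" %in% names(columns) &&
            columns[["feature_space"]] %in% names(raw)) {
    raw[[columns[["feature_space"]]]]
  } else {
    rep(feature_space, nrow(out))
  }
  bad_fs <- !fs %in% c("circular360", "orientation180")
  if (any(bad_fs)) {
    stop("read_trials(): unknown feature space in row(s) ",
         paste(utils::head(which(bad_fs), 5), collapse = ", "), call. = FALSE)
  }
  if (any(out$set_size < 1 | out$set_size != round(out$set_size))) {
    bad <- which(out$set_size < 1 | out$set_size != round(out$set_size))
    stop("read_trials(): non-positive-integer set size in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  period <- ifelse(fs == "orientation180", 180, 360)
  bad_ang <- !is.finite(out$target) | !is.finite(out$response) |
    abs(out$target) > period | abs(out$response) > period
  if (any(bad_ang)) {
    stop("read_trials(): missing or out-of-range angle in row(s) ",
         paste(utils::head(which(bad_ang), 5), collapse = ", "), call. = FALSE)
  }
  scale <- ifelse(fs == "orientation180", 2, 1)   # double onto full circle
  out$target <- wrap_angle(deg2rad(out$target * scale))
  out$response <- wrap_angle(deg2rad(out$response * scale))
  out$feature_space <- fs
  attr(out, "halve_sd") <- any(fs == "orientation180")
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write a trial table back to CSV
#'
#' Inverse of [read_trials()]: radians are converted to degrees and
#' orientation rows halved back onto their native 180-degree space. Row
#' order and fields are preserved.
#'
#' @param trials A `trial_table` from [read_trials()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  fs <- if ("feature_space" %in% names(trials)) trials$feature_space
        else rep("circular360", nrow(trials))
  scale <- ifelse(fs == "orientation180", 2, 1)
  out <- as.data.frame(trials)
  out$target <- rad2deg(wrap_angle(out$target)) / scale
  out$response <- rad2deg(wrap_angle(out$response)) / scale
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' @param k_pm_method,k_sd_method Capacity estimator variants, see
#'   [capacity_pair()].
#' @param exclude_ceiling Also report results with ceiling-level subjects
#'   excluded?
#' @param bootstrap_reps Bootstrap repetitions for the attenuation stage
#'   (`0` disables the stage).
#' @param hierarchical Run the hierarchical stage?
#' @param mcmc Settings list for [fit_hierarchical()].
#' @param sim A [sim_config()] used when no trial data are supplied.
#' @param seed Master seed for the run.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @return List of class `run_config`.
#' @export
run_config <- function(k_pm_method = "max_npm", k_sd_method = "plateau",
                       exclude_ceiling = TRUE, bootstrap_reps = 0,
                       hierarchical = FALSE,
                       mcmc = list(n_chains = 4, n_adapt = 500,
                                   n_burn = 500, n_iter = 1000),
                       sim = NULL, seed = 1L, out_dir = NULL) {
  stopifnot(k_pm_method %in% c("max_npm", "bilinear"),
            k_sd_method %in% c("plateau", "bilinear"),
            bootstrap_reps >= 0)
  structure(list(k_pm_method = k_pm_method, k_sd_method = k_sd_method,
                 exclude_ceiling = exclude_ceiling,
                 bootstrap_reps = bootstrap_reps,
                 hierarchical = hierarchical, mcmc = mcmc, sim = sim,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(obj, name, out_dir, stamp) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (inherits(obj, "data.frame")) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    df <- cbind(obj, config_hash = stamp$hash, seed = stamp$seed)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    path <- file.path(out_dir, paste0(name, ".json"))
    payload <- c(unclass(obj), list(config_hash = stamp$hash, seed = stamp$seed))
    payload <- payload[!vapply(payload, inherits, logical(1), "data.frame")]
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(NULL)
}

#' Run the full self-consistency pipeline
#'
#' Mixture fits per subject and set size, capacity pairs, consistency tests
#' (per study when a study column is present, pooled raw, pooled z-scored,
#' and with ceiling-level subjects excluded), and optionally the attenuation
#' and hierarchical stages. With `trials = NULL`, an experiment is simulated
#' from `config$sim` first. All artifacts are written to `config$out_dir`
#' (CSV/JSON), each stamped with the seed and an MD5 hash of the
#' configuration; a run log records stage order, cell counts and drops.
#'
#' @param config A [run_config()].
#' @param trials Optional `trial_table` (radians). If `NULL`, `config$sim`
#'   must be set.
#' @return List of class `pipeline_result`: `fits`, `pairs`, `consistency`
#'   (list of `consistency_result`s), optional `reliability` and
#'   `hierarchical`, plus `log`.
#' @export
run_pipeline <- function(config, trials = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  stamp <- list(hash = unname(tools::md5sum(tf)), seed = config$seed)
  unlink(tf)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(as.character(cfg_json), file.path(config$out_dir, "config.json"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(trials)) {
    if (is.null(config$sim)) stop("run_pipeline(): no trials and no sim config",
                                  call. = FALSE)
    trials <- stage("simulate", {
      params <- sample_population(config$sim)
      tr <- simulate_experiment(params, config$sim)
      say("simulate: %d subjects, %d trials", nrow(params), nrow(tr))
      tr
    })
  }
  fits <- stage("fit", {
    f <- fit_all_cells(trials)
    say("fit: %d cells (%d unconverged)", nrow(f), sum(!f$converged))
    f
  })
  write_stage(fits, "mixture_fits", config$out_dir, stamp)
  pairs <- stage("capacity", {
    p <- capacity_pairs(fits, k_pm_method = config$k_pm_method,
                        k_sd_method = config$k_sd_method)
    say("capacity: %d subjects", nrow(p))
    p
  })
  write_stage(pairs, "capacity_pairs", config$out_dir, stamp)
  consistency <- stage("consistency", {
    res <- list(overall = equality_vs_regression(pairs))
    if ("study" %in% names(pairs) && length(unique(pairs$study)) >= 2) {
      res$pooled_raw <- pooled_analysis(pairs, zscore = FALSE)
      res$pooled_z <- pooled_analysis(pairs, zscore = TRUE)
      for (s in unique(pairs$study)) {
        sub <- pairs[pairs$study == s, , drop = FALSE]
        if (nrow(sub) >= 3) {
          res[[paste0("study_", s)]] <- equality_vs_regression(sub)
        }
      }
    }
    if (config$exclude_ceiling) {
      kept <- exclude_at_ceiling(pairs)
      say("ceiling exclusion: %d of %d retained", nrow(kept), nrow(pairs))
      if (nrow(kept) >= 3) res$ceiling_excluded <- equality_vs_regression(kept)
    }
    say("consistency: overall p = %.4g, r = %.3f",
        res$overall$p_equality, res$overall$r_pearson)
    res
  })
  for (nm in names(consistency)) {
    write_stage(consistency[[nm]], paste0("consistency_", nm),
                config$out_dir, stamp)
  }
  out <- list(fits = fits, pairs = pairs, consistency = consistency)
  if (config$bootstrap_reps > 0) {
    out$reliability <- stage("attenuation", {
      rel_pm <- bootstrap_reliability(trials, "k_pm", n_reps = config$bootstrap_reps)
      rel_sd <- bootstrap_reliability(trials, "k_sd", n_reps = config$bootstrap_reps)
      corr <- correct_attenuation(consistency$overall$r_pearson,
                                  rel_pm$reliability, rel_sd$reliability)
      say("attenuation: r_xx = %.3f, r_yy = %.3f, corrected r = %.3f",
          rel_pm$reliability, rel_sd$reliability, corr$r_corrected)
      list(r_xx = rel_pm$reliability, r_yy = rel_sd$reliability,
           n_reps = config$bootstrap_reps,
           r_raw = consistency$overall$r_pearson,
           r_corrected = corr$r_corrected, clipped = corr$clipped)
    })
    write_stage(out$reliability, "attenuation", config$out_dir, stamp)
  }
  if (isTRUE(config$hierarchical)) {
    out$hierarchical <- stage("hierarchical", {
      hf <- fit_hierarchical(hier_data_from_fits(fits),
                             n_chains = config$mcmc$n_chains,
                             n_adapt = config$mcmc$n_adapt,
                             n_burn = config$mcmc$n_burn,
                             n_iter = config$mcmc$n_iter,
                             seed = config$seed)
      say("hierarchical: posterior mean rho = %.3f%s",
          hf$summary$mean[hf$summary$param == "rho"],
          if (hf$converged) "" else " (convergence warning)")
      hf
    })
    write_stage(out$hierarchical$summary, "hierarchical_summary",
                config$out_dir, stamp)
    if (!is.null(config$out_dir)) {
      utils::write.csv(as.data.frame(out$hierarchical$draws),
                       file.path(config$out_dir, "hierarchical_draws.csv"),
                       row.names = FALSE)
    }
  }
  out$log <- log_lines
  if (!is.null(config$out_dir)) {
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("self-consistency pipeline result\n")
  cat(sprintf("  %d cells fitted, %d subjects\n", nrow(x$fits), nrow(x$pairs)))
  print(x$consistency$overall)
  invisible(x)
}
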