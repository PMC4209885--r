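#' Configuration of a full comparative study
#'
#' Bundles every parameter of the comparative benchmark with the
#' pipeline's standard values as defaults: 10 subjects, 50 Hz, two phases
#' at 80% and 15% MVC with 5 repetitions each, per-stream preprocessing
#' (1 Hz low-pass for sEMG, 0.5 Hz high-pass for FSR), `lambda = 1`,
#' `D = 300`, bandwidth by grid search.
#'
#' @param n_subjects cohort size.
#' @param master_seed master seed; all outputs are deterministic functions
#'   of the configuration and this seed.
#' @param hmis named list of [sensor_config()]s, or a character vector of
#'   stream names expanded through [default_sensor_config()] (`fsr2` takes
#'   the `fsr` defaults).
#' @param phases named numeric vector of phase force levels.
#' @param n_repetitions repetitions per phase.
#' @param sample_rate acquisition rate, Hz.
#' @param segment_durations trapezoid timing passed to [make_protocol()].
#' @param lambda ridge coefficient.
#' @param D number of random Fourier features.
#' @param sigma fixed RFF bandwidth, or `NULL` for grid search.
#' @param sigma_grid_size grid size for the bandwidth search.
#' @param scenarios subset of `c("accuracy", "stability")`.
#' @param gt_modes training ground-truth modes for the accuracy scenario.
#' @param stability_hmis streams entering the stability scenario.
#' @param drift logical; use each stream's default drift model.
#' @param log_level "debug", "info", "warn" or "error".
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_subjects = 10L,
                         master_seed = 1L,
                         hmis = c("semg", "fsr", "fsr2", "us_features"),
                         phases = c(high = 0.80, low = 0.15),
                         n_repetitions = 5L,
                         sample_rate = 50,
                         segment_durations = c(rest = 2, ramp_up = 1,
                                               plateau = 3, ramp_down = 1,
                                               rest_post = 2),
                         lambda = 1,
                         D = 300L,
                         sigma = NULL,
                         sigma_grid_size = 5L,
                         scenarios = c("accuracy", "stability"),
                         gt_modes = c("force", "stimulus"),
                         stability_hmis = c("semg", "fsr"),
                         drift = TRUE,
                         log_level = "info") {
  if (is.character(hmis)) {
    hmis <- lapply(stats::setNames(hmis, hmis), function(nm) {
      default_sensor_config(if (nm == "fsr2") "fsr" else nm, drift = drift)
    })
  }
  bad <- setdiff(names(hmis), c("semg", "fsr", "fsr2", "us_features"))
  if (length(bad)) stop("Unknown HMI(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  gt_modes <- match.arg(gt_modes, c("force", "stimulus"), several.ok = TRUE)
  structure(list(n_subjects = as.integer(n_subjects),
                 master_seed = master_seed, hmis = hmis, phases = phases,
                 n_repetitions = as.integer(n_repetitions),
                 sample_rate = sample_rate,
                 segment_durations = segment_durations,
                 lambda = lambda, D = as.integer(D), sigma = sigma,
                 sigma_grid_size = as.integer(sigma_grid_size),
                 scenarios = scenarios, gt_modes = gt_modes,
                 stability_hmis = intersect(stability_hmis, names(hmis)),
                 drift = drift, log_level = log_level),
            class = "study_config")
}

.log_levels <- c(debug = 1, info = 2, warn = 3, error = 4)

hmib_log <- function(threshold, level, ..., file = NULL) {
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible())
  msg <- sprintf("[%s] %s", toupper(level), paste0(...))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible()
}

.model_config_for <- function(config, hmi) {
  if (hmi == "us_features") {
    list(feature_map = "identity", lambda = config$lambda)
  } else {
    list(feature_map = "rff", lambda = config$lambda, D = config$D,
         sigma = config$sigma,
         sigma_grid = NULL, sigma_grid_size = config$sigma_grid_size)
  }
}

#' Run the full comparative study
#'
#' For every subject, phase and interface: simulates the session,
#' preprocesses each stream with its standard filter, runs the
#' repetition-wise cross-validated accuracy evaluation (for each requested
#' ground-truth mode) and the train-on-first-repetition stability
#' evaluation, and writes tidy CSV results, a JSON summary (means plus
#' standard error of the mean across subjects) and a run manifest with
#' content hashes. A failing subject-interface combination is logged and
#' skipped; the returned report records it.
#'
#' @param config a [study_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return (invisibly) the study report: `accuracy` and `stability` tidy
#'   data.frames, `summary`, `failures`, `config`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_file <- file.path(out_dir, "study.log")
    if (file.exists(log_file)) file.remove(log_file)
  }
  lg <- function(level, ...) hmib_log(config$log_level, level, ...,
                                      file = log_file)
  acc_rows <- list(); stab_rows <- list(); failures <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- sample_subject(derive_seed(config$master_seed, "subject", s))
    for (ph in names(config$phases)) {
      protocol <- make_protocol(config$phases[[ph]],
                                n_repetitions = config$n_repetitions,
                                sample_rate = config$sample_rate,
                                segment_durations = config$segment_durations)
      session <- simulate_session(protocol, subject, streams = config$hmis,
                                  seed = config$master_seed, phase = ph,
                                  subject_id = s)
      for (hmi in names(config$hmis)) {
        res <- tryCatch({
          mc <- .model_config_for(config, hmi)
          eval_seed <- derive_seed(config$master_seed, "eval", s, ph, hmi)
          out <- list()
          if ("accuracy" %in% config$scenarios) {
            for (gt in config$gt_modes) {
              cv <- crossval_repetitionwise(session, hmi, gt,
                                            model_config = mc,
                                            k = config$n_repetitions,
                                            seed = derive_seed(eval_seed, gt))
              out$acc[[gt]] <- cbind(subject = s, hmi = hmi, phase = ph,
                                     gt = gt, cv$per_fold)
            }
          }
          if ("stability" %in% config$scenarios &&
              hmi %in% config$stability_hmis) {
            st <- stability_eval(session, hmi, model_config = mc,
                                 seed = derive_seed(eval_seed, "stability"))
            out$stab <- list(
              rows = cbind(subject = s, hmi = hmi, phase = ph,
                           st$per_repetition),
              slope = data.frame(subject = s, hmi = hmi, phase = ph,
                                 slope = st$slope))
          }
          out
        }, error = function(e) e)
        if (inherits(res, "error")) {
          lg("warn", sprintf("subject %d / %s / %s failed: %s", s, ph, hmi,
                             conditionMessage(res)))
          failures[[length(failures) + 1L]] <-
            data.frame(subject = s, phase = ph, hmi = hmi,
                       error = conditionMessage(res))
        } else {
          acc_rows <- c(acc_rows, res$acc)
          if (!is.null(res$stab)) stab_rows <- c(stab_rows, list(res$stab))
          lg("debug", sprintf("subject %d / %s / %s done", s, ph, hmi))
        }
      }
      lg("info", sprintf("subject %d phase %s done", s, ph))
    }
  }
  accuracy <- if (length(acc_rows)) do.call(rbind, acc_rows) else NULL
  stability <- if (length(stab_rows)) {
    do.call(rbind, lapply(stab_rows, `[[`, "rows"))
  } else NULL
  slopes <- if (length(stab_rows)) {
    do.call(rbind, lapply(stab_rows, `[[`, "slope"))
  } else NULL
  report <- list(accuracy = accuracy, stability = stability, slopes = slopes,
                 summary = .summarize_study(accuracy, slopes),
                 failures = if (length(failures)) do.call(rbind, failures) else NULL,
                 config = config)
  if (!is.null(out_dir)) .write_report(report, out_dir, lg)
  if (length(failures)) lg("warn", sprintf("%d combination(s) failed",
                                           length(failures)))
  invisible(report)
}

# means +/- standard error of the mean across subjects, the convention of
# the accuracy/stability figures
.summarize_study <- function(accuracy, slopes) {
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  out <- list(note = "t-tests in compare_hmis() are unadjusted two-tailed paired")
  if (!is.null(accuracy)) {
    per_subject <- stats::aggregate(nrmse ~ subject + hmi + phase + gt,
                                    accuracy, mean)
    agg <- stats::aggregate(nrmse ~ hmi + phase + gt, per_subject,
                            function(v) c(mean = mean(v), sem = sem(v),
                                          n = length(v)))
    out$accuracy <- do.call(data.frame,
                            c(agg[c("hmi", "phase", "gt")],
                              list(mean_nrmse = agg$nrmse[, "mean"],
                                   sem = agg$nrmse[, "sem"],
                                   n_subjects = agg$nrmse[, "n"])))
  }
  if (!is.null(slopes)) {
    agg <- stats::aggregate(slope ~ hmi + phase, slopes,
                            function(v) c(mean = mean(v), sem = sem(v),
                                          n = length(v)))
    out$stability_slopes <- do.call(data.frame,
                                    c(agg[c("hmi", "phase")],
                                      list(mean_slope = agg$slope[, "mean"],
                                           sem = agg$slope[, "sem"],
                                           n_subjects = agg$slope[, "n"])))
  }
  out
}

.write_report <- function(report, out_dir, lg) {
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(out_dir, name)
    data.table::fwrite(df, path)
    files <<- c(files, path)
  }
  wr(report$accuracy, "accuracy.csv")
  wr(report$stability, "stability.csv")
  wr(report$slopes, "stability_slopes.csv")
  wr(report$failures, "failures.csv")
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(report$summary, summary_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  files <- c(files, summary_path)
  cfg <- report$config
  cfg_flat <- list(n_subjects = cfg$n_subjects, master_seed = cfg$master_seed,
                   hmis = names(cfg$hmis), phases = as.list(cfg$phases),
                   n_repetitions = cfg$n_repetitions,
                   sample_rate = cfg$sample_rate,
                   segment_durations = as.list(cfg$segment_durations),
                   lambda = cfg$lambda, D = cfg$D, sigma = cfg$sigma,
                   scenarios = cfg$scenarios, gt_modes = cfg$gt_modes,
                   stability_hmis = cfg$stability_hmis, drift = cfg$drift)
  manifest <- list(
    config = cfg_flat,
    config_hash = unname(.hash_obj(cfg_flat)),
    r_version = R.version.string,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lg("info", sprintf("wrote %d result file(s) to %s", length(files), out_dir))
}

.hash_obj <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  tools::md5sum(tmp)
}

#' Pairwise comparison of interfaces across subjects
#'
#' Per phase, ground-truth mode and DOF: a two-tailed paired t-test of the
#' per-subject mean nRMSE between every pair of interfaces. P-values are
#' reported unadjusted for multiple testing (flagged in the output
#' attributes); significance is marked at 0.05.
#'
#' @param report a [run_study()] report, or its tidy `accuracy`
#'   data.frame.
#' @param by_dof if `FALSE`, compare per-subject means pooled over DOFs.
#' @return data.frame with columns `hmi_a`, `hmi_b`, `phase`, `gt`, `dof`,
#'   `t`, `p`, `significant`, `n_subjects`; attribute
#'   `p_adjustment = "none"`.
#' @export
compare_hmis <- function(report, by_dof = TRUE) {
  acc <- if (is.data.frame(report)) report else report$accuracy
  if (is.null(acc)) stop("No accuracy results to compare.", call. = FALSE)
  if (length(unique(acc$subject)) < 2) {
    stop("Paired comparison needs at least 2 subjects.", call. = FALSE)
  }
  fml <- if (by_dof) nrmse ~ subject + hmi + phase + gt + dof else
    nrmse ~ subject + hmi + phase + gt
  per_subject <- stats::aggregate(fml, acc, mean)
  if (!by_dof) per_subject$dof <- "all"
  hmis <- sort(unique(per_subject$hmi))
  if (length(hmis) < 2) stop("Need at least 2 HMIs to compare.", call. = FALSE)
  cells <- unique(per_subject[c("phase", "gt", "dof")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- merge(per_subject, cell)
    for (a_i in seq_along(hmis)) for (b_i in seq_along(hmis)) {
      if (a_i >= b_i) next
      a <- sub[sub$hmi == hmis[a_i], ]
      b <- sub[sub$hmi == hmis[b_i], ]
      m <- merge(a[c("subject", "nrmse")], b[c("subject", "nrmse")],
                 by = "subject", suffixes = c("_a", "_b"))
      if (nrow(m) < 2) next
      d <- m$nrmse_a - m$nrmse_b
      if (all(abs(d) < .Machine$double.eps * 100)) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- t.test(m$nrmse_a, m$nrmse_b, paired = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hmi_a = hmis[a_i], hmi_b = hmis[b_i],
        phase = cell$phase, gt = cell$gt, dof = cell$dof,
        t = unname(tt$statistic), p = tt$p.value,
        significant = tt$p.value < 0.05, n_subjects = nrow(m))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "p_adjustment") <- "none"
  attr(out, "test") <- "two-tailed paired t-test on per-subject mean nRMSE"
  out
}
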