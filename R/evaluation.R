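#' Build a realistic-scenario training set from a session
#'
#' The realistic protocol trains only on what an amputee could provide:
#' samples at minimal force (rest: the stimulus is exactly zero on every
#' DOF) and at maximal force (the central 80% of each plateau, avoiding the
#' ramp transients and filter settling at the plateau edges). Targets come
#' either from the measured forces or from the MVC-scaled stimulus — the
#' harder, sensor-free ground-truth choice.
#'
#' @param session a [simulate_session()] recording.
#' @param hmi stream name in `session$streams`.
#' @param gt ground-truth source for the targets: "force" or "stimulus".
#' @param repetitions repetition ids to draw samples from.
#' @param X optional pre-filtered stream matrix (e.g. from
#'   [preprocess_stream()]); default preprocesses `hmi` with the stream's
#'   standard filter.
#' @param plateau_central fraction of each plateau kept, centred (default
#'   0.8).
#' @return an object of class `training_set`: `X`, `Y` (N), `mask` (sample
#'   indices into the session), `gt`, `repetitions`.
#' @export
build_realistic_training_set <- function(session, hmi,
                                         gt = c("force", "stimulus"),
                                         repetitions,
                                         X = NULL,
                                         plateau_central = 0.8) {
  gt <- match.arg(gt)
  if (is.null(X)) X <- preprocess_stream(session, hmi)
  if (!all(repetitions %in% unique(session$repetition_id))) {
    stop("Requested repetitions are not all present in the session.",
         call. = FALSE)
  }
  in_rep <- session$repetition_id %in% repetitions
  rest <- session$segment == "rest"
  lo <- (1 - plateau_central) / 2
  plateau_core <- session$segment == "plateau" &
    !is.na(session$plateau_pos) &
    session$plateau_pos >= lo & session$plateau_pos <= 1 - lo
  mask <- which(in_rep & (rest | plateau_core))
  if (length(mask) == 0) {
    stop("Realistic selection produced an empty training set.", call. = FALSE)
  }
  Y <- if (gt == "force") session$forces else session$stimulus
  structure(list(X = X[mask, , drop = FALSE],
                 Y = Y[mask, , drop = FALSE],
                 mask = mask, gt = gt,
                 repetitions = sort(unique(repetitions))),
            class = "training_set")
}

#' Normalized root-mean-squared error per DOF
#'
#' `sqrt(mean((pred - truth)^2)) / (max(truth) - min(truth))`, computed
#' independently per target column over the test samples. Dimensionless;
#' zero iff the prediction equals the ground truth.
#'
#' @param pred,truth `n x q` matrices (vectors treated as one column).
#' @return named numeric vector of `q` nRMSE values.
#' @export
#' @examples
#' truth <- cbind(seq(0, 10, length.out = 50))
#' nrmse(truth + 1, truth)  # constant offset of 10% of range -> 0.1
nrmse <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` must have identical dimensions.", call. = FALSE)
  }
  if (nrow(truth) < 2) stop("Need at least 2 test samples.", call. = FALSE)
  rng <- apply(truth, 2, function(v) diff(range(v)))
  if (any(rng <= 0)) {
    stop("Degenerate target: zero range in at least one DOF.", call. = FALSE)
  }
  stats::setNames(sqrt(colMeans((pred - truth)^2)) / rng,
                  colnames(truth))
}

#' Repetition-wise cross-validated prediction accuracy
#'
#' One fold per repetition: the model is trained on a realistic-scenario
#' selection from the other `k - 1` repetitions and tested on every sample
#' of the held-out repetition — the full force range including ramps.
#' Scoring is always against the measured forces, whatever the training
#' ground truth, so the stimulus-trained condition is evaluated on real
#' force data.
#'
#' @param session a [simulate_session()] recording.
#' @param hmi stream name.
#' @param gt training ground truth, "force" or "stimulus".
#' @param model_config list passed to [fit_model()] (fields `feature_map`,
#'   `lambda`, `D`, `sigma`, `sigma_grid`); see [default_model_config()].
#' @param k number of folds; the phase must contain exactly `k`
#'   repetitions.
#' @param seed integer seed (feature-map draws, grid-search folds).
#' @return an object of class `evaluation_result`: `per_fold` data.frame
#'   (fold x DOF nRMSE), `per_dof_mean`, `mean`, and metadata.
#' @export
crossval_repetitionwise <- function(session, hmi, gt = c("force", "stimulus"),
                                    model_config = default_model_config(hmi),
                                    k = 5L, seed = 1L) {
  gt <- match.arg(gt)
  reps <- sort(unique(session$repetition_id))
  if (length(reps) != k) {
    stop(sprintf("Phase has %d repetitions; expected exactly k = %d.",
                 length(reps), k), call. = FALSE)
  }
  Xfull <- preprocess_stream(session, hmi)
  cfg <- model_config
  # bandwidth search once per (session, hmi, gt) on the full realistic set,
  # then reused across folds
  if (identical(cfg$feature_map, "rff") && is.null(cfg$sigma)) {
    ts_all <- build_realistic_training_set(session, hmi, gt, reps, X = Xfull)
    grid <- cfg$sigma_grid
    if (is.null(grid)) {
      ng <- if (is.null(cfg$sigma_grid_size)) 10L else cfg$sigma_grid_size
      grid <- median_heuristic_grid(ts_all$X, n_grid = ng, seed = seed)
    }
    cfg$sigma <- grid_search_sigma(ts_all$X, ts_all$Y, lambda = cfg$lambda,
                                   D = cfg$D, sigma_grid = grid, seed = seed)
  }
  rows <- lapply(seq_along(reps), function(i) {
    test_rep <- reps[i]
    ts <- build_realistic_training_set(session, hmi, gt,
                                       setdiff(reps, test_rep), X = Xfull)
    model <- do.call(fit_model, c(list(X = ts$X, Y = ts$Y,
                                       seed = derive_seed(seed, "fold", i)),
                                  cfg[intersect(names(cfg),
                                                c("lambda", "feature_map",
                                                  "D", "sigma"))]))
    test_idx <- which(session$repetition_id == test_rep)
    err <- nrmse(predict(model, Xfull[test_idx, , drop = FALSE]),
                 session$forces[test_idx, , drop = FALSE])
    data.frame(fold = i, repetition = test_rep, dof = session$dofs,
               nrmse = unname(err), row.names = NULL)
  })
  per_fold <- do.call(rbind, rows)
  per_dof <- tapply(per_fold$nrmse, per_fold$dof, mean)[session$dofs]
  structure(list(per_fold = per_fold,
                 per_dof_mean = per_dof,
                 mean = mean(per_fold$nrmse),
                 hmi = hmi, gt = gt, phase = session$phase,
                 subject_id = session$subject_id,
                 model_config = cfg),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s, gt = %s, phase = %s: mean nRMSE %.3f\n",
              x$hmi, x$gt, x$phase, x$mean))
  print(round(x$per_dof_mean, 3))
  invisible(x)
}

#' Default decoder per interface
#'
#' Ultrasound features are decoded linearly (ridge); sEMG and FSR need the
#' nonlinear Random Fourier Feature extension. `lambda = 1` and `D = 300`
#' throughout; `sigma = NULL` means grid search.
#'
#' @param hmi stream name.
#' @param sigma optional fixed bandwidth (skips the grid search).
#' @return a model-config list for [fit_model()].
#' @export
default_model_config <- function(hmi, sigma = NULL) {
  if (hmi %in% c("us_features")) {
    list(feature_map = "identity", lambda = 1)
  } else {
    list(feature_map = "rff", lambda = 1, D = 300L, sigma = sigma,
         sigma_grid = NULL)
  }
}

#' Train-on-first-repetition stability analysis
#'
#' Fits the decoder on a realistic selection from repetition 1 only, then
#' tests on each subsequent repetition separately (full samples, measured
#' forces as ground truth). The least-squares slope of nRMSE versus
#' repetition index, averaged over the six DOFs, summarizes how quickly
#' prediction degrades as the signal drifts.
#'
#' @inheritParams crossval_repetitionwise
#' @param n_test_reps number of test repetitions after the first
#'   (default 4, i.e. repetitions 2..5).
#' @return an object of class `stability_summary`: `per_repetition`
#'   data.frame (repetition x DOF nRMSE), `slope` (mean over DOFs),
#'   `slope_by_dof`, and metadata.
#' @export
stability_eval <- function(session, hmi,
                           model_config = default_model_config(hmi),
                           n_test_reps = 4L, seed = 1L) {
  reps <- sort(unique(session$repetition_id))
  if (length(reps) < n_test_reps + 1L) {
    stop(sprintf("Need %d repetitions; session has %d.",
                 n_test_reps + 1L, length(reps)), call. = FALSE)
  }
  Xfull <- preprocess_stream(session, hmi)
  ts <- build_realistic_training_set(session, hmi, "force", reps[1],
                                     X = Xfull)
  cfg <- model_config
  if (identical(cfg$feature_map, "rff") && is.null(cfg$sigma)) {
    grid <- cfg$sigma_grid
    if (is.null(grid)) {
      ng <- if (is.null(cfg$sigma_grid_size)) 10L else cfg$sigma_grid_size
      grid <- median_heuristic_grid(ts$X, n_grid = ng, seed = seed)
    }
    cfg$sigma <- grid_search_sigma(ts$X, ts$Y, lambda = cfg$lambda,
                                   D = cfg$D, sigma_grid = grid, seed = seed)
  }
  model <- do.call(fit_model, c(list(X = ts$X, Y = ts$Y,
                                     seed = derive_seed(seed, "stab")),
                                cfg[intersect(names(cfg),
                                              c("lambda", "feature_map",
                                                "D", "sigma"))]))
  test_reps <- reps[2:(n_test_reps + 1L)]
  rows <- lapply(seq_along(test_reps), function(i) {
    idx <- which(session$repetition_id == test_reps[i])
    err <- nrmse(predict(model, Xfull[idx, , drop = FALSE]),
                 session$forces[idx, , drop = FALSE])
    data.frame(repetition = i + 1L, dof = session$dofs,
               nrmse = unname(err), row.names = NULL)
  })
  per_repetition <- do.call(rbind, rows)
  sl <- stability_slope(per_repetition)
  structure(list(per_repetition = per_repetition,
                 slope = sl$slope, slope_by_dof = sl$by_dof,
                 hmi = hmi, phase = session$phase,
                 subject_id = session$subject_id, model_config = cfg),
            class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf("<stability_summary> %s, phase = %s: slope %.5f nRMSE/repetition\n",
              x$hmi, x$phase, x$slope))
  invisible(x)
}

#' Mean linear slope of error versus repetition index
#'
#' Per DOF, the ordinary least-squares slope of nRMSE against repetition
#' index over the four test repetitions; the summary is the mean over
#' DOFs. Units: nRMSE per repetition.
#'
#' @param per_repetition data.frame with columns `repetition`, `dof`,
#'   `nrmse`, four repetitions per DOF.
#' @return list with `slope` (scalar mean) and `by_dof` (named vector).
#' @export
#' @examples
#' d <- data.frame(repetition = 2:5, dof = "little",
#'                 nrmse = c(0.1, 0.2, 0.3, 0.4))
#' stability_slope(d)$slope  # 0.1
stability_slope <- function(per_repetition) {
  stopifnot(all(c("repetition", "dof", "nrmse") %in% names(per_repetition)))
  if (any(!is.finite(per_repetition$nrmse))) {
    stop("Non-finite error values.", call. = FALSE)
  }
  by_dof <- vapply(split(per_repetition, per_repetition$dof), function(d) {
    if (nrow(d) < 2) stop("Each DOF needs >= 2 repetitions.", call. = FALSE)
    x <- d$repetition; y <- d$nrmse
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }, numeric(1))
  list(slope = mean(by_dof), by_dof = by_dof)
}
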