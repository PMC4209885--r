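#' Write a session recording to disk
#'
#' One CSV per stream (columns: `time`, `repetition_id`, `phase`, then the
#' channel names) plus `forces.csv`, `stimulus.csv` and a JSON metadata
#' sidecar carrying the annotations and configuration. Values are written
#' at full double precision so the round-trip is lossless well beyond
#' 1e-12 relative.
#'
#' @param session a [simulate_session()] recording.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  head_cols <- data.table::data.table(
    time = session$time,
    repetition_id = session$repetition_id,
    phase = session$phase)
  wr <- function(mat, name) {
    dt <- cbind(head_cols, data.table::as.data.table(mat))
    data.table::fwrite(dt, file.path(dir, paste0(name, ".csv")))
  }
  wr(session$forces, "forces")
  wr(session$stimulus, "stimulus")
  for (nm in names(session$streams)) wr(session$streams[[nm]], nm)
  meta <- list(
    subject_id = session$subject_id, phase = session$phase,
    sample_rate = session$sample_rate, dofs = session$dofs,
    force_level = session$force_level, seed = session$seed,
    streams = names(session$streams),
    active_dof = session$active_dof, segment = session$segment,
    plateau_pos = session$plateau_pos)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read a session recording written by [write_session()]
#'
#' @param dir directory containing the CSV files and `session.json`.
#' @return a `session_recording`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  rd <- function(name) {
    dt <- data.table::fread(file.path(dir, paste0(name, ".csv")))
    m <- as.matrix(dt[, -(1:3)])
    list(m = m, time = dt$time, repetition_id = dt$repetition_id)
  }
  forces <- rd("forces")
  stimulus <- rd("stimulus")
  streams <- lapply(stats::setNames(meta$streams, meta$streams),
                    function(nm) rd(nm)$m)
  structure(list(
    time = forces$time,
    forces = forces$m,
    stimulus = stimulus$m,
    repetition_id = as.integer(forces$repetition_id),
    active_dof = meta$active_dof,
    segment = meta$segment,
    plateau_pos = as.numeric(meta$plateau_pos),
    phase = meta$phase,
    subject_id = meta$subject_id,
    sample_rate = meta$sample_rate,
    dofs = meta$dofs,
    force_level = meta$force_level,
    streams = streams,
    seed = meta$seed
  ), class = "session_recording")
}

#' Serialize a fitted model to JSON
#'
#' All numeric content (weights, RFF frequencies and phases) is written at
#' 17 significant digits, which round-trips IEEE doubles exactly.
#'
#' @param model an `hmi_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hmi_model"))
  obj <- list(feature_map = model$feature_map,
              lambda = model$lambda,
              input_dim = model$input_dim,
              target_names = model$target_names,
              weights = unclass(model$weights))
  if (model$feature_map == "rff") {
    obj$map <- list(Omega = unclass(model$map$Omega), b = model$map$b,
                    d = model$map$d, D = model$map$D,
                    sigma = model$map$sigma, seed = model$map$seed)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return an `hmi_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- NULL
  if (obj$feature_map == "rff") {
    map <- structure(list(Omega = obj$map$Omega, b = obj$map$b,
                          d = as.integer(obj$map$d), D = as.integer(obj$map$D),
                          sigma = obj$map$sigma, seed = obj$map$seed),
                     class = "rff_map")
  }
  W <- as.matrix(obj$weights)
  colnames(W) <- obj$target_names
  structure(list(feature_map = obj$feature_map, map = map, weights = W,
                 lambda = obj$lambda, input_dim = as.integer(obj$input_dim),
                 target_names = obj$target_names),
            class = "hmi_model")
}
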