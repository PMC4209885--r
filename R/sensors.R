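#' Sensor configuration for a simulated interface stream
#'
#' Describes how a multi-channel forearm sensor responds to the six
#' finger-force channels: a non-negative channel-by-DOF coupling (mixing)
#' matrix, a monotone saturating response nonlinearity, an optional drift
#' model, and additive measurement noise.
#'
#' Drift models:
#' \describe{
#'   \item{`none`}{repetition-stationary stream.}
#'   \item{`multiplicative_gain_ramp`}{channel gain ramps linearly with
#'     elapsed time, `gain(t) = 1 + rate * t`, plus an additive offset ramp
#'     `offset_rate * t` — the fatigue/sweat/electrode-shift failure mode of
#'     sEMG. Survives low-pass envelope filtering.}
#'   \item{`additive_baseline_walk`}{a slow additive baseline: per-channel
#'     linear ramp (`rate` units/s, seeded sign/magnitude jitter) plus a
#'     random walk (`walk_sd` units per step). Its power lies far below
#'     0.5 Hz, so the stated third-order high-pass removes it — the baseline
#'     wander of force-sensing resistors.}
#' }
#'
#' @param n_channels number of channels (10 for sEMG/FSR, 543 for US features).
#' @param mixing optional `n_channels x 6` non-negative coupling matrix; if
#'   `NULL` a smooth seeded ring-topology placement is drawn when the stream
#'   is simulated (each DOF couples to a few neighbouring channels).
#' @param nonlinearity list with `kind` ("tanh", "hill" or "linear") and
#'   `gain`; all are monotone and map 0 to 0 and 1 to 1.
#' @param drift_model list with `kind` (one of the models above) and rate
#'   parameters: `rate` (per second), `offset_rate` (gain ramp only),
#'   `walk_sd` (baseline walk only).
#' @param baseline resting channel output, signal units.
#' @param noise_sd additive Gaussian noise SD, signal units.
#' @return an object of class `sensor_config`.
#' @export
sensor_config <- function(n_channels = 10L,
                          mixing = NULL,
                          nonlinearity = list(kind = "tanh", gain = 1.5),
                          drift_model = list(kind = "none"),
                          baseline = 0.05,
                          noise_sd = 0.03) {
  if (n_channels < 1) stop("`n_channels` must be >= 1.", call. = FALSE)
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_channels) {
      stop("`mixing` must have `n_channels` rows.", call. = FALSE)
    }
    if (any(mixing < 0)) stop("`mixing` entries must be >= 0.", call. = FALSE)
    if (any(colSums(mixing) == 0)) {
      stop("Every DOF must couple to at least one channel.", call. = FALSE)
    }
  }
  if (!nonlinearity$kind %in% c("tanh", "hill", "linear")) {
    stop("Unknown nonlinearity kind.", call. = FALSE)
  }
  if (!drift_model$kind %in% c("none", "multiplicative_gain_ramp",
                               "additive_baseline_walk")) {
    stop("Unknown drift model.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), mixing = mixing,
                 nonlinearity = nonlinearity, drift_model = drift_model,
                 baseline = baseline, noise_sd = noise_sd),
            class = "sensor_config")
}

#' Default stream configurations for the three interfaces
#'
#' `semg`: 10 channels, saturating response, multiplicative gain drift.
#' `fsr`: 10 channels, saturating response, slow additive baseline drift.
#' `us_features`: 543 linear drift-free features.
#' Set `drift = FALSE` for stationarity (control experiments).
#'
#' @param stream one of "semg", "fsr", "us_features".
#' @param drift logical; include the stream's default drift model.
#' @return a `sensor_config`.
#' @export
default_sensor_config <- function(stream = c("semg", "fsr", "us_features"),
                                  drift = TRUE) {
  stream <- match.arg(stream)
  switch(stream,
    semg = sensor_config(
      n_channels = 10L,
      nonlinearity = list(kind = "tanh", gain = 1.5),
      drift_model = if (drift) {
        list(kind = "multiplicative_gain_ramp", rate = 0.002,
             offset_rate = 3e-4)
      } else list(kind = "none"),
      baseline = 0.05, noise_sd = 0.03),
    fsr = sensor_config(
      n_channels = 10L,
      nonlinearity = list(kind = "hill", gain = 0.4),
      drift_model = if (drift) {
        list(kind = "additive_baseline_walk", rate = 0.002, walk_sd = 5e-4)
      } else list(kind = "none"),
      baseline = 0.10, noise_sd = 0.02),
    us_features = sensor_config(
      n_channels = 543L,
      nonlinearity = list(kind = "linear", gain = 1),
      drift_model = list(kind = "none"),
      baseline = 0.5, noise_sd = 0.02))
}

# monotone saturating responses, fixed at resp(0)=0, resp(1)=1
.apply_nonlinearity <- function(u, nl) {
  switch(nl$kind,
    linear = u,
    tanh = tanh(nl$gain * u) / tanh(nl$gain),
    hill = (u / (nl$gain + u)) * (nl$gain + 1))
}

# smooth ring-topology electrode placement: DOF d peaks at an angular
# position on the 10-channel bracelet, coupling decays with ring distance
.draw_mixing <- function(n_channels, n_dof, seed) {
  with_seed(seed, {
    centers <- (seq_len(n_dof) - 1) * n_channels / n_dof +
      runif(n_dof, -0.8, 0.8)
    width <- runif(n_dof, 1.0, 1.8)
    ch <- seq_len(n_channels) - 1
    m <- sapply(seq_len(n_dof), function(d) {
      dd <- abs(ch - centers[d])
      dd <- pmin(dd, n_channels - dd)  # ring distance
      exp(-(dd / width[d])^2)
    })
    m[m < 0.05] <- 0
    m <- sweep(m, 2, apply(m, 2, max), "/")  # each DOF: peak coupling 1
    m
  })
}

#' Simulate ground-truth forces from a stimulus protocol
#'
#' Converts the normalized stimulus trace into newtons by scaling each DOF
#' with the subject's MVC, then models the subject's tracking behaviour as
#' a first-order lag plus Gaussian tracking noise, clipped at zero.
#'
#' @param protocol a [make_protocol()] object.
#' @param subject a [subject_params()] object.
#' @param seed integer seed for the tracking noise.
#' @return list with `forces` and `stimulus` matrices (`n_samples x 6`, N).
#' @export
simulate_forces <- function(protocol, subject, seed) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(subject, "subject_params"))
  stim_n <- sweep(protocol$stimulus, 2, subject$mvc, "*")
  dt <- 1 / protocol$sample_rate
  forces <- stim_n
  if (subject$tracking_lag > 0) {
    a <- exp(-dt / subject$tracking_lag)
    forces <- apply(stim_n, 2, function(x)
      as.numeric(signal::filter(signal::Arma(b = 1 - a, a = c(1, -a)), x)))
  }
  if (subject$tracking_noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(length(forces), 0,
                                          subject$tracking_noise_sd),
                                    nrow(forces)))
    forces <- forces + noise
  }
  forces <- pmax(forces, 0)
  dimnames(forces) <- dimnames(stim_n)
  list(forces = forces, stimulus = stim_n)
}

# shared force->channel response for sEMG and FSR
.sensor_response <- function(forces, mvc, config, seed) {
  fnorm <- sweep(forces, 2, mvc, "/")
  mixing <- config$mixing
  if (is.null(mixing)) {
    mixing <- .draw_mixing(config$n_channels, ncol(forces),
                           derive_seed(seed, "mixing"))
  }
  act <- fnorm %*% t(mixing)                       # n x channels, >= 0
  .apply_nonlinearity(pmin(act, 1.5), config$nonlinearity)
}

#' Simulate a 10-channel sEMG-envelope stream
#'
#' Channels respond to the DOF forces through a non-negative mixing matrix
#' and a saturating nonlinearity (amplified, rectified, smoothed electrode
#' outputs). Under the `multiplicative_gain_ramp` drift model the channel
#' gain grows linearly with elapsed time and a small additive offset ramps
#' up — the progressive change attributed to sweat, electrode shift and
#' fatigue. Output is non-negative.
#'
#' @param forces `n x 6` force matrix in N.
#' @param mvc per-DOF MVC used to normalize forces.
#' @param config a [sensor_config()] with 10 channels.
#' @param time sample times in seconds (drift covariate).
#' @param seed integer seed.
#' @return `n x n_channels` matrix.
#' @export
simulate_semg <- function(forces, mvc, config, time, seed) {
  stopifnot(inherits(config, "sensor_config"), length(time) == nrow(forces))
  resp <- .sensor_response(forces, mvc, config, seed)
  out <- config$baseline + resp
  dm <- config$drift_model
  if (dm$kind == "multiplicative_gain_ramp") {
    gain <- 1 + dm$rate * time
    offset <- (if (is.null(dm$offset_rate)) 0 else dm$offset_rate) * time
    out <- out * gain + offset
  } else if (dm$kind != "none") {
    stop("sEMG supports drift models 'none' and 'multiplicative_gain_ramp'.",
         call. = FALSE)
  }
  if (config$noise_sd > 0) {
    out <- out + with_seed(derive_seed(seed, "noise"),
                           matrix(rnorm(length(out), 0, config$noise_sd),
                                  nrow(out)))
  }
  out <- pmax(out, 0)
  colnames(out) <- sprintf("semg_%02d", seq_len(ncol(out)))
  out
}

#' Simulate a 10-channel force-sensing-resistor stream
#'
#' The force-locked component is drift-free; drift enters as a slow
#' additive baseline (per-channel linear ramp plus random walk) whose
#' spectrum lies below 0.5 Hz, so the stated third-order high-pass filter
#' removes it.
#'
#' @inheritParams simulate_semg
#' @return `n x n_channels` matrix.
#' @export
simulate_fsr <- function(forces, mvc, config, time, seed) {
  stopifnot(inherits(config, "sensor_config"), length(time) == nrow(forces))
  resp <- .sensor_response(forces, mvc, config, seed)
  out <- config$baseline + resp
  dm <- config$drift_model
  if (dm$kind == "additive_baseline_walk") {
    n <- nrow(out)
    drift <- with_seed(derive_seed(seed, "drift"), {
      slope_sd <- if (is.null(dm$slope_sd)) dm$rate / 3 else dm$slope_sd
      slopes <- rnorm(ncol(out), dm$rate, slope_sd)
      walk_sd <- if (is.null(dm$walk_sd)) 0 else dm$walk_sd
      ramp <- outer(time, slopes)
      if (walk_sd > 0) {
        ramp + apply(matrix(rnorm(n * ncol(out), 0, walk_sd), n), 2, cumsum)
      } else ramp
    })
    out <- out + drift
  } else if (dm$kind != "none") {
    stop("FSR supports drift models 'none' and 'additive_baseline_walk'.",
         call. = FALSE)
  }
  if (config$noise_sd > 0) {
    out <- out + with_seed(derive_seed(seed, "noise"),
                           matrix(rnorm(length(out), 0, config$noise_sd),
                                  nrow(out)))
  }
  out <- pmax(out, 0)
  colnames(out) <- sprintf("fsr_%02d", seq_len(ncol(out)))
  out
}

#' Simulate a 543-dimensional ultrasound-feature stream
#'
#' Gray-level features of the deforming forearm cross-section are modelled
#' as linear in the instantaneous forces: `features = forces A' + b +
#' noise`, with a dense seeded map `A` and constant offset `b`. Drift-free
#' by default, matching the assumption that a linear decoder suffices for
#' this modality.
#'
#' @inheritParams simulate_semg
#' @param config a [sensor_config()]; `n_channels` defaults to 543.
#' @return `n x n_channels` matrix.
#' @export
simulate_us_features <- function(forces, mvc, config, time, seed) {
  stopifnot(inherits(config, "sensor_config"))
  fnorm <- sweep(forces, 2, mvc, "/")
  p <- config$n_channels
  AB <- with_seed(derive_seed(seed, "usmap"), {
    list(A = matrix(rnorm(p * ncol(forces), 0, 0.25), p),
         b = abs(rnorm(p, config$baseline, 0.1)))
  })
  out <- fnorm %*% t(AB$A)
  out <- sweep(out, 2, AB$b, "+")
  if (config$noise_sd > 0) {
    out <- out + with_seed(derive_seed(seed, "noise"),
                           matrix(rnorm(length(out), 0, config$noise_sd),
                                  nrow(out)))
  }
  colnames(out) <- sprintf("us_%03d", seq_len(ncol(out)))
  out
}

#' Simulate a stack of synthetic ultrasound frames
#'
#' A phantom cross-section: smooth Gaussian blobs whose centroid positions
#' and intensities shift affinely with the instantaneous forces, plus pixel
#' noise. Intended as input for [extract_us_features()]; this is a
#' geometric stand-in, not speckle physics.
#'
#' @param forces `n x 6` force matrix in N.
#' @param mvc per-DOF MVC (normalizes forces).
#' @param image_config list: `height`, `width` (pixels), `n_blobs`,
#'   `displacement_gain` (pixels per unit normalized force), `noise_sd`
#'   (gray-level units in \[0,1\]).
#' @param seed integer seed.
#' @return `height x width x n` array of gray levels in `[0, 1]`.
#' @export
simulate_us_images <- function(forces, mvc,
                               image_config = list(height = 48L, width = 64L,
                                                   n_blobs = 6L,
                                                   displacement_gain = 6,
                                                   noise_sd = 0.01),
                               seed = 1L) {
  h <- image_config$height; w <- image_config$width
  if (h < 4 || w < 4) stop("Frames must be at least 4 x 4 pixels.", call. = FALSE)
  nb <- image_config$n_blobs
  fnorm <- sweep(forces, 2, mvc, "/")
  n <- nrow(fnorm); nd <- ncol(fnorm)
  blobs <- with_seed(derive_seed(seed, "blobs"), {
    list(cy = runif(nb, 0.2 * h, 0.8 * h),
         cx = runif(nb, 0.2 * w, 0.8 * w),
         amp = runif(nb, 0.4, 0.9),
         sigma = runif(nb, 2.5, 4.5),
         # per-blob 2 x 6 displacement map and intensity modulation
         disp = array(rnorm(nb * 2 * nd, 0, image_config$displacement_gain),
                      c(nb, 2, nd)),
         imod = matrix(rnorm(nb * nd, 0, 0.3), nb, nd))
  })
  noise <- if (image_config$noise_sd > 0) {
    with_seed(derive_seed(seed, "pixnoise"),
              array(rnorm(h * w * n, 0, image_config$noise_sd), c(h, w, n)))
  } else array(0, c(h, w, n))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  frames <- array(0, c(h, w, n))
  for (i in seq_len(n)) {
    f <- fnorm[i, ]
    img <- matrix(0.1, h, w)
    for (b in seq_len(nb)) {
      dy <- sum(blobs$disp[b, 1, ] * f)
      dx <- sum(blobs$disp[b, 2, ] * f)
      amp <- blobs$amp[b] * (1 + sum(blobs$imod[b, ] * f))
      img <- img + amp * exp(-(((yy - blobs$cy[b] - dy)^2 +
                                (xx - blobs$cx[b] - dx)^2) /
                               (2 * blobs$sigma[b]^2)))
    }
    frames[, , i] <- pmin(pmax(img + noise[, , i], 0), 1)
  }
  frames
}

#' Simulate one complete experimental session phase
#'
#' Generates ground-truth forces under the stimulus protocol and the
#' requested interface streams on a shared 50 Hz time base, with
#' hierarchical seeding (master seed, subject id, stream name).
#'
#' @param protocol a [make_protocol()] object.
#' @param subject a [subject_params()] object.
#' @param streams named list of `sensor_config`s; names from
#'   `semg`, `fsr`, `fsr2`, `us_features`. (`fsr2` is a second,
#'   identically-behaving pressure bracelet stream with an independent
#'   noise/drift draw, mirroring a repeated FSR session.)
#' @param seed master seed for this session.
#' @param phase phase label ("high" or "low").
#' @param subject_id identifier folded into the seed hierarchy.
#' @return an object of class `session_recording`: time, forces, stimulus
#'   (N), repetition/segment annotations, and the named streams.
#' @export
#' @examples
#' sess <- simulate_session(make_protocol(0.8), subject_params(),
#'                          streams = list(semg = default_sensor_config("semg")),
#'                          seed = 1)
#' str(sess$streams$semg[1:2, 1:3])
simulate_session <- function(protocol, subject,
                             streams = list(
                               semg = default_sensor_config("semg"),
                               fsr = default_sensor_config("fsr"),
                               us_features = default_sensor_config("us_features")),
                             seed = 1L, phase = "high", subject_id = 1L) {
  base_seed <- derive_seed(seed, "subject", subject_id, "phase", phase)
  ft <- simulate_forces(protocol, subject, derive_seed(base_seed, "forces"))
  sim <- list(semg = simulate_semg, fsr = simulate_fsr, fsr2 = simulate_fsr,
              us_features = simulate_us_features)
  out_streams <- lapply(stats::setNames(names(streams), names(streams)),
    function(nm) {
      if (!nm %in% names(sim)) stop("Unknown stream: ", nm, call. = FALSE)
      sim[[nm]](ft$forces, subject$mvc, streams[[nm]], protocol$time,
                derive_seed(base_seed, "stream", nm))
    })
  structure(list(
    time = protocol$time,
    forces = ft$forces,
    stimulus = ft$stimulus,
    repetition_id = protocol$repetition_id,
    active_dof = protocol$active_dof,
    segment = protocol$segment,
    plateau_pos = protocol$plateau_pos,
    phase = phase,
    subject_id = subject_id,
    sample_rate = protocol$sample_rate,
    dofs = protocol$dofs,
    force_level = protocol$force_level,
    streams = out_streams,
    seed = seed
  ), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> subject %s, phase %s: %d samples at %g Hz; streams: %s\n",
    format(x$subject_id), x$phase, length(x$time), x$sample_rate,
    paste(names(x$streams), collapse = ", ")))
  invisible(x)
}
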