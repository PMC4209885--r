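#' Default degree-of-freedom labels
#'
#' The six finger-force channels measured by the ground-truth rig: flexion
#' of the little, ring, middle and index fingers, thumb adduction and thumb
#' flexion/rotation.
#' @export
dof_names <- function() {
  c("little", "ring", "middle", "index", "thumb_add", "thumb_flex")
}

#' Build the timed single-DOF stimulus protocol for one session phase
#'
#' Each repetition asks the subject for one isolated flexion per DOF in
#' turn; every activation follows a trapezoidal profile
#' rest - ramp up - plateau - ramp down - rest. The plateau height is the
#' phase force level as a fraction of the maximal voluntary contraction
#' (0.80 for the high-force phase, 0.15 for the low-force phase).
#'
#' @param force_level plateau height as a fraction of MVC, in (0, 1].
#' @param n_repetitions repetitions per phase (default 5).
#' @param sample_rate sampling rate in Hz (default 50).
#' @param segment_durations named numeric vector of segment durations in
#'   seconds: `rest`, `ramp_up`, `plateau`, `ramp_down`, `rest_post`.
#' @param dofs ordered DOF labels (default [dof_names()]).
#' @return an object of class `stimulus_protocol`: a list with the stimulus
#'   trace (`n_samples x 6`, in `[0, force_level]`), per-sample
#'   `repetition_id`, `active_dof`, `segment`
#'   (rest/ramp_up/plateau/ramp_down), `plateau_pos` (position within the
#'   current plateau in `[0, 1]`, `NA` elsewhere), `time` in seconds, and
#'   the configuration fields.
#' @export
#' @examples
#' p <- make_protocol(force_level = 0.8)
#' dim(p$stimulus)       # 13500 x 6 at the defaults
#' max(p$stimulus)       # 0.8
make_protocol <- function(force_level,
                          n_repetitions = 5L,
                          sample_rate = 50,
                          segment_durations = c(rest = 2, ramp_up = 1,
                                                plateau = 3, ramp_down = 1,
                                                rest_post = 2),
                          dofs = dof_names()) {
  if (!is.numeric(force_level) || length(force_level) != 1L ||
      force_level <= 0 || force_level > 1) {
    stop("`force_level` must be a single value in (0, 1].", call. = FALSE)
  }
  need <- c("rest", "ramp_up", "plateau", "ramp_down", "rest_post")
  if (!all(need %in% names(segment_durations))) {
    stop("`segment_durations` must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  segment_durations <- segment_durations[need]
  if (any(segment_durations <= 0) || sample_rate <= 0 || n_repetitions < 1) {
    stop("Durations, sample rate and repetition count must be positive.",
         call. = FALSE)
  }
  n_dof <- length(dofs)
  seg_n <- round(segment_durations * sample_rate)
  if (any(seg_n < 1)) stop("Every segment must span at least one sample.", call. = FALSE)
  act_n <- sum(seg_n)

  # one trapezoid in stimulus units [0, force_level]
  tpz <- c(rep(0, seg_n["rest"]),
           seq_len(seg_n["ramp_up"]) / seg_n["ramp_up"],
           rep(1, seg_n["plateau"]),
           rev(seq_len(seg_n["ramp_down"]) - 1) / seg_n["ramp_down"],
           rep(0, seg_n["rest_post"]))
  seg_lab <- c(rep("rest", seg_n["rest"]),
               rep("ramp_up", seg_n["ramp_up"]),
               rep("plateau", seg_n["plateau"]),
               rep("ramp_down", seg_n["ramp_down"]),
               rep("rest", seg_n["rest_post"]))
  plat_pos <- rep(NA_real_, act_n)
  plat_idx <- which(seg_lab == "plateau")
  plat_pos[plat_idx] <- (seq_along(plat_idx) - 0.5) / length(plat_idx)

  n_total <- act_n * n_dof * n_repetitions
  stimulus <- matrix(0, n_total, n_dof, dimnames = list(NULL, dofs))
  repetition_id <- integer(n_total)
  active_dof <- character(n_total)
  segment <- character(n_total)
  plateau_pos <- rep(NA_real_, n_total)

  at <- 0L
  for (rep_i in seq_len(n_repetitions)) {
    for (d in seq_len(n_dof)) {
      idx <- at + seq_len(act_n)
      stimulus[idx, d] <- tpz * force_level
      repetition_id[idx] <- rep_i
      active_dof[idx] <- dofs[d]
      segment[idx] <- seg_lab
      plateau_pos[idx] <- plat_pos
      at <- at + act_n
    }
  }

  structure(list(
    dofs = dofs,
    n_repetitions = as.integer(n_repetitions),
    force_level = force_level,
    sample_rate = sample_rate,
    segment_durations = segment_durations,
    time = (seq_len(n_total) - 1) / sample_rate,
    stimulus = stimulus,
    repetition_id = repetition_id,
    active_dof = active_dof,
    segment = segment,
    plateau_pos = plateau_pos
  ), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %d DOFs x %d repetitions at %.0f%% MVC, %g Hz, %d samples (%.0f s)\n",
    length(x$dofs), x$n_repetitions, 100 * x$force_level, x$sample_rate,
    nrow(x$stimulus), max(x$time) + 1 / x$sample_rate))
  invisible(x)
}

#' Per-subject parameters of the simulated cohort
#'
#' Holds the per-DOF maximal voluntary contraction (MVC) in newtons, the
#' force-tracking noise level and the tracking lag (subjects follow the
#' visual stimulus with a first-order delay).
#'
#' @param mvc per-DOF MVC in N; a single value is recycled to 6 DOFs.
#' @param tracking_noise_sd standard deviation of tracking noise, N.
#' @param tracking_lag first-order tracking lag time constant, s.
#' @param dofs DOF labels.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(mvc = 22.6,
                           tracking_noise_sd = 0.5,
                           tracking_lag = 0.15,
                           dofs = dof_names()) {
  if (length(mvc) == 1L) mvc <- rep(mvc, length(dofs))
  if (length(mvc) != length(dofs) || any(!is.finite(mvc)) || any(mvc <= 0)) {
    stop("`mvc` must be positive and match the number of DOFs.", call. = FALSE)
  }
  if (tracking_noise_sd < 0 || tracking_lag < 0) {
    stop("`tracking_noise_sd` and `tracking_lag` must be non-negative.",
         call. = FALSE)
  }
  structure(list(mvc = stats::setNames(mvc, dofs),
                 tracking_noise_sd = tracking_noise_sd,
                 tracking_lag = tracking_lag),
            class = "subject_params")
}

#' Draw a random subject from the cohort model
#'
#' Subject-level MVC is drawn around a population mean of 22.6 N with an
#' across-subject standard deviation of 2.1 N, plus independent per-DOF
#' variation; values are kept above a physiological floor.
#'
#' @param seed integer seed for the draw.
#' @param mean_mvc,sd_mvc population mean and SD of subject-level MVC, N.
#' @param dof_sd SD of per-DOF deviation around the subject level, N.
#' @inheritParams subject_params
#' @return a `subject_params` object.
#' @export
sample_subject <- function(seed, mean_mvc = 22.6, sd_mvc = 2.1, dof_sd = 2.0,
                           tracking_noise_sd = 0.5, tracking_lag = 0.15,
                           dofs = dof_names()) {
  with_seed(seed, {
    base <- rnorm(1, mean_mvc, sd_mvc)
    mvc <- pmax(5, base + rnorm(length(dofs), 0, dof_sd))
    subject_params(mvc, tracking_noise_sd, tracking_lag, dofs)
  })
}
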