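test_that("noiseless lag-free forces equal the MVC-scaled stimulus", {
  p <- tiny_protocol()
  ft <- simulate_forces(p, clean_subject(mvc = 20), seed = 1)
  expect_equal(ft$forces, ft$stimulus, tolerance = 1e-14)
  expect_equal(max(ft$forces), 20 * 0.8)
  # plateau force is exactly level * mvc
  expect_true(all(ft$forces[p$segment == "plateau",][
    cbind(seq_len(sum(p$segment == "plateau")),
          match(p$active_dof[p$segment == "plateau"], p$dofs))] == 16))
})

test_that("force simulation is bit-reproducible and non-negative", {
  p <- tiny_protocol()
  subj <- subject_params(20, tracking_noise_sd = 1, tracking_lag = 0.2)
  a <- simulate_forces(p, subj, seed = 7)
  b <- simulate_forces(p, subj, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$forces >= 0))
  c <- simulate_forces(p, subj, seed = 8)
  expect_false(identical(a$forces, c$forces))
})

test_that("tracking lag converges to the plateau level", {
  p <- make_protocol(0.8)  # 3 s plateau >> 0.15 s lag
  subj <- subject_params(20, tracking_noise_sd = 0, tracking_lag = 0.15)
  ft <- simulate_forces(p, subj, seed = 1)
  idx <- which(p$segment == "plateau" & p$plateau_pos > 0.5 &
                 p$active_dof == "little")
  expect_equal(unname(ft$forces[idx, "little"]), rep(16, length(idx)),
               tolerance = 1e-4)
})

test_that("generators are deterministic and stationary without drift", {
  sess1 <- quiet_session(seed = 3)
  sess2 <- quiet_session(seed = 3)
  expect_identical(sess1$streams, sess2$streams)
  # no drift, no noise: repetition 1 and 2 channel responses identical
  for (nm in names(sess1$streams)) {
    r1 <- sess1$streams[[nm]][sess1$repetition_id == 1, ]
    r2 <- sess1$streams[[nm]][sess1$repetition_id == 2, ]
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("hierarchical seeding isolates streams from one another", {
  s_both <- quiet_session(seed = 5, streams = c("semg", "fsr"))
  s_one <- quiet_session(seed = 5, streams = "semg")
  expect_identical(s_both$streams$semg, s_one$streams$semg)
})

test_that("noiseless sensor responses are monotone in each force component", {
  cfg <- default_sensor_config("semg", drift = FALSE)
  cfg$noise_sd <- 0
  mvc <- rep(20, 6)
  grid <- seq(0, 20, length.out = 21)
  for (d in c(1, 4)) {
    f <- matrix(0, length(grid), 6)
    f[, d] <- grid
    out <- simulate_semg(f, mvc, cfg, time = rep(0, nrow(f)), seed = 2)
    expect_true(all(diff(out[, colSums(out) > 0, drop = FALSE]) >= -1e-12))
  }
})

test_that("zero forces yield baseline plus noise only", {
  cfg <- default_sensor_config("fsr", drift = FALSE)
  cfg$noise_sd <- 0
  f <- matrix(0, 100, 6)
  out <- simulate_fsr(f, rep(20, 6), cfg, time = seq(0, 1.98, by = 0.02),
                      seed = 1)
  expect_true(all(out == cfg$baseline))
})

test_that("sEMG multiplicative gain drift follows the configured ramp law", {
  cfg <- default_sensor_config("semg", drift = FALSE)
  cfg$noise_sd <- 0
  rate <- 0.01
  cfg_d <- cfg
  cfg_d$drift_model <- list(kind = "multiplicative_gain_ramp", rate = rate,
                            offset_rate = 0)
  p <- tiny_protocol()
  subj <- clean_subject()
  ft <- simulate_forces(p, subj, seed = 1)
  base <- simulate_semg(ft$forces, subj$mvc, cfg, p$time, seed = 9)
  drifted <- simulate_semg(ft$forces, subj$mvc, cfg_d, p$time, seed = 9)
  # pointwise: drifted = base * (1 + rate * t), exact by the drift law
  expect_equal(drifted, base * (1 + rate * p$time), tolerance = 1e-12)
})

test_that("FSR ramp drift integrates to rate times elapsed time", {
  cfg <- default_sensor_config("fsr", drift = FALSE)
  cfg$noise_sd <- 0
  r <- 0.005
  cfg_d <- cfg
  cfg_d$drift_model <- list(kind = "additive_baseline_walk", rate = r,
                            walk_sd = 0, slope_sd = 0)
  n <- 60 * 50  # 60 s at 50 Hz
  f <- matrix(0, n, 6)
  tm <- (seq_len(n) - 1) / 50
  out <- simulate_fsr(f, rep(20, 6), cfg_d, tm, seed = 4)
  base <- simulate_fsr(f, rep(20, 6), cfg, tm, seed = 4)
  expect_equal(unname(out[n, ] - base[n, ]), rep(r * tm[n], ncol(out)),
               tolerance = 1e-10)
})

test_that("US features are exactly linear in forces when noiseless", {
  sess <- quiet_session(streams = "us_features")
  X <- sess$streams$us_features
  # least squares on [forces, 1] reproduces every feature exactly
  A <- cbind(sess$forces, 1)
  coefs <- qr.solve(A, X)
  expect_equal(A %*% coefs, X, tolerance = 1e-8)
})

test_that("US feature noise matches the configured level", {
  cfg <- default_sensor_config("us_features")
  cfg$noise_sd <- 0.05
  f <- matrix(runif(400 * 6, 0, 20), 400)
  out <- simulate_us_features(f, rep(20, 6), cfg, time = NULL, seed = 3)
  out0 <- simulate_us_features(f, rep(20, 6),
                               modifyList(cfg, list(noise_sd = 0)),
                               time = NULL, seed = 3)
  resid <- out - out0
  expect_equal(sd(as.numeric(resid)), 0.05, tolerance = 0.02)
})

test_that("synthetic ultrasound frames respond geometrically to forces", {
  f0 <- matrix(0, 3, 6)
  frames0 <- simulate_us_images(f0, rep(20, 6),
                                image_config = list(height = 48, width = 64,
                                                    n_blobs = 4,
                                                    displacement_gain = 6,
                                                    noise_sd = 0),
                                seed = 11)
  # zero forces: all frames identical without pixel noise
  expect_equal(frames0[, , 1], frames0[, , 3], tolerance = 1e-14)
  # determinism
  frames0b <- simulate_us_images(f0, rep(20, 6),
                                 image_config = list(height = 48, width = 64,
                                                     n_blobs = 4,
                                                     displacement_gain = 6,
                                                     noise_sd = 0),
                                 seed = 11)
  expect_identical(frames0, frames0b)
})

test_that("doubling the displacement gain doubles the centroid shift", {
  centroid <- function(img) {
    w <- img - min(img)
    c(sum(row(img) * w), sum(col(img) * w)) / sum(w)
  }
  f <- rbind(rep(0, 6), c(8, 0, 0, 0, 0, 0))
  mk <- function(gain) {
    simulate_us_images(f, rep(20, 6),
                       image_config = list(height = 64, width = 80,
                                           n_blobs = 1,
                                           displacement_gain = gain,
                                           noise_sd = 0),
                       seed = 21)
  }
  fr1 <- mk(3); fr2 <- mk(6)
  shift1 <- centroid(fr1[, , 2]) - centroid(fr1[, , 1])
  shift2 <- centroid(fr2[, , 2]) - centroid(fr2[, , 1])
  expect_equal(shift2, 2 * shift1, tolerance = 0.05)
})

test_that("invalid sensor configurations are rejected", {
  expect_error(sensor_config(noise_sd = -1), "noise_sd")
  expect_error(sensor_config(mixing = matrix(-1, 10, 6)), ">= 0")
  expect_error(sensor_config(mixing = matrix(0, 10, 6)), "couple")
  expect_error(sensor_config(drift_model = list(kind = "nope")), "drift")
})
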