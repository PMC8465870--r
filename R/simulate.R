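#' Default mCTSIB condition specifications
#'
#' The four conditions of the modified Clinical Test of Sensory Interaction
#' and Balance cross support surface (firm / foam) with vision (eyes open /
#' closed).  The default root-mean-square sway targets encode the expected
#' ordering: sway grows from condition 1 to 4, the anterior-posterior (AP)
#' effect is larger than the mediolateral (ML) one, and ML sway barely moves
#' between the two eyes-open conditions (1 and 3) because vision is what
#' stabilises the frontal plane.
#'
#' @param ml_rms_cm Numeric length 4, ML displacement RMS targets (cm) for
#'   conditions 1--4.
#' @param ap_rms_cm Numeric length 4, AP displacement RMS targets (cm).
#' @param sway_bandwidth_hz Sway bandwidth (Hz) of the band-limited sway
#'   process; must stay below the 4 Hz analysis low-pass so the pipeline's
#'   filter passes the signal.
#'
#' @return A tibble with columns `condition`, `surface`, `vision`,
#'   `ml_rms_cm`, `ap_rms_cm`, `sway_bandwidth_hz`.
#' @export
#' @examples
#' mctsib_conditions()
mctsib_conditions <- function(ml_rms_cm = c(0.30, 0.45, 0.32, 0.60),
                              ap_rms_cm = c(0.40, 0.70, 0.90, 1.40),
                              sway_bandwidth_hz = 1) {
  stopifnot(length(ml_rms_cm) == 4, length(ap_rms_cm) == 4,
            all(ml_rms_cm >= 0), all(ap_rms_cm >= 0),
            sway_bandwidth_hz > 0)
  tibble::tibble(
    condition = 1:4,
    surface = c("firm", "firm", "foam", "foam"),
    vision = c("open", "closed", "open", "closed"),
    ml_rms_cm = ml_rms_cm,
    ap_rms_cm = ap_rms_cm,
    sway_bandwidth_hz = sway_bandwidth_hz
  )
}

#' Synthetic subject anthropometrics
#'
#' Draws subject heights from a normal distribution matching a young healthy
#' adult cohort (mean 173.6 cm, sd 6.8 cm) and assigns each subject a
#' centre-of-mass height `L = com_fraction * height`, the inverted-pendulum
#' lever arm used by the ground projection.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param seed Integer seed.
#' @param mean_height_cm,sd_height_cm Height distribution parameters (cm).
#' @param com_fraction Fraction of stature at which the centre of mass sits;
#'   0.53 is the standard anthropometric value.
#'
#' @return A tibble with columns `subject_id`, `height_cm`, `com_height_cm`.
#' @export
subject_profiles <- function(n_subjects = 23, seed = 1,
                             mean_height_cm = 173.6, sd_height_cm = 6.8,
                             com_fraction = 0.53) {
  stopifnot(n_subjects >= 1, mean_height_cm > 0, sd_height_cm >= 0,
            com_fraction > 0, com_fraction < 1)
  heights <- withr::with_seed(seed,
    rnorm(n_subjects, mean_height_cm, sd_height_cm))
  tibble::tibble(
    subject_id = seq_len(n_subjects),
    height_cm = heights,
    com_height_cm = com_fraction * heights
  )
}

#' Derive a reproducible stream seed from a master seed
#'
#' Counter scheme: `seed = (master mod 2^20) * 2^11 + subject * 2^6 +
#' condition * 2^3 + channel`, guaranteed below 2^31 so it is a valid R
#' integer seed.  Any subset of subjects/conditions therefore reproduces
#' exactly, independent of generation order.
#'
#' @param master Master integer seed.
#' @param subject Subject counter (0--31).
#' @param condition Condition counter (0--7).
#' @param channel Channel counter (0--7).
#' @return An integer seed.
#' @export
derive_seed <- function(master, subject = 0, condition = 0, channel = 0) {
  stopifnot(subject >= 0, subject < 32, condition >= 0, condition < 8,
            channel >= 0, channel < 8)
  as.integer((master %% 2^20) * 2048 + subject * 64 + condition * 8 + channel)
}

# Band-limited noise channel anchored at zero initial displacement and
# rescaled so the sample RMS equals `target` exactly.
sway_channel <- function(target, bandwidth, n, fs, seed) {
  if (target == 0) return(rep(0, n))
  w <- withr::with_seed(seed, rnorm(n))
  bf <- signal::butter(2, bandwidth / (fs / 2), type = "low")
  w <- as.numeric(signal::filter(bf, w))
  w <- w - w[1]
  s <- sqrt(mean(w^2))
  if (s == 0) stop("degenerate sway path: zero variance after filtering")
  w * (target / s)
}

#' Generate a planar quasi-static sway path
#'
#' Gaussian white noise low-pass filtered (2nd-order Butterworth) at the
#' sway bandwidth, anchored at zero initial displacement (the subject starts
#' upright, which is also the inclination-offset reference the downstream
#' kinematics subtract), then scaled so the sample RMS of each direction
#' equals its target.
#'
#' @param ml_rms_cm,ap_rms_cm Target displacement RMS (cm) for the ML (x)
#'   and AP (y) directions.
#' @param duration_s Recording duration (s).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed (the two directions use `seed` and `seed + 1`).
#' @param sway_bandwidth_hz Bandwidth of the sway process (Hz).
#'
#' @return A tibble with columns `t` (s), `dx_cm`, `dy_cm`.
#' @export
#' @examples
#' p <- generate_sway_path(0.3, 0.8, duration_s = 30, fs = 60, seed = 7)
#' sqrt(mean(p$dy_cm^2)) # = 0.8
generate_sway_path <- function(ml_rms_cm, ap_rms_cm, duration_s, fs, seed,
                               sway_bandwidth_hz = 1) {
  if (fs <= 0 || duration_s <= 0)
    stop("`fs` and `duration_s` must be positive")
  stopifnot(ml_rms_cm >= 0, ap_rms_cm >= 0, sway_bandwidth_hz > 0)
  n <- round(duration_s * fs)
  if (n < 2) stop("need at least 2 samples: increase `duration_s` or `fs`")
  tibble::tibble(
    t = (seq_len(n) - 1) / fs,
    dx_cm = sway_channel(ml_rms_cm, sway_bandwidth_hz, n, fs, seed),
    dy_cm = sway_channel(ap_rms_cm, sway_bandwidth_hz, n, fs, seed + 1L)
  )
}

#' Convert a ground sway path to quasi-static tri-axial acceleration
#'
#' Inverts the inverted-pendulum ground projection under the quasi-static
#' assumption that the resultant acceleration is 1 g: `a_x = -(d_x/L)`,
#' `a_y = -(d_y/L)`, `a_z = sqrt(1 - a_x^2 - a_y^2)` (all in g).  Feeding
#' the output back through [project_sway()] recovers the path exactly.
#'
#' @param dx_cm,dy_cm Ground displacement series (cm).
#' @param L_cm Centre-of-mass height above ground (cm).
#'
#' @return A tibble with columns `ax_g`, `ay_g`, `az_g`.
#' @export
sway_to_accel <- function(dx_cm, dy_cm, L_cm) {
  stopifnot(length(dx_cm) == length(dy_cm), L_cm > 0)
  if (any(abs(dx_cm) >= L_cm) || any(abs(dy_cm) >= L_cm))
    stop("pendulum geometry violated: |displacement| must be < L")
  ax <- -dx_cm / L_cm
  ay <- -dy_cm / L_cm
  s2 <- 1 - ax^2 - ay^2
  if (any(s2 < 0))
    stop("pendulum geometry violated: dx^2 + dy^2 must be < L^2")
  tibble::tibble(ax_g = ax, ay_g = ay, az_g = sqrt(s2))
}

#' Quantize an acceleration series to integer sensor counts
#'
#' Adds Gaussian sensor noise, scales by the accelerometer sensitivity
#' (LSB/g), rounds to the nearest integer and clips to the full-scale range
#' `[-full_scale * sensitivity, full_scale * sensitivity - 1]`, emulating a
#' two's-complement digital output (16,384 LSB/g at the +/-2 g range).
#'
#' @param accel_g Acceleration series in g.
#' @param sensitivity Sensitivity scale factor (LSB/g), default 16384.
#' @param full_scale Full-scale range in g, default 2.
#' @param noise_sd Sensor noise standard deviation (g).
#' @param seed Integer seed for the noise draw (ignored when `noise_sd = 0`).
#'
#' @return Integer LSB series.
#' @export
#' @examples
#' quantize_to_lsb(1, noise_sd = 0) # 16384
quantize_to_lsb <- function(accel_g, sensitivity = 16384, full_scale = 2,
                            noise_sd = 0, seed = 1) {
  stopifnot(sensitivity > 0, full_scale > 0, noise_sd >= 0)
  if (noise_sd > 0)
    accel_g <- accel_g +
      withr::with_seed(seed, rnorm(length(accel_g), 0, noise_sd))
  counts <- round(accel_g * sensitivity)
  lo <- -full_scale * sensitivity
  hi <- full_scale * sensitivity - 1
  as.integer(pmin(pmax(counts, lo), hi))
}

#' Simulate an mCTSIB accelerometer cohort
#'
#' Generates one 30 s tri-axial recording per subject and condition: a
#' band-limited sway path with condition-specific RMS targets, mapped to
#' quasi-static tri-axial acceleration through the subject's pendulum lever
#' arm, then corrupted with sensor noise and quantized to integer counts.
#' Between-subject variability comes from two per-subject lognormal factors:
#' one on the RMS amplitude targets (sd `amplitude_jitter_sd` on the log
#' scale) and one on the sway bandwidth (sd `bandwidth_jitter_sd`), which
#' spreads the position/velocity/acceleration RMS ratios the way real
#' cohorts do.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param conditions Condition specification tibble, see
#'   [mctsib_conditions()].
#' @param profiles Optional subject profile tibble ([subject_profiles()]);
#'   generated from `seed` when `NULL`.
#' @param fs Sampling rate (Hz, default 60).
#' @param duration_s Duration per condition (s, default 30).
#' @param sensitivity Accelerometer sensitivity (LSB/g, default 16384).
#' @param full_scale Full-scale range (g, default 2).
#' @param noise_sd Sensor noise sd (g, default 5e-4, a low-pass-configured
#'   MEMS accelerometer noise floor).
#' @param amplitude_jitter_sd,bandwidth_jitter_sd Log-scale sd of the
#'   per-subject multiplicative jitters.
#' @param seed Master integer seed; all stream seeds derive from it via
#'   [derive_seed()].
#'
#' @return A nested tibble with one row per recording: `subject_id`,
#'   `condition`, `height_cm`, `com_height_cm`, `fs`, and a `data` list
#'   column of tibbles with columns `t`, `x`, `y`, `z` (integer LSB).
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 2, duration_s = 5, seed = 1)
#' nrow(cohort) # 8 recordings
simulate_cohort <- function(n_subjects = 23,
                            conditions = mctsib_conditions(),
                            profiles = NULL,
                            fs = 60, duration_s = 30,
                            sensitivity = 16384, full_scale = 2,
                            noise_sd = 5e-4,
                            amplitude_jitter_sd = 0.15,
                            bandwidth_jitter_sd = 0.7,
                            seed = 1) {
  stopifnot(nrow(conditions) == 4, fs > 0, duration_s > 0, sensitivity > 0)
  if (is.null(profiles))
    profiles <- subject_profiles(n_subjects, seed = derive_seed(seed, 0, 0, 7))
  stopifnot(nrow(profiles) >= n_subjects)
  profiles <- profiles[seq_len(n_subjects), ]

  jit <- withr::with_seed(derive_seed(seed, 0, 0, 6), list(
    amp = exp(rnorm(n_subjects, 0, amplitude_jitter_sd)),
    bw = exp(rnorm(n_subjects, 0, bandwidth_jitter_sd))
  ))

  grid <- tidyr::expand_grid(s = seq_len(n_subjects), c = seq_len(4))
  recs <- purrr::pmap(grid, function(s, c) {
    spec <- conditions[c, ]
    prof <- profiles[s, ]
    # keep the sway process inside the 4 Hz analysis band
    bw <- min(max(spec$sway_bandwidth_hz * jit$bw[s], 0.2), 3, 0.45 * fs)
    path <- generate_sway_path(
      ml_rms_cm = spec$ml_rms_cm * jit$amp[s],
      ap_rms_cm = spec$ap_rms_cm * jit$amp[s],
      duration_s = duration_s, fs = fs,
      seed = derive_seed(seed, s %% 32, c, 0),
      sway_bandwidth_hz = bw
    )
    acc <- sway_to_accel(path$dx_cm, path$dy_cm, prof$com_height_cm)
    tibble::tibble(
      t = path$t,
      x = quantize_to_lsb(acc$ax_g, sensitivity, full_scale, noise_sd,
                          derive_seed(seed, s %% 32, c, 1)),
      y = quantize_to_lsb(acc$ay_g, sensitivity, full_scale, noise_sd,
                          derive_seed(seed, s %% 32, c, 2)),
      z = quantize_to_lsb(acc$az_g, sensitivity, full_scale, noise_sd,
                          derive_seed(seed, s %% 32, c, 3))
    )
  })

  out <- tibble::tibble(
    subject_id = profiles$subject_id[grid$s],
    condition = grid$c,
    height_cm = profiles$height_cm[grid$s],
    com_height_cm = profiles$com_height_cm[grid$s],
    fs = fs,
    data = recs
  )
  attr(out, "sensitivity") <- sensitivity
  attr(out, "full_scale") <- full_scale
  out
}

#' Write a cohort to recording CSVs plus a manifest
#'
#' One CSV per subject x condition named `S<id>_C<condition>.csv` with
#' header `t,x,y,z` (t in seconds, x/y/z integer LSB), and a manifest CSV
#' `manifest.csv` with columns
#' `subject_id,height_cm,L_cm,condition,file`.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("S%d_C%d.csv", cohort$subject_id, cohort$condition)
  purrr::walk2(cohort$data, files,
               ~ readr::write_csv(.x, file.path(dir, .y)))
  manifest <- tibble::tibble(
    subject_id = cohort$subject_id,
    height_cm = cohort$height_cm,
    L_cm = cohort$com_height_cm,
    condition = cohort$condition,
    file = files
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort back from a manifest directory
#'
#' @param dir Directory containing `manifest.csv` and the recording CSVs
#'   written by [write_cohort()].
#' @param fs Sampling rate (Hz) of the recordings.
#' @return A cohort tibble in the [simulate_cohort()] layout.
#' @export
read_cohort <- function(dir, fs = 60) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  tibble::tibble(
    subject_id = manifest$subject_id,
    condition = manifest$condition,
    height_cm = manifest$height_cm,
    com_height_cm = manifest$L_cm,
    fs = fs,
    data = purrr::map(manifest$file, ~ readr::read_csv(
      file.path(dir, .x), show_col_types = FALSE,
      col_types = readr::cols(
        t = readr::col_double(),
        x = readr::col_integer(),
        y = readr::col_integer(),
        z = readr::col_integer()
      )))
  )
}
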