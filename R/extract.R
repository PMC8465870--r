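#' Convert integer sensor counts to acceleration in g
#'
#' Divides the digital output (LSB) by the accelerometer's sensitivity
#' scale factor (LSB/g); 16,384 LSB/g corresponds to the +/-2 g full-scale
#' range.
#'
#' @param raw Integer (or numeric) LSB series.
#' @param sensitivity Sensitivity scale factor in LSB/g; must be positive.
#' @return Numeric series in g.
#' @export
#' @examples
#' lsb_to_g(16384) # 1 g
lsb_to_g <- function(raw, sensitivity = 16384) {
  if (!is.numeric(sensitivity) || length(sensitivity) != 1 || sensitivity <= 0)
    stop("`sensitivity` must be a single positive number (LSB/g)")
  as.numeric(raw) / sensitivity
}

#' Low-pass filter an acceleration channel
#'
#' Second-order Butterworth low-pass at 4 Hz (defaults), applied causally in
#' a single forward pass with unit DC gain.  The filter state is initialised
#' at steady state for the first sample value, so a channel resting at a
#' constant (e.g. the gravity-dominated vertical axis) passes through
#' without a start-up transient.  A zero-phase two-pass variant is available
#' but doubles the effective order, so it is off by default.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cut-off frequency (Hz), must lie in (0, fs/2).
#' @param order Filter order (default 2).
#' @param zero_phase If `TRUE`, filter forward and backward (zero phase lag,
#'   squared magnitude response).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_sway <- function(x, fs, cutoff = 4, order = 2, zero_phase = FALSE) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("`cutoff` must lie strictly between 0 and the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # pole decay ~ exp(-4.4 * cutoff / fs) per sample: 8 fs/cutoff settles
  # the start-up transient below 1e-12
  pad <- ceiling(8 * fs / cutoff)
  run <- function(v) {
    y <- as.numeric(signal::filter(bf, c(rep(v[1], pad), v)))
    y[-seq_len(pad)]
  }
  y <- run(x)
  if (zero_phase) y <- rev(run(rev(y)))
  y
}

#' Project tri-axial acceleration to ground sway displacement
#'
#' Inverted-pendulum ground projection: the resultant acceleration
#' `R = sqrt(a_x^2 + a_y^2 + a_z^2)` defines directional cosines
#' `cos(alpha) = a_x / R`, `cos(beta) = a_y / R`, `cos(gamma) = a_z / R`,
#' from which the centre-of-mass ground displacements follow as
#' `d_x = -L cos(alpha)`, `d_y = -L cos(beta)` and the projected height as
#' `H = L cos(gamma)`, with `L` the (constant) centre-of-mass height.  The
#' projection depends only on the direction of the acceleration vector, so
#' it is invariant to the acceleration units.
#'
#' @param ax,ay,az Tri-axial acceleration series (any common unit).
#' @param L_cm Centre-of-mass height above ground (cm).
#' @return A tibble with columns `R`, `cos_alpha`, `cos_beta`, `cos_gamma`,
#'   `dx_cm`, `dy_cm`, `H_cm`.
#' @export
#' @examples
#' project_sway(0, 0, 1, L_cm = 100) # upright: dx = dy = 0, H = 100
project_sway <- function(ax, ay, az, L_cm) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  if (L_cm <= 0) stop("`L_cm` must be positive")
  R <- sqrt(ax^2 + ay^2 + az^2)
  bad <- which(R == 0)
  if (length(bad))
    stop("degenerate sample: zero resultant acceleration at index ", bad[1])
  tibble::tibble(
    R = R,
    cos_alpha = ax / R,
    cos_beta = ay / R,
    cos_gamma = az / R,
    dx_cm = -L_cm * ax / R,
    dy_cm = -L_cm * ay / R,
    H_cm = L_cm * az / R
  )
}

#' Sway kinematics by first differences
#'
#' Removes the inclination offset by subtracting the first displacement
#' sample (`D_n = d_n - d_1`), then forms velocity and acceleration by
#' first differences with sampling period `T = 1/fs`:
#' `V_n = (D_n - D_{n-1}) / T`, `A_n = (V_n - V_{n-1}) / T`.  Leading
#' undefined entries are dropped, so position spans samples 1..N, velocity
#' 2..N and acceleration 3..N.
#'
#' @param d_cm Displacement series (cm), length >= 3.
#' @param fs Sampling rate (Hz).
#' @return An object of class `sway_kinematics`: a list with elements
#'   `position` (cm), `velocity` (cm/s), `acceleration` (cm/s^2), `fs`.
#' @export
#' @examples
#' derive_kinematics(c(0, 1, 2), fs = 60)$velocity # 60 60
derive_kinematics <- function(d_cm, fs) {
  if (length(d_cm) < 3)
    stop("insufficient data: need at least 3 samples")
  stopifnot(fs > 0)
  D <- d_cm - d_cm[1]
  V <- diff(D) * fs
  A <- diff(V) * fs
  structure(list(position = D, velocity = V, acceleration = A, fs = fs),
            class = "sway_kinematics")
}

#' Root-mean-square sway features
#'
#' RMS of each kinematic component over its own valid length:
#' `D_RMS = sqrt(mean(D_n^2))` and likewise for velocity and acceleration.
#'
#' @param kin A [derive_kinematics()] result.
#' @return A one-row tibble with columns `rms_position_cm`,
#'   `rms_velocity_cms`, `rms_acceleration_cms2`.
#' @export
rms_features <- function(kin) {
  stopifnot(inherits(kin, "sway_kinematics"))
  rms <- function(v) sqrt(mean(v^2))
  tibble::tibble(
    rms_position_cm = rms(kin$position),
    rms_velocity_cms = rms(kin$velocity),
    rms_acceleration_cms2 = rms(kin$acceleration)
  )
}

#' Extract ML/AP sway features from a cohort of raw recordings
#'
#' Full first-stage chain per recording: LSB -> g conversion, 4 Hz
#' second-order Butterworth low-pass per axis, inverted-pendulum ground
#' projection with the subject's centre-of-mass height, first-difference
#' kinematics per direction, and RMS feature computation.  Sensor axes map
#' to body directions through `axis_map` (device worn on the lower back:
#' x = mediolateral, y = anterior-posterior, z = vertical by default).
#'
#' @param cohort Cohort tibble ([simulate_cohort()] / [read_cohort()]).
#' @param sensitivity Sensitivity (LSB/g); taken from the cohort attribute
#'   when present.
#' @param cutoff,order Low-pass parameters (Hz / filter order).
#' @param axis_map Named character vector mapping directions `ml`, `ap` to
#'   recording columns.
#' @param zero_phase Passed to [lowpass_sway()].
#' @return A tibble with one row per subject x condition x direction:
#'   `subject_id`, `condition`, `direction` ("ML"/"AP"),
#'   `rms_position_cm`, `rms_velocity_cms`, `rms_acceleration_cms2`.
#' @export
extract_sway_features <- function(cohort, sensitivity = NULL,
                                  cutoff = 4, order = 2,
                                  axis_map = c(ml = "x", ap = "y"),
                                  zero_phase = FALSE) {
  stopifnot(all(c("ml", "ap") %in% names(axis_map)),
            all(axis_map[c("ml", "ap")] %in% c("x", "y")))
  if (is.null(sensitivity))
    sensitivity <- attr(cohort, "sensitivity") %||% 16384
  rows <- purrr::pmap(
    list(cohort$data, cohort$com_height_cm, cohort$fs,
         cohort$subject_id, cohort$condition),
    function(rec, L, fs, sid, cond) {
      g <- purrr::map(rec[c("x", "y", "z")],
                      ~ lowpass_sway(lsb_to_g(.x, sensitivity), fs,
                                     cutoff, order, zero_phase))
      sw <- project_sway(g$x, g$y, g$z, L)
      disp <- list(
        ML = sw[[paste0("d", substr(axis_map[["ml"]], 1, 1), "_cm")]],
        AP = sw[[paste0("d", substr(axis_map[["ap"]], 1, 1), "_cm")]]
      )
      purrr::imap_dfr(disp, function(d, dir) {
        dplyr::bind_cols(
          tibble::tibble(subject_id = sid, condition = cond, direction = dir),
          rms_features(derive_kinematics(d, fs))
        )
      })
    })
  dplyr::bind_rows(rows)
}

#' Write / read a sway feature table
#'
#' CSV layout: `subject_id,condition,direction,rms_position_cm,
#' rms_velocity_cms,rms_acceleration_cms2`.
#'
#' @param features Feature tibble from [extract_sway_features()].
#' @param path CSV path.
#' @return `write_features()` returns `features` invisibly;
#'   `read_features()` returns the tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
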