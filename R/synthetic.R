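with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a participant-by-visit loading table
#'
#' Two-way data with additive participant and visit components:
#' `loading(i, j) = target + b_i + e_ij`, with `b_i ~ N(0, sd_between^2)`
#' (stable participant offsets, e.g. rigging idiosyncrasies) and
#' `e_ij ~ N(0, sd_within^2)` (per-visit noise). The implied single-measures
#' agreement ICC, `sd_between^2 / (sd_between^2 + sd_within^2)`, is attached
#' as attribute `true_icc`, and the target as `target_pct`.
#'
#' Defaults mirror a three-visit lunar-gravity standing study: 19
#' participants, 16.5 %BW target, and 2 %BW for both noise components
#' (total per-visit sd ~2.8 %BW).
#'
#' @param n_participants,n_visits Table dimensions.
#' @param target_pct Target loading, %BW.
#' @param sd_between,sd_within Between-participant and within-participant
#'   standard deviations, %BW (>= 0).
#' @param seed Optional integer seed; a fixed seed reproduces the table
#'   exactly and leaves the global RNG state untouched.
#' @return A long tibble `participant`, `visit`, `loading_pct` with
#'   attributes `true_icc` and `target_pct`.
#' @examples
#' sim_loading_table(n_participants = 6, seed = 42)
#' @export
sim_loading_table <- function(n_participants = 19, n_visits = 3,
                              target_pct = 16.5,
                              sd_between = 2, sd_within = 2, seed = NULL) {
  if (sd_between < 0 || sd_within < 0) abort("standard deviations must be >= 0")
  tab <- with_seed_maybe(seed, {
    b <- rnorm(n_participants, 0, sd_between)
    tidyr::crossing(participant = seq_len(n_participants),
                    visit = paste0("v", seq_len(n_visits))) |>
      dplyr::mutate(loading_pct = target_pct + b[.data$participant] +
                      rnorm(dplyr::n(), 0, sd_within))
  })
  true_icc <- if (sd_between == 0 && sd_within == 0) 1 else
    sd_between^2 / (sd_between^2 + sd_within^2)
  attr(tab, "true_icc") <- true_icc
  attr(tab, "target_pct") <- target_pct
  tab
}

#' Simulate a quasi-static standing force-platform trial
#'
#' Generates a constant axial load equal to `true_loading_pct` of bodyweight
#' plus low-pass-shaped Gaussian noise (white noise filtered to 20 Hz and
#' rescaled to `noise_sd_n`), emulating a participant standing quietly on
#' the plate. When `fy_fraction > 0` the load is split between the vertical
#' and anteroposterior channels (foot not perfectly perpendicular to the
#' plate) such that the Fz-Fy resultant carries the full load.
#'
#' @param duration_s Trial length, s.
#' @param sample_rate_hz Sampling rate, Hz (default 2000).
#' @param true_loading_pct Ground-truth loading, %BW.
#' @param bodyweight_n Earth bodyweight, N.
#' @param noise_sd_n Noise standard deviation, N (default 5).
#' @param fy_fraction Fraction of the resultant carried by the
#'   anteroposterior channel, in \[0, 1) (default 0: no `fy_n` column).
#' @param seed Optional integer seed.
#' @return A trial tibble (`time_s`, `fz_n`, optionally `fy_n`) with
#'   attributes `true_loading_pct` and `bodyweight_n`.
#' @examples
#' trial <- sim_standing_trial(duration_s = 5, sample_rate_hz = 200,
#'                             true_loading_pct = 16.5,
#'                             bodyweight_n = 77.3 * 9.81, seed = 1)
#' standing_loading(trial, 77.3 * 9.81, window_s = 3)
#' @export
sim_standing_trial <- function(duration_s = 30, sample_rate_hz = 2000,
                               true_loading_pct = 16.5, bodyweight_n,
                               noise_sd_n = 5, fy_fraction = 0, seed = NULL) {
  if (duration_s <= 0 || sample_rate_hz <= 0) {
    abort("`duration_s` and `sample_rate_hz` must be positive")
  }
  if (fy_fraction < 0 || fy_fraction >= 1) {
    abort("`fy_fraction` must lie in [0, 1)")
  }
  n <- floor(duration_s * sample_rate_hz) + 1
  time_s <- (seq_len(n) - 1) / sample_rate_hz
  force <- true_loading_pct * bodyweight_n / 100
  noise <- with_seed_maybe(seed, {
    raw <- rnorm(n + 2000)
    if (noise_sd_n > 0 && sample_rate_hz > 50) {
      bf <- signal::butter(2, min(20 / (sample_rate_hz / 2), 0.99), "low")
      shaped <- as.numeric(signal::filter(bf, raw))[-seq_len(2000)]
      shaped / sd(shaped) * noise_sd_n
    } else {
      raw[-seq_len(2000)] * noise_sd_n
    }
  })
  fz_share <- sqrt(1 - fy_fraction^2)
  trial <- tibble::tibble(time_s = time_s,
                          fz_n = force * fz_share + noise * fz_share)
  if (fy_fraction > 0) {
    trial$fy_n <- force * fy_fraction + noise * fy_fraction
  }
  attr(trial, "true_loading_pct") <- true_loading_pct
  attr(trial, "bodyweight_n") <- bodyweight_n
  trial
}

#' Simulate a manikin suspension campaign
#'
#' Repeats suspensions at a set of tilt angles and summarises measured
#' loading per condition, with the same schema as
#' `validation_table("manikin_graded")` for drop-in comparison. Each trial's
#' measured loading is `100 sin(theta) + bias + noise`, with Gaussian
#' trial-to-trial noise.
#'
#' @param angles_deg Tilt angles, degrees, each in \[0, 30\].
#' @param reps Trials per condition (default 30).
#' @param noise_sd_pct Trial-to-trial noise sd, %BW (default 0.7).
#' @param bias_pct Constant measurement offset, %BW (default 0).
#' @param seed Optional integer seed.
#' @return A tibble `gravity_g`, `plate_angle_deg`, `target_pct`,
#'   `measured_pct`, `measured_sd`, `n_trials`, one row per angle, plus the
#'   per-trial values as attribute `trials`.
#' @examples
#' sim_manikin_campaign(c(0, 9.5, 11.5), reps = 5, seed = 7)
#' @export
sim_manikin_campaign <- function(angles_deg, reps = 30, noise_sd_pct = 0.7,
                                 bias_pct = 0, seed = NULL) {
  if (any(angles_deg < 0) || any(angles_deg > 30)) {
    abort("`angles_deg` must lie in [0, 30]")
  }
  trials <- with_seed_maybe(seed, {
    tidyr::crossing(theta_deg = angles_deg, rep = seq_len(reps)) |>
      dplyr::mutate(
        target_pct = axial_loading_pct(.data$theta_deg),
        measured_pct = .data$target_pct + bias_pct +
          rnorm(dplyr::n(), 0, noise_sd_pct))
  })
  summary <- dplyr::summarise(
    dplyr::group_by(trials, .data$theta_deg),
    gravity_g = sin(deg2rad(.data$theta_deg[1])),
    plate_angle_deg = foot_plate_angle(.data$theta_deg[1]),
    target_pct = .data$target_pct[1],
    measured_sd = if (dplyr::n() > 1) sd(.data$measured_pct) else 0,
    measured_pct = mean(.data$measured_pct),
    n_trials = dplyr::n(),
    .groups = "drop")
  out <- dplyr::select(summary, "gravity_g", "plate_angle_deg", "target_pct",
                       "measured_pct", "measured_sd", "n_trials")
  attr(out, "trials") <- trials
  out
}
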