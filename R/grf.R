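#' Read and write force-platform trial files
#'
#' Trials are delimited text with one header line and columns `time_s`,
#' `Fz_N` and optionally `Fy_N` (vertical and anteroposterior ground reaction
#' force). Column names are matched case-insensitively and normalised to
#' `time_s`, `fz_n`, `fy_n`.
#'
#' @param path File path.
#' @return `read_trial()`: a tibble of samples. `write_trial()`: the input,
#'   invisibly.
#' @export
read_trial <- function(path) {
  x <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(x) <- tolower(names(x))
  needed <- c("time_s", "fz_n")
  if (!all(needed %in% names(x))) {
    abort("trial file must have columns time_s and Fz_N (Fy_N optional)")
  }
  keep <- intersect(c("time_s", "fz_n", "fy_n"), names(x))
  tibble::as_tibble(x[keep])
}

#' @rdname read_trial
#' @param trial A trial tibble with `time_s`, `fz_n` and optionally `fy_n`.
#' @export
write_trial <- function(trial, path) {
  out <- trial
  names(out) <- c(time_s = "time_s", fz_n = "Fz_N", fy_n = "Fy_N")[names(trial)]
  readr::write_csv(out, path)
  invisible(trial)
}

sample_rate_of <- function(trial) {
  dt <- diff(trial$time_s)
  if (length(dt) < 1 || any(dt <= 0)) {
    abort("`time_s` must be strictly increasing with at least 2 samples")
  }
  1 / stats::median(dt)
}

#' Zero-phase Butterworth low-pass filter for force channels
#'
#' Applies a Butterworth low-pass of the stated design order to every force
#' column (`fz_n`, `fy_n`), forward and backward (zero phase), leaving time
#' untouched. DC gain is exactly 1, so static loads pass unchanged. Typical
#' settings for standing/locomotion force data are 20 Hz at order 2 or 50 Hz
#' at order 4.
#'
#' @param trial A trial tibble (see [read_trial()]).
#' @param cutoff_hz Cut-off frequency; must be below the Nyquist frequency.
#' @param order Filter design order (default 2).
#' @param sample_rate_hz Sampling rate; inferred from `time_s` when NULL.
#' @return The trial with filtered force columns; attribute `filtered` set to
#'   TRUE so windowed means know to trim edge transients.
#' @export
grf_lowpass <- function(trial, cutoff_hz, order = 2, sample_rate_hz = NULL) {
  if (is.null(sample_rate_hz)) sample_rate_hz <- sample_rate_of(trial)
  nyquist <- sample_rate_hz / 2
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1 ||
      cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    abort(sprintf("`cutoff_hz` must lie in (0, %.1f) Hz (below Nyquist)", nyquist))
  }
  if (!is.numeric(order) || length(order) != 1 || order < 1 ||
      order != round(order)) {
    abort("`order` must be a positive integer")
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  out <- trial
  n <- nrow(trial)
  # odd-reflection padding so start-up transients die inside the pad, not the
  # record (the plain forward-backward pass assumes zero initial conditions)
  pad <- min(n - 1, ceiling(10 * sample_rate_hz / cutoff_hz))
  for (col in intersect(c("fz_n", "fy_n"), names(trial))) {
    x <- trial[[col]]
    front <- 2 * x[1] - x[(pad + 1):2]
    back <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(front, x, back)))
    out[[col]] <- y[(pad + 1):(pad + n)]
  }
  attr(out, "filtered") <- TRUE
  out
}

#' Resultant of vertical and anteroposterior force
#'
#' Per-sample magnitude `sqrt(Fz^2 + Fy^2)`, used when foot placement is not
#' perfectly perpendicular to the plate so part of the axial load registers
#' on the anteroposterior channel.
#'
#' @param fz_n,fy_n Equal-length force vectors, N.
#' @return Resultant force vector, N; pointwise >= `abs(fz_n)`.
#' @examples
#' resultant_force(3, 4)  # 5
#' @export
resultant_force <- function(fz_n, fy_n) {
  if (length(fz_n) != length(fy_n)) {
    abort("`fz_n` and `fy_n` must have equal length")
  }
  sqrt(fz_n^2 + fy_n^2)
}

#' Standing weight-bearing from a force-platform trial
#'
#' Mean force over the final `window_s` seconds of the trial, expressed as a
#' percentage of same-day Earth bodyweight. Optionally low-pass filters first
#' and/or uses the Fz-Fy resultant. When a filter was applied (here or
#' upstream), 0.5 s at each end of the record is excluded before the window
#' is taken, to avoid edge transients. A per-trial baseline offset (platform
#' zeroing error) is subtracted before analysis.
#'
#' @param trial A trial tibble (see [read_trial()]).
#' @param bodyweight_n Same-day bodyweight in N (mass x g).
#' @param window_s Averaging window in seconds; must fit inside the usable
#'   record.
#' @param use_resultant Use `sqrt(fz^2 + fy^2)` instead of `fz` (requires an
#'   `fy_n` column). Default FALSE.
#' @param filter NULL for no filtering, or a list with elements `cutoff_hz`
#'   and `order` passed to [grf_lowpass()].
#' @param baseline_n Baseline offset subtracted from every force channel, N.
#' @param edge_trim_s Edge exclusion applied when the signal was filtered
#'   (default 0.5 s).
#' @return A one-row tibble: `mean_force_n`, `loading_pct`
#'   (`100 * mean_force / bodyweight`), `window_s`, `n_samples`.
#' @examples
#' trial <- tibble::tibble(time_s = seq(0, 30, by = 1 / 200),
#'                         fz_n = rep(125, 6001))
#' standing_loading(trial, bodyweight_n = 77.3 * 9.81, window_s = 10)
#' @export
standing_loading <- function(trial, bodyweight_n, window_s,
                             use_resultant = FALSE, filter = NULL,
                             baseline_n = 0, edge_trim_s = 0.5) {
  if (!is.numeric(bodyweight_n) || length(bodyweight_n) != 1 ||
      bodyweight_n <= 0) {
    abort("`bodyweight_n` must be a single positive bodyweight in N")
  }
  if (!is.null(filter)) {
    trial <- grf_lowpass(trial, cutoff_hz = filter$cutoff_hz,
                         order = filter$order %||% 2)
  }
  filtered <- isTRUE(attr(trial, "filtered"))
  force <- if (use_resultant) {
    if (!"fy_n" %in% names(trial)) {
      abort("`use_resultant = TRUE` requires an `fy_n` column")
    }
    resultant_force(trial$fz_n - baseline_n, trial$fy_n)
  } else {
    trial$fz_n - baseline_n
  }
  t <- trial$time_s
  t_end <- max(t) - if (filtered) edge_trim_s else 0
  t_start_min <- min(t) + if (filtered) edge_trim_s else 0
  if (window_s <= 0 || t_end - window_s < t_start_min - 1e-9) {
    abort("`window_s` does not fit inside the usable record")
  }
  keep <- t >= t_end - window_s & t <= t_end
  mean_force <- mean(force[keep])
  tibble::tibble(
    mean_force_n = mean_force,
    loading_pct = 100 * mean_force / bodyweight_n,
    window_s = window_s,
    n_samples = sum(keep)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
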