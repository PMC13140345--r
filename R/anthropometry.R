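#' Default body-segment fraction table
#'
#' Per-rope-group mass fractions and attachment-height fractions used to plan
#' a suspension. Each suspended body region is served by one rope group:
#' `thorax` (head, neck, thorax and arms on one central rope), `pelvis` (one
#' central rope), `knee` (left + right ropes carrying the thighs and the upper
#' half of each shank) and `ankle` (left + right ropes carrying the lower half
#' of each shank and the feet). Mass fractions are the group totals (both
#' sides for bilateral groups) derived from standard anthropometric segment
#' fractions, with the shank split 50/50 between the knee and ankle ropes;
#' they sum to exactly 1. Attachment-height fractions locate each rope's
#' attachment along the body axis as a fraction of stature, measured from the
#' foot plate.
#'
#' The table is an implementation default, not a measured constant: alternate
#' segment models drop in via the `segments` argument of [body_model()] or a
#' plain-text table read with [read_segment_table()].
#'
#' @return A tibble with columns `rope` (ankle, knee, pelvis, thorax, in
#'   ascending attachment height), `mass_fraction` (of total body mass, group
#'   total), `height_fraction` (of stature) and `bilateral` (logical; TRUE for
#'   the leg groups that are rigged one rope per side).
#' @examples
#' hutsim_segments()
#' @export
hutsim_segments <- function() {
  tibble::tibble(
    rope = c("ankle", "knee", "pelvis", "thorax"),
    mass_fraction = c(0.075, 0.247, 0.150, 0.528),
    height_fraction = c(0.039, 0.285, 0.53, 0.81),
    bilateral = c(TRUE, TRUE, FALSE, FALSE)
  )
}

validate_segments <- function(segments) {
  required <- c("rope", "mass_fraction", "height_fraction", "bilateral")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0) {
    abort(paste0("`segments` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!identical(segments$rope, c("ankle", "knee", "pelvis", "thorax"))) {
    abort("`segments$rope` must be exactly ankle, knee, pelvis, thorax (in that order)")
  }
  if (any(segments$mass_fraction <= 0) || any(segments$mass_fraction >= 1)) {
    abort("`mass_fraction` values must lie strictly between 0 and 1")
  }
  if (abs(sum(segments$mass_fraction) - 1) > 1e-9) {
    abort(sprintf("`mass_fraction` must sum to 1 (got %.12f)",
                  sum(segments$mass_fraction)))
  }
  if (any(segments$height_fraction <= 0) || any(segments$height_fraction >= 1)) {
    abort("`height_fraction` values must lie strictly between 0 and 1")
  }
  if (any(diff(segments$height_fraction) <= 0)) {
    abort("`height_fraction` must strictly increase ankle -> knee -> pelvis -> thorax")
  }
  invisible(segments)
}

#' Read a body-segment fraction table from a delimited text file
#'
#' Expects a header line and the columns `rope`, `mass_fraction`,
#' `height_fraction`, `bilateral`, one row per rope group in ascending
#' attachment order (ankle, knee, pelvis, thorax). The packaged default lives
#' at `system.file("extdata", "segment_fractions.csv", package = "hutsim")`.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A validated segment tibble (see [hutsim_segments()]).
#' @export
read_segment_table <- function(path) {
  segments <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  segments <- tibble::as_tibble(segments)
  segments$bilateral <- as.logical(segments$bilateral)
  validate_segments(segments)
  segments[c("rope", "mass_fraction", "height_fraction", "bilateral")]
}

#' Build a body model for suspension planning
#'
#' Scales a segment-fraction table to one participant, giving per-rope-group
#' masses and attachment heights along the body axis (measured from the foot
#' plate). The height and mass windows reflect the rig's design envelope and
#' safe working load.
#'
#' @param height_m Stature in metres; must lie in (1.0, 2.3).
#' @param mass_kg Body mass in kilograms; must lie in (30, 125), the safe
#'   working load of the suspension rig.
#' @param segments Segment-fraction table; defaults to [hutsim_segments()].
#' @return A `body_model` tibble with one row per rope group and columns
#'   `rope`, `mass_fraction`, `height_fraction`, `bilateral`,
#'   `segment_mass_kg` and `attachment_height_m`, carrying `height_m` and
#'   `mass_kg` as attributes.
#' @examples
#' body_model(1.75, 77.3)
#' @export
body_model <- function(height_m, mass_kg, segments = hutsim_segments()) {
  if (!is.numeric(height_m) || length(height_m) != 1 ||
      height_m <= 1.0 || height_m >= 2.3) {
    abort("`height_m` must be a single value in (1.0, 2.3) m")
  }
  if (!is.numeric(mass_kg) || length(mass_kg) != 1 ||
      mass_kg <= 30 || mass_kg >= 125) {
    abort("`mass_kg` must be a single value in (30, 125) kg (safe working load)")
  }
  validate_segments(segments)
  body <- dplyr::mutate(
    segments,
    segment_mass_kg = .data$mass_fraction * mass_kg,
    attachment_height_m = .data$height_fraction * height_m
  )
  attr(body, "height_m") <- height_m
  attr(body, "mass_kg") <- mass_kg
  class(body) <- c("body_model", class(body))
  body
}

assert_body_model <- function(body) {
  if (!inherits(body, "body_model")) {
    abort("`body` must be a `body_model` created by `body_model()`")
  }
  invisible(body)
}

#' Axial offsets of each rope attachment relative to the ankle
#'
#' Distance along the body axis from the ankle rope attachment to each
#' subsequent rope group's attachment. The ankle is the reference segment, so
#' its offset is zero.
#'
#' @param body A [body_model()].
#' @return A tibble with columns `rope` and `d_axial_m`.
#' @examples
#' axial_offsets(body_model(1.75, 77.3))
#' @export
axial_offsets <- function(body) {
  assert_body_model(body)
  height_m <- attr(body, "height_m")
  tibble::tibble(
    rope = body$rope,
    d_axial_m = (body$height_fraction - body$height_fraction[1]) * height_m
  )
}

#' Counterbalance loads per suspension rope
#'
#' Each rope's constant-force balance is set to the weight of the body region
#' it carries, rendering that region weightless transverse to the body axis.
#' Bilateral groups (knee, ankle) are reported one row per side, each side
#' carrying half the group mass; the central pelvis and thorax ropes get the
#' full group mass.
#'
#' @param body A [body_model()].
#' @param gravity Gravitational acceleration in m s^-2 (default 9.81).
#' @return A tibble with columns `rope`, `side` (left/right/centre),
#'   `mass_kg`, `force_n` and `kg_equivalent` (the dial setting of a balance
#'   graduated in kg). Forces over all rows sum to total body weight.
#' @examples
#' counterbalance_loads(body_model(1.80, 80))
#' @export
counterbalance_loads <- function(body, gravity = GRAVITY_EARTH) {
  assert_body_model(body)
  if (!is.numeric(gravity) || length(gravity) != 1 || gravity <= 0) {
    abort("`gravity` must be a single positive value in m s^-2")
  }
  per_rope <- purrr::pmap_dfr(
    body[c("rope", "segment_mass_kg", "bilateral")],
    function(rope, segment_mass_kg, bilateral) {
      if (bilateral) {
        tibble::tibble(rope = rope, side = c("left", "right"),
                       mass_kg = segment_mass_kg / 2)
      } else {
        tibble::tibble(rope = rope, side = "centre", mass_kg = segment_mass_kg)
      }
    }
  )
  dplyr::mutate(per_rope,
                force_n = .data$mass_kg * gravity,
                kg_equivalent = .data$mass_kg)
}
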