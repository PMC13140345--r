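#' Axial acceleration at a head-up tilt angle
#'
#' In head-up-tilt (HUT) suspension the component of Earth's gravity acting
#' along the head-to-foot axis of the body is `g * sin(theta)`. Tilting to
#' 9.5 deg therefore simulates lunar gravity (0.17 g) and 22.3 deg Martian
#' gravity (0.38 g).
#'
#' @param theta_deg Tilt angle(s) from horizontal, degrees, in \[0, 90\].
#' @param gravity Gravitational acceleration, m s^-2.
#' @return Axial acceleration(s) in m s^-2.
#' @seealso [axial_loading_pct()] for the same quantity as percent bodyweight,
#'   [angle_for_g()] for the inverse.
#' @examples
#' axial_g(9.5)   # lunar
#' axial_g(22.3)  # Martian
#' @export
axial_g <- function(theta_deg, gravity = GRAVITY_EARTH) {
  if (!is.numeric(theta_deg) || any(theta_deg < 0) || any(theta_deg > 90)) {
    abort("`theta_deg` must lie in [0, 90] degrees")
  }
  gravity * sin(deg2rad(theta_deg))
}

#' Axial loading as percent bodyweight at a tilt angle
#'
#' @inheritParams axial_g
#' @return Loading in percent of Earth bodyweight, `100 * sin(theta)`.
#' @examples
#' axial_loading_pct(9.5)  # ~16.5 %BW
#' @export
axial_loading_pct <- function(theta_deg) {
  100 * axial_g(theta_deg, gravity = 1)
}

#' Tilt angle that simulates a target gravity fraction
#'
#' Inverse of [axial_g()]: the head-up tilt angle at which the axial component
#' of gravity equals `target_fraction * g`.
#'
#' @param target_fraction Simulated gravity level(s) as a fraction of g, in
#'   \[0, 1\] (e.g. 0.165 for the Moon, 0.38 for Mars).
#' @return Tilt angle(s) in degrees.
#' @examples
#' angle_for_g(0.165)  # ~9.5 deg
#' angle_for_g(0.38)   # ~22.3 deg
#' @export
angle_for_g <- function(target_fraction) {
  if (!is.numeric(target_fraction) ||
      any(target_fraction < 0) || any(target_fraction > 1)) {
    abort("`target_fraction` must lie in [0, 1]")
  }
  rad2deg(asin(target_fraction))
}

#' Foot-plate angle for a suspension angle
#'
#' The plate the feet rest on is oriented perpendicular to the body axis, so
#' its inclination from horizontal is `90 - theta`. The rig's plate can be
#' inclined between 0 and 30 deg of body tilt.
#'
#' @param theta_deg Suspension angle(s) from horizontal, degrees, in \[0, 30\].
#' @return Foot-plate angle(s) from horizontal, degrees.
#' @examples
#' foot_plate_angle(9.5)  # 80.5
#' @export
foot_plate_angle <- function(theta_deg) {
  if (!is.numeric(theta_deg) || any(theta_deg < 0) || any(theta_deg > 30)) {
    abort("`theta_deg` must lie in [0, 30] degrees (plate inclination range)")
  }
  90 - theta_deg
}

#' Per-rope geometry for a tilted suspension
#'
#' With the body tilted head-up by `theta`, rope attachments further from the
#' ankle sit progressively higher, so (with fixed overhead pulleys) their
#' ropes are progressively shorter: `h_i = d_axial_i * tan(theta)` and
#' `L_i = L_ankle - h_i`. At `theta = 0` all ropes have equal length.
#'
#' @param body A [body_model()].
#' @param theta_deg Suspension angle from horizontal, degrees, in \[0, 30\].
#' @param l_ankle_m Ankle rope length in metres (body to overhead pulley).
#' @param min_length_m Feasibility floor for any rope length; a configuration
#'   driving a rope below this is rejected, naming the rope. Default 0.1 m.
#' @return A tibble with columns `rope`, `d_axial_m` (axial offset from the
#'   ankle attachment), `h_m` (height above the ankle attachment,
#'   perpendicular to the ropes) and `length_m`.
#' @examples
#' rope_geometry(body_model(1.75, 77.3), theta_deg = 9.5, l_ankle_m = 2.5)
#' @export
rope_geometry <- function(body, theta_deg, l_ankle_m, min_length_m = 0.1) {
  assert_body_model(body)
  if (!is.numeric(theta_deg) || length(theta_deg) != 1 ||
      theta_deg < 0 || theta_deg > 30) {
    abort("`theta_deg` must be a single angle in [0, 30] degrees")
  }
  if (!is.numeric(l_ankle_m) || length(l_ankle_m) != 1 || l_ankle_m <= 0) {
    abort("`l_ankle_m` must be a single positive length in metres")
  }
  offsets <- axial_offsets(body)
  geom <- dplyr::mutate(
    offsets,
    h_m = .data$d_axial_m * tan(deg2rad(theta_deg)),
    length_m = l_ankle_m - .data$h_m
  )
  short <- geom$length_m <= min_length_m
  if (any(short)) {
    abort(sprintf(
      "infeasible rig: rope length for %s would be %.3f m (<= %.2f m); increase `l_ankle_m` or reduce `theta_deg`",
      paste(geom$rope[short], collapse = ", "),
      min(geom$length_m[short]), min_length_m))
  }
  geom
}

#' Expected standing loading including a back-support plate
#'
#' The rigid hip-to-head support cradle is suspended with the participant, so
#' its mass contributes to the axial load measured at the feet. The expected
#' loading, as percent of the participant's own Earth bodyweight, is
#' `100 * sin(theta) * (body_mass + plate_mass) / body_mass`. The plate's
#' axial-equivalent mass (`plate_mass * sin(theta)`) is reported alongside.
#'
#' @param body_mass_kg Participant mass in kg.
#' @param plate_mass_kg Back-support plate mass in kg (0 for no plate).
#' @param theta_deg Suspension angle(s), degrees, in \[0, 90\].
#' @return A tibble with columns `theta_deg`, `loading_pct` and
#'   `plate_axial_mass_kg`.
#' @examples
#' expected_loading_with_plate(77.3, 16.4, 9.5)
#' @export
expected_loading_with_plate <- function(body_mass_kg, plate_mass_kg, theta_deg) {
  if (!is.numeric(body_mass_kg) || any(body_mass_kg <= 0)) {
    abort("`body_mass_kg` must be positive")
  }
  if (!is.numeric(plate_mass_kg) || any(plate_mass_kg < 0)) {
    abort("`plate_mass_kg` must be >= 0")
  }
  sin_t <- sin(deg2rad(theta_deg))
  if (any(theta_deg < 0) || any(theta_deg > 90)) {
    abort("`theta_deg` must lie in [0, 90] degrees")
  }
  tibble::tibble(
    theta_deg = theta_deg,
    loading_pct = 100 * sin_t * (body_mass_kg + plate_mass_kg) / body_mass_kg,
    plate_axial_mass_kg = plate_mass_kg * sin_t
  )
}

#' Rig sheet for a planned suspension
#'
#' One-stop planning summary: tilt angle for the requested gravity level,
#' foot-plate angle, per-rope lengths and heights, and per-rope counterbalance
#' loads.
#'
#' @param body A [body_model()].
#' @param target_g Simulated gravity level as a fraction of g (ignored when
#'   `theta_deg` is given).
#' @param theta_deg Suspension angle, degrees; overrides `target_g`.
#' @param l_ankle_m Ankle rope length in metres.
#' @param plate_mass_kg Back-support plate mass in kg, default 0.
#' @param gravity Gravitational acceleration, m s^-2.
#' @return A list with elements `settings` (one-row tibble: `theta_deg`,
#'   `foot_plate_angle_deg`, `target_loading_pct`, `expected_loading_pct`,
#'   `plate_axial_mass_kg`), `ropes` (per-rope geometry joined with
#'   counterbalance loads).
#' @examples
#' plan_suspension(body_model(1.75, 77.3), target_g = 0.165, l_ankle_m = 2.5,
#'                 plate_mass_kg = 16.4)
#' @export
plan_suspension <- function(body, target_g = NULL, theta_deg = NULL,
                            l_ankle_m, plate_mass_kg = 0,
                            gravity = GRAVITY_EARTH) {
  assert_body_model(body)
  if (is.null(theta_deg)) {
    if (is.null(target_g)) abort("supply either `target_g` or `theta_deg`")
    theta_deg <- angle_for_g(target_g)
  }
  geom <- rope_geometry(body, theta_deg, l_ankle_m)
  loads <- counterbalance_loads(body, gravity)
  loads_by_rope <- dplyr::summarise(
    dplyr::group_by(loads, .data$rope),
    force_n_per_rope = .data$force_n[1],
    kg_equivalent_per_rope = .data$kg_equivalent[1],
    n_ropes = dplyr::n(), .groups = "drop")
  settings <- tibble::tibble(
    theta_deg = theta_deg,
    foot_plate_angle_deg = foot_plate_angle(theta_deg),
    target_loading_pct = axial_loading_pct(theta_deg),
    expected_loading_pct = expected_loading_with_plate(
      attr(body, "mass_kg"), plate_mass_kg, theta_deg)$loading_pct,
    plate_axial_mass_kg = plate_mass_kg * sin(deg2rad(theta_deg))
  )
  list(settings = settings,
       ropes = dplyr::left_join(geom, loads_by_rope, by = "rope"))
}
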