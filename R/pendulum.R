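#' Rope angle under horizontal suspension
#'
#' With all ropes vertical and of equal length the suspended body behaves as a
#' point mass on a single pendulum: an axial displacement `s` swings every
#' rope through `asin(s / L)`.
#'
#' @param s_axial_m Axial displacement(s) of the body away from equilibrium,
#'   metres, in \[0, L\].
#' @param length_m Rope length L in metres.
#' @return Rope angle(s) from vertical, degrees.
#' @examples
#' rope_angle_horizontal(1.25, 2.5)  # 30 deg
#' @export
rope_angle_horizontal <- function(s_axial_m, length_m) {
  if (!is.numeric(length_m) || any(length_m <= 0)) {
    abort("`length_m` must be positive")
  }
  if (!is.numeric(s_axial_m) || any(s_axial_m < 0)) {
    abort("`s_axial_m` must be >= 0 (motion away from the plate)")
  }
  if (any(s_axial_m > length_m)) {
    abort("`s_axial_m` cannot exceed the rope length")
  }
  rad2deg(asin(s_axial_m / length_m))
}

#' Restoring axial acceleration under horizontal suspension
#'
#' The component of gravity perpendicular to a swung rope is `g sin(theta)`;
#' its projection back onto the body axis is `g sin(theta) cos(theta)`. This
#' pendulum-effect acceleration is the error superimposed on the simulated
#' 0 g axial condition whenever the body displaces.
#'
#' @param rope_angle_deg Rope angle(s) from vertical, degrees, in \[0, 90\].
#' @param gravity Gravitational acceleration, m s^-2.
#' @return Axial acceleration(s), m s^-2. Maximal at 45 deg (`g / 2`).
#' @export
axial_accel_horizontal <- function(rope_angle_deg, gravity = GRAVITY_EARTH) {
  if (!is.numeric(rope_angle_deg) ||
      any(rope_angle_deg < 0) || any(rope_angle_deg > 90)) {
    abort("`rope_angle_deg` must lie in [0, 90] degrees")
  }
  th <- deg2rad(rope_angle_deg)
  gravity * sin(th) * cos(th)
}

#' Rope angle under head-up-tilt suspension
#'
#' At equilibrium every rope already sits at the suspension angle (ropes are
#' perpendicular to the tilted body). A rigid-body axial displacement `s`
#' swings rope `i` of length `L_i` to `asin(s / L_i) + theta_suspension`;
#' shorter ropes (those further from the ankle) swing further for the same
#' displacement.
#'
#' @param s_axial_m Axial displacement(s), metres, in \[0, L_i\].
#' @param length_m Rope length(s) `L_i`, metres.
#' @param theta_suspension_deg Suspension angle, degrees.
#' @return Rope angle(s), degrees. Values beyond 90 + theta are geometrically
#'   impossible and flagged by the `s_axial_m > length_m` guard.
#' @export
rope_angle_hut <- function(s_axial_m, length_m, theta_suspension_deg) {
  rope_angle_horizontal(s_axial_m, length_m) + theta_suspension_deg
}

#' Axial acceleration on a segment under head-up-tilt suspension
#'
#' At equilibrium each segment experiences the target simulated level
#' `g sin(theta_suspension)`. When its rope swings to `theta_rope >
#' theta_suspension` the axial acceleration grows to
#' `g sin(theta_rope) cos(theta_rope - theta_suspension)`: the gravity
#' component perpendicular to the rope, projected onto the (still tilted)
#' body axis. This reduces to the horizontal model at `theta_suspension = 0`
#' and to the equilibrium value at `theta_rope = theta_suspension`, and the
#' excess over equilibrium - the pendulum-effect error - is always >= 0.
#'
#' `printed_form = TRUE` selects the alternative expression
#' `g sin(theta_suspension) cos(theta_rope - theta_suspension)`, retained for
#' comparison only; it decreases below the equilibrium value as the rope
#' swings and so cannot represent the restoring error.
#'
#' @param theta_rope_deg Rope angle(s), degrees; must be >=
#'   `theta_suspension_deg` (the body between plate and equilibrium is
#'   outside model validity).
#' @param theta_suspension_deg Suspension angle, degrees.
#' @param gravity Gravitational acceleration, m s^-2.
#' @param printed_form Use the non-restoring variant (default FALSE).
#' @return Axial acceleration(s), m s^-2.
#' @export
axial_accel_hut <- function(theta_rope_deg, theta_suspension_deg,
                            gravity = GRAVITY_EARTH, printed_form = FALSE) {
  if (!is.numeric(theta_rope_deg) || !is.numeric(theta_suspension_deg)) {
    abort("angles must be numeric (degrees)")
  }
  if (any(theta_rope_deg < theta_suspension_deg - 1e-12)) {
    abort("`theta_rope_deg` must be >= `theta_suspension_deg` (displacement away from the plate)")
  }
  tr <- deg2rad(theta_rope_deg)
  ts <- deg2rad(theta_suspension_deg)
  if (printed_form) {
    gravity * sin(ts) * cos(tr - ts)
  } else {
    gravity * sin(tr) * cos(tr - ts)
  }
}

#' Mass-weighted total axial acceleration
#'
#' Combines per-rope-group axial accelerations into the whole-body value by
#' weighting each with its group's share of total body mass.
#'
#' @param accel_ms2 Per-group axial accelerations, m s^-2.
#' @param mass_fraction Matching mass fractions; must sum to 1 within 1e-9.
#' @return Scalar total axial acceleration, m s^-2; always lies between the
#'   smallest and largest per-group value.
#' @export
total_axial_accel <- function(accel_ms2, mass_fraction) {
  if (length(accel_ms2) != length(mass_fraction)) {
    abort("`accel_ms2` and `mass_fraction` must have equal length")
  }
  if (abs(sum(mass_fraction) - 1) > 1e-9) {
    abort(sprintf("`mass_fraction` must sum to 1 (got %.12f)", sum(mass_fraction)))
  }
  sum(accel_ms2 * mass_fraction)
}

# Whole-body axial acceleration field a_total(s) for a given rig; returns a
# vectorised function of displacement. Shared by error_curve and jump_apex.
total_accel_field <- function(body, theta_deg, l_ankle_m,
                              gravity = GRAVITY_EARTH) {
  geom <- rope_geometry(body, theta_deg, l_ankle_m)
  lengths <- geom$length_m
  fractions <- body$mass_fraction
  function(s) {
    vapply(s, function(si) {
      angles <- rope_angle_hut(si, lengths, theta_deg)
      total_axial_accel(axial_accel_hut(angles, theta_deg, gravity), fractions)
    }, numeric(1))
  }
}

#' Pendulum-effect error curve for a rig
#'
#' Evaluates, over a displacement grid, each rope group's angle, axial
#' acceleration and additional acceleration above the simulated equilibrium
#' level, plus the mass-weighted whole-body total (rows with `rope ==
#' "total"`). The additional acceleration is the pendulum-effect error that
#' inflates the simulated gravity level during dynamic movement; it shrinks
#' as ropes get longer.
#'
#' @param body A [body_model()].
#' @param theta_deg Suspension angle, degrees, in \[0, 30\].
#' @param l_ankle_m Ankle rope length, metres.
#' @param s_max_m Largest displacement evaluated; must be smaller than the
#'   shortest rope.
#' @param n_points Grid size (default 101, including 0).
#' @param gravity Gravitational acceleration, m s^-2.
#' @return A `pendulum_curve` tibble with columns `s_axial_m`, `rope`
#'   (ankle/knee/pelvis/thorax/total), `rope_angle_deg` (NA for total),
#'   `axial_accel_ms2` and `additional_accel_ms2`.
#' @examples
#' curve <- pendulum_error_curve(body_model(1.75, 77.3), 9.5, 2.5, s_max_m = 0.7)
#' head(curve)
#' @export
pendulum_error_curve <- function(body, theta_deg, l_ankle_m, s_max_m,
                                 n_points = 101, gravity = GRAVITY_EARTH) {
  geom <- rope_geometry(body, theta_deg, l_ankle_m)
  if (!is.numeric(s_max_m) || length(s_max_m) != 1 || s_max_m <= 0 ||
      s_max_m >= min(geom$length_m)) {
    abort(sprintf(
      "`s_max_m` must lie in (0, %.3f), the shortest rope length",
      min(geom$length_m)))
  }
  s_grid <- seq(0, s_max_m, length.out = n_points)
  equil <- axial_g(theta_deg, gravity)
  per_rope <- tidyr::crossing(
    tibble::tibble(s_axial_m = s_grid),
    geom[c("rope", "length_m")]
  )
  per_rope <- dplyr::mutate(
    per_rope,
    rope_angle_deg = rope_angle_hut(.data$s_axial_m, .data$length_m, theta_deg),
    axial_accel_ms2 = axial_accel_hut(.data$rope_angle_deg, theta_deg, gravity),
    additional_accel_ms2 = .data$axial_accel_ms2 - equil
  )
  per_rope <- dplyr::left_join(
    per_rope,
    body[c("rope", "mass_fraction")], by = "rope")
  totals <- dplyr::summarise(
    dplyr::group_by(per_rope, .data$s_axial_m),
    rope = "total",
    rope_angle_deg = NA_real_,
    axial_accel_ms2 = sum(.data$axial_accel_ms2 * .data$mass_fraction),
    additional_accel_ms2 = sum(.data$additional_accel_ms2 * .data$mass_fraction),
    .groups = "drop")
  out <- dplyr::bind_rows(
    per_rope[c("s_axial_m", "rope", "rope_angle_deg",
               "axial_accel_ms2", "additional_accel_ms2")],
    totals[c("s_axial_m", "rope", "rope_angle_deg",
             "axial_accel_ms2", "additional_accel_ms2")])
  out <- dplyr::arrange(out, .data$s_axial_m)
  attr(out, "theta_deg") <- theta_deg
  attr(out, "l_ankle_m") <- l_ankle_m
  attr(out, "gravity") <- gravity
  class(out) <- c("pendulum_curve", class(out))
  out
}

#' Apex of a vertical jump under suspension
#'
#' Integrates the axial equation of motion `s'' = -a_total(s)` from take-off
#' (`s = 0`, `s' = v0`) to the apex (`s' = 0`), where `a_total` is the
#' mass-weighted whole-body axial acceleration including both the simulated
#' gravity level and the pendulum-effect error. Because the error grows with
#' displacement, the apex is always below the ballistic prediction
#' `v0^2 / (2 g sin(theta))`, converging to it as ropes get long.
#'
#' Uses a fixed-step velocity-Verlet scheme, halving the step until the apex
#' changes by less than `tol_m`; the integration is deterministic.
#'
#' @param body A [body_model()].
#' @param theta_deg Suspension angle, degrees, in (0, 30\].
#' @param l_ankle_m Ankle rope length, metres.
#' @param v0 Take-off speed along the body axis, m s^-1 (>= 0).
#' @param headroom_m Displacement ceiling above which the result is flagged
#'   (default 0.7 m, the rig's jump headroom).
#' @param tol_m Apex convergence tolerance, metres (default 1e-6).
#' @param gravity Gravitational acceleration, m s^-2.
#' @return A one-row tibble: `apex_m`, `time_to_apex_s`, `flight_time_s`
#'   (symmetric up-down trajectory, 2x time to apex), `ballistic_apex_m`
#'   (the long-rope limit) and `headroom_exceeded`.
#' @examples
#' jump_apex(body_model(1.75, 77.3), 9.5, 2.5, v0 = 1.0)
#' @export
jump_apex <- function(body, theta_deg, l_ankle_m, v0, headroom_m = 0.7,
                      tol_m = 1e-6, gravity = GRAVITY_EARTH) {
  assert_body_model(body)
  if (!is.numeric(v0) || length(v0) != 1 || v0 < 0) {
    abort("`v0` must be a single speed >= 0")
  }
  if (theta_deg <= 0) {
    abort("`theta_deg` must be > 0 (no restoring equilibrium at 0 deg)")
  }
  geom <- rope_geometry(body, theta_deg, l_ankle_m)
  s_valid <- min(geom$length_m) * (1 - 1e-9)
  ballistic <- v0^2 / (2 * axial_g(theta_deg, gravity))
  if (v0 == 0) {
    return(tibble::tibble(apex_m = 0, time_to_apex_s = 0, flight_time_s = 0,
                          ballistic_apex_m = 0, headroom_exceeded = FALSE))
  }
  accel <- total_accel_field(body, theta_deg, l_ankle_m, gravity)

  integrate_apex <- function(dt) {
    s <- 0; v <- v0; t <- 0
    a <- accel(s)
    repeat {
      s_new <- s + v * dt - 0.5 * a * dt^2
      if (s_new > s_valid) {
        abort("trajectory leaves the valid displacement range (apex beyond the shortest rope); reduce `v0`")
      }
      a_new <- accel(max(s_new, 0))
      v_new <- v - 0.5 * (a + a_new) * dt
      if (v_new <= 0) {
        # linear interpolation of the zero crossing inside the last step
        frac <- v / (v - v_new)
        t_ap <- t + frac * dt
        s_ap <- s + v * (frac * dt) - 0.5 * a * (frac * dt)^2
        return(c(apex = s_ap, time = t_ap))
      }
      s <- s_new; v <- v_new; a <- a_new; t <- t + dt
    }
  }

  dt <- max(v0 / gravity / 50, 1e-4)
  res <- integrate_apex(dt)
  repeat {
    dt <- dt / 2
    res_new <- integrate_apex(dt)
    if (abs(res_new["apex"] - res["apex"]) < tol_m) {
      res <- res_new
      break
    }
    res <- res_new
    if (dt < 1e-8) break
  }
  apex <- unname(res["apex"])
  if (apex > headroom_m) {
    warn(sprintf("apex %.3f m exceeds the %.1f m jump headroom", apex, headroom_m))
  }
  tibble::tibble(
    apex_m = apex,
    time_to_apex_s = unname(res["time"]),
    flight_time_s = 2 * unname(res["time"]),
    ballistic_apex_m = ballistic,
    headroom_exceeded = apex > headroom_m
  )
}
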