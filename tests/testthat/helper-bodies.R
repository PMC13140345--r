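# Reference participant used across tests: 1.75 m, 77.3 kg (the human study's
# mean stature/mass), lunar tilt, 2.5 m ankle rope.
ref_body <- function() body_model(1.75, 77.3)

LUNAR_DEG <- 9.5
G <- 9.81

# Independent energy-balance oracle for the jump apex: solves
# integral_0^A a_total(s) ds = v0^2 / 2 by quadrature + root finding,
# sharing no code with the time-stepping integrator.
apex_energy_oracle <- function(body, theta_deg, l_ankle_m, v0) {
  geom <- rope_geometry(body, theta_deg, l_ankle_m)
  a_of_s <- function(s) {
    vapply(s, function(si) {
      th <- asin(si / geom$length_m) * 180 / pi + theta_deg
      a <- 9.81 * sin(th * pi / 180) * cos((th - theta_deg) * pi / 180)
      sum(a * body$mass_fraction)
    }, numeric(1))
  }
  f <- function(A) stats::integrate(a_of_s, 0, A, rel.tol = 1e-10)$value - v0^2 / 2
  stats::uniroot(f, c(1e-9, min(geom$length_m) * 0.999), tol = 1e-10)$root
}
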