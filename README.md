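# hutsim

Physics and analysis toolkit for **head-up-tilt (HUT) whole-body suspension**,
a ground-based analogue for studying human movement in hypogravity (the Moon's
0.17 g, Mars's 0.38 g). A participant is suspended by ropes — ankle, knee,
pelvis and thorax groups, each counterbalanced by a constant-force spring
balance equal to its body segment's weight — and tilted head-up by an angle
θ so that a chosen fraction of Earth's gravity acts along the body axis.

The package is for biomechanists and exercise physiologists running (or
designing) such rigs: it plans suspensions, quantifies the model's dynamic
error, turns force-platform recordings into weight-bearing estimates, and
runs the standard validity/reliability analytics on loading tables.

## The model

**Static tilt law.** The axial (head-to-foot) acceleration at suspension
angle θ is

    a_axial = g · sin θ

so 9.5° simulates lunar gravity (16.5 % bodyweight) and 22.3° Martian
gravity (≈38 % bodyweight). The foot plate stays perpendicular to the body,
at 90 − θ from horizontal. A rigid back-support cradle of mass m_p adds
m_p · sin θ of axial-equivalent mass to the measured load.

**Rope geometry.** With overhead pulleys at a fixed height, attachments
further from the ankle sit higher and their ropes are shorter:
h_i = d_axial,i · tan θ and L_i = L_ankle − h_i, where d_axial,i comes from
anthropometric height fractions (ankle 0.039 H, knee 0.285 H, pelvis 0.53 H,
thorax 0.81 H).

**Pendulum-effect error.** When the body displaces axially by s (jumping,
gait), each rope swings to θ_rope,i = asin(s / L_i) + θ and the segment's
axial acceleration grows to

    a_axial,i = g · sin θ_rope,i · cos(θ_rope,i − θ)

exceeding the simulated level g·sin θ; the whole-body error is the
mass-fraction-weighted sum Σ (m_i / M) · a_axial,i. `jump_apex()` integrates
s̈ = −a_total(s) to predict how much this error suppresses jump height
relative to the ballistic apex v₀² / (2 g sin θ).

**Analytics.** Standing loading is the windowed mean of the (optionally
Butterworth-filtered, optionally Fz–Fy resultant) platform force over
same-day bodyweight; agreement and reliability use Bland–Altman bias/limits
of agreement with t-based confidence intervals and the two-way
absolute-agreement single-measures intraclass correlation
ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)).

## Worked example

Plan a lunar-gravity suspension for a 1.75 m, 77.3 kg participant on a
2.5 m ankle rope with the 16.4 kg back-support plate:

```r
library(hutsim)
body <- body_model(1.75, 77.3)
plan <- plan_suspension(body, target_g = 0.165, l_ankle_m = 2.5,
                        plate_mass_kg = 16.4)
plan$settings
#>   theta_deg foot_plate_angle_deg target_loading_pct expected_loading_pct plate_axial_mass_kg
#> 1      9.50                 80.5               16.5                 20.0                2.71
plan$ropes
#>   rope   d_axial_m    h_m length_m force_n_per_rope kg_equivalent_per_rope n_ropes
#> 1 ankle      0     0          2.5              28.4                   2.90       2
#> 2 knee       0.430 0.0720     2.43             93.7                   9.55       2
#> 3 pelvis     0.859 0.144      2.36            114.                   11.6        1
#> 4 thorax     1.35  0.226      2.27            400.                   40.8        1
```

Tilt to 9.5°, set the plate to 80.5°, cut the thorax rope 22.6 cm shorter
than the ankle rope, and dial each spring balance to the listed load. The
plate adds 2.7 kg of axial-equivalent mass, so this participant should read
about 20 % — not 16.5 % — bodyweight while standing.

The pendulum effect then caps a v₀ = 1 m s⁻¹ jump well below its ballistic
apex:

```r
jump_apex(body, theta_deg = 9.5, l_ankle_m = 2.5, v0 = 1)
#>   apex_m time_to_apex_s flight_time_s ballistic_apex_m headroom_exceeded
#> 1  0.238          0.444         0.887            0.309 FALSE
```

Reliability of the packaged three-visit standing campaign (14 complete
cases):

```r
t4 <- validation_table("standing_study2")
cc <- t4[stats::complete.cases(t4), ]
bland_altman(cc, loading_v1, loading_v2)
#> Bland-Altman agreement (n = 14 complete pairs)
#>   bias -1.69 [-4.62, 1.23]
#>   LOA  -11.63 [-16.70, -6.56] to 8.25 [3.17, 13.32]
```

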