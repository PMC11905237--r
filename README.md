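# seccheck

Independent ("secondary") dose and monitor-unit verification for a 1.5 T
MR-linear accelerator (Elekta Unity class, 7 MV FFF), written for medical
physicists who need a transparent, auditable check of treatment-planning-
system output — especially in online-adaptive workflows where the secondary
calculation is the only pre-treatment verification of the day's plan.

## What it computes

The engine is a TG-71-style factorization of dose at a point, relative to
the absolute calibration (1 cGy/MU at a 10 × 10 cm field, source-to-plane
138.5 cm, depth 5 cm):

```
D(p) = MU · (D_ref / MU_ref) · S_c,p(s) ·
       PDD(s, d_rad) F_May / [PDD(s_cal, d_cal) F_May,cal] ·
       ISF · OAR(p) · CF(θ)
```

* `s` — Sterling equivalent square `2XY/(X+Y)` of the DLG-widened open
  aperture (jaws ∩ MLC);
* `PDD` — bilinear lookup in the commissioned depth-dose grid (SSD 133.5
  cm), converted to the field's SSD with the Mayneord F factor;
* `d_rad` — radiological depth from a Siddon ray trace through the
  relative-electron-density phantom;
* `ISF` — inverse-square ratio of the dmax planes;
* `OAR` — off-axis ratio from an erf-penumbra × FFF-envelope profile
  model whose cross-plane component is translated by a Lorentz shift
  (the 1.5 T field sweeps secondary electrons laterally); a point under
  closed leaves receives the MLC transmission instead;
* `CF(θ)` — gantry-angle cryostat attenuation correction, normalized to
  1 at 0°.

On top of the factor chain, `pencil_beam_dose()` integrates a finite-size
pencil-beam kernel (radially double-exponential, Lorentz-shifted) over the
beamlet-discretized MLC aperture for modulated segments. The toolkit also
covers the commissioning workflow (DLG grid-search optimization, MLC
transmission derivation, cryostat normalization, PDD comparison), global
1-D/2-D gamma analysis, plan-level 5%/5 MU and 5%/5 cGy tolerance
verdicts, and automatic calculation-point selection (> 3 mm from tissue
interfaces, > 1 cm from field edges, inside the 90% isodose).

## Worked example

```r
library(seccheck)

model <- unity_beam_model()              # packaged 7X-FFF beam model
field <- field_spec(jaw_x = c(-50, 50), jaw_y = c(-50, 50),
                    mu = 100, ssd = 1335)
res <- point_dose(model, field, phantom = NULL, dose_point(0, 0, 100))
res
#> <dose_result> 0.863684 Gy for 100 MU
#>   eq. square 100 mm, radiological depth 100 mm
#>   factors: scp=1  pdd=0.80455  isf=1.0756  mayneord=0.99809  oar=1  cryostat=1
```

86.37 cGy for 100 MU at 10 cm depth, SSD 133.5 cm — within 0.2% of the
86.5 cGy ion-chamber measurement for this geometry in the packaged
validation set (`load_validation_points()`). Each factor in the breakdown
can be audited separately; their product reproduces the dose exactly.

Checking a whole plan:

```r
plan <- make_step_and_shoot_plan(model, n_segments = 3, seed = 5)
plan <- plan_with_engine_tps(model, plan)          # self-consistent TPS values
check_plan(model, perturb_plan_mu(plan, 2, 1.07))  # +7% MU on segment 2
#> <plan_check_report> step_and_shoot_3 — FAIL
#>   field tps_mu engine_mu percent_diff mu_diff verdict note
#>  seg_01    100    100.00         0.00    0.00    pass
#>  seg_02    107    100.00        -6.54   -7.00    FAIL
#>  seg_03    100    100.00         0.00    0.00    pass
```

A thin command-line front end lives at `inst/cli/seccheck`
(`seccheck calc`, `check-plan`, `gamma`, `optimize-dlg`, `build-model`,
`make-fixtures`).

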