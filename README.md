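# mkmrbe

Microdosimetric kinetic model (MKM) estimation of RBE-weighted dose for
proton therapy beams, in R.

## The problem

Proton treatment planning prescribes the *RBE-weighted dose* — the absorbed
(physical) dose multiplied by the relative biological effectiveness (RBE) of
the beam at each depth. Clinically a constant RBE of 1.1 is common, but the
biological effectiveness of protons rises steeply near the end of range,
where slowing protons deposit energy densely. The MKM predicts this
variation from a purely physical, measurable quantity: the dose distribution
of lineal energy, *d(y)*, scored in a sub-micrometre sensitive site. This
package implements that estimation chain for radiation physicists and
medical-physics researchers who have per-depth *d(y)* spectra (from a
transport code or a TEPC) — or who want a self-contained synthetic beam to
exercise the method end to end.

## The model

For a site of mean chord length l̄ and mass m, the saturation-corrected
dose-mean specific energy per event is

    z*₁D = (l̄/m) y* = 0.1602 · y₀² ∫ [1 − exp(−y²/y₀²)] · d(y)/y dy / (ρ π r_d²)

with y in keV/μm, domain radius r_d in μm, density ρ in g/cm³ and z*₁D in
Gy. The saturation parameter y₀ caps the effectiveness of densely ionizing
events (overkill). The MKM then takes the linear-quadratic (LQ) survival
coefficient of the beam as

    α = α₀ + β z*₁D ,    S(D) = exp(−αD − βD²)

with β independent of radiation quality, and the RBE at a survival endpoint
S (default 10%) as the dose ratio

    RBE(S) = D_ref(S) / D_beam(S)

against a 200 kVp X-ray reference (α = 0.19 Gy⁻¹, β = 0.05 Gy⁻²). Two HSG
cell parameter sets are built in: `SET_A` (α₀ 0.155 Gy⁻¹, β 0.0615 Gy⁻²,
r_d 0.282 μm, y₀ 93.4 keV/μm) for survival-depth analysis, and `SET_B`
(α₀ 0.13 Gy⁻¹, β 0.05 Gy⁻², r_d 0.42 μm, y₀ 150 keV/μm), the default for
RBE-weighted dose.

A synthetic beam generator (Bragg–Kleeman range–energy power law, Gaussian
range straggling, non-negative least-squares SOBP superposition, and
depth-dependent log-normal *d(y)* mixtures pinned to the local stopping
power) stands in for Monte Carlo transport so the whole chain runs from
analytic inputs. It targets the qualitative structure of clinical beams, not
transport-code fidelity.

## Worked example

```r
library(mkmrbe)

beam <- generate_beam(beam_config(modulation_width = 60,
                                  depth_grid = seq(0, 150, by = 0.5)))
fit  <- mkm_rbe(beam)            # SET_B, 200 kVp reference, S = 0.1
summary(fit)
```

```
MKM RBE-weighted depth-dose profile
  279 depths on [0, 139] mm (0 excluded: missing spectra)
  params: SET_B: alpha0 0.13, beta 0.05, rd 0.42 um, y0 150 keV/um
  reference: 200 kVp X-rays; endpoint S = 0.1; window +/- 1.5 mm
  RBE range: 0.9361 (entrance 0.9361) to 1.419
  Bragg peak (argmax dose): 76.5 mm; SOBP center (95% rule): 100.8 mm
  entrance: dose 0.2625 Gy, RBE 0.9361, weighted 0.2458 Gy
  at peak:  dose 0.4341 Gy, RBE 0.9616, weighted 0.4174 Gy
```

The entrance RBE sits below 1 — high-energy protons are sparsely ionizing
compared with 200 kVp X-rays — and rises across the distal half of the SOBP,
so the RBE-weighted plateau tilts upward even though the physical plateau is
flat to ±0.09%. Continuing:

```r
fit2 <- normalize_profile(fit, "sobp_center", target_dose = 2, on = "rbe_weighted")
sv   <- survival_depth_profile(mkm_rbe(beam, params = mkm_preset("SET_A")),
                               survival_at_center = 0.1)
attr(sv, "center_dose_Gy")    # physical dose giving 10% survival at the center
#> [1] 4.264279
```

The same chain is scriptable from a shell via `exec/mkmtool`
(`spectrum-stats`, `rbe`, `depth-profile`, `synth-beam`, `survival`), which
reads and writes the delimited-text spectrum, series and profile formats
described in the function documentation.

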