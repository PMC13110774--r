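# dimerdeer

Pulsed dipolar EPR (DEER/PELDOR) and continuous-wave (CW) EPR analysis for
ligand occupancy in a homodimeric enzyme. The package implements, as tested
reusable components, the inference chain by which DEER distance
measurements on a spin-labelled amino-acid ligand (a nitroxide-bearing
non-canonical amino acid) bound to the pyrrolysyl-tRNA synthetase (PylRS)
homodimer lead to a binding-site model: one ligand in a catalytic pocket
and a second in the secondary ("waiting") site of the *opposite* monomer.

It is intended for spectroscopists and methods developers who want each
step of such an analysis — forward simulation, inversion, spin counting,
cooperativity testing, spectral unmixing, hypothesis discrimination — as a
separate, testable function with synthetic ground truth available at every
stage.

## What it computes

**Dipolar forward model and inversion.** A two-spin DEER trace is modelled
as

    V(t) = [(1 − Δ) + Δ ∫ K(t, r) P(r) dr] · exp(−k t),

with the orientation-averaged kernel
`K(t, r) = ∫₀¹ cos[(3x² − 1) ω(r) t] dx`, `ω(r) = 2π D / r³`,
`D = 52.04 MHz nm³`. `invert_trace()` recovers `P(r)` by
Tikhonov-regularized non-negative least squares with a second-difference
penalty, GCV selection of the regularization parameter, a residual
bootstrap uncertainty band, and a cube-root reliability limit
`r_max = 3.494 · t_max^(1/3)` nm on the recorded window.

**Occupancy statistics.** With modulation depth `Δ = λ q` (λ the pump
inversion efficiency, `q = 2 f2 / (f1 + 2 f2)` the fraction of bound spins
with an in-dimer partner) and bound-spin signal `m = f1 + 2 f2`,
`infer_occupancy()` recovers the per-dimer fractions `(f0, f1, f2)` of
empty, singly and doubly occupied dimers. `cooperativity_test()` compares
`f2` with the binomial expectation `p²` at equal mean load
(`p = m / 2`), with a multinomial parametric bootstrap CI.

**CW unmixing.** `unmix()` decomposes a first-derivative CW spectrum into a
sharp fast-motion (free ligand) and a broad rigid-limit (bound ligand)
template by non-negative least squares; fractions are spin-count fractions
because both templates carry unit absorption double integral.

**Pairing hypotheses.** `rank_hypotheses()` scores candidate site-pairing
models (cross pairing at 2.5 nm, both-catalytic at 4.1 nm, intra-monomer
at 3.0 nm under the default four-site geometry) against a recovered
distribution by their overlap coefficient inside the reliable window.

**Synthetic scenarios.** `generate_scenario()` emulates the in vitro and
in-cell experiments end to end (gated or independent binding, pair
distances from the site geometry, exponential background, white noise,
nitroxide reduction in the cell, two-component CW spectra), with full
ground truth saved for recovery tests. `run_pipeline()` composes the whole
chain from a scenario directory to a discrimination report.

## Worked example

```r
library(dimerdeer)

dir <- tempfile()
write_bundle(generate_scenario(preset_scenario("invitro")), dir)
report <- run_pipeline(dir)
report
#> <run_report>
#>   inversion: mode 2.5 nm, depth 0.194, reliable to 4.4 nm
#>   occupancy: f0 0.695, f1 0.207, f2 0.0973 (cooperative, ratio 2.41)
#>   cw free fraction: 0.09
#>   top hypothesis: cross (consistent, score 0.855)
```

Reading the output: the synthetic in vitro trace inverts to a single
narrow distance at 2.5 nm, well inside the 4.4 nm reliability limit of a
2 µs window. Spin counting on the modulation depth and bound-spin signal
recovers roughly 70/21/9% empty/singly/doubly occupied dimers; the doubly
occupied fraction is ~2.4× the random-binding expectation, so binding is
called cooperative. The CW spectrum unmixes to 9% free ligand. Among the
candidate site pairings, only the cross hypothesis (catalytic site of one
monomer + secondary site of the other, both variants superposing at
2.5 nm) is consistent with the recovered distribution; the both-catalytic
pairing (4.1 nm) is excluded.

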