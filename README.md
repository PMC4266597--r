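# forcespec

Analysis of constant-speed AFM single-molecule force spectroscopy (SMFS)
experiments on polyprotein-tethered receptor–ligand complexes, built
around the mechanically ultrastable XMod-Dockerin:Cohesin interaction
that anchors the *Ruminococcus flavefaciens* cellulosome to cellulose.
It is written for single-molecule biophysicists who need a tested,
scriptable version of the standard reduction from raw force–extension
sawtooth curves to receptor–ligand kinetics.

The package implements:

* **Polymer elasticity** — the parameter-free freely rotating chain with
  quantum-mechanical backbone corrections (QM-FRC; bonds *b* = 0.11 nm at
  fixed angle *γ* = 41°) for unfolded polypeptide, and the Marko–Siggia
  worm-like chain for PEG linkers.
* **Contour-length transformation** — every sample (*F*, *x*) above a
  force threshold maps to an apparent contour length
  *L* = *x* / (ratio(*F*) · stretch(*F*)); per-curve histograms are
  assembled into a master barrier-position histogram by cross-correlation
  alignment, and peak-to-peak spacings give the unfolding increments
  (Xyn ≈ 89 nm, CBM ≈ 56 nm).
* **Fingerprint screening and bond history** — curves are "specific" when
  their increments match the Xyn + CBM templates (±8 nm); a final rupture
  is "shielded" when X-module unfolding preceded it, "intact" otherwise.
* **Bell-Evans kinetics** — off-rate *k*(*F*) = *k*_off · exp(*F*Δ*x*/*k*BT);
  closed-form rupture-force distributions at constant loading rate, the
  most-probable-force relation
  *F*\* = (*k*BT/Δ*x*) · ln(*r* Δ*x* / *k*_off *k*BT), an inverse-CDF
  sampler, Gaussian modal estimation per pulling speed, and least-squares
  dynamic force spectrum fits in (ln *r*, *F*\*) space.
* **A kinetic Monte Carlo simulator** of the full pulling experiment
  (cantilever–PEG–polyprotein–complex in series, stochastic unfolding via
  Bell hazards, ground-truth event logs), standing in for instrument data
  so that every pipeline stage can be validated against known truth.

## Worked example

```r
library(forcespec)

## the ultrastable complex: most probable rupture force at 10 and 100 nN/s
p <- bell_params(k_off = 7.3e-7, delta_x = 0.13)
most_probable_force(c(1e4, 1e5), p)
#> [1] 629.3137 702.1816

## simulate a small configuration-I campaign and run the full reduction
ds  <- simulate_dataset(default_system(), protocol_spec(seed = 1), 60)
rep <- run_pipeline(ds$curves)
print(rep)
#> Pipeline report
#>   curves: 60 total, 60 with events, 58 specific (33 intact / 25 shielded)
#>   domain increments (nm):
#>  name expected measured from to
#>   Xyn   89.075       88    1  3
#>   CBM   55.955       55    4  4
#>  XMod   33.825       33    5  5
```

The rupture-force relation puts the intact complex in the 600–750 pN band
over the experimental loading-rate range. In the simulated campaign, 58
of 60 curves carry the Xyn + CBM fingerprint; the master histogram
recovers the programmed unfolding increments (89/56/34 nm) within the
1 nm binning; and 25 of the 58 specific traces took the shielded path
(the programmed branch probability is 0.375). A single-speed dataset
cannot support a dynamic force spectrum fit — spread the traces across
speeds (`simulate_dataset(..., pulling_speeds = c(200, 400, 800, 1600,
3200))`) and `run_pipeline()` additionally returns per-history-class
Bell-Evans fits (`rep$fits$intact$params`).

A thin command-line front end is installed with the package
(`inst/scripts/forcespec`): `forcespec simulate`, `forcespec analyze` and
`forcespec dfs` chain the same functions over TSV curve containers, CSV
event tables and JSON fit reports, configured by YAML files mirroring
`run_config()`.

The methods vignette (`vignettes/forcespec-methods.Rmd`) documents the
models, every default that matters, and the known limitations.

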