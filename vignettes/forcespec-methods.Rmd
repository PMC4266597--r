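---
title: "Models and methods behind forcespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forcespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcespec)
```

## The experiment being analysed

forcespec analyses constant-speed AFM single-molecule force spectroscopy
(SMFS) of a mechanically ultrastable receptor--ligand pair: the
XMod-Dockerin:Cohesin complex that anchors the *Ruminococcus flavefaciens*
cellulosome to its substrate. In the pulling configuration the package
models ("configuration I"), a Xyn--XMod--Doc fusion on the glass surface is
pulled against a Coh--CBM fusion on the cantilever through PEG linkers. A
successful single-molecule trace shows, in order: PEG stretching, a
three-peaked xylanase unfolding fingerprint (~89 nm of contour length in
total), CBM unfolding (~56 nm), and the final complex rupture -- either at
very high force with the X-module folded ("intact"), or, in roughly 35--40%
of traces, at much lower force immediately after the X-module has unfolded
("shielded"). The package implements the full reduction from raw
force--extension traces to per-history-class Bell-Evans kinetics, plus a
kinetic Monte Carlo (KMC) simulator that stands in for instrument data,
with ground-truth event logs so that every stage can be validated.

## Polymer elasticity

Unfolded polypeptide is described by a freely rotating chain with
quantum-mechanical backbone corrections (QM-FRC): rigid bonds of length
`b = 0.11` nm joined at a fixed angle `gamma = 41` degrees. The model has
no fitted parameters. Its fractional extension is implemented in two
regimes, split at the crossover force `F* = kBT l_p / b^2` (about 124 pN),
where `l_p = b cos(gamma/2) / |ln cos gamma|` (about 0.366 nm) is the
effective persistence length:

* `F <= F*`: semiflexible behaviour, evaluated with the Marko--Siggia
  interpolation at persistence length `l_p`;
* `F > F*`: the discrete-bond regime `x/L = 1 - kBT / (2 F b)`.

The two branches join continuously at the crossover (the fractional
extension changes by far less than one histogram bin across it). The
backbone itself stretches elastically at high force; this is carried as a
multiplicative contour-length factor `1 + c1 F + c2 F^2`, a quadratic
parametrization of ab initio backbone elasticity giving ~0.6% elongation
at 600 pN and ~3% at 2 nN. Disabling the correction
(`qm_correction = NULL`) reproduces the bare FRC exactly. The thermal
energy defaults to `kBT = 4.114` pN nm (about 298 K); temperature is not a
measured quantity here, and the value is configurable.

PEG linkers use the worm-like chain (Marko--Siggia) with persistence
length 0.38 nm and 32 nm of contour per 5 kDa linker (two linkers in
series by default). PEG's force-dependent helix--coil transition is
ignored; this mostly distorts the low-force region that the transform
excludes anyway.

## Contour-length transformation

Each sample `(F, x)` with `F` above a threshold is mapped to the apparent
contour length `L0 = x / (ratio(F) * stretch(F))` of the QM-FRC chain that
would produce it. Between unfolding events the apparent contour length is
constant, so a trace becomes a ladder of levels ("barrier positions") whose
steps are the unfolding increments.

The transform is restricted to a *common force window*, 90--160 pN by
default. The reason is systematic, not cosmetic: the extension also
contains the PEG linkers and the folded domains, which do not follow the
FRC. Dividing them by the FRC ratio contributes a force-dependent offset
to the apparent contour length. If different inter-event segments are
sampled over different force ranges (the final segment reaches 600+ pN,
the fingerprint segments only ~150 pN), the offsets differ between
segments and the peak-to-peak spacings are biased by several nm. Keeping
one narrow window that every segment traverses makes the offset common to
all segments, and spacings become unbiased estimates of the increments.
The window sits just below the fingerprint unfolding forces; both bounds
are configuration options, and `force_max = Inf` recovers the broad
transform.

Per-curve histograms (1 nm bins) are assembled into a master histogram by
iterative cross-correlation alignment: each curve is shifted by the
integer-bin offset (within +/- 10 nm) that maximizes the correlation of
counts with the running master, compensating per-curve tether-length
differences. Peaks are found by prominence (default 5% of the maximum
count) and spacings between successive peaks are the measured increments.

## Fingerprint matching and bond history

Expected increments come from residue counting: `N x 0.365 nm` minus the
folded N--C length of the domain. The shipped table reproduces the
canonical Xyn (~89 nm), CBM (~56 nm) and XMod (~34 nm) increments; its
residue counts and folded lengths are synthetic placeholders chosen to be
consistent with those increments, not structure-derived measurements.

Measured increments are matched to templates in construct order: each
template takes the earliest contiguous run of unmatched increments whose
sum lies within tolerance (+/- 8 nm by default). The xylanase fingerprint
is three-peaked, so its template may span up to three consecutive
sub-increments; single-step domains match exactly one. Construct-order
matching is what makes the assignment robust: a best-error greedy matcher
will happily match the 89 nm template to the *sum* of the CBM and XMod
increments (55 + 33 = 88 nm), which is numerically closer than a
slow-speed-biased Xyn triplet. A curve is "specific" when Xyn and CBM both
match; its final rupture is tagged "shielded" when the XMod template also
matched (its unfolding preceded the rupture) and "intact" otherwise.

For per-curve levels the common force window is widened (30--500 pN) for
any segment with too few samples inside it -- the segment between X-module
unfolding and the immediately following rupture rarely revisits 90--160
pN, and at the slowest speeds the first Xyn unfolding can occur below 90
pN. The wider window costs a few nm, acceptable at the +/- 8 nm
classification tolerance; the master histogram keeps the strict window.

## Event detection and loading rates

Sawtooth peaks are detected on a 5-sample running median: local maxima
above 50 pN followed by a drop of at least 30 pN within 5 nm of extension,
with non-maximum suppression within that radius. Each accepted peak is
re-localized on the raw trace at the sample preceding the steepest raw
drop -- the drop (tens to hundreds of pN in one sample) is a far sharper
landmark than the noisy maximum, and localization is exact to a sample or
two at 5 pN noise.

The loading rate at a rupture is the slope of a least-squares line on
force vs time over the window spanning the final 20% of the force rise to
that peak. The window fraction trades noise against curvature: the loading
rate grows along the rise, so long windows systematically under-estimate
the tangent at the peak (about 15% at 30%, under 10% at 20% of the rise).

## Bell-Evans kinetics

The bond-rupture model is `k(F) = k_off exp(F delta_x / kBT)`. At constant
loading rate `r` the rupture-force density and survival have closed forms,
and the most probable rupture force is
`F* = (kBT / delta_x) ln(r delta_x / (k_off kBT))`. The sampler inverts
the analytic survival function (no rejection), so sampler and density can
be cross-checked by Kolmogorov--Smirnov distance -- this is also the
primary oracle for the KMC simulator.

At each pulling speed, the most probable rupture force and loading rate
are estimated by least-squares Gaussian fits to Freedman--Diaconis
histograms; loading-rate histograms are fitted in log10 space by default
(the per-speed loading-rate distribution is closer to log-normal; linear
space is one configuration switch away). The dynamic force spectrum
`(ln r*, F*)` is then fitted by linear least squares: the slope gives
`delta_x = kBT / slope` and the intercept gives `k_off`. Fits are
unweighted by default, with per-point `n_events` weighting available.
`k_off` is exponentially sensitive to the intercept -- a 10% error in
`delta_x` moves `k_off` by an order of magnitude -- so its uncertainty is
reported as a multiplicative factor, and recovery tests demand agreement
within a factor rather than a percentage. Negative predicted `F*` at very
low loading rates is clamped to zero with a warning so spectra remain
drawable.

## The KMC simulator

`simulate_trace()` advances the series circuit cantilever (50 pN/nm) --
PEG -- polyprotein -- complex at constant retraction speed. At each time
step the separation `v t` is partitioned between cantilever deflection
`F/k_c` and polymer extension by solving the monotone series force
balance (table inversion plus Newton refinement on spline representations
of the two elasticity curves; the test suite re-derives the polymer
extension from the event log and checks the recorded curves against it).
Unfolding and rupture are sampled from step-integrated Bell hazards
(trapezoidal rule over each step, exponential clock), which keeps the
discretization error of rupture forces below the force quantization of a
step (~1 pN at default settings). Unfolding grows the unfolded contour by
`delta_Lc` plus the released folded length and the force relaxes through
the force balance. Gaussian noise (5 pN) is added to the reported force
only. After the final rupture a short baseline tail (10 ms) is recorded,
as an instrument would, so that the last drop is detectable.

Defaults define the simulated study conditions: pulling speeds in the
experimental 200--6400 nm/s range (1600 nm/s when unspecified), 20 kHz
sampling, fingerprint kinetics placed so that most probable unfolding
forces land at ~115 pN (Xyn sub-steps, 30/30/29 nm) and ~155 pN (CBM), the
X-module and the two complex classes at the fitted values
(`delta_x` = 0.15/0.13/0.19 nm, `k_off` = 2.6e-6/7.3e-7/4.7e-4 1/s).

Whether a trace takes the shielded path is decided by an explicit branch
probability (0.375) rather than emergent rate competition: with the fitted
X-module and intact-complex parameters, naive competition does not
reproduce the observed 35--40% branch fraction (the X-module's most
probable unfolding force lies ~120 pN below the intact rupture force, so
competition would make shielding dominate). The emergent mode remains
available behind `emergent_competition = TRUE` for exploring that
discrepancy. A configurable fraction of "junk" traces -- random WLC
peeling events with no fingerprint -- exercises the screening stage.

What the simulator does not emulate: thermal cantilever dynamics and
hydrodynamic drag, surface adhesion, drift, multiple tethers, PEG's
conformational transition, and refolding within a trace (domain refolding
between traces is a dataset-level property; the xylanase is marked
non-refoldable). Passing tests on synthetic data therefore demonstrate
the correctness of the reduction pipeline under the modelled physics, not
robustness to every instrumental artifact of real curves.

## Known limitations

* The shielded-class dynamic force spectrum is intrinsically biased: a
  shielded rupture follows X-module unfolding within milliseconds, before
  a fresh force ramp is established, so modal forces partly reflect the
  post-unfolding force rather than a constant-rate rupture. The end-to-end
  test therefore requires exact recovery for the intact class but only
  order-of-magnitude agreement for the shielded class.
* In mixed-speed campaigns the lowest (pre-Xyn) barrier peak of the master
  histogram smears, because unfolding forces -- and with them the
  force-window sampling of the first segment -- shift with speed; domain
  increments from a master histogram are most reliable per speed, as in
  the single-speed fingerprint-recovery test.
* Curve containers are plain-text TSV (single-curve files or a long-format
  dataset directory); configuration files are YAML.

## Problem sizes used by the test suite

Fingerprint recovery runs 200 simulated configuration-I traces at 1600
nm/s; parameter recovery samples 500 rupture forces at each of 5 loading
rates; the simulator-vs-closed-form check uses 2000 single-bond traces;
the end-to-end recovery uses 500 traces across five speeds (200--3200
nm/s); the branch-fraction check uses 600 traces at reduced sampling.
These sizes put the stochastic checks comfortably inside their tolerances
(binomial or KS margins of at least two standard errors) while keeping the
whole suite fast.
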