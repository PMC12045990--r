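---
title: "Models and methods behind organoidmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind organoidmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(organoidmech)
```

This vignette is the package's own account of the four analyses it
implements: what each model assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generators
emulate (and what they deliberately do not), and the numerical choices
made where the methods literature leaves the design open.

## 1. Creep rheology under micropipette aspiration

A brain organoid held against a pipette of inner radius $R_p$ under
constant suction $\Delta P$ is aspirated a length $L(t)$ into the
pipette. In the half-space approximation — valid while $L \lesssim R_p$
and the organoid is much larger than the pipette opening — the creep
compliance is

$$J(t) = \frac{2\pi L(t)}{3 \phi R_p \Delta P},$$

with $\phi = 2.1$ a geometric wall factor. The formula is dimensionally
safe only when $L$ and $R_p$ share units; `compute_creep_compliance`
takes both in micrometers so their ratio is dimensionless and $J$ carries
units of $\mathrm{Pa^{-1}}$.

Organoid creep is well described by the minimal solid-like viscoelastic
model, the standard linear solid: a spring $k_1$ in parallel with a
Maxwell arm (spring $k_2$ in series with dashpot $\mu$). Its creep
function in the intuitive parameterization is

$$J_{SLS}(t) = \frac{1}{k_{st}}\!\left(1 -
  \frac{k_0 - k_{st}}{k_0} e^{-t/\tau}\right),
  \qquad k_0 = k_1 + k_2,\; k_{st} = k_1,\;
  \tau = \frac{\mu (k_1 + k_2)}{k_1 k_2}.$$

The model assumes linear response (small deformations, constant load), an
instantaneous elastic jump $J(0^+) = 1/k_0$, and a finite steady state
$1/k_{st}$ — a *solid*, not a fluid; tissues that flow indefinitely under
load would need an additional free dashpot and are out of scope.

**Fitting.** `fit_sls` runs Levenberg–Marquardt least squares in
log-parameter space over $(\log k_{st}, \log k_2, \log \tau)$ with
$k_2 = k_0 - k_{st}$, which enforces positivity and the ordering
$k_0 \ge k_{st}$ by construction rather than by penalty. Starting values
come from the data: $k_0$ from the first post-onset compliance, $k_{st}$
from the final 10% of samples, $\tau$ from the midpoint crossing. These
endpoint-based guesses put the optimizer inside the correct basin for any
monotone rising record; a pathological near-zero first sample caps the
$k_0$ guess at $20 k_{st}$. A flat record (pure elastic response) makes
$\tau$ unidentifiable; the fit then reports $k_0 = k_{st} = 1/\bar J$
with a `degenerate_tau` flag instead of pretending to a timescale.
$R^2$ uses the total sum of squares about the mean of $J$ over the
fitted window — the conventional definition.

**Onset detection.** Records include a lead-in of about two seconds
before suction. The onset is the first of three consecutive samples
exceeding the baseline mean plus $\max(3\sigma_{baseline},\,10\%$ of the
rise to the plateau$)$. The 10% floor exploits the physics: the SLS
elastic jump is a large fraction ($k_{st}/k_0$, here $\ge 0.6$) of the
plateau, so the floor sits far above tracking noise yet far below any
genuine onset; isolated baseline spikes can then never contaminate the
fitted window. An explicit `suction_onset` always overrides detection.

**Group statistics.** Two-condition comparisons use the pooled-variance
Student $t$; three or more use the one-way ANOVA $F$. Both are written
from their closed forms (and cross-checked against `t.test`/`aov` in the
test suite) so the module's statistical outputs are fully auditable.

## 2. The diluted fiber-network model of tissue stiffness

The ECM of a tissue cross-section is modeled as a two-dimensional
triangular lattice (rest length $l_0 = 1$) whose edges are fiber
segments; a straight line of edges along one of the three principal
directions is one collagen fiber. Cells are individual lattice triangles
with an area stiffness. The energy is

$$E = \frac{k_s}{2}\sum_{\langle ij\rangle} p_{ij}(l_{ij}-l_0)^2
    + \frac{k_b}{2}\sum_{\langle ijk\rangle} p_{ij}p_{jk}
      (\theta_{ijk}-\pi)^2
    + \sum_{n=1}^{N_c} \lambda q_n (A_n - A_0)^2,$$

stretching over occupied edges, bending over pairs of consecutive
collinear occupied edges (rest angle $\pi$; no bending at fiber
crossings, since only collinear runs constitute one fiber), and an area
penalty for each of the $N_c$ cell triangles. The dimensionless ratio
$R = k_s/(k_b l_0^2)$ compares stretching to bending stiffness; with
$l_0 = 1$ the defaults are $k_b = 1$, $k_s = R = 10$, $\lambda = 1$. The
default system is the study configuration: $N = 64$ nodes as an
$8\times8$ lattice (read as total nodes, the natural reading of
"$N$ nodes"), $N_c = 32$ cells, periodic horizontally and open
vertically.

**Dilution.** Random mode keeps each edge independently with probability
$p$ — disorganized ECM. Patterned mode removes the edges whose midpoints
are nearest the system center, which is exactly the midpoint-in-circle
rule with the circle radius solved to match the target occupied fraction
within one edge (ties at equal distance broken by a seeded shuffle) —
ECM cleared from one localized region. Bending terms carry the product
$p_{ij}p_{jk}$, so a triple dies with either member edge. Dangling edges
and floating clusters are retained; they carry no load and their only
effect is honest bookkeeping of the realized $p$.

**Compression and stiffness.** Strain $\gamma$ clamps the top and bottom
node rows to a height $(1-\gamma)H_0$ (boundary nodes slide freely
horizontally; the periodic width is fixed); interior degrees of freedom
relax by L-BFGS with the analytic gradient to a projected-gradient
tolerance of $10^{-8}$, each strain continuing from the previous relaxed
state. The interior angle enters through the wrapped signed angle between
the two arm vectors, which is smooth at the rest angle $\pi$ — the
formulation matters, since a naive $\arccos$ has a singular gradient
exactly at rest. Stiffness is

$$K = \frac{1}{A_{sys}} \frac{d^2 E_{min}}{d\gamma^2},$$

by central differences with $\Delta\gamma = 10^{-3}$ at an evaluation
strain of $\gamma = 0.01$, inside the near-linear regime. The intensive
prefactor is taken as the undeformed system area $A_{sys}$ rather than
the cell rest area $A_0$; the two readings differ only by a constant, so
every *relative* comparison (including the patterned-versus-random
contrast) is invariant to the choice, and $K$ is reported in simulation
units throughout. Replicates redraw both the dilution and the random
cell placement per seed.

On the default configuration the patterned network at $p = 0.85$ is
substantially softer than the random network at $p = 0.95$
(`compare_patterning` reports the relative increase, about 40–45% over
20 seeds). The direction and nonlinearity of the effect — a localized
hole is a weak spot that compression concentrates into — is robust; the
precise percentage depends on parameters with no printed values (cell
stiffness $\lambda$, bending stiffness $k_b$, the evaluation strain),
all fixed here a priori at their simplest choices.

## 3. ADC distributions from multi-b diffusion MRI

The signal of a diffusion-weighted acquisition decays with the b-value as
$S(b) = S_0 e^{-b\,\mathrm{ADC}}$ under the mono-exponential model (no
tensor anisotropy, no multi-compartment water — deliberate scope limits).
`fit_adc_map` solves the log-linear least-squares problem per voxel in
closed form over all b-values; voxels with any non-positive intensity or
a negative fitted ADC are excluded and counted rather than floored, so
exclusions remain auditable. Tissue is segmented on the highest-b image
(where free medium has decayed away) by Otsu thresholding with
small-object removal; a manual threshold and a per-well label map are
accepted alternatives.

The masked ADC values per group form a 100-bin histogram normalized to
unit sum (unit area is the other convention; the maximal-likelihood
position is invariant to the choice). The histogram range defaults to the
group's min–max, with a shared-range option for overlays. Denoising
zeroes all DFT components above the 10 lowest nonzero frequencies —
enough to remove bin-level sampling noise while preserving a unimodal
envelope; the cutoff is exposed and keeping all 50 modes is the identity.
Negative post-inverse ripple is clipped at zero before peak finding.

Because the distribution is asymmetric, the robust location is the
**2/3·Imax rule**: find the denoised peak height, interpolate the left
and right crossings of two-thirds that height (nearest the peak when
ripple yields several), and take the midpoint. A distribution truncated
at the histogram edge has no crossing on one side and raises an error
rather than returning a biased midpoint.

Scans repeated over hours drift upward in ADC. The per-scan relative
deviation $(\mathrm{ADC}_{group} - \mathrm{ADC}_{ref})/\mathrm{ADC}_{ref}$
cancels any drift common to the groups exactly (up to histogram-bin
quantization of the rescaled values), and the matched $t$ statistic over
scans tests each contrast against zero.

## 4. Radial (Sholl) profiling of collagen signal

The section center and radius come either from a manually drawn widest
diameter (center = midpoint, radius = half-length, the original
procedure) or automatically from the mask centroid and its maximal
distance to the boundary. Concentric circles at normalized radii
$0.02, 0.04, \dots, 1$ (50 circles; the increment is exposed) are
rasterized at sub-pixel angular steps, and each contiguous arc of
signal-positive pixels on a circle counts as one intersection — the
Sholl-intersection semantics. Counts are invariant to intensity rescaling
above threshold and stable under image rotation up to rasterization
(±1 per bin). Normalizing distances by the section radius makes sections
of different sizes comparable.

Condition comparisons pool per-circle observations — by default the
counts themselves; optionally each intersection's radius
(`pooling = "radius_weighted"`), which compares radial positions instead
of local signal density; the observation unit entering the original
rank-sum comparison is not fully specified, so both poolings are exposed.
The Mann–Whitney U statistic is computed from the rank-sum closed form,
with exact enumeration of all arrangements for combined $n \le 20$ and
the tie-corrected normal approximation (no continuity correction) above.

## 5. What the synthetic data emulate — and what they do not

All generators are pure functions of their seed.

- **Creep traces**: SLS kinematics inverted through the compliance
  relation, a two-second quiet baseline, multiplicative tracking noise on
  the tongue length (tracking error scales with length). Default noise
  is 1%, the level at which synthetic fits show exactly the fit quality
  the real aspiration measurements report ($R^2$ typically > 0.98 per
  trace, > 0.99 on mean curves); the generator does not emulate pipette
  wall friction, pre-stress from the engagement pressure, or tissue
  heterogeneity under the pipette.
- **DWI phantoms**: disk organoids in per-group wells on a 96×96 grid,
  log-normal within-organoid ADC heterogeneity (positive support,
  right-skewed — the asymmetry the 2/3·Imax rule exists for), b-values
  $\{0, 200, 400, 600, 1000, 1200\}$ s/mm², Rician magnitude noise at
  SNR 30, a common 2%-per-scan multiplicative ADC drift over five scans.
  Not emulated: partial-volume edges, susceptibility distortion,
  registration error.
- **Collagen images**: a solid annulus at normalized radius 0.8
  (peripheral, early-stage-like; smaller radii model the later
  internalized ring) versus uniformly scattered puncta painted until the
  signal area matches the ring's, so the phenotypes differ in
  organization but not total intensity — mirroring the equal-intensity,
  different-distribution observation. Gaussian background noise; no
  autofluorescence gradients or sectioning artifacts.

Passing tests on these phantoms demonstrates that the *pipeline* is
correct and sensitive at realistic noise levels; it does not certify
performance on real images whose artifacts the generators exclude.

## 6. Numerical choices and problem sizes

- Energy minimization: L-BFGS-B, `pgtol` $10^{-8}$, analytic gradients
  (verified against numerical differentiation to $10^{-10}$); failures
  raise errors with diagnostics instead of returning silently.
- Stiffness: central differences, $\Delta\gamma = 10^{-3}$; halving the
  step moves $K$ by < 1% on seeded networks. The tiny-lattice Hessian
  quadratic form (with pseudo-inverse for the periodic zero mode) agrees
  with the finite-difference $K$ to < 1%.
- The test suite and the acceptance script use the study-scale
  configuration (64 nodes, 32 cells, 20 seeds per condition; 96×96
  phantoms over 5 scans; 50 creep traces), which completes in a few
  minutes of single-core compute — the model is intentionally a minimal,
  desk-scale representation, not a production finite-element solver.
- Degenerate inputs are first-class: flat compliance records flag a
  degenerate $\tau$; empty masks, uniform images, unmatched scan sets,
  unreachable dilution patterns, and too-small lattices all raise typed
  invalid-input errors.

## 7. Known limitations

- The fiber network is two-dimensional (a cross-section); no
  three-dimensional generalization is attempted.
- Matrix proteolysis is represented only as reduced occupation
  probability, not as enzyme kinetics.
- The aspiration module consumes extracted $L(t)$ series; it does not
  track the tongue in microscopy video.
- The exact percentage of the patterned-versus-random stiffness contrast
  depends on unprinted model parameters (see Section 2); the package
  reports its own computed value rather than tuning toward any external
  one.
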