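---
title: "Methods: reduced-order FFR modelling and virtual PCI planning in serial coronary disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order FFR modelling and virtual PCI planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrplan)
```

## Scope and assumptions

`ffrplan` models a single epicardial conduit under steady, maximal
hyperemia. The working assumptions are:

* **steady state** — invasive FFR is a cycle-averaged hyperemic Pd/Pa; a
  0D/1D steady model has no pulsatile content to reproduce, so the simulated
  pressure-wire pullback is simply the steady FFR profile traversed distal
  to proximal;
* **rigid walls, Newtonian blood** — μ = 0.0035 Pa·s, ρ = 1050 kg/m³ by
  default (conventional values; both configurable);
* **circular lumen** — area A = πr² from the sampled radius profile;
* **single conduit** — no bifurcations and no branch flow loss along the
  vessel. Daughter-branch steal is real physiology but is deliberately out
  of scope; all flow entering the ostium reaches the outlet.

Units are mmHg, mL/s and mm at every interface; conversion to SI happens
internally with 1 mmHg = 133.322 Pa, fixed.

## The pressure-drop law

A segment's pressure drop at flow $Q$ is

$$\Delta P(Q) = R_v\,Q + S\,Q\lvert Q\rvert,$$

with the viscous part the Poiseuille integral over the sampled profile,
$R_v = \int 8\pi\mu/A(s)^2\,ds$ (trapezoidal rule), and the inertial part
the classical post-stenotic expansion (separation) loss per constriction,

$$S = \frac{K_t\,\rho}{2}\left(\frac{1}{A_\min} - \frac{1}{A_{out}}\right)^2,
\qquad K_t = 1.52,$$

where $A_\min$ is the throat area and $A_{out}$ the lumen area at the
constriction's exit. $K_t = 1.52$ is the standard empirical expansion
coefficient for smooth axisymmetric stenoses. This linear-plus-quadratic
structure in $Q$ is exactly what the two-point resistance calibration below
assumes, and it is parameterized by nothing beyond $A(s)$, μ and ρ.

Constrictions are found by comparing the profile against its **least
concave majorant** (upper hull) — the tightest healthy envelope consistent
with a narrowing-only disease model. Each contiguous run of samples whose
narrowing versus the envelope exceeds a small edge fraction, and whose peak
percent stenosis exceeds 5%, contributes one expansion term. Bulges
(r above the envelope) never generate a term, and their measured radii
enter the viscous integral as-is: mild aneurysmal segments therefore only
*lower* resistance, which is the physically conservative treatment for a
model that does not attempt aneurysm hemodynamics.

The fine-grid solver (`oracle_solve()`, default grid 0.05 mm) assembles
these coefficients over the whole vessel and finds the flow satisfying
$P_a - P_v = \Delta P_{epi}(Q) + R_{micro} Q$ by bracketed root-finding
(bracket $[10^{-6}, 50]$ mL/s, `uniroot` tolerance $10^{-12}$, Newton
polish to a residual below $10^{-9}(P_a - P_v)$). Within the profile, each
expansion loss is recovered linearly between throat and exit, so pressures
are monotone non-increasing. Halving the grid moves distal FFR by well
under 0.002 on two-lesion vessels; this solver is the package's ground
truth wherever "true" gradients are quoted.

## Hyperemic boundary conditions

The microvascular outlet follows three principles, in deliberately
simplified, configurable form:

1. resting flow scales allometrically with subtended myocardial mass,
   $Q_{rest} = q_{scale} M^k$, $k = 0.75$ (metabolic exponent);
2. subtended mass scales with vessel caliber: a vessel of inlet radius $r$
   is assigned $M \propto (r/1.8\,\mathrm{mm})^{2.6}$, so larger vessels
   carry proportionally more flow;
3. maximal hyperemia multiplies the resting microvascular resistance
   $R_{rest} = (P_a - P_v)/Q_{rest}$ by a fixed factor, default 0.24 — the
   canonical adenosine value in the CT-FFR literature.

The defaults `myocardial_mass_g = 100`, `q_scale = 0.013` were fixed once
by simulating the default synthetic cohort and requiring its pre-PCI distal
FFR distribution to bracket the severity mix of a serial-disease study
population (mean in 0.60–0.75, range covering [0.45, 0.90]); the default
cohort lands at mean ≈ 0.65–0.67 with SD ≈ 0.21. Population-derived
resistance models in clinical CT-FFR products are proprietary; these
constants are this package's own calibration and should be re-fitted if
absolute (rather than comparative) flows matter to an application.

## Reference lumen, percent stenosis and idealization

Quantitative coronary angiography derives a lesion's reference diameter by
interpolating between the adjacent normal segments. The package adopts the
same rule: inside a lesion extent the reference radius is the **chord
between the measured radii at the extent boundaries**; outside lesions the
reference is the measured radius. Percent diameter stenosis is
$100(1 - r_\min/r_{ref})$ at the sampled throat. Whether proprietary
CT-FFR pipelines use a QCA-style interpolation or a learned healthy-lumen
model is not public; the chord rule is the defensible, transparent choice
and is applied consistently everywhere (detection, idealization, fallback
coefficients).

Virtual stenting (`idealize_lumen()`) replaces radii inside the stented
extent by this reference — a perfectly deployed stent with no recoil,
foreshortening or malapposition. The operation is idempotent, leaves every
sample outside the extent bit-identical, and drives the percent stenosis of
any treated sub-extent to zero. Post-PCI remodelling of the *untreated*
lesion under its higher operating pressure is a known physiological effect
that is deliberately not modelled.

### Lesion detection

`detect_lesions()` separates two thresholds that a single number cannot
serve. `min_pct` (default 30, the angiographic inclusion threshold) gates a
narrowing's **peak** severity; the lesion's **extent**, however, is
delimited where narrowing versus the concave-majorant envelope exceeds
`edge_frac` (default $10^{-8}$). Smooth-shouldered stenoses approach their
reference tangentially, so any sizeable edge threshold would clip their
shoulders and a pure `min_pct` extent rule would report only the deep core
of each lesion. With the tiny default, planted generator lesions are
recovered to within one sample spacing; for measured profiles with
segmentation noise `edge_frac` of 0.01–0.05 is more appropriate. Extents
separated by less than `min_gap` (default 10 mm, the study-style normal-gap
rule) merge into one lesion before severity is assessed. Lesions are
half-open intervals `[start, end)` in mm from the ostium, which keeps
shared boundaries unambiguous when segments tile the vessel.

## Reduced-order calibration

Each segment (one per lesion, one per healthy stretch — granularity chosen
so serial interplay remains representable) carries the flow-dependent
resistance $R(Q) = R_{in} + R_{sl} Q$. Calibration solves the whole vessel
twice: under hyperemia, and under hyperemia with the microvascular
resistance lowered by 40% ($R_{micro} \leftarrow 0.6 R_{micro}$ — the
reduction is applied to the microvascular bed, which is the only resistance
a pharmacological stimulus could plausibly shift). With flows $Q, Q^*$ and
per-segment resistances $R = \Delta P/Q$, $R^* = \Delta P^*/Q^*$:

$$R_{sl} = \frac{R^* - R}{Q^* - Q}, \qquad R_{in} = R - R_{sl} Q.$$

The fit reproduces both calibration states exactly. When the achieved flow
separation $Q^* - Q$ falls below `flow_tol` (default 0.05 mL/s — no
published threshold exists; at this value the finite difference loses
roughly two significant digits and is no longer trustworthy), the
coefficients are replaced by the analytic law itself: $R_{in} = R_v$,
$R_{sl} = S$ over the segment. This happens precisely when epicardial
disease dominates the total resistance — severe vessels — where the
analytic coefficients are also at their most accurate.

The assembled network solves a single quadratic for flow, then accumulates
per-segment drops; its FFR profile is piecewise linear between segment
boundaries. On 80-vessel cohorts the network's distal FFR agrees with the
fine-grid solver to a few times $10^{-5}$ on average (the acceptance suite
requires mean ≤ 0.01, max ≤ 0.03 and TOST equivalence at ±0.02).

`plan_pci()` re-uses the pre-PCI calibration for untouched segments — their
geometry is unchanged, and the flow-dependence of $R(Q)$ is exactly what
makes the coefficients transferable across flow states — and refreshes
stent-overlapping segments with analytic coefficients on the idealized
lumen. A plan evaluation after the one-time calibration therefore costs a
quadratic solve plus bookkeeping: well under 50 ms on one core.

## Pullback metrics and statistics

Per-lesion gradients are read `margin` mm beyond the lesion shoulders
(default 2 mm, clear of the separation zone; when two lesions sit closer
than twice the margin the readings shrink to the half-gap with a warning).
The same read points serve the apparent (pre-PCI), true (companion-removed)
and planner-predicted gradients, so method comparisons are not confounded
by read-point choice. The paper-style protocol — idealize the companions,
re-solve on the fine grid, re-read the target — defines `true_gradient()`.

`assess_cohort()` reports discrepancy (truth − estimate; positive =
underestimation) mean and SD, mean relative error
($100\lvert d\rvert / \text{truth}$, averaged), Pearson r, Bland-Altman
bias with 1.96·SD limits of agreement (the "95% CI" dashed lines of the
standard display), a two-tailed paired t test, and TOST equivalence as the
larger of the two one-sided paired-t p-values at ±`tost_margin` (default
0.02 FFR; equivalence margins are a study-design choice, and 0.02 is well
inside clinical decision resolution). Zero-variance differences with a
nonzero mean are reported as undefined rather than fabricated.

## The synthetic cohort

The generator emulates the anatomy a serial-disease study enrols, not CT
imaging: a linear-taper healthy baseline (length U(80, 140) mm, inlet
radius U(1.4, 2.2) mm, taper U(10, 30)%) times raised-cosine narrowings
(depth such that percent stenosis ~ U(40, 85), length U(8, 25) mm), two per
vessel, separated by ≥ 10 mm of normal lumen and kept 5 mm clear of both
ends, placed by rejection sampling. Because the dip multiplies the local
baseline, the planted depth *is* the percent stenosis at the throat, which
makes detection round-trips exact. Each vessel draws from its own RNG
substream derived from `(seed, index)` via a fixed LCG step, so cohorts are
bit-reproducible and order-independent.

What the generator does **not** emulate — lumen segmentation error, CT
blooming and motion artifacts, eccentric or non-axisymmetric stenoses,
bifurcations, microvascular heterogeneity — bounds what green tests mean:
they validate the reduced-order machinery against the 1D ground truth and
reproduce the *direction and structure* of serial-stenosis underestimation,
not the absolute error statistics of any clinical cohort.

## Numerical choices and degenerate inputs

* resampling default 0.25 mm (finer than any generator lesion), fine-grid
  solver 0.05 mm; both arguments everywhere;
* vessels need ≥ 10 samples, strictly increasing arc length, positive
  radii; lesions touching a vessel endpoint have no healthy flank and are
  rejected rather than guessed at;
* plan rankings break ties deterministically: higher predicted distal FFR,
  then shorter stent, then more proximal start;
* experiment cohorts assess each lesion once with its companion stented
  (policy `"both"`); the single-PCI policies `most_severe`, `proximal`,
  `distal` mirror an operator treating one lesion per the clinical
  protocol;
* test and acceptance problem sizes — 80 vessels for network-vs-solver
  equivalence, 100 two-lesion vessels (both ≥ 50%) for the underestimation
  and planner-accuracy checks — are the package's chosen study conditions:
  large enough for stable cohort statistics, small enough to keep the whole
  suite in well under a minute.

## Known limitations

Single conduit, steady flow, axisymmetric lumen, no branch steal, no
post-PCI remodelling of untreated lesions, no pressure-wire artifacts
(drift, whipping), no resting indices (iFR). The fine-grid 1D law is the
package's ground truth; a 3D solver would additionally resolve
lesion-eccentricity and jet-impingement effects that no 1D law represents,
and nothing here claims otherwise.
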