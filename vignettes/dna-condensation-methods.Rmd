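---
title: "Models and methods: DNA length-dependent condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DNA length-dependent condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacondense)
```

# Scope

DNA in a crowded or cationic environment undergoes two related,
length-dependent transitions: a single molecule in dilute solution
collapses from coil to globule once the solvent is poor enough, and at
higher concentration the solution demixes into a dense condensate phase
coexisting with a dilute phase. Experimentally, the resulting
condensates range from liquid-like droplets that recover quickly after
photobleaching to static, irregular aggregates. This package implements
both sides of that story: the Post–Zimm extension of Flory–Huggins
theory that predicts how chain length shifts collapse and coexistence,
and the measurement pipeline used to characterize condensates —
FRAP recovery fitting, aspect-ratio morphometry with fluidity-class
clustering, and intensity-decay/molecule-counting analysis of
surface-anchored condensates under flow. Everything is exercised on
synthetic data with known ground truth; no microscopy data ships with
the package.

# The polymer model

## Free energy

The solution free energy per lattice site (units of $kT$, solvent site
volume $V_s$; $V_s$ cancels from all coexistence conditions and never
needs a value) is

$$
g(\phi,\alpha) = (1-\phi)\ln(1-\phi) + \frac{\phi}{N}\ln\phi
 + \chi\,\phi(1-\phi) + \frac{\phi}{N}\,A(\alpha),
$$

the classic Flory–Huggins mixing terms plus, per chain, the internal
free energy of a Gaussian chain with expansion factor $\alpha$ (radius
of gyration relative to the $\theta$-solvent state):

$$
A(\alpha) = N\!\left[(\chi-1) + \frac{B_2\,\omega}{2^{3/2}\alpha^3}
 + \frac{B_3\,\omega^2}{2\cdot 3^{5/2}\alpha^6}\right]
 + \frac{3}{2}(\alpha^2 - 1) - 3\ln\alpha .
$$

The $B_2$ and $B_3$ terms are the two- and three-body intersegment
contact contributions of the virial expansion evaluated over the
Gaussian segment cloud; the remaining terms are the elastic entropy of
deforming the chain. Setting $\partial A/\partial\alpha = 0$ gives the
degree-8 stationarity polynomial

$$
3\alpha^8 - 3\alpha^6 - N\left(\frac{3 B_2 \omega \alpha^3}{2^{3/2}}
 + \frac{B_3 \omega^2}{3^{3/2}}\right) = 0,
$$

whose positive real roots `expansion_alpha()` obtains exactly with
`polyroot()`; the free energy is evaluated at every root and at the
interval boundary ($0 \le \alpha \le 1.5$) and the global minimum wins.
Above the collapse point the minimum jumps discontinuously from the
coil branch ($\alpha \approx 1$) to a compact globule
($\alpha^3 \approx \omega B_3 2^{3/2} / (3^{5/2}|B_2|)$, typically
$\alpha \sim 10^{-2}$ for kb-scale DNA).

## Parameters and units

| parameter | default | meaning |
|---|---|---|
| mass per bp | 650 g/mol | standard average for double-stranded DNA |
| $N$ | $M/4000$ | lattice segments per chain (solvent reference mass 4000 g/mol) |
| $\langle h_0^2\rangle$ | $4\times 10^{-15} M^{8/7}$ cm$^2$ | unperturbed mean-square end-to-end length ($M$ in g/mol) |
| $\omega$ | $9\pi M / (N_A \rho \langle h_0^2\rangle^{3/2})$ | flexibility measure: scaled segment volume fraction inside the unperturbed coil |
| $q$ | 10 | lattice coordination number |
| $\rho$ | 1.8 g/cm$^3$ | DNA density; converts $\phi$ to mass concentration $c = \phi\rho$ |
| $B_2$ | $1/2 - \chi$ | two-body virial coefficient |
| $B_3$ | $1 + \chi^2/(2q) - \chi^3/(6q^2)$ | three-body virial coefficient |

Two groupings of the $B_3$ expression circulate for this model family;
the series grouping $1 + \chi^2 q/2 - \chi^3 q^2/6$ is also provided
(`virial_B3_series()`) but is **not** the default because it turns
negative for $\chi \gtrsim 0.52$ at $q = 10$, which removes the
three-body repulsion stabilizing the globule: $A(\alpha) \to -\infty$
as $\alpha \to 0$ and the model loses its minimum over most of the
interesting solvent range. The default grouping keeps $B_3 > 0$ and
$O(1)$ everywhere. The constant in $\omega$ fixes only the
logarithmic elastic penalty of the globule; together with the
boundedness requirement it was chosen so that the model reproduces the
characteristic behavior it exists to describe — a collapse threshold
$\chi$ that falls from $\approx 1.1$ at 200 bp to $\approx 0.5$ at
chromosome scale, and a dilute-branch coexistence concentration at
$\chi = 0.7$ of order $10^2$ mg/mL for 200 bp versus order
$10^{-1}$ µg/mL for 2.5 kb (six orders of magnitude apart). Both
numbers are computed, not asserted, by `analysis/01_theory_phase_diagrams.R`
and the test suite.

## Binodal construction

At coexistence the DNA and solvent chemical potentials (obtained by
differentiating the extensive free energy with respect to molecule
numbers; the test suite checks the analytic forms against Richardson
finite differences) are equal between phases. Following the model's
physical picture, the dilute phase uses the collapse solution
$\alpha(\chi)$ while the dense phase uses the unperturbed
$\theta$-solvent value $\alpha(\chi = 0.5)$ — in a condensate,
intermolecular contacts replace the intramolecular ones that drive
single-chain collapse (`alpha_dense = "unity"` pins it at exactly 1
instead; the dilute branch moves by well under a percent).

Numerically, `binodal_point()` does not solve the raw 2-D system: for
kb-scale chains the admissible dense window is only $\sim 10^{-5}$ wide
in $\phi_2$, and for chromosome-scale chains $\phi_1$ underflows IEEE
doubles ($\ln\phi_1 \sim -10^5$). Instead the dilute branch is
parameterized by $u = \ln\phi_1$ and, for each $u$, the dense
$\phi_2$ matching the solvent potential is found on the branch above
the upper extremum of $\mu_s(\phi)$ (the extrema are roots of
$2\chi\phi^2 - (2\chi - 1 + 1/N)\phi + 1/N$), where $\mu_s$ is strictly
decreasing, so the match is unique. The outer root of the DNA-potential
mismatch in $u$ is bracketed analytically (the valid window is bounded
below by $\mu_s$-level matching when $\mu_s(\phi_b) < 0$) and polished
with `uniroot()` at tolerance $10^{-13}$; residuals are checked against
$10^{-8}$ ($|\Delta\mu_{DNA}|$ assessed per segment so the criterion is
meaningful for $N \sim 10^7$). Below the critical point (no real
$\mu_s$ extrema, or no sign change) the result is a typed
"no coexistence" value, not an error. `log10_c_dilute` is reported
alongside the linear concentration so orderings remain exact after
underflow.

The collapse line of a phase diagram is defined operationally: the
smallest grid $\chi$ at which $\alpha$ drops below 0.5 or jumps down by
more than 0.2 between grid points (both configurable), since the
transition is a first-order-like jump whose exact visual criterion is
otherwise arbitrary.

# FRAP analysis

Normalized recovery follows the single-exponential exchange model
$\mathrm{FRAP}(t) = a(1 - e^{-kt})$ with mobile fraction $a$, exchange
rate $k$, and $t_{1/2} = -\ln(0.5)/k$. Because the model fixes
$\mathrm{FRAP}(0) = 0$, `normalize_frap()` maps the pre-bleach mean to
1 and the first post-bleach value to 0 (an affine transform only, so
camera gain and offset cancel exactly). Fitting uses bounded
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
$a \in [0, 1.2]$ and $k \in [10^{-5}, 10]$ s$^{-1}$, started from the
late-time plateau and the time-to-half-plateau; parameters landing on a
bound flag the fit. Any immobile contribution — including molecules
pinned to the glass surface — folds into $1 - a$ and is not modeled
separately. No multi-component or diffusion-reaction recovery model is
offered; within this package's scope the single-exponential form is the
measurement model. Acquisition-cadence defaults (300 frames at 0.8 s)
match standard practice for these condensates.

# Morphology and fluidity classes

`segment_condensates()` thresholds a Gaussian-smoothed image
($\sigma = 1$ px) with Otsu's method, labels connected components, and
drops objects under 20 px (all configurable; a distance-map watershed
splits touching objects on request). The shape statistic is
$(R_{max} - R_{min})/(R_{max} + R_{min})$ with $R$ the distances from
the (intensity-weighted) centroid to the boundary contour — 0 for a
circle, $\to 1$ for a rod, and exactly $(a-b)/(a+b)$ for an ellipse
with semi-axes $a \ge b$, which anchors the tests (a 2:1 ellipse gives
1/3). Boundary pixels quantize the contour, so tolerances of 0.03 at
radii $\ge 30$ px apply; half-Feret radii are available as an
alternative convention. Single-pixel masks get aspect ratio 0 with a
degeneracy flag.

Conditions (one length-concentration cell each) are clustered on
min-max-scaled mean aspect ratio and mean mobile fraction with
Euclidean complete-linkage `hclust`, cut at $k = 3$; z-scoring is
available. Clustering operates per condition, not per condensate.
Cluster identities are arbitrary, so clusters are mapped to classes by
decreasing mean mobile fraction — region I (liquid-like) is defined by
its dynamics — with ties broken by increasing mean aspect ratio.
Conditions without condensates are excluded and labeled
"no condensates".

# Flow stability and molecule counting

Two-channel stacks are registered with integer-pixel FFT
cross-correlation shifts estimated on channel 1 and applied to both
channels; sub-pixel registration is deliberately omitted because the
max-pixel statistic is insensitive to sub-pixel error. Per condensate
and frame the trace is the maximum pixel inside the frame-1 mask minus
the mean of a surrounding ring (mask dilated by 2 px to 5 px,
configurable), which removes any spatially uniform background exactly.
Only condensates detected in both channels are kept. Disassembly
kinetics are fitted with bounded single- or double-exponential decays
(amplitudes $\ge 0$; double fits returned fast-component-first); the
offset term defaults to off, modeling decay to zero, and
`compare_decay_models()` selects between the forms by AICc. Molecule
numbers are the condensate intensity divided by the single-dye
intensity (median of a calibration measurement,
`estimate_single_dye()`) and the labeled fraction, reported as a
continuous estimate with a rounded convenience column. For aggregate
decay curves, per-condensate traces are normalized to the mean of their
first three frames and averaged with SEM.

# Synthetic data: what it does and does not emulate

The generators provide every input with embedded truth: FRAP curves at
the standard cadence with Gaussian noise ($\sigma = 0.02$ normalized
units by default) and presets spanning the characteristic regimes
(mobile fractions 0.66/0.58/0.40/0.25 with time constants 99/60/69/60 s;
the low-concentration preset's time constant is the package's choice,
as only its mobile-fraction range is characteristic); disc, ellipse and
Eden-growth aggregate images (the growth bias parameter spans aspect
ratios from $\approx 0$ to $\approx 0.6$); two-channel spot stacks with
per-spot molecule numbers, two-population exponential disassembly,
optional integer drift, Poisson shot and Gaussian read noise; and
length-concentration condition grids in which the mobile-fraction drop
precedes the aspect-ratio rise with increasing length (sigmoid
midpoints 1.6 kb and 5 kb), the per-length critical concentration
falls steeply with length, and both features shift mildly with depth
into the two-phase region. All generators are deterministic under a
seed and restore the caller's RNG state.

Deliberately not emulated: optical point-spread convolution of extended
objects (spots are ideal Gaussians; shapes are binary masks plus
noise), condensate coarsening/fusion dynamics, photobleaching during
acquisition, and correlated camera noise. Passing the recovery tests
therefore demonstrates correctness of the estimators under the stated
noise models, not robustness to every imaging artifact of real
microscopy.

# Problem sizes and numerical choices in the test suite

The suite fixes its own scales: 200 Monte-Carlo FRAP curves per regime
(bias tolerances 0.02 on the mobile fraction, 5% on the rate), 60
double-exponential replicates at 2% noise (10% rate tolerance), a
5-length × 21-$\chi$ sweep of the collapse solver against a
$\Delta\alpha = 10^{-4}$ grid oracle, 100 random states for the
finite-difference check of the chemical potentials (relative tolerance
$10^{-4}$), molecule-count recovery over the 2–4, 5–12 and 20–50
molecule regimes (mean relative error below 15%, dominated by shot
noise on the max-pixel statistic), and byte-level determinism of the
pipeline CSVs. The end-to-end drivers under `analysis/` use the same
sizes.

# Known limitations

* The Gaussian-chain description ignores the persistence length, so
  the model is most meaningful well above ~150 bp; the 12 bp entries of
  the condition grid are phenomenological.
* Chromosome-scale dilute concentrations are far below any physical or
  numerical floor ($10^{-10^5}$ g/mL); they are reported in log10 form
  and mean "effectively zero".
* The aspect-ratio statistic is computed from pixel-level contours;
  below ~15 px radius discretization dominates.
* Registration is integer-pixel and assumes a dominant static scene;
  it will not track fast per-spot motion.
* The cluster-to-class mapping assumes exactly three classes; with
  $k \ne 3$ classes are labeled by mobility rank only.
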