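---
title: "Methods: membrane tubulation energetics in memtub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane tubulation energetics in memtub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtub)
```

# The problem

Bacterial ESCRT-III proteins of the PspA family assemble into helical
rods that internalize lipid membranes as highly curved tubules. Whether a
tubule stays inside a rod is a competition between two energies: the
binding free energy released as amphipathic N-terminal helices (α0)
insert into the outer leaflet, and the Helfrich cost of bending the
bilayer into the rod lumen. `memtub` provides the quantitative pieces of
that argument — surface fitting, curvature energetics, PMF-based binding
free energies, rod lattice geometry, contact statistics, and tomographic
summaries — each testable against synthetic inputs with known truth.

# Leaflet surfaces

Membrane shape enters through marker points (phosphate-plane positions)
per leaflet. To remove local fluctuation curvature while keeping the
protein-induced deformation, each leaflet is fitted by a 2D Gaussian
height function

$$h(x, y) = z_0 + A \exp\!\left(-\frac{(x - x_0)^2}{2\sigma_x^2}
          - \frac{(y - y_0)^2}{2\sigma_y^2}\right),$$

with a single isotropic width by default (the energy maps downstream are
parameterized by one width); anisotropic widths are opt-in
(`isotropic = FALSE`). The baseline $z_0$ is a free parameter by default:
pinning it to the far-field membrane plane is a special case the user can
impose through the `lower`/`upper` bounds, and a free baseline is the
safer default when the far field is not sampled evenly.

Numerical choices:

* Initialization: baseline at the median z, amplitude from the larger of
  max/min deviation, centre at the extreme point, width from the rms
  radius of points beyond half height. This is robust on noisy clouds
  where a naive moment estimate is not.
* Levenberg–Marquardt (`minpack.lm`), with optional box bounds. A fit
  that stops without the convergence flag is an error carrying the last
  iterate — silently returning non-converged surfaces would poison every
  downstream energy.
* Flatness: exactly flat input short-circuits; a converged fit explaining
  less than 1% of the z variance, or with amplitude below
  $3\,\mathrm{rms}/\sqrt{n}$, is flagged `flat`. The variance criterion
  matters because near-flat noisy data otherwise converge to a
  huge-amplitude, huge-width surface that is degenerate with a baseline
  shift.
* Leaflet assignment: labels are honoured when present; otherwise points
  are split at a local (per xy-cell) median — a global median fails once
  the bump height exceeds the bilayer thickness — then reassigned once to
  the nearer fitted surface. Ties and midplane points go to the lower
  leaflet, for determinism.

# Helfrich bending energy

Curvatures come from exact analytic derivatives of the Gaussian in Monge
gauge:

$$H = \frac{(1 + h_y^2)h_{xx} - 2h_xh_yh_{xy} + (1 + h_x^2)h_{yy}}
           {2(1 + h_x^2 + h_y^2)^{3/2}}, \qquad
  K = \frac{h_{xx}h_{yy} - h_{xy}^2}{(1 + h_x^2 + h_y^2)^2}.$$

An upward bump has $H < 0$ at its apex ($H = -A/\sigma^2$,
$K = A^2/\sigma^4$ there). The energy density is

$$e = 2\kappa(H - c_0)^2 + \bar\kappa K,$$

integrated over the curved area element
$\mathrm{d}A = \sqrt{1 + |\nabla h|^2}\,\mathrm{d}x\,\mathrm{d}y$. The
$2\kappa H^2$ convention (with $H$ the mean of the principal curvatures)
is algebraically identical to $(\kappa/2)(2H)^2$; the factor lives in
`bending_moduli()` so it is explicit and auditable.

**Moduli.** Defaults are $\kappa = 20\,k_BT$ (≈ 11.92 kcal mol⁻¹ at
300 K) and $\bar\kappa = -0.8\,\kappa$, literature-typical values for
fluid phospholipid bilayers, with $c_0 = 0$ for a symmetric bilayer.
Absolute energies scale linearly in the moduli, so any comparison to
published plateau values must state its $\kappa, \bar\kappa$; the
shape, monotonicity and decomposition properties tested here are
modulus-independent.

**Quadrature.** Polar grid centred at the fitted peak: composite
Gauss–Legendre in radius (64 panels × 8 nodes by default) and, for
anisotropic fits, a uniform periodic angle grid (trapezoid rule, which is
spectrally accurate for periodic integrands); isotropic fits integrate
the angle analytically. Truncation defaults to $5\sigma$ in the projected
X/Y plane (radial integration is over the projected disc, matching how
cumulative energy-versus-integration-limit curves are drawn); truncation
below $3\sigma$ is recorded as a warning in the result metadata. The
quadrature error estimate compares full and half radial resolution.
Cumulative radial profiles fall out of the panel sums at no extra cost.

Tested consequences (see `test-helfrich.R` and the acceptance suite): a
flat surface costs exactly zero; energy is invariant under uniform
scaling $(A, \sigma) \to (2A, 2\sigma)$ at $c_0 = 0$; the small-slope
limit reproduces $\kappa\pi(A/\sigma)^2$ within 1% at $A/\sigma = 0.02$;
the full-plane Gauss term vanishes (Gauss–Bonnet) below $10^{-3}$ of the
mean term; and the polar quadrature agrees with a brute-force Cartesian
mesh sum within 2% at $A/\sigma = 3$.

# PMF and standard binding free energy

`wham_pmf()` is a binned, self-consistent WHAM: window shifts $f_i$ are
iterated to a tolerance of $10^{-7}$ kcal mol⁻¹ (the estimator choice is
deliberately kept behind a PMF-profile interface, so a different
estimator could be dropped in). Adjacent windows must share sampled
support; a gap is an error naming the two window centres. Two hygiene
rules keep the profile honest: bins with fewer than `min_count = 10`
total samples are dropped (the noise of $-k_BT\ln p$ diverges as counts
go to zero), and the profile is trimmed to the span of the window centres
(outside it the coordinate is unrestrained tail extrapolation, where
bin-discretization bias of the harmonic weight also grows). The profile
is re-referenced to the mean over the unbound plateau — by default the
top 20% of the sampled range.

`standard_binding_dg()` integrates the Boltzmann factor over the bound
region ($W < 0$ relative to the plateau; the threshold is configurable
because the bound cutoff is a convention, and disjoint bound stretches
are integrated separately rather than bridged) and converts to the 1 M
standard state with $V^0 = 1661$ Å³ and the sampled cross-sectional area
supplied by the user (box area versus restraint-defined area is a
protocol choice, so it is a parameter). The entropy correction is an
explicit additive input, default 0: its value depends on restraint
bookkeeping outside this package's scope, and keeping it visible in the
component breakdown makes any chosen correction auditable. Consequently
the package does not claim to reproduce any particular published
$\Delta G^0$; it reproduces closed-form oracles (square well, pure volume
term) to < 0.1 kcal mol⁻¹ and recovers generator truths.

`jarzynski_select()` implements $F = -k_BT\ln\langle e^{-W/k_BT}\rangle$
(log-sum-exp, overflow-safe) and picks the replica with work closest to
$F$ (ties to the lowest index), the restart rule of adaptive steered-MD
protocols. $F \le \bar W$ by Jensen's inequality is property-tested.

# Helical lattice

With $n$ subunits per circumferential rung (equal to the Bessel order of
the ~110 Å layer line) and diameter $D$, the subunit arc is
$s = \pi D / n$ and the constant-arc diameter increment is
$\Delta D = s/\pi = D/n$ — 20 Å for the narrowest (200 Å, $n = 10$)
class. The model is deliberately minimal: applied with the $n = 10$ arc
it predicts the wider classes only within ~15 Å, because the measured
arc itself shrinks from 62.8 to 60.2 Å across the series; the deviation
is reported, not hidden. The rung spacing is carried as metadata only.
Diameter classification assigns measurements to the nearest class
centre, with exact midpoints going to the lower class.

# Contacts and the energy balance

A contact is a residue-bead/headgroup-bead pair within a cutoff
(default 6 Å between representative beads — the underlying criterion is
a convention, so the cutoff is always reported in the output).
Availability scaling divides per-type counts by
(composition fraction × area per lipid; defaults 70 Å² PG, 65 Å² PE),
turning raw counts into a per-available-surface propensity — the
normalization that makes a minority anionic lipid's preference visible.
Bound-helix counting uses vertical distance to the fitted surface with
defaults of ≥ 3 residues within 8 Å; both knobs are configurable because
the published criterion is supplementary material, and they are
parameters of the result, not claims.

`energy_balance()` compares $n \times |\Delta G^0_{\rm helix}|$ with the
bending energy under a dead band: beyond the tolerance it is favorable or
unfavorable, inside it balanced — the regime consistent with a tubule
that neither retracts nor advances.

# Tomographic quantification

`vesicle_stats()` reports raw fractions plus integer percentages under
both floor and half-up rounding, side by side, because published
percentage pairs that sum to 99 demonstrate truncation in at least one
printed value; a zero denominator yields an explicit "undefined" marker
rather than NaN. `rod_content_hist()` gives integer-binned tube/disc
histograms with a modal range (contiguous counts at ≥ half the modal
frequency).

# Synthetic data: what it emulates, and what it does not

The generators supply every input with recorded truth:

* `gen_leaflet_cloud()` — two leaflets of constant 34 Å separation (the
  measured tubule bilayer thickness), both displaced by the same
  Gaussian bump, defaults A = 150 Å, σ = 50 Å in a 426.6 Å box, with
  isotropic Gaussian noise in z only (markers emulate phosphate planes;
  which atoms define a leaflet is itself a convention the generator
  leaves behind). `n_points` counts markers per leaflet.
* `gen_umbrella_dataset()` — Metropolis sampling of the biased density
  per window (burn-in 1000, thinning 10, proposal width
  $\sqrt{k_BT/k}$). Metropolis rather than exact rejection sampling is
  deliberate: real umbrella data are autocorrelated, and thinning is the
  knob that controls it.
* `gen_rod_assembly()`, `gen_contact_frames()`, `gen_vesicle_table()` —
  ideal cylinder lattices, frames with exact per-residue contact
  propensities, and categorical tables whose default probabilities are
  the observed frequencies (106/165, 59/165; 84/249, 165/249; tubes
  uniform on 1–2, discs on 2–5).

All randomness flows through a per-call seed and the caller's RNG state
is restored, so every generated object is bit-reproducible.

What passing against these generators does **not** show: real leaflets
have undulation spectra, protrusions and asymmetry that a single
Gaussian bump lacks; real umbrella windows have correlated,
non-Markovian noise and slow orthogonal degrees of freedom; real rods
are conical and flexible. The tests certify the estimators and the
energy algebra, not force-field accuracy.

# Problem sizes and runtimes

The test suite runs clouds of $10^3$–$5\times10^4$ points, umbrella sets
of 10–20 windows × 3000–20000 samples, 100-frame contact sets, and
Helfrich quadratures of 64 × 8 radial nodes — sizes at which every
statistical tolerance in the suite (3-sigma bands, 1–2% recovery bounds)
is comfortably resolved while the whole suite completes in well under a
minute. Umbrella spring constants in the tests (0.2–1 kcal mol⁻¹ Å⁻²)
are chosen so that adjacent windows overlap, as in any competent umbrella
design.

# Known limitations

* No membrane tension, area-difference elasticity, or dynamics; the
  pearling/fission argument is treated only through the sign of the
  Gauss-curvature term.
* Anisotropic fits have no rotation angle (principal axes are assumed
  along x/y); in-plane rotation invariance of the energy is exact only
  for isotropic widths.
* The PMF uncertainty is a within-window bootstrap (opt-in,
  `n_boot`); no autocorrelation-aware error model.
* The entropy correction to $\Delta G^0$ is an input, not a computation.
* Power-spectrum indexing (assigning the Bessel order from images) is
  out of scope; $n$ is always an input.
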