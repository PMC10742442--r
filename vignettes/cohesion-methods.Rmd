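---
title: "Incoherence and cohesion: measuring the replicability of stochastic simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incoherence and cohesion: measuring the replicability of stochastic simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesr)
```

## The problem

Repeated runs of an agent-based model, a digital twin, or a lab protocol
under identical macro-parameters often do not converge on one outcome
distribution. Complex dynamics — tipping points, feedback loops, attraction
basins — make the system *non-ergodic*: each replicate settles into one of
several possible end states. Classical uncertainty decompositions (variance
within a distribution, sampling error across observations) do not capture
the resulting uncertainty about *which* distribution the system will
manifest.

`cohesr` computes two complementary statistics over an *ensemble* of
replicate distributions:

* **Incoherence** `I` — how different the replicate distributions are.
  With per-replicate entropies $H_k$ and $\tilde H$ the entropy of the
  pooled (point-wise mean) distribution,
  $$I = \sqrt{\frac{1}{\tilde H}\sum_k w_k\,(\tilde H - H_k)^2}.$$
  `I = 0` iff every replicate entropy equals the pooled entropy; a large
  `I` means a single pooled summary misrepresents the ensemble.
* **Cohesion** `C` — how *organised* the disagreement is. All
  $K(K-1)/2$ pairwise Jensen–Shannon divergences
  $$d_{ab} = w_a(\tilde H_{ab} - H_a) + w_b(\tilde H_{ab} - H_b)$$
  are collected, normalised by their theoretical maximum $\ln 2$, and the
  entropy $H(G)$ of this divergence set is estimated with the
  density-variance estimator below. Then $C = (1 - H(G))^2$: 1 when all
  replicates are identical, high when replicates fall into a few clean
  scenarios (a tight cluster of within-scenario divergences near 0 plus a
  tight cluster of cross-scenario divergences), and near 0 when the
  divergences spread evenly — no recognisable scenario structure.

The JSD is used rather than the Kullback–Leibler divergence because it
remains finite and symmetric for distributions with disjoint support,
which is the typical situation on the two sides of a tipping point.

A system must be incoherent before it can be incohesive: if `I = 0` all
divergences vanish and `C = 1` by construction. The informative regime is
high `I` with high `C` (a few distinct attractors — plan contingencies per
scenario) versus high `I` with low `C` (no scenario structure — a single
run tells you little).

## The density-variance entropy estimator

The divergence set is a small continuous sample on $[0, 1]$, often with
only tens of values, so a histogram entropy would be hostage to the bin
count. The density-variance estimator is bin-free. For observations
$o_1..o_N$ and $R$ evenly spaced reference points $r_j$,

$$g_j = \frac{1}{N}\sum_i e^{-k\,\lVert r_j - o_i\rVert}, \qquad
  G_j = \sqrt{g_j}, \qquad
  H = 1 - \frac{\widehat{\mathrm{Var}}(G) - V_0}{V_1 - V_0},$$

clipped to $[0, 1]$. $V_1$ is the profile variance of a point mass at 0
(minimal entropy) and $V_0$ that of a dense uniform sample on $[0, 1]$
(maximal entropy), so the two anchors map exactly to $H = 0$ and $H = 1$.
The square root linearises the profile: without it the kernel densities
over-emphasise differences between small divergences.

Defaults: `k = 100`, `R = 500` reference points over `[-0.5, 1.5]`, all
dimensionless since the estimator is applied to normalised divergences.
The variance is the population variance (divide by $R$).

Two numerical choices matter and are fixed as follows:

* **Zero-anchored reference grid.** The grid uses spacing
  $(\text{upper}-\text{lower})/(R-1)$ but is anchored so that 0 is exactly
  a reference point: the data the estimator sees (normalised divergences)
  have a natural minimum at 0, and anchoring there evaluates the
  point-mass calibration anchor at its mode. With the defaults this grid
  reproduces $V_1 = 0.0097117$ to 0.005% and, with a $10^5$-point uniform,
  $V_0 = 0.0047684$ to 0.02%. A plain endpoint-inclusive grid misses
  $V_1$ by 1.5% because 0 falls three-quarters of the way between two
  reference points.
* **Deterministic uniform for calibration.** $V_0$ is calibrated from an
  even deterministic grid over $[0, 1]$ (default resolution $10^5$), not
  random draws: it is seed-free and converges to the continuum limit the
  constant approximates.

One property worth knowing: for a uniform sample on $[0, x]$ the estimator
returns $H \approx x$ — it is *linear* in the occupied fraction of the
support. A bin-normalised Shannon entropy instead returns
$\log(bx)/\log b$, which is log-compressed. The two agree at the extremes
($x \to 0$, $x = 1$) but differ by up to ~0.4 in between; when comparing
against histogram baselines this linear response must be kept in mind.
For cohesion this linearity is a feature: $H(G)$ responds proportionally
to how widely the divergences spread.

## Ensembles, estimation choices, weighting

Samples are either categorical counts (entropies are plain Shannon, in
nats internally, base 2 on request) or 1-D continuous observations.
Continuous samples are discretised on *one shared bin scheme* per
ensemble — Freedman–Diaconis on the pooled observations by default
(capped at 1024 bins, with a single-bin fallback for constant data) — so
that per-sample histograms and their point-wise mean live on the same
support. Pairwise JSD weights default to $w = 1/2$ (appropriate when
sample volumes are biased but each sample is adequately represented);
proportional weights $w = n/N$ are available for re-sampling designs. The
divergence normaliser is the fixed theoretical maximum $\ln 2$ rather
than the observed maximum, which keeps `C = 1` attainable and avoids a
divide-by-zero for identical ensembles.

Eq-wise, the printed incoherence is ambiguous between the root form and
its square; both are computed (`incoherence(..., variant =)`), the rooted
form — an RMS of entropy deviations, scale-consistent with $\tilde H$ —
is the default, and reports name the variant used.

For *near-degenerate* continuous ensembles (all replicates essentially a
point mass at the same value) the pooled entropy is 0; incoherence is
then reported as 0 with a `degenerate` flag rather than an error.

`incoherence()` also offers `estimator = "density"`: per-replicate and
pooled entropies from the density-variance estimator applied to the raw
observations, affinely rescaled from `scale_range` to $[0, 1]$. Because
these entropies are normalised and smooth at sub-resolution scales, this
variant is robust exactly where the binned form is fragile — ensembles
whose replicates agree to within measurement resolution — and it is used
for the Daisyworld temperature traces (below).

## The organised-noise generator

The first validation system emulates a detector receiving bursts of
continuous values over time, where each burst realises one "letter" of an
unknown alphabet. A letter is a mixture of two Gaussian components with
means uniform on $[0, 20)$, standard deviations drawn from
Normal(1, 0.5) truncated below at 0.05 (the untruncated law admits
non-positive widths), and a per-component observation count fixed per
letter, uniform on the integers 1..9 — so a burst carries between 2 and
18 points. Each timestep picks a letter uniformly and draws fresh noise.
Messages default to 20 bursts; the length is configurable since only the
per-burst structure is prescribed.

Treating each burst as one replicate sample, median cohesion over seeds
decreases strictly with alphabet size (2 letters > 5 letters > one unique
letter per burst): cohesion reads the *number of patterns*, not their
spread. The naive dispersion summaries $\sigma$, $\sigma(\mu)$,
$\sigma(\sigma)$ carry no such normalised interpretation; at these
conditions their seed-medians happen to grow with alphabet size, but
per-seed their orderings are unreliable (correct for roughly half the
seeds), so they cannot be read as an organisation scale.

The absolute cohesion level of a 2-letter message depends strongly on the
continuous entropy estimator applied to 2–18-point bursts; with the
default shared-bin pipeline the median is ≈ 0.13–0.24. Bursts this small
carry an irreducible $O(1/n)$ JSD noise floor, so within-letter
divergences do not collapse to a point; estimator variants that smooth
this away require a bandwidth constant with no independent
justification, and are not defaulted.

## The Daisyworld port

The second validation system is the classic two-species Daisyworld: a
29×29 toroidal grid of patches (Moore 8-neighbourhoods), black daisies
(albedo 0.25), white daisies (0.75), bare ground (0.4), driven by a solar
luminosity $l$. Per tick:

1. **Heating.** `absorbed = (1 - albedo) * l * solar_constant`;
   local heating `72*log(absorbed) + 80` (80 when nothing is absorbed);
   the patch temperature moves to the mean of its current value and the
   local heating.
2. **Diffusion.** Each patch keeps 50% of its temperature and splits the
   rest equally among its 8 neighbours.
3. **Ageing.** Every daisy ages one tick and dies on reaching `max_age`
   (25).
4. **Sprouting.** Each surviving daisy, visited in freshly shuffled
   order, attempts with probability
   `0.1457*T - 0.0032*T^2 - 0.6443` (clipped to $[0,1]$) to seed one
   uniformly chosen Moore neighbour, succeeding only if that patch is
   currently empty. The parabola is positive roughly for
   $T \in [5, 40]$ °C, which realises the viability band through the
   reproduction rate rather than a kill rule; a strict-kill variant
   (`hard_kill = TRUE`) is available for sensitivity analysis.

The seeding rule deserves a note: targeting *one random neighbour and
failing on occupied patches* makes the growth rate proportional to local
emptiness. Under the alternative (always seeding some empty neighbour if
one exists) black daisies survive ~0.1 higher in luminosity and the world
saturates, which contradicts the regime boundaries this model is known
for; the emptiness-proportional rule reproduces them (dead below
$l \approx 0.52$, black-only to $l \approx 0.8$, coexistence around
$l \approx 0.9$–$1.1$, black extinction by $l \approx 1.30$, with a
bistable dead/alive band at $l \approx 0.52$–$0.53$).

Worlds start as a random dispersion of 30% white, 30% black, 40% empty
with ages uniform on `0..max_age-1` and temperatures at 0 °C; 400 ticks
comfortably reaches equilibrium. The inner loop is compiled (Rcpp) and
draws from R's RNG, so `set.seed()` governs every run; sweep replicate
seeds are split from one master seed by drawing one integer per run.

### Sweep diagnostics and tipping points

`dw_sweep()` runs replicate ensembles across a luminosity grid and
reports, per luminosity, incoherence and cohesion for (a) the final
per-patch temperature distributions and (b) the species-count
distributions, along with $\sigma(\mu)$, $\sigma(\sigma)$, the pooled
mean and the mean of replicate means (identical for equal replicate
sizes).

Temperature ensembles are discretised on fixed 1 °C bins
(`temp_bin_width`): temperatures are physical quantities with a natural
resolution, and per-ensemble adaptive bins would resolve the sub-degree
equilibrium noise of a lifeless or fully-vegetated world into spurious
entropy. Even so, Eq-form incoherence divides by the pooled entropy,
which amplifies noise when distributions collapse to one or two bins. The
headline `incoherence_temp` trace therefore uses the density-variance
estimator on one absolute temperature scale shared across the sweep,
which is quiet inside stable regimes and elevated where replicate
ensembles split between attractors; the shared-bin Shannon value is kept
alongside as `incoherence_temp_binned`.

`detect_peaks()` operationalises tipping-point reading: maximal runs of
consecutive luminosities whose incoherence exceeds the trace mean plus
one standard deviation. On a 0.05-step grid with 10 replicates and 200
ticks the trace shows the transition into coexistence (~0.80–0.85) and
the black-extinction band (~1.25–1.30). The dead-to-black tipping point
is *not* detectable on that grid: the bistable band is roughly
$l \in (0.52, 0.53)$ — confirmed directly by running replicates at
$l = 0.53$, where both extinction and survival occur — and a grid of
0.05 multiples never samples it. A finer grid (or one containing 0.53)
exposes it as a strong spike, and the species-count trace finds the same
transitions.

## Problem sizes and test design

The test suite builds everything programmatically: calibration at
$10^5$-point resolution (<1 s), cohesion medians over 21 seeds for the
two-scenario (5 × 200 observations) and message systems, and a
21-luminosity × 10-replicate × 200-tick sweep (~3 s compiled). Property
tests fuzz JSD symmetry/bounds and entropy bounds over random categorical
ensembles, and verify incoherence and divergences against independent
plain-loop summation oracles at $10^{-12}$ on ensembles small enough to
hand-check. Deterministic anchors (identical ensembles, calibration
anchors, closed-form kernel profiles) are asserted exactly.

## Limitations

* Categorical and 1-D continuous data only; no multivariate joint
  densities.
* The continuous-sample entropy estimator is a genuine modelling choice;
  results for very small samples (tens of points) depend on it
  materially. The package defaults to shared-bin histograms and exposes
  the density-variance alternative; neither abolishes the small-sample
  noise floor of pairwise divergences.
* Incoherence is unbounded above and unit-dependent (through
  $1/\tilde H$); compare traces only within one estimator and unit.
* The Daisyworld port fixes NetLogo-derived constants (heating rule,
  diffusion fraction, sprouting parabola, max age); these are exposed in
  `dw_config()` but not calibrated to data.
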