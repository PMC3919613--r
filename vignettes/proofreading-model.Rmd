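---
title: "A post-passage proofreading model of topoisomerase II topology simplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A post-passage proofreading model of topoisomerase II topology simplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoproof)
```

## The problem

A covalently closed DNA circle carries an integer topological invariant,
the linking number Lk. A population of otherwise identical plasmids is
resolved on an agarose gel as a ladder of *topoisomers* differing by one
Lk unit. Left to thermal fluctuation (e.g. relaxed by a type-I
topoisomerase, which nicks and reseals one strand), the topoisomer
fractions settle into a Boltzmann distribution over Lk. Type-II
topoisomerases do something a passive enzyme cannot: using ATP, they leave
the population *narrower* than thermal equilibrium — "topology
simplification". Since the enzyme is much smaller than the plasmid and
senses only local DNA, how it measures global topology is a genuine
puzzle.

`topoproof` implements a quantitative answer built from three gates of the
type-II enzyme. A T-segment (the duplex to be transported) is captured by
the ATP-operated **N-gate**, passed through the transiently cleaved
G-segment at the **DNA-gate**, and finally released through the exit
**C-gate**. The model's central idea is that selection happens *after*
passage: the C-gate challenges the passed T-segment to dissociate, and
when dissociation is slow the N-gate reopens first and the T-segment
*backtracks*, cancelling the transport. Transports that move topology
uphill in free energy dissociate more slowly, so they are preferentially
cancelled — a proofreading step, paid for by ATP hydrolysis, that rectifies
an otherwise equilibrium-bound capture step.

## The model

### Energetics

For plasmids of N ≥ ~1 kb the supercoiling free energy is quadratic in the
linking-number deviation ΔLk from the relaxed center Lk⁰:

$$ G(\Delta Lk)/kT = \frac{K}{N}\,\Delta Lk^2
   = \frac{\Delta Lk^2}{2\sigma^2_{eq}}, \qquad
   \sigma^2_{eq} = \frac{N}{2K}. $$

`K` (`nk_coefficient`, default **1100**) is the literature consensus for
plasmids above ~2 kb; with N = 4300 bp it gives σ² = 1.95 and an
equilibrium adjacent-topoisomer ratio C(−2)/C(0) = exp(−4/2σ²) ≈ 0.36,
matching what relaxation by a type-I enzyme produces on a gel. Lk⁰ moves
with temperature because DNA unwinds on heating; we use the standard
coefficient **0.011°/(bp·°C)** (`helical_temp_coeff`), so
ΔLk⁰ = −0.011·N·ΔT/360. Temperature enters the simulator *only* through
this shift of the free-energy minimum; σ²_eq is held constant, because the
narrowing ratio it controls is observed to be stable over 10–45 °C while
the center shift is not. The center is a real number; topoisomer states
remain integers.

```{r energetics}
pbr322 <- plasmid_spec("pBR322", 4300)
en43 <- energetics_model(pbr322)
eq <- equilibrium_distribution(en43)
adjacent_topoisomer_ratio(eq, -2, 0)
```

### Capture: detailed balance at the N-gate

Per N-gate closure, capture of a T-segment whose passage would take state
k to k ± 2 occurs with probability

$$ p(k \to k\pm2) = p_0\, e^{-[G(k\pm2)-G(k)]/2}. $$

The symmetric exponent split is the minimal form whose forward/backward
*ratio* is the Boltzmann factor (detailed balance); one-passage assay
measurements constrain only that ratio. Consequently capture alone can
only reproduce equilibrium — it cannot narrow the distribution, which is
the model's first falsifiable statement and is what the one-passage
(AMPPNP) assay shows: the measured conversion-probability ratio matches
the *equilibrium* concentration ratio (≈0.35), not the steady-state one
(≈0.17). The baseline efficiency `p0` is calibrated once against the
measured conversion probability 0.50 from ΔLk = −2 to 0 on the 4.3-kb
plasmid (`calibrate_p0()` gives p0 ≈ 0.2998).

### Release: the proofreading exponent

After passage the C-gate release competes with N-gate reopening. We
parametrize the outcome, not the rates (the data constrain no absolute
timescale):

$$ \pi(\Delta G) = \min\{1,\ \pi_0\, e^{-\alpha\,\Delta G/2}\}, $$

with ΔG the free-energy change of the transport just made. `alpha` is the
proofreading strength; `alpha = 0` makes release topology-blind. Combining
capture and release, the effective move kernel is ∝ exp(−(1+α)ΔG/2),
which is detailed-balanced with respect to exp(−(1+α)G): the stationary
distribution is a Gaussian-weighted integer law with variance
σ²_eq/(1+α). Hence two closed-form anchors:

* the variance ratio R_Lk = ⟨ΔLk²⟩_eq / ⟨ΔLk²⟩_ss = **1 + α**, and
* steady-state adjacent ratios C(−2)/C(0) = [C(−2)/C(0)]_eq^(1+α).

The package default is the measurement-anchored calibration
1 + α = ln 0.17 / ln 0.35 ≈ 1.688 from the measured ratio pair; the
predicted R_Lk ≈ 1.69 then lands on the independently measured ~1.6.
`pi0` defaults to 0.5; it scales how often an encounter completes but
cancels out of every stationary quantity.

```{r stationary}
g <- gate_model()           # calibrated p0 and alpha
c(p0 = g$p0, alpha = g$alpha)
ss <- stationary_closed_form(en43, g)
adjacent_topoisomer_ratio(ss, -2, 0)
```

### Enzyme modes

The experimental perturbations map onto two switches
(`enzyme_mode(n_gate_agent, c_gate)`):

| mode | semantics |
|---|---|
| ATP, intact | full cycle: capture → passage → release-vs-backtrack |
| AMPPNP or ICRF-193, intact | N-gate cannot reopen: no backtracking, one passage per enzyme |
| ATP, locked | passed T-segment trapped in the chamber; it backtracks out of the reopened N-gate with per-cycle probability `trap_backtrack` (default 1) and the enzyme may recapture |
| AMPPNP, locked | both gates shut: frozen after one passage |
| any, deleted | no release challenge: transport follows capture alone |

AMPPNP and ICRF-193 share simulator semantics (both prevent N-gate
reopening); the labels are kept distinct for reporting. A blocked enzyme
is single-use and its one N-gate closure is consumed whether or not a
T-segment was juxtaposed, so it transports with probability equal to its
capture probability — this is what makes post-block broadening
stoichiometric in enzyme while approaching, never overshooting, thermal
equilibrium.

## Ensemble dynamics and protocols

Time is discretized into encounter cycles; absolute kinetics are out of
scope. Each cycle each molecule is visited by an enzyme with probability
min(1, enzyme/DNA ratio). `simulate_population()` runs the vectorized
engine; `apply_protocol()` carries the ensemble across mid-run events
(agent switch, temperature shift, ratio change), reproducing the three
perturbation designs: temperature inversion with a locked C-gate
(trapped passages collapse and reform on the other side when the
free-energy minimum crosses the start state — but only when ATP allows the
N-gate to reopen), stoichiometric broadening on N-gate block, and the
C-gate-deleted enzyme that relaxes supercoils to R_Lk ≈ 1 but never
below.

`stationary_numeric()` is an independent oracle for the closed form: it
assembles the per-cycle transition matrix from the same outcome
probabilities the Monte Carlo engine uses and solves the stationary
vector by linear algebra. Because passage moves Lk in steps of two, odd
and even states are separate communicating classes; the solver works per
class and combines the classes with the target Boltzmann masses (the
physical parity split is fixed by the initial condition, so a comparable
convention is needed; it is user-overridable).

## Statistics

`lk_variance()` offers the fitted-center second moment (default) and the
densitometry-literal convention that takes moments about an integer
reference topoisomer near the center. The literal convention
overestimates the variance whenever the true center is fractional, so the
fitted-center convention is the default; because R_Lk is a ratio, the
essential requirement is consistency across the two lanes being compared.
`distribution_center()` estimates Lk^S / Lk⁰ as the apex of a weighted
quadratic fit to log-fractions, fitting both parity classes jointly with
a shared center, and falls back to the weighted mean for degenerate
inputs. `r_lk()`, `delta_lk_s()`, `adjacent_topoisomer_ratio()` and
`parity_split()` complete the lane-plot statistics.

## Synthetic densitometry

`synth_lane()` renders a distribution as a 1-D lane: Gaussian bands
(common width, area = fraction) at positions given by a monotone,
saturating map of the *magnitude* of effective writhe,
x = g·s/(1 + s/s_max) with s = |ΔLk + chloroquine offset| — on a real
chloroquine gel the intercalator shifts every topoisomer's writhe so the
relaxed ladder runs ahead of nicked circles. With the default offset of 0
the +k and −k bands comigrate exactly; `quantify_lane()` therefore
apportions a shared band's intensity equally among comigrating states,
which is exact for the symmetric distributions this model produces. With
an offset that clears the support (the experiment runners' default),
every state gets its own band and the round trip recovers individual
fractions to ~1e−2 at low noise.

Quantification estimates the baseline as the 10% intensity quantile,
requires a local maximum above 5× a robust noise estimate near each
expected position (absent bands are flagged at zero), and apportions the
baseline-subtracted profile among Gaussian bands by non-negative least
squares, so overlapping bands are split by the fitted mixture rather than
by hard windows. Gaussian band shape and additive Gaussian noise are
deliberately the simplest model that exercises the quantifier; gel
"smile", streaking and 2-D gels are out of scope. Passing round-trip
tests therefore shows the statistics layer is self-consistent, not that
real gel images would quantify as cleanly.

## Numerical choices

* **Probability validity and clipping.** The capture form p₀·e^(−ΔG/2)
  exceeds 1 far downhill. With the calibrated p₀ ≈ 0.30 this happens
  roughly beyond |ΔLk| ≈ 4σ²/2 states from the center — states whose
  occupancy is negligible (< 10⁻³) in every run the package performs.
  `capture_probabilities()` treats overflow as an error by default so
  misparametrized analyses fail loudly; the Monte Carlo engine clamps to
  1 (rescaling a pair that sums above 1) so rare tail excursions remain
  well-defined. Release clips at 1 with a warning. Exact oracle
  comparisons (closed form vs. matrix solve at 1e−8) are run with
  parameters small enough that no clipping occurs anywhere on the
  support, where both routes are exact.
* **Support.** Default ±⌈8σ⌉ around the center (±12 states for 4.3 kb,
  ±15 for 7.9 kb), with a Gaussian tail bound rejecting supports whose
  truncated mass exceeds 1e−10.
* **Ensemble sizes.** Defaults of 5000 molecules × 300 cycles at
  enzyme/DNA = 0.5 give ≈ 20 completed transports per molecule —
  comfortably past relaxation to the stationary law — with Monte Carlo
  error on R_Lk of ≈ 0.03. The test suite uses 1000–10000 molecules
  depending on the sharpness of the assertion.
* **Seeds.** Every stochastic entry point requires a seed; trajectories
  and reports are bit-reproducible from config + seed.

## What the defaults represent

The generator defaults *are* the study conditions: plasmids of 4300 and
7900 bp referenced to 25 °C; enzyme/DNA molar ratio 0.5; one-passage
assays at n = 10⁴ molecules; temperature-inversion phases at 15 and
40 °C; N-gate block at ratios 1 and 2. The gate defaults are the two
one-time calibrations described above. None of these are tuning knobs:
changing them describes a different experiment.

## Limitations

The model treats only Lk (no knots or catenanes), ignores
sequence/salt-dependent stiffness and the writhe/twist partition, models
no absolute timescales or ATP-concentration dependence, and represents
the reduced thermal deviation of Lk^S (the apparent shortening of free
DNA length during the proofreading step) only through the direction of
the temperature-inversion design, not quantitatively. The C-gate-deleted
enzyme is assumed unable to pass T-segments in reverse.
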