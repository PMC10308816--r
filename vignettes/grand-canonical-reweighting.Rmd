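---
title: "Grand-canonical reweighting of fixed-N simulations: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grand-canonical reweighting of fixed-N simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcreweight)
```

## The statistical model

A simulation box is partitioned into a binding region A and a buffer region
B, assumed decoupled enough that the canonical weight of a configuration
with k of N particles in region A factorizes as Ω_A(k)·Ω_B(N−k). Under this
assumption the per-trajectory occupancy law is

$$P^N(k) = \frac{\Omega_A(k)\,\Omega_B(N-k)}{Z_N}, \qquad
  Z_N = \sum_k \Omega_A(k)\,\Omega_B(N-k),$$

and the likelihood of the pooled count matrix $t_{Nk}$ (frames of the
N-copy trajectory seen with occupancy k) is a product of multinomials.
Maximizing it over the two partition-function vectors, after eliminating
the per-N normalization multipliers analytically, gives the coupled
fixed-point equations implemented in `solve_partition_functions()`:

$$\Omega_A(k) \leftarrow \frac{A_k}{\sum_N L_N\,\Omega_B(N-k)/Z_N},
\qquad
\Omega_B(k) \leftarrow \frac{B_k}{\sum_N L_N\,\Omega_A(N-k)/Z_N},$$

with $A_k=\sum_N t_{Nk}$, $B_k=\sum_N t_{N,N-k}$ and $L_N=\sum_k t_{Nk}$.
The iteration recomputes every $Z_N$ each sweep, re-fixes the gauge
$\Omega_A(0)=\Omega_B(0)=1$, and monitors the log-likelihood, which is
non-decreasing across sweeps (asserted by the test suite on every fixture).
Missing simulations are simply rows with $L_N = 0$. Because the Dirichlet
bootstrap rescales rows by real-valued weights, the solver accepts
fractional counts unchanged — nothing in the equations requires integers.

### Gauge freedom

The likelihood is invariant under
$\Omega_{A}(k)\to\lambda^k\Omega_A(k)$, $\Omega_B(k)\to\lambda^k\Omega_B(k)$:
the fixed point is a one-parameter ridge and the solver lands on an
arbitrary tilt. This is harmless by construction — the chemical potential is
never interpreted absolutely but always re-calibrated from a buffer
concentration, and a tilt by $\lambda$ shifts the calibrated $\beta\mu$ by
exactly $-\log\lambda$, leaving every concentration-indexed observable
unchanged. This is tested (to 1e-10), not assumed. For direct comparison
with reference partition functions, `gauge_align()` removes the tilt by a
least-squares fit on region-B log ratios.

### From concentration to weights

The grand-canonical law $P(k)\propto\Omega(k)e^{\beta\mu k}$ is evaluated in
the log domain (`log-sum-exp`), so extreme $|\beta\mu|$ cannot overflow. The
buffer concentration maps to a target mean occupancy through the fixed
conversion 1 particle/nm³ ≡ 1.660539 mol/L; `mu_from_concentration()`
inverts the strictly increasing map $\beta\mu \mapsto \langle k_B\rangle$ by
geometric bracket expansion plus bisection to a relative occupancy tolerance
of 1e-12, which makes the concentration round trip accurate to well below
the 1e-8 level the tests require. Frame weights are
$w(k) \propto P_A^{GC}(k)/A_k$ — the target grand-canonical mass at k spread
uniformly over the pooled frames observed at k. Frames with equal k are
exchangeable under the decoupling assumption, and this is the unique weight
form for which the weighted occupancy histogram reproduces $P_A^{GC}$
*exactly* (an identity, asserted at 1e-12). Occupancies never observed
($A_k = 0$) have $\Omega_A(k)$ pinned to zero and are excluded from update
denominators; requesting weights at such k is an error, never a silent zero.

### The concentration ceiling

The support of the estimated $\Omega_B$ is truncated at the largest sampled
occupancy, so mean buffer occupancies — hence concentrations — beyond the
sampled range are not representable. `mu_from_concentration()` refuses
targets at or above the ceiling and names the attainable maximum. This is
the method's main structural limitation: near the ceiling the calibration
saturates, which superlinearizes *every* reactivity curve, not just
cooperative ones. Test fixtures therefore keep the tested concentrations
well below the ceiling (the cooperativity fixtures use 19 trajectories with
free region-A slots precisely so that truncation never binds).

## Geometry: occupancies and binding states

Region membership uses the probe center of mass against a closed ball of
radius r_A (default 3 nm) around the per-frame RNA center of mass; the
center of mass matches the "copies in region A" bookkeeping better than any
single atom, and the boundary convention is fixed (closed) for determinism.
Binding requires (a) the nucleotide's O2′ to be the nearest one to the
probe's reactive carbonyl carbon (C7) and (b) that distance to be strictly
below r_th = 3.5 Å; ties in (a) are broken toward the lowest nucleotide
index (a measure-zero event; determinism preferred). Distances use the
triclinic minimum-image convention when a box is supplied. No check is made
that a binding probe is also inside region A: 3.5 Å ≪ 3 nm makes that
implied. The subsequent acylation chemistry is outside the model. Trajectory
input goes through `bio3d` (multi-model PDB and DCD); selections default to
O2′/O2* atom names for nucleotides and the C7 atom within the probe residue,
and restrained terminal bases can be excluded by residue number.

## Cooperativity statistics

Reactivity $R_i(C)$ is the weighted frequency of nucleotide i's bound state
at the $\beta\mu$ calibrated for C; curves are smooth in C by construction.
Power laws $R=\alpha C^\beta$ are fitted by ordinary least squares of
$\log R$ on $\log C$ over a window defaulting to [1e-3, 1e-2] M — the range
where higher-order concentration dependence emerges — so $\beta$ is the
local log-log slope and $\alpha$ the 1 M extrapolation. Pairwise couplings
use the double-mutant-cycle odds ratio

$$\Delta\Delta G_{ij} = -k_BT\,
  \ln\frac{p_{11}\,p_{00}}{p_{10}\,p_{01}},$$

reported in k_BT by default (temperature enters only for the kcal/mol
conversion); negative values are cooperative. The alternative reading of a
frequency ratio, (p00+p11)/(p01+p10), was considered and rejected: it is not
a free-energy coupling, while the odds ratio reduces exactly to the pairwise
interaction energy in the generator's Boltzmann model (verified by
enumeration at every fugacity). Pairs with an empty cell are flagged
undefined and excluded from testing rather than imputed as infinite. The
representative coupling matrix is reported at C = 5.7 mM, an intermediate
concentration among the tested ones.

Uncertainties come from a Bayesian bootstrap that treats each constant-N
trajectory as one data point: per iteration, flat-Dirichlet weights rescale
the trajectories' count-matrix rows *and* their frames, the partition
functions are re-solved (warm-started from the point estimate), $\mu$ is
re-calibrated, and the observable recomputed; 10000 iterations by default.
Empirical sign p-values use the (r+1)/(B+1) finite-sample correction, and
Benjamini–Hochberg step-up selection (via `stats::p.adjust`) controls the
FDR at α = 0.01 over the $\binom{8}{2}=28$ pair hypotheses of an
8-nucleotide analysis, separately for the cooperative and anticooperative
directions.

## The synthetic generators

`lattice_model()` is the exact validation system: S_A and S_B mutually
exclusive sites, optionally one stabilizing site in region A contributing
eps k_BT. All of its quantities have closed forms (binomial coefficients,
hypergeometric occupancy law, Vandermonde normalization), so canonical
sampling draws k directly from the exact law — no Markov chain, no site
bookkeeping.

`synth_binding_model()` generates binding tables with known ground truth: N
exchangeable particles over M nucleotide sites (energies e_i, pairwise
couplings J_ij), F free region-A slots and S_B buffer slots, all mutually
exclusive. Every per-N ensemble is enumerated exactly (guarded at M ≤ 12),
so exact $\Omega$, exact $R_i$ and exact $\Delta\Delta G_{ij}=J_{ij}$ are
available for oracle comparisons. What these generators deliberately do
*not* emulate: spatial correlation, probe orientation, binding kinetics,
force-field realism, or autocorrelated frames — passing tests demonstrate
the correctness of the estimators under the model's own assumptions, not the
accuracy of any particular force field or sampling protocol.

## Study sizes and numerical defaults

* Solver: tol 1e-10 on the maximum relative change of any nonzero Ω entry,
  max 1e5 sweeps, non-convergence flagged, never silent.
* Lattice oracle checks: S_A = 3, S_B = 5, N = 1..6, 1e5 frames per
  trajectory; recovery is judged against 3 trajectory-bootstrap standard
  errors.
* Cooperativity fixtures: 19 trajectories (M = 3 sites, J12 = −1 k_BT,
  16 free slots, S_B = 25), V_B = 437 nm³ so that C = 5.7 mM corresponds to
  1.5 buffer particles; 1500–8000 frames per trajectory depending on the
  check; 100 replicates for sign recovery, 40 replicates × 150 bootstrap
  iterations for CI coverage.
* Default temperature 300 K; all chemical potentials handled as the
  dimensionless βμ.

## Known limitations

* Concentrations above the sampled ceiling are unrepresentable (see above);
  the ceiling is always reported in the refusal message.
* The decoupling assumption (weight depends on a frame only through k) is
  inherited from the region split; a poorly chosen r_A breaks it silently.
* Trajectory-level bootstrap SEs are mildly optimistic when the
  grand-canonical weights concentrate on a few trajectories: the flat
  Dirichlet carries a (n−1)/(n+1) variance factor in the effective number of
  contributing trajectories. In the package's coverage study the nominal 95%
  normal intervals cover the true coupling in 90% of replicates — acceptable,
  but worth remembering when quoting error bars.
* `V_B` is user-supplied, because region A is an analysis-time choice; the
  helper `buffer_volume()` computes V_box − (4/3)πr_A³ on request. Published
  values for comparable setups are not always numerically consistent with
  that formula (a 439 nm³ dodecahedral box with r_A = 3 nm gives ≈ 326 nm³,
  not 316 nm³); the helper reports the formula value.
* Experimental read normalization clips negative reads to zero *before* the
  channel sum: dividing by a sum containing negatives could flip signs. The
  per-channel scaling by nominal concentration makes the output invariant to
  channel gain but ties the absolute β scale to the channel-sum trend; group
  *differences* in β are the identified quantity, and the group comparison
  uses Welch's t-test by default (unequal group sizes and variances are the
  norm), with a pooled-variance option.
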