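---
title: "Inferring conformational landscapes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring conformational landscapes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confland)
```

`confland` condenses massively parallel molecular-dynamics data — many
short trajectories launched from a few seed structures — into a kinetic
model of an enzyme's conformational landscape, and couples that landscape
to the stopped-flow binding kinetics used to test it experimentally. This
vignette explains the models, the assumptions behind them, the tunable
parameters and their defaults, the numerical choices, and what the
package's synthetic validation does and does not establish about real
trajectory data.

## The synthetic-data generator

Every statistical claim in the package is validated against data whose
ground truth is known exactly. `make_generator()` builds a metastable
hidden-Markov ground truth with three layers:

* a **reversible macrostate chain** `macro_T` whose non-unit eigenvalues
  are placed exactly at `exp(-Δt/tᵢ)` for the requested relaxation
  timescales. A random symmetric count-like matrix is row-normalized
  (detailed balance by construction) and its spectrum rescaled; draws that
  would produce negative transition probabilities are rejected and, if no
  draw succeeds (steep timescale ladders), a deterministic hierarchical
  eigenvector basis with uniform stationary distribution is used instead —
  positivity is then guaranteed for any descending eigenvalue ladder;
* **categorical microstate emissions** with disjoint support: each
  microstate belongs to exactly one macrostate. This makes the microstate
  process itself exactly Markov (its transition matrix and stationary
  distribution are available in closed form as `micro_T`, `micro_pi`), so
  MSM estimators can be checked against exact truth rather than against
  another estimator;
* **isotropic Gaussian feature emissions** around microstate centers
  (default sd 0.25), the simplest model under which tICA and k-means
  recovery are provable.

Trajectories are assigned round-robin to seed groups ("RUNs"), so group
shuffle-splits exercise several groups even for small datasets. The
defaults used throughout the tests and the acceptance script — 3
macrostates, 12 microstates, timescales of 80 and 15 steps, 200 × 5,000
frames for recovery checks — are the package's frozen study conditions.

What the generator does **not** emulate: non-Markovian memory from
projecting out fast degrees of freedom, anisotropic or state-dependent
feature noise, periodic-boundary artifacts, force-field error, and the
~10²–10³-fold larger state and feature counts of production datasets.
Passing tests demonstrate correctness of the estimators under their own
assumptions, not that a particular real dataset satisfies those
assumptions — that is what the validation tools (implied timescales,
Chapman–Kolmogorov, cross-validated scoring) are for.

The bead-chain ensembles (`make_bead_chain_ensemble()`) are geometric
fixtures: seeded penalty minimization places an n-bead chain so that a
requested set of residue contacts is formed (< 0.4 nm) and every other
eligible pair stays clear (> 0.55 nm, a margin the 0.005 nm frame jitter
cannot erode), with ~0.38 nm bonds. They give contact-map and RMSD
operations an exactly known truth table; they are not meant to look like
proteins.

## Featurization

Distances are *minimum heavy-atom* inter-residue distances in nm, for
pairs separated in sequence by at least two residues (|i − j| ≥ 3 — the
literal reading, enforced identically in featurization and contact maps).
The logistic transform `1/(1 + exp(steepness·(d − center)))` with
steepness 5 nm⁻¹ and center 0.5 nm emphasizes near-contact distances;
it maps the center to exactly 0.5 for any steepness. Binary contact maps
use a 0.4 nm (4.0 Å) cutoff — the same threshold that defines "dynamic"
pairs (pairs whose distance crosses 0.4 nm at least once in the dataset).
Dihedral features are (sin, cos) pairs of declared torsions; undefined
angles are omitted, never zero-filled, to avoid constant columns that
would distort tICA.

## tICA

`fit_tica()` solves `C(τ) v = λ C(0) v` on mean-free data pooled over
trajectories; lagged pairs never span trajectory boundaries. Numerical
choices, each isolated and testable:

* `C(τ)` is symmetrized before the eigenproblem, enforcing a real
  spectrum on finite data;
* covariance eigenpairs below `1e-10` of the largest are discarded before
  whitening (deterministic, scale-aware rank control);
* eigenvalues are clipped to (−1, 1]; components with non-positive
  eigenvalue have no defined timescale, carry no resolvable kinetics, and
  are never retained;
* *kinetic content* of component i is defined as `tᵢ/2` — the commute-map
  variance — normalized over retained components. The 95 % rule keeps the
  smallest component count whose cumulative content reaches the target.
  The commute scaling is `sqrt(tᵢ/2)`; it lives in one function so an
  alternative convention can be substituted in one place.

## Microstates and the reversible MSM

`discretize_kmeans()` is k-means++ seeding followed by Lloyd iterations
(relative inertia tolerance `1e-6`, cap 500); an emptied cluster is
re-seeded from the farthest point. These exact rules are part of the
package's contract, which is why the clustering is implemented here rather
than delegated; `stats::kmeans` serves as a cross-check in the tests.

Transition counts use a sliding window (all t → t+τ pairs). This
overcounts correlated transitions by a factor of the lag — deliberately:
the escape-probability analysis corrects for exactly this with
`Neff = N/τ`. The reversible maximum-likelihood transition matrix comes
from the standard self-consistent `x_ij` fixed-point iteration on the
largest strongly connected component (tolerance `1e-12` on the largest
`x_ij` change, cap 10⁶ sweeps; both are this package's choices, as no
canonical values exist). The stationary distribution is the fixed point's
row sums, so detailed balance holds to machine precision.

## Scoring, validation, escape probabilities

The VAMP-2 score is rank-capped at 10. In sample it is `1 + Σᵢ₌₂ λᵢ²`.
Out of sample, no formula is canonical, so the estimator is pinned to one
construction: a reversible MSM is estimated from the *test* counts
restricted to the train active set (unseen states dropped frame-wise,
with the dropped fraction reported), its `C00`, `C0t`, `Ctt` are assembled
in the train model's top-rank eigenfunction basis, and the score is
`‖C00^{−1/2} C0t Ctt^{−1/2}‖²_F`, capped at the rank. The construction is
validated by an exact identity: for test = train it reduces to the
in-sample score to 1e-8. Splits are over seed groups at 50:50, because
trajectories within a group share their starting conformation and are not
exchangeable.

The Chapman–Kolmogorov test compares `T(τ)^k` against re-estimation at
`kτ`, aggregated over metastable sets (argmax of PCCA-style memberships
by default), with count-based binomial error bars deflated by the
sliding-window factor. On generator data it passes; on a constructed
hidden fast/slow mixture it fails by tens of standard errors — both
behaviours are asserted in the tests.

Escape probabilities follow the `f = M/N` estimator with
`Beta(Neff·f, Neff·(1−f))` 95 % intervals and trajectory-level bootstrap
(default 40 replicates; estimates averaged, CI bounds the 2.5th/97.5th
percentiles of per-replicate bounds). The acceptance check measures
empirical CI coverage at a self-transition probability of ~0.89, the
moderate regime the Beta approximation targets, and finds ~95 %. A known
limitation: very close to f = 1 the interval becomes mildly conservative
(~97 % empirical coverage in our experiments) because of the Beta
distribution's skew near the boundary.

## Coarse-graining (HMM)

Baum–Welch runs on lag-strided frames (one hidden step per lag — sub-lag
correlations are deliberately not modeled, consistent with building the
model *at* the Markovian lag), with discrete emissions floored at `1e-12`
before renormalization so held-out microstates cannot zero the
likelihood. Initialization is PCCA+-style: simplex-vertex search in the
space of the top eigenvectors, barycentric memberships, negative entries
clipped. Stopping is |Δloglik| < 1e-6 or 500 iterations; the loglik trace
is stored and its monotonicity asserted. Macrostate-count selection is a
user decision: `hmm_sweep()` reports likelihood and timescales per count,
but the structural-separation judgment that fixes the final count is not
automated. Ties in argmax membership assignment go to the lower
macrostate index and are reported.

## The landscape

Fluxes use the third matrix power to eliminate sparsity,
`Fᵢⱼ = πᵢ(T³)ᵢⱼ/(3τ)` — the per-unit-time normalization by `3τ` is this
package's convention (the alternative, probability per 3τ, differs by a
constant factor and is confined to `flux_matrix`). The 2-D embedding runs
metric MDS by SMACOF stress majorization on `log(1/F)` dissimilarities
(shifted only if negative), restarted from ≥ 50 random initializations.
Where the original analysis selected the projection with the fewest
crossing flux arrows — a manual aesthetic criterion — this package returns
the minimum-stress embedding and records every restart's stress so a user
can re-select by any criterion. Free energies are anchored at the most
populated state (minimum exactly 0, invariant to rescaling π). RMSD
annotation superposes on a fit selection (by default the conformationally
homogeneous SET motifs, residues 257–290 and 327–376, for SETD8-like
numbering) via Kabsch, then measures RMSD over the full Cα selection;
structural diversity of a 100-frame sample is the minimum over reference
frames of the mean RMSD to the other 99.

## Coverage and mutant contact analysis

Coverage analyses are exact set combinatorics and are tested bit-exactly
against brute-force oracles. The coverage contour draws trajectories
without replacement per grid point and averages five draws; for a fixed
draw the grid is exactly monotone in both axes. Differential contact maps
subtract mean contact fractions, set the relative change to zero where
the wild-type value is zero (a pair the wild type never forms cannot be
expressed as a fold change), and select pairs exceeding *both* 0.2
absolute and 3-fold relative change — strict inequalities, since the
printed thresholds do not specify. Candidate-frame extraction keeps
frames with all top-positive contacts formed or none of the top-negative
contacts formed, striding by 10, or by 20 beyond 7,500 qualifying frames;
burn-in (750 ns in the original study conditions) is a parameter.
Cluster expansion uses the 0.3 nm RMSD threshold.

## Binding kinetics

The two-step induced-fit scheme is integrated per concentration. In the
pseudo-first-order regime ([S] ≥ 10× enzyme, as in the 16–2000 µM vs 1 µM
experiment) the linear system is solved exactly by eigen-decomposition;
below that ratio the full bimolecular system with ligand depletion is
integrated stiff-safely (lsoda, absolute tolerance 1e-12). Species
conservation holds to 1e-9 and is asserted.

Global fitting is Levenberg–Marquardt on the four rates with the
fluorescence coefficients profiled out linearly at each step (variable
projection) — this halves the nonlinear dimension and removes coefficient
/rate start-value interactions. Starting values come from the
conventional analysis itself: double-exponential prefits of every trace,
a line fit of `k_obs^fast` against [S] (slope → k₁, intercept → the sum of
the other three), prefits faster than the sampling can resolve discarded;
log-uniform random restarts (default 20) guard against prefit failure.
Standard errors come from the full-parameter Jacobian at the optimum.

Two identifiability facts shape the implementation and the tests:

* with total enzyme conserved, the background `bkg` is collinear with the
  species coefficients; the profiled fit reports `bkg = 0` and only
  differences such as a − c are identified. Rates are unaffected;
* an *unconstrained* conformational-selection fit can reproduce two-step
  data exactly — both schemes are 3-state linear chains whose eigenvalue
  sums and products are linear in [S]. The physical content of the
  comparison is that E and E' hold the fluorophore in the same
  (ligand-free) environment and therefore share one coefficient; with
  that constraint the conformational-selection fit fails on biphasic
  induced-fit data (residual norm about twice the two-step fit's at 1 %
  noise), which is exactly the discrimination the experiment relies on.

`kobs_predictions()` exposes the printed relations as stated — including
the additive `k₁[S]` term in the slow-phase expression alongside the
S-independent plateau `k₂ + k₋₂`; the tension between the two is
documented rather than resolved, and both quantities are returned.
Equilibrium constants use `K_d1 = k₋₁/k₁`, `K_eq = k₋₂/k₂`,
`K_d = K_d1·K_eq/(1+K_eq)` (strictly below `K_d1` for finite `K_eq`),
with first-order error propagation through the fit covariance; the
delta-method errors are validated against Monte-Carlo propagation in the
moderate-error regime where a first-order method is applicable. The
instrument dead time (default 5 ms) truncates traces before fitting.

## Problem sizes

The test suite and the acceptance script run the recovery analyses at
3 macrostates / 12 microstates with up to 200 × 5,000-step trajectories
(10⁶ frames per replicate, 10 replicates for the MSM medians), 10⁵-frame
tICA problems, 500-replicate CI-coverage studies, and 8-concentration ×
200-point kinetic datasets over 20 noise seeds. These sizes were chosen
so the full validation is a desk-scale computation while keeping every
statistical check well-powered; all of them are parameters, and the same
code paths run unchanged at production scale.

## Known limitations

* The out-of-sample VAMP-2 estimator is one defensible construction among
  several; it is pinned, isolated and identity-validated, but scores are
  not numerically comparable to other software's out-of-sample scores.
* The HMM models dynamics only at the chosen lag; sub-lag kinetics are
  invisible by design.
* Escape-probability intervals are mildly conservative very close to
  f = 1 (see above).
* The bead-chain fixtures validate geometry codepaths, not molecular
  realism; dihedral features on bead chains use consecutive-quadruplet
  torsions, not φ/ψ/χ₁ definitions, which require an atomistic topology.
* MDS embeddings are reported at minimum stress; with few states several
  near-degenerate embeddings can exist, and the recorded restart stresses
  should be inspected before interpreting distances quantitatively.
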