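---
title: "Markov state models of disordered-lid binding and docking evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state models of disordered-lid binding and docking evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidmsm)
```

# The scientific problem

MDM2 carries an intrinsically disordered N-terminal "lid" (residues 1–25)
that competes with the p53 transactivation domain for the p53-binding cleft.
Because the lid is disordered, its association with the cleft is not a
transition between two well-defined structures but an exchange between two
*diffuse conformational basins*.  This package provides the analysis
machinery to (i) detect and quantify such two-state-but-diffuse kinetics
from large ensembles of short molecular-dynamics trajectories via Markov
state models (MSMs), and (ii) evaluate whether receptor conformations
harvested from the MSM are useful for computational docking of
cleft-binding ligands, including helical peptides rigidified for docking.

Everything is testable without trajectory data: the `synthetic_data` module
plants known kinetics and emissions, so each stage of the pipeline has a
parameter-recovery test against an analytic ground truth.

# The modeling chain

## Featurization

Conformations are encoded as pairwise C-alpha distances (Å) over the union
of the lid residues (default 1–24) and the binding-site residues, where the
site is defined as every receptor residue with any atom within a 5 Å cutoff
of any atom of a bound reference ligand (`select_binding_site()`).  Two
pair rules are offered and recorded with every output: `all` (all unordered
pairs over the union; $n(n-1)/2$ features) and `cross` (lid × site pairs
only).  Both are kept because neither rule is canonical for this receptor —
the exact composition of a published distance set is generally not
reconstructible from a feature count alone, and the choice measurably
affects tICA input dimension.  Distance features are invariant under global
rotation and translation, which the tests assert explicitly.

Secondary structure enters only as DSSP letter strings, mapped to helix
(letters G, H, I) and sheet (letters B, E) fractions; all other letters,
including unknown ones, count as coil.  No DSSP computation is performed
here.

## tICA

Time-lagged independent component analysis finds the linear feature
combinations of maximal autocorrelation at a lag $\tau$: with mean-free
features $x(t)$,

$$C_0 = \langle x x^\top \rangle, \qquad
  C_\tau = \tfrac12 \langle x(t)x(t+\tau)^\top + x(t+\tau)x(t)^\top \rangle,
  \qquad C_\tau v = \lambda\,(C_0 + \epsilon I)\, v .$$

Numerical choices, all deliberate:

* **Symmetrized** $C_\tau$ forces a real spectrum, the appropriate
  estimator for reversible dynamics.
* **Ridge** $\epsilon = 10^{-10}\,\mathrm{tr}(C_0)/d$ by default, so frozen
  (zero-variance) features — common when parts of a structure are
  restrained — do not make $C_0$ singular.  With the ridge disabled, a
  singular $C_0$ raises an error naming the zero-variance features.
* **Pooling weights every transition pair equally**, not every trajectory,
  matching the transition-count weighting of the MSM stage.
* **Deterministic sign**: each component's largest-magnitude loading is
  positive.
* Default lag: 1 frame (one stored snapshot).

At lag 1 on a univariate AR(1) signal the single tICA eigenvalue equals the
lag-1 autocorrelation, which is the unit test's oracle; the spectrum is
invariant under invertible linear feature mixing, which is the property
test.

## Discretization

`k_centers()` is the default: a deterministic farthest-point traversal
(first center = frame at `start_index`, default the first frame; ties to
the lowest frame index).  It is fully reproducible with no random state and
its cover radius is within a factor 2 of the optimal k-center radius — the
test checks this against exhaustive search on small instances.
`k_means_lloyd()` provides Lloyd iterations *initialized from the k-centers
solution* (movement tolerance $10^{-8}$, 500 iterations cap); a cluster
that empties is re-seeded at the frame farthest from its assigned center.
The base-R `kmeans()` is not used because its initialization and
empty-cluster policies are randomized, and bit-reproducibility of the
discretization is a design goal here.  Assignment ties go to the lowest
center index.

## Transition matrices and spectra

Transitions are counted with a sliding window by default (every pair
$(t, t+\tau)$; uses all data, appropriate for likelihood estimation at
short lags); a strided mode is available for independence checks.  The
count graph is trimmed to its largest strongly connected component
(ties broken toward the component holding more counts); the untrimmed
matrix and the dropped-state report are always retained on the object.

Two estimators:

* `estimate_nonreversible()`: the multinomial MLE
  $T_{ij} = C_{ij}/\sum_j C_{ij}$.  Complex eigenvalue pairs are flagged
  and reported, never silently truncated.
* `estimate_reversible_mle()`: maximizes the likelihood subject to
  detailed balance $\pi_i T_{ij} = \pi_j T_{ji}$ via the standard fixed
  point on symmetric auxiliary variables
  $x_{ij} \leftarrow (C_{ij}+C_{ji})\,/\,(C_i/x_i + C_j/x_j)$, converged
  when the maximum relative change drops below $10^{-10}$ (cap $10^6$
  iterations; non-convergence is an error reporting the residual).  On
  symmetric counts the fixed point is immediate and the result equals row
  normalization *exactly*, which the tests assert bitwise.

`spectral_analysis()` completes a row-stochastic $T$ into eigenvalues
$\mu_n$ (sorted descending), biorthonormal mode pairs, the stationary
distribution $\pi$, and implied timescales
$\tau_n = -\tau_{\mathrm{lag}} / \ln \mu_n$.  Internally matrices are
row-stochastic; column-stochastic external conventions are the transpose,
with the roles of the two eigenvector families swapped, and belong at the
I/O boundary.  The stored families follow the master-equation convention:
`phi` are distribution-like modes ($\phi_0 = \pi$), `psi` are
observable-like projectors ($\psi_0 = $ constant), with
$\psi_m^\top \phi_n = \delta_{mn}$.  Population dynamics follow the
spectral solution of the master equation,

$$p(k\tau) \;=\; \sum_n (\psi_n \cdot p(0))\; \mu_n^{\,k}\; \phi_n,$$

implemented in `propagate()` with $\mu^k$ rather than
$e^{-t/\tau_n}$ — identical for $0<\mu<1$ but also exact for
non-positive eigenvalues — and verified against iterated application of
$T$ to $10^{-10}$.

**Sign convention.**  For $n \ge 1$ the entries of $\phi_n$ sum to zero by
biorthogonality with the constant mode, so no sign can be attached there.
Instead each pair is flipped so that $\sum_i (\psi_n)_i \ge 0$: then every
amplitude $(\psi_n \cdot p_0)$ is non-negative when $p_0$ is uniform, and
relaxation from a uniform start is a superposition of positive-amplitude
decaying modes.  If the projector sum is zero within tolerance, the first
nonzero entry of $\phi_n$ is made positive.

The general dense eigensolver is used for both reversible and
non-reversible input *on purpose*: the similarity transform
$D_\pi^{1/2} T D_\pi^{-1/2}$ (symmetric for reversible $T$) then remains a
genuinely independent oracle in the test suite rather than being the
implementation itself.

## Implied-timescale diagnostics

`implied_timescale_curves()` repeats count → reversible MLE → spectra over
a ladder of lags and reports the slowest timescales and the gap ratio
$\tau_1/\tau_2$ per lag.  A flat $\tau_1(\mathrm{lag})$ indicates the
discretization resolves Markovian dynamics; a persistent large gap
diagnoses effective two-state kinetics even when each basin is internally
diffuse — exactly the signature expected for a disordered lid exchanging
between cleft-associated and dissociated ensembles.

## Model selection (GMRQ)

The generalized matrix Rayleigh quotient scores a training model's leading
$m$ eigenvectors $A$ (observable-like, on the state basis) on held-out
data: $\mathrm{tr}[(A^\top S A)^{-1} (A^\top C A)]$ with $S$ the diagonal
test state-visit frequencies and $C$ the symmetrized test transition
frequencies.  At the optimum this is the sum of the leading $m$ propagator
eigenvalues, so it is variationally bounded above by
$1 + \sum_{n=1}^{m-1}\mu_n(\mathrm{true})$ — the test suite checks the
bound with a sampling allowance of 0.1, about three standard deviations of
the score fluctuation at the test's sample sizes.  $m = 1$ scores exactly 1
regardless of data (the stationary mode), a useful self-check.  Folds split
whole trajectories, never frames, preserving temporal correlations;
training states never visited in a test fold get a $10^{-10}$ pseudocount
on the overlap diagonal, with a warning.  Default $m = 3$: the stationary
mode plus the two slow modes that a two-component tICA is meant to capture.

## Coarse-graining (BACE-style)

`bace_merge()` agglomerates microstates by repeatedly merging the
kinetically connected pair with the smallest log Bayes factor between their
outgoing transition-count distributions,

$$\ln \mathrm{BF}(i,j) = \sum_k \left[ C_{ik}\ln\frac{p_{ik}}{q_k}
  + C_{jk}\ln\frac{p_{jk}}{q_k} \right],$$

with $q$ the count-weighted average row of the merged state.  This is the
leading log-likelihood-ratio term of the Bayesian agglomerative criterion;
the exact posterior form involves priors the method's users rarely vary,
and the leading term is isolated in one function so it can be swapped.
Only pairs with at least one observed transition are candidates (never
merge kinetically disconnected states); ties go to the lowest index pair,
making the merge sequence deterministic.  Counts are conserved exactly
under aggregation, and for a lumpable chain (block-constant rows) the
coarse stationary distribution equals the aggregated fine one to $10^{-8}$.

## Contact enrichment

Regions of the 2-D tICA landscape are compared by a smoothed odds-ratio
Bayes factor per residue pair: with pseudocount $\alpha$ (default 1),
$f = (k+\alpha)/(n+2\alpha)$ in-region and over all frames, and
$\mathrm{BF} = [f_r/(1-f_r)]\,/\,[f_a/(1-f_a)]$.  The complement event has
exactly the reciprocal Bayes factor.  One consequence of smoothing worth
knowing: a pair never in contact anywhere scores
$(n_a+\alpha)/(n_r+\alpha)$, not 1 — with few in-region frames the prior
odds dominate.  BF = 1 arises exactly when in-region and overall
frequencies coincide.  Quadrants of the landscape are defined about the
per-component *medians* by default (robust to the arbitrary sign and
offset of tICA coordinates; zero-centering is available as an option);
frames exactly on a boundary go to the lower quadrant index, so degenerate
inputs land in Q1.  A median split halves each margin exactly (even frame
counts), but joint quadrant counts fluctuate like $\sqrt{n}$ — only the
margin property is guaranteed and tested.

# The synthetic-data generator

`chain_spec()`/`simulate_chain()` generate what the downstream stages need
to be tested against: many short trajectories from a planted Markov chain
with Gaussian emissions in feature space.  The defaults emulate the
statistical shape of a distributed-computing trajectory dataset for this
receptor: trajectory lengths roughly exponential with mean 67 frames
truncated at 945 (resampled above the maximum, floored at 2 frames), and
24 round-robin initial conditions (capped at the state count), mirroring
an NMR-ensemble worth of starting structures.

The planted chain `planted_chain_4state()` is an exact closed form: a
doubly stochastic two-block matrix whose spectrum is
$\{1, 0.95, 0.5, 0.3\}$ — slow exchange between blocks $\{1,2\}$ and
$\{3,4\}$ (implied timescale $-1/\ln 0.95 = 19.496$ steps) with faster
within-block mixing.  This gives the pipeline a "two-state with internal
structure" target whose ground truth is analytic.  Emissions are isotropic
Gaussians (default sd 0.5) about per-state means drawn once from a seeded
standard normal scaled by 2 in 10 dimensions, giving tICA a nontrivial
high-dimensional problem with known low-dimensional latent structure.

Seeding uses a splitmix-style counter scheme: trajectory $i$'s seed is a
fixed hash of (master seed, $i$), so enlarging the ensemble never
reshuffles earlier trajectories, and all generators are bit-reproducible.

`simulate_double_well()` is the continuous analogue: overdamped Langevin
dynamics (Euler–Maruyama, $kT = 1$) on
$U(x,y) = h\,((x/a)^2-1)^2 + y^2/2w^2$, a two-basin coordinate $x$ plus a
broad "diffuse" coordinate $y$.  Divergence ($|x| > 10\times$ well
separation) aborts with an instability error rather than returning
garbage.  Its occupancy histogram is tested against Boltzmann weights
integrated on a grid.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: non-Markovian memory from projecting out fast
degrees of freedom, anisotropic and state-dependent noise, slow drift or
force-field bias, and the strong correlation structure of real distance
features.  Recovery results here certify the estimators, not any
particular molecular system.

# Docking evaluation

## Peptide rigidification and torsion accounting

Docking engines treat closed cycles as rigid while still relaxing them
locally, so a helical peptide ligand can be docked with a fixed backbone by
adding an **artificial bond between its terminal alpha-carbons**, closing a
macrocycle that absorbs every backbone phi/psi/omega bond (the variant bond
between the backbone N and C termini is available as an option).  Ring
perception is uniform and exact: a bond is in a ring iff it is not a bridge
of the heavy-atom bond graph, which covers aromatic rings, the proline
pyrrolidine and the artificial macrocycle with one rule.

The rotatable-torsion convention (`count_torsions()`) is a single documented
rule: a non-ring bond rotates iff *both* sides carry at least one further
heavy atom, **or** its terminal atom is an sp3 O/N bearing a polar hydrogen
attached to an sp3 atom (Ser/Thr/Cys hydroxyls and thiols, Lys NZ, the
N-terminal amine).  Methyls and other all-hydrogen carbon rotors are not
counted; the tyrosine phenol and Asn/Gln amide N–H are excluded as
conjugated; the terminal C$\alpha$–carboxylate bond counts (it moves two
heavy oxygens) and, like the N-terminal amine, dangles outside the
macrocycle and so stays rotatable after cyclization.

This convention reproduces the rigidified counts of both peptide ligands in
the test set exactly: cyclized ETFSDLWKLLPE → 29, cyclized TSFAEYWALLSP
→ 21.  For the *linear* form an instructive arithmetic fact applies:
cyclization can remove at most the backbone bonds absorbed into the
macrocycle — for a 12-mer with one proline that is $10 + 11 + 11 = 32$
bonds — so *no* bond-counting convention can take the same 12-mer from 66
to 29 (a reduction of 37).  The linear count of 66 is recovered exactly for
the full 13-residue crystallographic p53 transactivation-domain fragment
ETFSDLWKLLPEN, from which the docked 12-mer is trimmed; the 12-mer itself
has 61 linear torsions under this convention.  Both numbers are computed
and asserted in the tests; the package reports the 13-mer linear count as
the linear-form reference value and documents the discrepancy rather than
hiding it.

`rigid_segments()` lists the rigid fragments (≥ 5 heavy atoms by default)
left after deleting rotatable bonds — the candidate anchors of an
anchor-and-grow search.  Only the report is provided; no search is
performed here.

## Outcome taxonomy and enrichment

A docking outcome for one (ligand, receptor) cell is classified from its
pose list with the 2.0 Å success rule: **success** if the best-scoring
pose is within 2.0 Å of the crystal pose; **scoring failure** if a
≤ 2.0 Å pose was sampled but not top-scored; **sampling failure** if no
such pose exists.  The three classes partition all cells.  Pose RMSD is
computed in the receptor frame with *no superposition* (the docking
convention), matching atoms by name.  `enrichment_curve()` ranks each
ligand's receptors by best pose score (ties by receptor id) and reports
the fraction of ligands with a success among their top-$N$ receptors;
TPR($N$) is non-decreasing and reaches the ligand success fraction at
$N = $ all receptors.  `funnel_table()` exports (score, RMSD) pairs with
per-ligand Spearman correlations — a funnel-shaped, positively correlated
cloud means low scores predict good poses.

# Problem sizes and runtimes

The test suite and the acceptance checks run at desk scale by design: the
parameter-recovery run uses 200 trajectories with truncated-exponential
lengths (mean 500, max 5000 frames; ~10^5 frames total), 10-D emissions,
two tICA components, 50 k-centers microstates, and lags 1–20 — enough to
recover the planted slow timescale within 15% and a gap ratio above 5 in a
few seconds.  GMRQ comparisons use 50 independent repeats of 16 short
trajectories; fuzzing of the docking statistics uses 1000 random tables.
These sizes were chosen so that statistical tolerances (binomial and
spectral standard errors) are met with margin.

# Known limitations

* tICA is linear; kinetic-map scalings and kernel variants are out of
  scope.
* No transition-path theory, committors, or rate-matrix (generator)
  estimation — only the discrete-time propagator is modeled.
* BACE uses the leading likelihood-ratio term, not the full posterior.
* Peptide topology templates cover the 20 standard residues at dominant
  pH-7 protonation; no nonstandard residues, caps, or tautomer handling.
* The docking module evaluates docking *outputs*; it contains no scoring
  grids, minimizers, or conformer search.
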