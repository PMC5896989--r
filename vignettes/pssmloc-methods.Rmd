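---
title: "Methods: PSSM correlation features, kernel discriminant analysis and genetic bandwidth search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSSM correlation features, kernel discriminant analysis and genetic bandwidth search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmloc)
```

This vignette documents the statistical machinery in `pssmloc`, the
assumptions behind it, the tunable parameters and their defaults, and the
numerical decisions that make results reproducible across platforms.

## The prediction problem

Protein subnuclear localization asks which compartment of the cell nucleus
(nucleolus, chromatin, nuclear speckle, ...) a protein resides in, given
only sequence-derived information. The signal exploited here is
evolutionary: a position-specific scoring matrix (PSSM) produced by
iterative profile search records, for every sequence position `i` and every
residue type `j`, the log-odds score of `i` mutating to `j` over evolution.
Proteins sharing a compartment tend to share profile statistics even when
raw sequence identity is low. PSSM generation itself (PSI-BLAST against a
reference database) is outside the package; the parsers consume the
standard ASCII output.

## Feature representations

**CoPSSM (210-D).** Column means `M_j = mean_i M[i, j]` compress the
variable-length profile into a 20-vector of residue-wise evolutionary
propensities; the representation is the set of all pairwise products
`M_j * M_k` over index pairs `j <= k`. Three choices deserve note:

* *The diagonal is included.* The pair range `j <= k` yields exactly
  `20 * 21 / 2 = 210` components only if the squares `M_j^2` are kept; the
  alternative reading ("products of two *different* elements",
  `j < k`) would give 190. We treat "different" as referring to the two
  index positions, not to distinct values, which is the only reading
  consistent with the stated 210-dimensionality.
* *Ordering is lexicographic* over `(j, k)` with residues alphabetical —
  `(1,1), (1,2), ..., (1,20), (2,2), ..., (20,20)` — fixed so feature
  tables are column-stable across runs and input dialects. Parsers reorder
  any input column order into the alphabetical one.
* *Scores are used raw.* Log-odds integers, possibly negative, enter the
  means unscaled; no sigmoid or per-protein normalization is applied.
  Any affine rescaling the classifier needs is absorbed by the kernel
  bandwidth downstream.

Useful identities, enforced by tests: CoPSSM is invariant to PSSM row
permutation; scaling all scores by `a` scales every component by `a^2`; and
`c(j,j) * c(k,k) = c(j,k)^2` exactly.

**PSSM400 (400-D).** The classical fixed-length baseline sums profile rows
grouped by the residue observed at that position into a 20 × 20 matrix
(row-major flattening, observed residue outermost). Sums are not divided by
sequence length; the description of this representation in the literature
is additive, and any normalization would again be absorbed by the kernel.
Rows at nonstandard positions (B/Z/X/U) are excluded from the grouping —
group identity is undefined for them — but retained in the CoPSSM column
means, which are defined over all rows.

**PseAAC (20 + 2β)-D.** Amphiphilic pseudo-amino-acid composition:
residue count frequencies `f_u` plus `2β` sequence-order correlation
factors, `tau[2m-1] = mean_i H1(R_i) H1(R_{i+m})` and
`tau[2m] = mean_i H2(R_i) H2(R_{i+m})` for lags `m = 1..β`, combined as
`p_u = f_u / (sum f + w sum tau)` and `p_{20+t} = w tau_t / (same)`.
Defaults: `β = 10` (40-D output; β must be smaller than the sequence
length), `w = 0.05`. The hydropathy scales (Tanford-type hydrophobicity,
Hopp–Woods hydrophilicity) ship as an editable JSON table and are
standardized to mean 0 and unit mean square over the 20 residues — the
conventional normalization in this literature. Because published variants
of the scales differ, exact numeric agreement with any particular external
implementation depends on supplying that implementation's raw scales via
`pseaac_scales(path)`. The degenerate case `sum f + w sum tau <= 0`
(possible in principle with strongly negative correlation sums) is an
error, not a silent division.

## Kernel discriminant analysis

`klda_fit()` implements generalized discriminant analysis in dual form.
With Gaussian Gram matrix `K` (entries `exp(-||x_i - x_j||^2 / 2 sigma^2)`):

1. double-center: `Kc = H K H`, `H = I - 11'/N`;
2. between-class dual scatter `S_B = sum_i N_i m_i m_i'` with
   `m_i` the mean of class-`i` columns of `Kc` (the global mean column
   vanishes after centering);
3. within-class dual scatter `S_W = Kc Kc - S_B`;
4. regularize `S_W + eps I`, `eps = 1e-8 * trace(S_W) / N` — the Gram
   matrix is rank-deficient whenever `N` exceeds the effective rank, so an
   unregularized solve is ill-posed;
5. solve the generalized eigenproblem by symmetric whitening
   (Cholesky of the regularized `S_W`, then a symmetric `eigen`), keeping
   the top `d` eigenvectors as dual coefficients.

Projections of new points center the test kernel columns with the stored
training column means and grand mean, so `klda_transform(fit, train)`
reproduces the fit's own projections to machine precision.

Numerical conventions: eigenvector signs are fixed by making each
direction's largest-magnitude dual coefficient positive (LAPACK sign
indeterminacy would otherwise leak into serialized models); eigenvalues are
reported per direction and `d_effective` counts those above
`1e-9 * max(eigenvalue)`. For `K` classes at most `K - 1` discriminants
carry signal, yet the conventional reduced dimension equals the class
count; the default therefore keeps `d = K`, returns the trailing
near-null direction, and flags `d_effective = K - 1` with a warning.
Requests of `d > K` are capped at `K`.

## The dispersion-ratio criterion

Bandwidth quality is scored by `D_B / D_W` on the projected training data:
`D_W` sums squared distances of samples to their class means, `D_B` sums
squared distances of class means to the global sample mean. Two points are
deliberate:

* **`D_B` is unweighted over classes** — each class contributes once
  regardless of size. This is the criterion's printed form in the
  literature this package follows; a class-size-weighted variant
  (`weighted = TRUE`) is available and reduces to the unweighted one
  divided by the common class size on balanced data.
* **Sentinels make the optimizer's comparisons total.** `D_W = 0` with
  `D_B > 0` (perfectly collapsed, separated classes) scores `+Inf`, which
  compares greater than any finite fitness; both zero scores 0. The ratio
  is invariant to rigid translation and uniform scaling of the
  projections, so the criterion measures geometry, not units.

The criterion is computed on whatever data is passed in; the bandwidth
optimizer passes the full training projections (no holdout), matching the
design where the jackknife measures generalization separately.

## The dichotomous greedy genetic algorithm

`dgga_optimize()` is an interval-halving outer loop around a small
real-coded GA. Outer loop: draw a population on `[x0, xn]`; let `x_max` be
its best point; each iteration runs the GA on `[x0, x_max]` and
`[x_max, xn]`, keeps the subinterval with the larger best fitness, moves
the discarded endpoint to `x_max` and `x_max` to the winner's best point.
Inner GA per generation: 1-elitism; roulette (fitness-proportional) parent
selection for a `p_select` fraction of slots with the remainder carried by
rank; arithmetic crossover `child = lambda a + (1 - lambda) b`,
`lambda ~ U(0,1)`, with probability `p_cross`; uniform-resample mutation
within the interval with probability `p_mutate`; offspring clamped to the
interval. Chromosomes are the bandwidth itself (real-coded) — a binary
encoding would add nothing for a single positive scalar.

Defaults: population 10, outer iterations 10, inner generations 10,
`p = (0.5, 0.7, 0.1)`. The selection probability is read as *the fraction
of the next generation filled by roulette-selected parents* — of several
defensible readings of a scalar "selection probability", this one keeps
the constant meaningful at any population size. The inner generation count
is not prescribed anywhere; 10 mirrors the population/iteration constant
and is configurable.

Tie and edge rules (all asserted by tests): equal subinterval fitness
keeps the *left* subinterval; a zero-width subinterval (best point at an
endpoint) is skipped and the other used; the reported best is the global
best over all evaluations, so the trace's best fitness is non-decreasing
and every interval is nested in the initial one. Roulette weights shift
fitnesses to be nonnegative; a population containing `+Inf` fitness
selects only among the infinite-fitness individuals. Identical
`(interval, fitness, config, seed)` reproduce the trace exactly.

The default search interval for the KLDA bandwidth is
`[0.01 m, 100 m]` with `m` the median pairwise Euclidean distance of the
features — scale-adaptive and wide enough to cover both the
under-smoothing regime (Gram matrix near identity) and the over-smoothing
one (Gram matrix near all-ones).

## Evaluation protocols and metrics

Classification is cosine-distance KNN. Deterministic tie rules: distance
ties at the K-th rank are broken by training-set order (first wins); vote
ties go to the class whose nearest member is closest. A zero-norm vector
is at distance 1 from everything — degenerate features classify
uninformatively rather than aborting.

The jackknife removes each sample in turn, refits the KLDA projection on
the remaining `N - 1` points (the held-out sample is excluded from the
Gram matrix — the only leakage-free reading of leave-one-out; a fast mode
projecting through a single global fit exists and is labelled in the
report), projects both sides, classifies, and accumulates one-vs-rest
confusion counts. The bandwidth, by contrast, is optimized *once* on the
full dataset and reused across folds: re-running the genetic search inside
every fold multiplies cost by `N` for a parameter that is stable under
single-point deletion. This mild leakage is recorded in the report's
flags, and a strict `optimize_per_fold` mode is available. The independent
test fits everything on the training set only.

Reports scan `K = 1..20` and select the smallest K attaining the maximum
OSR (ties would otherwise be platform-ordering-dependent). Per class:
`SE = TP/(TP+FN)` (also that class's individual success rate),
`SP = TN/(TN+FP)`, `ACC = (TP+TN)/N`, and MCC; any zero denominator yields
an undefined value serialized as `"-"`. `OSR = sum TP / sum (TP+FN)`
equals plain label accuracy, and the two are computed through independent
code paths and asserted equal.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the structure the CoPSSM pipeline
assumes: classes differ in their *mean profile* over the 20 score columns.
Class means sit on orthogonal coordinate axes at mutual distance
`separation`; PSSM rows are the class mean plus i.i.d. Gaussian noise with
SD `spread` (default 1, so `separation` is in noise-SD units); sequences
are drawn from a per-class Dirichlet composition bias. Scores are
continuous by default — separability analysis is cleanest without
rounding — with an `integer_scores` flag producing PSI-BLAST-like integer
profiles for format round-trip fixtures.

What the generator does *not* emulate: correlation between a position's
residue and its score row (no substitution model), position-to-position
score dependence, length variation within a dataset, or the heavy class
imbalance of real benchmarks. Passing tests on synthetic data therefore
demonstrate correctness of the machinery and recovery of planted
mean-profile structure; they say nothing about attainable accuracy on real
compartment benchmarks, which depends on signal the generator does not
plant. `simulate_feature_clusters()` provides plain Gaussian blobs for
discriminant/search/KNN tests where PSSM structure is irrelevant; zero
within-class spread is allowed as the degenerate fixture driving the
criterion to its `+Inf` sentinel.

Test and acceptance problem sizes are modest by choice — datasets of 2–3
classes with 8–15 members, sequence length 25–40, 20-seed batteries for
stochastic properties — chosen as the smallest sizes at which the checked
properties are stable, keeping the full suite fast enough to run on every
change.

## Known limitations

* PseAAC results are scale-table-dependent; reproducing any specific
  published table requires that publication's exact raw scales.
* The `d = K` convention carries one near-null discriminant direction;
  analyses sensitive to it should use `d_effective`.
* The jackknife default's once-optimized bandwidth is mildly optimistic;
  the strict mode is exact but `N` times the cost.
* DGGA is a heuristic: on multimodal fitness landscapes the greedy
  interval halving can discard the global optimum's subinterval early; the
  guarantees asserted are monotonicity, containment and high-probability
  recovery on unimodal objectives (at least 18 of 20 seeds within 5% of a
  grid oracle), not global convergence.
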