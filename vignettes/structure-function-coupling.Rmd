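---
title: "Structure-function coupling analysis of brain connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling analysis of brain connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sfconn implements a complete two-group connectome analysis of the kind used
to study vascular cognitive impairment (VCI) against healthy controls (HC):
binary structural and functional network construction, a graph-topology
battery with degree-preserving null models and sparsity-AUC summaries,
per-node structure-function coupling, and covariate-adjusted group
inference with family-wise error (FWE) control plus partial correlations
between coupling and cognitive scores. Because subject-level MRI data of
this design are typically not redistributable, the package also ships a
seeded synthetic cohort generator with planted effects, so that every
downstream stage can be validated end to end with no external data. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## Network construction

**Structural networks.** Input is one streamline-count matrix per subject
(90 nodes in the default AAL-style parcellation). An edge is present when
the count is at least `fiber_threshold` (default 3), which suppresses
spurious single-streamline connections of deterministic tractography. A
group-consistency mask then retains only edges present in *strictly more*
than `group_consistency` (default 0.8) of subjects; we read "over 80%"
literally, so an edge present in exactly 80% of subjects is dropped. Both
constants are configuration values, never hard-coded. Whether the mask is
computed over all subjects or per group is genuinely ambiguous in this
design; the default is all subjects (`consistency_scope = "all"`) with a
per-group mode available, since masking per group can by itself create
spurious group differences in edge sets.

**Functional networks.** Regional BOLD series (default 200 timepoints) are
correlated pairwise (Pearson), Fisher z-transformed (`atanh`, with |r| ≥
1−1e−7 clipped and counted), and binarized over a sparsity grid, default
0.01 to 0.40 in steps of 0.01. At sparsity *s* the `floor(s·N(N−1)/2)`
largest positive z-values become edges; negative and zero weights never
do, following the dominant convention for binary small-world analysis of
functional networks. Ties at the cutoff break by ascending (row, column)
order, which makes thresholding bit-reproducible and makes edge sets
nested across the grid, so efficiency-type metrics are monotone in
sparsity by construction. Because `atanh` is strictly increasing,
binarization commutes with the z-transform; the transform matters for the
weighted matrices used in coupling, not for the binary graphs, and a test
asserts this invariance.

## Graph-topology battery

All metrics use standard binary-graph definitions on undirected graphs:
global efficiency `Eglob` (mean inverse shortest path with 1/∞ = 0), local
efficiency `Eloc` (mean over nodes of the global efficiency of the
neighbor-induced subgraph), clustering `Cp` (mean of C_i = 2e_i/k_i(k_i−1)
with C_i = 0 when k_i < 2; an exclude mode is available), characteristic
path length `Lp` (mean over *finite* pairwise distances with an explicit
`disconnected_flag` rather than ∞ or harmonic substitution, so low-sparsity
graphs stay summarizable while disconnection is surfaced), plus nodal
analogues (degree, exact betweenness normalized by (N−1)(N−2)/2, NEglob,
NEloc, NCp, NLp). Small-worldness is
`Sigma = (Cp/⟨Cp_null⟩)/(Lp/⟨Lp_null⟩)` over a Maslov–Sneppen ensemble:
degree-preserving double-edge swaps, `swaps_per_edge · E` attempts per
null (defaults: 100 nulls, 10 swaps per edge, seeded per subject and
level). Graphs admitting no legal swap (complete graphs) yield unmodified
copies with a warning, which correctly gives Sigma = 1. Functional metrics
are summarized across the sparsity grid by the trapezoidal area under the
curve; on a uniform grid trapezoid and rectangle rules differ only at the
endpoints, and the trapezoid is what the AUC tests freeze. AUC is refused
(not silently patched) when any level is undefined, e.g. nodal path length
of a node isolated at low sparsity.

The implementation delegates graph primitives (breadth-first distances,
betweenness, rewiring) to igraph; the test suite checks every metric
against independent brute-force oracles — Floyd–Warshall distances,
A³ triangle counts, exhaustive geodesic counting — on hundreds of seeded
random graphs to 1e−12, and calibrates Sigma: ≈1 on dense Erdős–Rényi
graphs, ≫1 on ring-lattice small-world graphs.

## Structure-function coupling

A node's structural profile is its column of the count matrix with the
self-entry removed; its functional profile is the matching column of the
weighted Fisher-z FC matrix (the pre-threshold matrix — coupling is about
graded connectivity signatures, not binary graphs). Coupling is Spearman's
rho, with average ranks for ties, over the components where the structural
entry is non-zero (`coupling_selection = "sc_nonzero"`; a `both_nonzero`
mode exists but differs only when FC values are exactly zero, which is
measure-zero for real data). Rho is flagged undefined — never imputed or
zeroed — when fewer than `min_coupling_pairs` (default 10, below which
rank correlations are unstable) components survive or a selected profile
is constant. Cohort summaries average defined values only and report the
number of contributing subjects per node.

The structural profile uses streamline *counts* by default. A binary
structural profile makes Spearman degenerate (constant vector), which is
why the count default exists even though the topology stage uses binary
graphs; the binary mode is retained for sensitivity analysis and warns
when it produces all-undefined output.

## Group inference

Analysis of a feature family (one family per metric type, e.g. the 90
nodal coupling values) proceeds as: (1) residualize each feature on an
intercept, age, a single sex indicator, and education by OLS — covariate
adjustment precedes testing; (2) route each feature by Shapiro–Wilk on the
two group residual samples (both p > 0.05 → pooled-variance independent
t-test; otherwise Mann–Whitney U; categorical demographics use
chi-squared); all tests two-tailed; (3) control FWE across the family.

The FWE procedure is configurable: Bonferroni, or the default permutation
max-statistic method, which is the standard choice for correlated nodal
neuroimaging features. Group labels are permuted (default 1000 draws,
seeded); for each permutation the maximum |t| over the family is recorded;
the adjusted p of feature *j* is `(1 + #{max_b ≥ |t_j|})/(B + 1)`. The
permutation statistic is a single family-wide statistic (pooled t on
residuals, or t on rank-transformed residuals with `fwe_stat = "rank"`,
which is invariant to feature-wise monotone rescaling) rather than the
per-feature routed statistic, so the maximum is taken over comparable
scales; routing still determines each feature's reported raw test.
Adjusted p-values are floored at the raw p-values, so `p_fwe ≥ p_raw`
holds by construction even though the two come from different
approximations. Under a simulated global null the empirical family-wise
error rate of this procedure stays at or below the nominal 0.05 (the
acceptance suite measures it at 200 simulations × 500 permutations × 90
features).

Partial correlations between nodal coupling and cognitive scores (AVLT,
SDMT, STT_B, BNT) correlate the covariate residuals of both variables
(rank-transformed first for Spearman), with two-tailed p from the
t-approximation on n − 3 − 2 degrees of freedom; the Pearson/Spearman
choice is routed by Shapiro–Wilk like the group tests, and both
coefficients are always reported. Missing scores are excluded pairwise and
the complete-case n is reported — never imputed. Within the pipeline these
correlations are computed at the nodes whose coupling differs between
groups, mirroring the usual reporting structure, and corrected with
Bonferroni across nodes per score.

## The synthetic cohort generator

The generator emulates the study design: 53 HC + 68 VCI subjects, 90
nodes, 200 BOLD timepoints. Its defaults are fixed design choices, not
dials to be tuned per run.

**Structure.** One backbone is drawn per cohort: a ring lattice of degree
`backbone_k = 24` rewired with probability 0.05 (a small-world graph, so
the topology stage sees Sigma > 1 as in cortex; density ≈ 0.27 is in the
range of pre-threshold AAL-90 count networks, and ≈ 23 profile entries per
node keep the Spearman coupling estimator usable). Edge weights are
lognormal (sdlog 0.6) with mean `count_scale = 30`; subject counts are
negative-binomial around the template weights (size 2.5), i.e.
overdispersed non-negative integers like streamline counts. VCI subjects
draw from a template whose edges incident to the 12 `deficit_nodes`
(precentral, posterior-cingulate, cuneus, occipital, postcentral, superior
parietal pairs) are scaled by 0.7, planting the structural-topology
deficit.

**Function.** Subject BOLD is multivariate normal with covariance
`Σ = W∘S + (1−W)∘R`: `S` is the subject's own count matrix,
square-root-compressed and scaled to peak off-diagonal amplitude 0.4 with
unit diagonal; `R` is a subject-specific random correlation matrix (a
well-conditioned Wishart-type draw) representing decoupled functional
organization; `W_ij = max(m_i, m_j)` blends them through per-node mixing
weights `m`. Two aspects deserve justification. The square-root
compression is rank-preserving (Spearman coupling is unaffected in the
large-sample limit) but keeps one extreme count from squashing the rest of
a profile below the sampling noise of the empirical correlation; the 0.4
amplitude keeps the blend positive definite in practice, so the diagonal
ridge — escalated geometrically by factors of 2 until the smallest
eigenvalue exceeds 1e−6, and uniformly attenuating (never reordering)
correlations when applied — is a rarely-triggered safety net instead of a
systematic signal damper. The max-blend (rather than averaging the two
incident nodal weights) makes a node designated as coupled have its entire
profile track structure, so the per-node ground truth `m_i` is the
quantity the per-node estimator actually estimates; with averaging, a
boosted node's edges to baseline neighbors carry half the planted effect
and the nodal ground truth blurs into its neighborhood.

**Planted effects and cognition.** HC subjects have `m = coupling_base`
(0.35) everywhere; VCI subjects get `coupling_base + coupling_boost`
(default +0.30) on the 10 `boost_nodes` (insula, calcarine, lingual,
inferior-occipital, superior-temporal pairs — regions of the coupling
literature, chosen disjoint from the deficit nodes so the planted
structural deficit does not degrade the coupling signal it is meant to
accompany). Per-subject truncated Gaussian jitter (sd 0.04) creates
within-group coupling variation. AVLT and SDMT are linear in the mean
boost-node mixing weight with negative slope (−30 score units per unit
mixing, ≈ 9 points across the planted contrast, consistent with the
magnitude of case-control cognitive gaps in this population), plus small
age and education terms and Gaussian noise (sd 5); MMSE, AVLT_N5, BNT are
null scores, and STT_B is lognormal, deliberately non-normal so the
Shapiro–Wilk routing is exercised. Covariates: age ~ Normal(68, 6)
truncated to [50, 75], education ~ rounded Normal(10.5, 2.5), sex ~
Bernoulli(0.44) male — matching typical demographics of such cohorts.

**Determinism.** One master seed drives everything through a hash-based
substream scheme (stage key × subject index), so regenerating a cohort —
or re-running the whole pipeline — is byte-identical, which the tests
assert via file hashes.

**What the synthetic validation shows, and what it does not.** Passing
tests establish that the estimators recover *this* generative structure:
rank-coupled covariances, exchangeable Gaussian noise, effects constant
within group. Real BOLD has autocorrelation, motion and physiological
artifacts, non-Gaussian tails; real tractography has distance- and
curvature-dependent biases; real effects are heterogeneous. Recovery rates
on synthetic cohorts are therefore upper bounds on what identical settings
would achieve on real data, and the generator makes no claim of
reproducing any published effect magnitude — the planted sizes are chosen
to be realistic and detectable at the study's sample size, since
quantitative coupling effect sizes are generally not published.

## Numerical and design choices

- Matrices are symmetrized by averaging only when asymmetry ≤ 1e−10;
  larger asymmetry errors (count matrices are symmetric by construction,
  so asymmetry means corrupt input). Non-zero diagonals are zeroed with a
  warning.
- Metric formula conventions follow the standard binary-graph toolbox
  definitions, since the named metric battery matches them exactly.
- The degree-preservation of every null network is asserted exactly at
  generation time.
- Sex is coded as one 0/1 indicator; covariates are not standardized (all
  tests used are invariant to affine rescaling of covariates).
- Problem sizes in the test and acceptance suites (e.g. 30 + 30 subjects
  at 500 timepoints for recovery, 200 simulations × 500 permutations for
  the FWER measurement, reduced sparsity grids for end-to-end runs) are
  chosen as the smallest designs at which the measured properties are
  statistically stable; single planted cohorts have noticeably variable
  detection counts, so recovery criteria average a few seeded cohorts.

## Known limitations

- Only binary-graph topology is implemented (no weighted metrics,
  modularity, or rich-club analysis), matching the analysis design this
  package reproduces.
- The permutation FWE machinery covers two-group contrasts; the
  coupling-cognition correlation family uses Bonferroni.
- The generator's BOLD model is a covariance mixture, not a biophysical
  model; it provides exactly the rank-association structure the coupling
  statistic assumes, and nothing more.
- Alpha defaults to 0.05 per analysis; reproducing multi-level reporting
  conventions (e.g. stricter figure-level thresholds) is left to the user
  via `sfc_config(alpha = ...)`.
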