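---
title: "Composite learning measures for the Morris water maze: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite learning measures for the Morris water maze: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The Morris water maze (MWM) measures spatial learning: a mouse swims in an
opaque circular pool and must find a hidden escape platform using distal
cues. No single tracked variable captures "learning". Escape latency
confounds speed and path choice; time in the periphery confounds anxiety
(thigmotaxis) and search strategy. `mwmpca` implements a multivariate
analysis for factorial MWM designs — here a 2-genotype (euploid vs
trisomic) x 4-treatment (untreated, environmental enrichment, EGCG,
combined) cohort — built around a supervised principal component analysis
of group-by-session medians of seven behavioral variables, with
permutation-based inference and censored mixed models for the
single-variable analyses.

# Behavioral variables

From each trial's 10 Hz position record the package computes:

* **latency** (s): time of first platform contact, right-censored at the
  60 s cutoff;
* **distance** (cm): summed Euclidean steps; **speed** = distance/latency;
* **Gallagher proximity index** (cm): distances to the goal averaged in
  1-second blocks, then averaged over blocks. A trailing partial block is
  averaged over its own sample count rather than dropped, so short trials
  are reproducible;
* **Whishaw corridor index** (%): share of path length inside the straight
  corridor joining release point and goal. A sub-step counts as inside
  only when both endpoints are in the corridor capsule. The one
  convention-free parameter is the corridor half-width; the default is the platform
  radius + 6 cm (12 cm), configurable in `mwm_geometry()`;
* **thigmotaxis** (%): samples in the outer peripheral band. "Periphery"
  has no published definition; the default band is the outer 20% of the
  pool radius (17 cm of 85 cm), explicit and configurable;
* **target-quadrant occupancy** (%): quadrant shares always sum to 100;
  points exactly on an axis are assigned to the counterclockwise-first
  quadrant so the tie-break is deterministic.

Two further protocol rules: mice that fail to reach the *visible* platform
in under 30 s in the cued session are excluded from all analyses (the
boundary is read strictly: exclusion at latency >= 30.0 s), and the
reversal platform is the point reflection of the training platform
through the pool center (the natural reading of "opposite quadrant").
The platform center is placed 22 cm from the wall; whether the protocol
distance refers to the platform center or edge is ambiguous and the
center reading is used.

# Supervised PCA on group medians

The ordination is fitted not to individuals but to the **group-by-session
median table**: with 8 groups and 5 acquisition sessions, 40 rows of the 7
variables (medians, not means, for robustness to outlying subjects; the
even-count median is the midpoint of the central order statistics).
Columns are Z-scored with the **population (divide-by-N) variance**
convention. This choice is deliberate: it makes the sum of eigenvalues
equal the number of variables and the between-group variance of the
scores exactly 1, so the variance decomposition below has a clean
normalization. The sample (N-1) convention would make the between-group
variance (N-1)/N and is rejected.

Row scores are kept in distance-preserving (principal) coordinates:
pairwise Euclidean distances between full-rank scores equal those between
Z-scored rows to machine precision, and scores times transposed loadings
reconstructs the Z-scored table. Axis-standardized coordinates would also
normalize the between-group variance but change the between-session
split; the distance-preserving choice is used consistently and stated
here because the alternative is defensible. Percent variance per
component is computed at full rank, with no component truncation.

Because eigenvector signs are arbitrary, component orientation is fixed
deterministically: PC1 is oriented so the Gallagher-index loading is
negative (high PC1 = search close to the target = better learning), PC2
so the speed loading is positive; higher components orient their
largest-magnitude loading positive. Variable contributions are
100 x squared loading, which sums to 100 per component.

Individual subject-sessions enter as **supplementary points**: centered
and scaled by the *median table's* constants and mapped through its
loadings, so they never influence the axes. Projection is affine, and a
median row projects exactly onto its own score. The reversal sessions are
analyzed by the same machinery on their own 8 x 3 median table.

# Variance decomposition

All variances use `V = 1/(v N) * sum(d_i^2)` with `v = 7` variables and
`d_i` the distance of object `i` from the origin of the ordination:

* between-group `V_B`: objects are the 40 median rows; population scaling
  makes `V_B = 1` identically;
* total `V_T`: objects are the supplementary individuals (86 subjects x 5
  sessions = 430 points);
* between-session `V_BS`: objects are the per-session averages of the
  group score vectors (`d_s^2 = sum_p (mean_j x_{s,p,j})^2`, the group
  average generalized from 1/8 to 1/G);
* within-session `V_WS = V_B - V_BS`, the average separation of groups
  within a session.

Percentages are taken against `V_T`. The identity `V_BS + V_WS = V_B`
holds exactly on every data set and every permutation draw, and the whole
decomposition equals a PCA-free computation on the Z-scored tables (the
scores are a rotation), which the tests exploit as an independent oracle.

# Permutation inference

Group separation is tested by re-deriving the entire chain — median
table, PCA, supplementary projection, decomposition — under random
reassignment of subjects to groups of the original sizes. Each subject
keeps its full session profile (session-linked relabeling). The
separation statistic is `V_WS` as a percentage of `V_T`; learning
differences at a chosen session use Welch two-sample t statistics on the
individual PC1 coordinates for every group pair, all pairs sharing one
permutation stream. The default is B = 10,000 draws. P-values use the
add-one convention `(1 + #{null >= obs}) / (1 + B)`, never exactly zero;
pairwise tests are two-sided on |t|, and a familywise-adjusted p against
the max-|t| null is reported alongside the raw per-pair values because
the multiplicity treatment of permutation p-values is otherwise open.
Welch rather than pooled t is used since group sizes differ (8-14).

Because the between-group variance is renormalized to 1 in every draw,
the separation statistic is scale-free: it detects the *proportion* of
group structure relative to individual spread, not its absolute size.
Saturated significance (`p = 1/(B+1)`) therefore requires separation on
several variables and more than two groups; with two equal groups the
relabeled halves overlap hypergeometrically and the null stays broad.

# Censored mixed models

Learning progression per variable is modeled as
`response ~ session * group` with a Gaussian random intercept per subject
(within-subject correlation across the repeated sessions) and `session`
numeric, so `session:group` terms estimate slope differences against the
reference group (both untreated genotypes are used as references).
Latency is modeled as `log(latency)` right-censored at `log(60)`: trials
stopped at the cutoff contribute the upper-tail probability to the
likelihood. Other metrics are fitted untransformed by the same code with
an infinite threshold, to which the censored likelihood reduces exactly.

The subject intercept is integrated by Gauss-Hermite quadrature
(default order 16, configurable). The quadrature is *adaptive*: nodes are
recentered at each subject's conditional posterior mode — refined by four
Newton steps whose censored terms enter through the normal hazard — and
rescaled by the local curvature. This makes the rule exact for the
uncensored Gaussian case at any order and accurate to ~1e-7 in the
coefficients between orders 16 and 64 under ~40% censoring. The
optimizer is BFGS from an OLS-based start plus deterministically jittered
restarts (3 by default); Wald z tests use the inverse observed
information, and the normal approximation is used for the reference
distribution since group counts enter through 400+ observations.
Slope-contrast p-values are Benjamini-Hochberg adjusted
(`stats::p.adjust`). Overall group effects per metric use
repeated-measures ANOVA (`aov` with a subject error stratum, giving
F(7, 78) for 86 subjects in 8 groups) and Tukey HSD on subject means,
BH-corrected.

# The synthetic cohort

The study's mouse data are not public, so a generator stands in for them
and is itself first-class, tested code. Two routes exist:

* `simulate_cohort()` draws full 10 Hz trajectories from a
  heading-persistence random walk: at each 0.1 s step the heading mixes
  the bearing to the goal (weight = session-dependent goal bias), a
  wall-following direction (weight = thigmotaxis), and the previous
  heading, plus Gaussian heading noise; steps are clamped radially into
  the pool. Crucially, the goal-directed component aims at a *remembered*
  location drawn around the true platform with SD
  `belief_error_scale x (1 - goal_bias) x pool_radius` and redrawn when
  reached or every few seconds — without this, any constant drift toward
  the platform produces unrealistically short escape latencies even for
  untrained animals. Probe trials keep the attraction but remove the
  contact; cued and pretraining trials have zero belief error (the
  platform is visible).
* `simulate_metric_table()` skips trajectories and draws subject-session
  metric records from multivariate normals around group-session mean
  curves, truncated to valid ranges, with latencies at the cutoff flagged
  censored. Everything downstream of the session-metric stage is a pure
  function of this table, so the fast route exercises the statistical
  machinery exactly.

Default group parameters encode the study's qualitative structure: the
published group sizes (10, 11, 14, 11, 11, 9, 12, 8), wild-type groups
learning fastest, combined enrichment + EGCG and enrichment alone
partially restoring learning in trisomic animals, untreated and EGCG-only
trisomic groups learning little, elevated thigmotactic bias in trisomic
groups, and an EGCG-linked reduction of baseline swim speed. Numerical
values (e.g. goal bias 0.30 rising by 0.13/session for wild types vs 0.18
rising by 0.02 for untreated trisomics; belief error scale 0.6) were
chosen once so that simulated latency curves, censoring rates (~10% in
untreated trisomics), thigmotaxis levels and the PCA structure (a
dominant learning PC1 with six similar contributions, a speed-dominated
PC2) fall in realistic ranges.

What the generator does *not* emulate: floating/immobility episodes,
inter-trial carry-over, platform climbing failures, tracking dropouts,
and any secular drift across days. Passing tests therefore demonstrate
the correctness and calibration of the *analysis* on data with the
assumed structure, not the behavioral fidelity of the simulator itself —
numbers reported for the real cohort this design mirrors (such as the
split of explained variance between the first two components or specific
slope estimates) are properties of those mice and are deliberately not
targets.

# Random numbers and determinism

One master seed determines everything. Each subject draws from a
substream seeded by a hash of (master seed, group index, subject index),
so enlarging one group leaves every other subject's data bit-identical.
Permutation tests and the pipeline accept explicit seeds; `(config,
seed)` fully determines all numeric outputs.

# Numerical choices and degenerate inputs

* Zero-variance metric columns abort the PCA with advice to drop or
  jitter; rank-deficient but nonzero tables are handled by the SVD.
* Empty (group, session) cells abort the median table with the cell named.
* The censored likelihood clamps hazard arguments at z = 35 to avoid
  overflow where the tail probability underflows; all-censored data are
  rejected as non-identifiable.
* KDE grids (`density_grid()`, matching the ggplot2 `stat_density_2d`
  parameters n = 100, h = 5, 6 bins used for the published density plots)
  extend three bandwidths beyond the data so the trapezoidal integral is
  ~1; the 6 contour levels are equally spaced in (0, max density).
* Problem sizes used by the test suite: the calibration of the
  separation test uses 200 null cohorts of 4 groups x 8 subjects at
  B = 500; censored-model recovery uses 200 data sets of 50 subjects x 5
  sessions with roughly a third of records censored. These sizes give
  Monte-Carlo errors small enough for 3-SE checks while keeping the suite
  quick to run.

# Known limitations

* The movement model is a stylized random walk; its parameters map onto
  the seven metrics' dynamic ranges but are not fitted to animal data.
* The censored model supports a random intercept only — no random slopes
  — matching the analysis it reimplements.
* Supplementary individuals use the median-table scaling; individuals far
  outside the group envelope are extrapolated linearly.
* The separation statistic's scale-freeness (above) means power comes
  from proportion, not magnitude, of separation; with very few groups it
  is conservative.
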