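---
title: "Latent-variable clustering and subject reclassification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable clustering and subject reclassification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clvclass)
```

## The problem

Clinical two-class labels (e.g. an ADHD diagnosis against typically
developing controls, assigned by DSM criteria) are categorical summaries of a
continuous, multidimensional phenotype. A natural question is how well a
purely data-driven partition of the same subjects — built from
psychophysiological measurements alone — agrees with the clinical one. The
setting is hostile to classical multivariate statistics: a few dozen subjects
against several hundred variables (ERP window measures over many channels and
conditions, task behavior, psychometric scores).

`clvclass` implements a complete pipeline for this question:

1. **Feature extraction** — ANT (Attention Network Test) behavioral scoring
   and ERP window measures into a subjects × variables table (VOI table);
2. **CLV** — clustering of variables around latent components, reducing
   hundreds of correlated variables to a handful of latent variables (LVs);
3. **Reclassification** — two-cluster k-means on the subjects' latent
   scores, aligned to the clinical classes;
4. **Concordance** — agreement, Cohen's kappa, sensitivity, specificity and
   chi-square against the reference labels;
5. **Validation** — stratified repeated train/test cross-validation with
   per-repetition selection of the number of LVs, and a scan over candidate
   channel sets;
6. **Synthetic data** — a seeded generator with planted latent group
   structure, so all of the above is testable without any recordings.

## Clustering of variables around latent components

Variables are standardized (sample SD, $n-1$). A partition of the $p$
variables into $K$ clusters $G_1,\dots,G_K$ is scored by the criterion

$$T \;=\; \sum_{k=1}^{K} \lambda_1\!\left(R_{G_k}\right),$$

the sum over clusters of the leading eigenvalue of the cluster's correlation
matrix. Equivalently, each cluster is summarized by its first standardized
principal component $c_k$ (the cluster's *latent variable*, unit variance)
and $T = \sum_k \sum_{j \in G_k} \mathrm{corr}(x_j, c_k)^2$: the criterion is
the total squared variable–latent correlation. $T$ ranges between
$\lambda_1(R)$ at $K=1$ and $p$ when every cluster is internally perfectly
correlated (a singleton cluster contributes exactly 1). Because squared
correlation is the similarity, the clustering is *directional*: flipping a
variable's sign changes neither memberships nor $T$, and loadings carry a
reported sign instead.

Fitting proceeds in the two classical stages:

* **Hierarchy** (`clv_hierarchy()`): agglomerative merging from singletons;
  at each step the pair $A, B$ minimizing the criterion decrease
  $\Delta = t(A) + t(B) - t(A \cup B) \ge 0$ is merged. Since variables are
  standardized, each cluster's Gram matrix ($n \times n$) is additive under
  merging, so a candidate evaluation is one small symmetric eigenvalue
  problem regardless of cluster size; with $n \approx 39$ subjects the whole
  hierarchy over $p = 130$ variables takes a couple of seconds. Ties are
  broken toward the lowest cluster indices, making runs reproducible.
* **Consolidation** (`clv_consolidate()`): given the hierarchy's partition at
  the chosen $K$, alternate (a) recomputing each cluster's latent and (b)
  reassigning each variable to the latent it squares-correlates with best
  (ties to the lowest cluster index). $T$ is non-decreasing across sweeps —
  the implementation asserts this every iteration — and iteration stops on a
  stable assignment (default cap: 100 sweeps). An emptied cluster is
  re-seeded with the currently worst-fitted variable.

All leading-eigenvalue work uses whichever of the $p_k \times p_k$ or
$n \times n$ cross-product is smaller; the two give identical results (the
tests check agreement with a direct decomposition to $10^{-8}$). The latent's
sign is oriented so the loading sum is non-negative. Within a cluster the
normalized loadings have squares summing to one; those squares are reported
as per-variable *importance*.

The criterion is deliberately not scaled by $n$ or $p$: only comparisons
across partitions of the same data feed the pipeline, so any fixed scaling
cancels.

**Projection.** A fitted model stores the training means, SDs and projection
weights $w_j = v_j/\sqrt{\lambda}$ per cluster. New subjects are standardized
with the *training* parameters and multiplied through; projecting the
training rows reproduces the training scores exactly. On genuinely new
subjects the projected score variance is close to, but systematically below,
one when $p \gg n$ — the familiar eigenvector-overfitting shrinkage — which
is why test subjects are classified by distance to training centroids rather
than by any variance-sensitive rule.

## Reclassification and concordance

`kmeans_two()` partitions subjects into two clusters from their latent
scores (50 seeded restarts by default; on the one-dimensional score vectors
that dominate this pipeline the restarts make the search effectively
exhaustive over threshold splits, and the tests verify exact agreement with
enumeration). Cluster labels are arbitrary, so `align_labels()` picks
whichever of the two cluster-to-class mappings maximizes agreement, breaking
exact ties toward mapping cluster 1 to the control class.

`concordance()` reports the 2×2 cross-table, agreement $p_o$, Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal products, sensitivity
(reference cases found in the case cluster), specificity (controls in the
control cluster), and the Pearson chi-square on the table (1 d.f.), with the
Yates-corrected value alongside. For the canonical published cross-table of
this design (20/19 subjects, 5 + 2 crossovers) the standard Cohen formula
gives $\kappa = 490/763 \approx 0.642$; published summaries of that table
sometimes quote a higher kappa and a smaller chi-square that no standard 2×2
formula reproduces from the printed counts, so this package reports the
standard values and treats the others as non-reproducible.

## Cross-validation and channel-set search

Each repetition draws a stratified split (default 20% held out; per-class
counts by floor-plus-largest-remainder, so 39 subjects at 20% give 31 train /
8 test with 4 + 4 held out), fits the CLV hierarchy once on the training
side, consolidates at each candidate $K$ (default 1–6), reclassifies the
training subjects at each $K$ and keeps the $K$ with the best training
agreement (smallest $K$ on ties — parsimony). Held-out subjects are
projected with the stored training standardization and weights and assigned
to the nearest training k-means centroid (Euclidean distance in latent
space) — the simplest prediction rule consistent with treating them as
independent observations. Nothing fitted ever sees a held-out row; a
dedicated test perturbs held-out rows and checks the training fit is
bit-identical. The master seed expands into per-repetition substreams.

`channel_set_scan()` repeats this over a configurable list of channel sets
(the default configuration ships 40 sets over the 10–20 montage — midline,
frontal, right/left, with and without the C3−C4 difference lead — plus
behavioral+WISC composites) on the peak-amplitude and peak-latency variables
only, and ranks sets by mean test agreement. Per-repetition $K$ selection
uses the consolidated partitions, since consolidation can only improve the
criterion. Exhaustive subset search is out of scope by design; the fixed
candidate list mirrors how such scans are reported.

**A calibration caveat worth knowing.** Under the null (no group structure),
mean *test* agreement sits visibly *below* 50%. The alignment is chosen to
maximize training agreement on a fixed finite sample; with the whole-sample
agreement pinned near 50%, inflating the training side by selection
necessarily deflates the complementary held-out side
($a_{test} = (n\,a_0 - n_{tr}\,a_{tr})/n_{te}$, and the 80/20 split
multiplies the deficit by four). The null test therefore compares the
observed mean against a permutation band computed from the same repetitions
(labels permuted, per-repetition cluster assignments kept, alignment redone
on each training side) rather than against a nominal 50% band.

## ERP features

Waveforms are epoch averages, time in ms with 0 at target onset (the cue
precedes the target by 1650 ms). Three windows are measured per channel —
cue-related potential (CUE, default −1400…−1100 ms, positive), the
contingent voltage variation between cue and target (CVV, −600…0 ms,
negative), and the target-related potential (TGT, 200…600 ms, positive).
Windows are closed intervals snapped to the sample grid and are configurable
per channel, since laboratories fix them from their own grand averages. In
each window three measures are taken: signed peak amplitude at the extremum
matching the window's polarity, its latency (plateau ties resolve to the
earliest sample), and the mean amplitude.

The default measurement schedule pairs windows with conditions where they
are defined: CUE in the two cued conditions plus the overall average (3),
CVV in every cue condition plus overall (4), TGT in every cue and congruency
condition plus overall (6) — 13 combinations, hence 39 variables per channel
with three measures. Over 18 scalp channels plus the C3−C4 difference lead
(the raw C3 and C4 signals are excluded because C3+C4 serves as the
recording reference) and with 29 behavioral plus 4 WISC columns this yields
the canonical 774-column VOI table. Mean amplitude inside a fixed window is
near-collinear with peak amplitude (the shipped diagnostic,
`diagnose_mean_amplitude()`, shows $r > 0.95$ on proportional bumps), so
`drop_redundant()` removes it, leaving 26 variables per channel — 130 for a
5-channel set, 78 for 3 channels.

## Behavioral features

From the trial table, `compute_behavior()` builds a 29-column schema:
accuracy, mean RT and IVRT (the within-subject SD of RT, correct trials
only, $n-1$) for the overall task and the five cue/congruency marginals
(18); the attention-network contrasts alerting = RT(no) − RT(neutral),
orienting = RT(neutral) − RT(spatial), conflict = RT(incongruent) −
RT(congruent) (3); mean RT of correct and of incorrect responses (2);
first- and last-block RT and IVRT (4); and the two learning-rate ratios
first/last for RT and IVRT (2). The exact 29-variable composition of such
schemas varies between reports; this one is the package default and each
element is individually computable, so a deposited layout can be matched.
The learning-rate orientation is switchable (`learning_direction`) because
both first/last and last/first conventions appear in circulation.

Subject exclusion (`qc_filter()`) removes subjects with accuracy below 70%
and, in the same single pass, subjects whose speed–accuracy tradeoff
AC × RT falls more than 2 sample SDs below the sample mean of that product.
The rule is deliberately not iterated on the survivors: re-running it would
keep trimming the tail of a shrinking sample.

## The synthetic generator

`sim_config()`/`simulate_study()` emulate the study design: two groups
(defaults 20 controls, 19 cases), 8 blocks × 24 trials of cued two-choice
behavior, and epoch-averaged waveforms per subject × channel × condition
built as one Gaussian bump per window plus white noise. What it emulates —
and what it does not — determines what passing tests can claim:

* **Group structure.** Each subject carries shared factor scores
  $F_{ik} \sim N(0,1)$. A (channel, window) amplitude mapped to factor $k$
  gets the unit-SD deviate
  $\sqrt{\rho}\,F_{ik} + \sqrt{1-\rho}\,u + d_k\,[\text{case}]$
  (`factor_cor` $\rho$, default 0.3), so mapped variables are
  block-correlated and the case-control amplitude shift is exactly
  $d_k \times$ `amp_sd`. The per-variable parameterization matters: had the
  shift been placed on the shared factor score itself, no pipeline could
  exceed $\Phi(d/2)$ recovery accuracy (≈84% at $d=2$), whereas with
  idiosyncratic components averaging out across a channel set the planted
  labels are recoverable at the rates the tests assert (≈94% at $d=2$ over
  the 130-variable set).
* **Behavior.** Trial RTs are shifted lognormal (positive, right-skewed — a
  standard minimal RT model; the design gives no distributional commitment)
  with additive cue, congruency and practice offsets, a subject-level mean
  tied to the behavior factor, and a case-group mean shift and scale
  inflation; accuracy is Bernoulli per group, lower on incongruent trials.
* **Determinism.** One master seed expands to per-subject substreams keyed
  by group and within-group index, so enlarging either group leaves every
  existing subject's data bit-identical, and identical configurations are
  bit-reproducible.
* **Defaults as study conditions.** 20/19 subjects, the 20-electrode 10–20
  montage, six condition labels (overall + three cue + two congruency),
  1000 Hz sampling over −1600…800 ms, and a planted effect of $d = 1.5$ on
  factor 1 (late target/cue amplitudes over Fz, Pz, F4, F8, C3 and the
  behavioral/WISC variables) with a null second factor over frontal CVV
  amplitudes. Published work in this design does not report per-window
  effect sizes, so $d$ defaults are stated placeholders chosen to land the
  final-model agreement in the realistic 80–95% range, and every
  recovery-style test states its own $d$.
* **Not emulated:** continuous EEG, blink/artifact structure and their
  correction, realistic ERP morphology beyond (peak, latency, mean) within
  the analysis windows, WISC item-level responses, or condition-specific
  ERP effects. Tests passing on this generator validate the *pipeline
  arithmetic and its statistical behavior*, not claims about real
  recordings.

Problem sizes in the test-suite and in `scripts/acceptance.R` use a 100 Hz
synthetic sampling rate and 50-repetition cross-validation runs — the window
measures of smooth Gaussian bumps are sampling-rate-stable (a test refines
the grid and checks convergence), and the CV aggregates at 50 repetitions
are within Monte-Carlo noise of the 100-repetition defaults.

## Numerical and design choices

* Zero-variance columns (e.g. a noiseless latency) cannot be standardized
  and are dropped with a warning before fitting.
* Largest-remainder rounding in the stratified split reproduces the
  canonical 31/8 for 39 subjects; `round(n * fraction)` fixes the total.
* k-means determinism: seeded restarts plus canonical cluster numbering
  (cluster 1 contains the first subject).
* Degenerate inputs error early and by name: unknown channels or
  conditions, windows outside the epoch span, empty windows after
  discretization, all-identical subjects in k-means, missing model variables
  at projection.
* The directional (squared-correlation) CLV variant is the right one here
  because ERP measures carry arbitrary polarity (positive and negative
  loadings are reported with signs); the variant with external data blocks
  and fuzzy memberships is out of scope.
* This is an analysis package driven from R: the exported functions,
  `scripts/acceptance.R` and this vignette are the interface, with readers
  and writers (`read_voi_csv()` with column mapping, trial/epoch CSVs,
  model bundles, YAML run configuration via `validate_run_config()`) for
  every on-disk artifact.

## Known limitations

* With $p \gg n$, training agreement is optimistically biased (the paper's
  own motivation for cross-validating); even the CV estimate carries the
  channel-set *selection* optimism when the scan winner is reported, and no
  multiplicity correction across the 40 sets is applied (by design, matching
  the original analysis).
* The chi-square on a 2×2 table from clustered predictions does not have a
  clean null interpretation (the prediction is not an independent rater); it
  is reported for completeness, not inference.
* CLV consolidation is a local optimizer; the tests verify global optimality
  only where enumeration is feasible ($p \le 8$) and on well-separated
  planted blocks.
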