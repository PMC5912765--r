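---
title: "Methods and design notes for domssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for domssr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domssr)
```

## The data model

`domssr` analyses dominantly scored SSR (microsatellite) fingerprints.
In high-ploidy crops such as sugarcane, allele dosage at a
microsatellite locus cannot be read from band intensity, so each
amplified fragment size is scored as a binary marker: present (1),
absent (0), or missing (NA). The container is an `ssr_matrix` —
individuals in rows, bands in columns, each band belonging to exactly
one primer pair and labelled `PRIMER.SIZE` (size in bp, zero-padded to
four digits, e.g. `SCB436.0186`). Every retained band must carry at
least one present call; all-absent columns are rejected at load rather
than dropped silently, because the allele accounting assumes every
scored band occurs somewhere in the panel. A companion
`ssr_partition` assigns every individual to exactly one named group
(e.g. commercial cultivars vs basic-germplasm species pools), with
group order fixed by first appearance.

Two caveats follow from dominant scoring and are assumed throughout:
band absence is uninformative about dosage, and bands are treated as
independent markers (no within-primer linkage model).

## Marker informativeness indices

For each primer, "allele frequencies" are band occurrences over total
band occurrences at that primer, so they sum to one; this is the
convention used by the downstream indices, not a per-individual
average.

* **PIC** (polymorphism information content), Botstein form:
  `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. The pair sum runs
  over strictly ordered pairs; a typeset-ambiguous double sum is
  sometimes printed in the literature, but only the `i<j` form keeps
  PIC in `[0, 1)` with `PIC = 0` exactly when one band carries all
  calls.
* **Multiplex ratio `n`**: mean number of bands amplified per
  individual at the primer. Individuals with any missing call at the
  primer are excluded from this mean (their band count is
  left-censored); missingness handling is otherwise band-wise.
* **`beta`**: fraction of the primer's bands that are polymorphic,
  with "polymorphic" meaning a carrier proportion strictly between 0
  and 1 — no 95% criterion is applied.
* **Effective multiplex ratio `E = n * beta`** and **marker index
  `MI = PIC * E`**. These identities hold exactly on the stored,
  unrounded values; reports round indices to 3 decimals and
  percentages to 1, so a rounded table may look inconsistent by one
  unit in the last digit.
* **Resolving power `Rp = sum_b Ib`**, `Ib = 1 - 2|0.5 - M_b|`, where
  `M_b` is the band's carrier proportion over non-missing calls. `Ib`
  peaks at bands carried by half the panel.
* **Profile discrimination**: the number of distinct presence/absence
  fingerprints a primer produces among individuals with complete data
  there. The percentage deliberately uses the *full* individual count
  as denominator, even when individuals were excluded for missing
  data — this is the convention that makes a primer resolving 134
  profiles in a 137-individual panel report 97.8%.
* **Gene diversity** within a group: `D_i = 1 - sum_j p_ij^2` per
  primer with within-group frequencies, averaged over primers with
  data. `k` equifrequent bands give `D = 1 - 1/k`.

## Allele accounting

Group presence is a set property: a band is present in a group if at
least one member carries it; a single carrier suffices for
exclusivity ("putative private allele"). `exclusive_alleles` reports
per-group private bands as percentages of the total distinct band
count. `absence_report` lists the bands a focal group lacks and
attributes each to the groups carrying it. `trace_exclusive` answers
a subtler question — which target-group individuals carry bands
private to a source group — and therefore judges exclusivity among
the *non-target* groups only: a band private to the source within the
germplasm may legitimately occur in the (hybrid-derived) target; that
co-occurrence is the tracing signal, not a violation.

## Dissimilarity, trees, ordination

Pairwise dissimilarity is the Jaccard complement `1 - a/(a+b+c)`
(shared presences `a`, one-sided presences `b`, `c`). Joint absences
carry no signal — the right choice for dominant markers, where 0 may
mean anything from a true null allele to amplification failure.
Missing cells are handled by pairwise deletion; the per-pair count of
compared bands is kept as a diagnostic, and a pair with no shared or
differing presences is an error rather than a silent zero. On
complete data the coefficient is a metric (the triangle inequality is
property-tested), and group summaries (within/between means,
accession-vs-group means, extreme pairs with lexicographic
tie-breaking) are plain averages over the relevant pair sets.

Neighbor-joining is the classical rate-corrected agglomeration
(Studier–Keppler `Q` criterion, standard limb-length formulas),
implemented in-package and exact on additive matrices; `ape` supplies
the tree container and Newick serialization only. Ties in `Q` are
broken toward the lexicographically smallest label pair, ranking
internal nodes by their smallest descendant leaf, so output is
deterministic. Negative branch lengths — possible on non-additive
input — are retained with a warning because clamping would silently
distort path distances. An "unweighted" NJ variant used by some
desktop software differs only in pair-joining weights and is not
emulated. Bootstrap support resamples *band columns* with
replacement (the standard marker-bootstrap for dominant data, not an
individual bootstrap), rebuilds the tree per replicate, and reports
the percentage of replicates containing each leaf bipartition;
replicates with an undefined pair are skipped and counted, with more
than 10% skipped treated as failure.

PCoA is classical metric scaling: Gower double-centering of
`-d^2/2`, eigendecomposition, coordinates scaled by the square root
of positive eigenvalues. Jaccard matrices are generally
non-Euclidean, so negative eigenvalues are expected; they are counted
and reported, and percent-explained is normalized over the *positive*
eigenvalues only. No Cailliez/Lingoes correction is applied by
default — percent-explained under a correction would not be
comparable across panels — but the negative-eigenvalue count makes
the distortion visible.

## AMOVA

The one-level analysis of molecular variance uses squared Euclidean
distance on 0/1 profiles, i.e. the band mismatch count — the standard
treatment of binary (RFLP-like) dominant data. With missing cells the
mismatch count `m` over `c` compared bands is rescaled to `L·m/c`
(`L` = total bands), keeping distances comparable across pairs; a
strict complete-band mode is available by filtering columns up front.
Sums of squares follow the classical identities (total and
within-group sums of pairwise squared distances divided by group
sizes), variance components use the weighted coefficient
`n0 = (N - sum(n_g^2)/N)/(G-1)`, and
`Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`, so the
among-group percentage of variation equals `100 * Phi_ST` by
construction. A negative among-group component is reported as-is
(slightly negative `Phi` values are meaningful evidence of absence of
structure, and truncation would bias permutation nulls). Significance
permutes individual group labels with sizes fixed, default 1,023
permutations, with the `+1` correction
`p = (1 + #{Phi_perm >= Phi_obs})/(P + 1)`, so the smallest
achievable p is `1/(P+1)`. The implementation is verified against an
independent brute-force oracle on small instances, and its
permutation p-values are checked for uniformity under a simulated
null.

## Marker sufficiency

How many markers suffice for stable dissimilarity estimates? For each
marker count `m` on a grid (default 3, 6, 9, … up to the panel size),
`B` bootstrap resamples of `m` band columns are drawn (with
replacement; a subsampling mode exists), the full Jaccard matrix is
computed per resample, and each individual pair gets
`CV_ij = 100·sd/mean` over its `B` sampled dissimilarities. The per-`m`
summary is the **median** over pairs — the median is deliberately
preferred to the mean because pairs of near-identical individuals
produce huge or undefined CVs; pairs with zero mean dissimilarity are
excluded outright. A per-resample pooled-CV variant is available
behind a flag for comparison.

The decay is summarized by fitting `CV(m) = a·m^b` by ordinary least
squares on the log–log scale. A power law is the default because
sampling theory for a mean of `m` resampled markers gives
`CV ∝ m^(-1/2)`; the loosely specified "exponential function" of
common practice has no canonical form, so `a·e^{bm}+c` is provided as
an explicit alternative rather than the default. The minimum marker
count for a CV threshold (default 10%, the conventional
acceptability cutoff) is the closed-form inversion
`m* = ceiling((threshold/a)^(1/b))`.

On tiny or highly structured panels many pairs are constant across
resamples (disjoint individuals always sit at `d = 1`), the median CV
can be 0, and the fit is then impossible; the pipeline still reports
the raw curve and flags the fit as unavailable.

## Evanno delta-K

Given repeated clustering-run log-likelihoods `lnP` at consecutive
`K`, `delta_k` computes `L'(K)` and `|L''(K)|` from the per-`K`
*means* (the original definition; per-run differencing inflates the
noise) and `deltaK = |L''(K)|/sd(lnP at K)` with the sample `(n-1)`
standard deviation, which is what the widely used summarization tools
report. `deltaK` exists only for interior `K`; zero run-to-run spread
is flagged undefined rather than treated as infinite evidence. The
Bayesian clustering itself is out of scope — the module consumes a
run-likelihood table from any source.

## The synthetic-data generator

`simulate_panel` exists so every downstream stage can be tested with
known truth. Its defaults state a fixed world resembling a large
sugarcane germplasm panel and are not tuning knobs: three core groups
of 81, 19 and 26 accessions plus 11 admixed "HYB" individuals; 12
primers with 10–43 bands each (≈ 300 bands); baseline band
frequencies from `Beta(1.2, 3)` (right-skewed — most SSR bands are
uncommon); `divergence = 0.35`, giving moderate group differentiation
of the order seen in crop-vs-wild panels (`Phi_ST` in the 0.1–0.25
range); 20% private bands; 1% missing cells. Where no value was
externally dictated, the choice was made once on these grounds and
not revisited.

The model: band `b` in group `g` is present with latent probability
`f_gb = (1-d)·p_b + d·t_gb`, a mixture of a shared baseline and an
independent per-group draw, so `d = 0` gives one panmictic pool and
`d = 1` fully independent groups. Private bands get `f = 0` outside a
single owner group and a `Uniform(0.3, 0.9)` frequency inside it (low
enough to be realistic, high enough that a moderate group almost
surely carries the band — which is what makes exact truth-recovery
tests meaningful). Frequencies in `(0, 0.02)` and `(0.98, 1)` are
nudged to the boundary to avoid accidental monomorphism, while exact
0/1 values are kept so fixed differences stay fixed; Beta shapes at
or below 0.01 are treated as the limiting point-mass mixture on
`{0, 1}`, making maximal-differentiation panels expressible. Hybrids
draw each band with probability `sum_g w_g f_gb` and are appended as
their own group, mimicking an "other species/exotic hybrids" pool.
Bands are generated independently — no linkage, no within-primer
dependence — and missingness is independent Bernoulli, so green tests
establish correctness of the *computations*, not robustness to
linked loci, structured dropout, or scoring error. Panels are fully
reproducible from the config seed; bands that end up all-absent are
dropped and recorded in the truth object.

`toy6()` ships a fixed 6-individual, 5-band worked example small
enough that every statistic in the test suite is hand-checkable.

## Numerical and interface choices

* Frequencies must sum to 1 within `1e-9` (contract-checked);
  distance symmetry and zero diagonals within `1e-12`.
* PIC uses the algebraic reduction
  `sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4` — exact and O(n).
* NJ tie-breaks and extreme-pair tie-breaks are lexicographic on
  sorted label pairs, making every output order-stable.
* The pipeline derives fixed per-stage seeds from one global seed
  (`seed+1` AMOVA, `seed+2` tree, `seed+3` sufficiency) so stages can
  be rerun independently yet reproducibly; the JSON manifest records
  everything needed for replay.
* Missing tokens: `"NA"` by default, `"?"` always accepted.
* Distance output formats: labeled square CSV and square PHYLIP.

## Known limitations

* No linkage or dosage model; dominant 0/1 scoring is taken at face
  value.
* AMOVA is one-level (no region/hierarchy) and assumes the
  squared-mismatch distance.
* PCoA percent-explained depends on the positive-part convention;
  with strongly non-Euclidean input the first axes can look inflated
  relative to corrected analyses.
* The sufficiency fit summarizes a median curve with a two-parameter
  law; confidence bands on `m*` are not provided.
* Bootstrap supports are bipartition frequencies, not posterior
  probabilities, and depend on the marker-resampling scheme.
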