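---
title: "Methods: NDR-centric interaction calling from proximity methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NDR-centric interaction calling from proximity methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtacr)
```

## The measurement and its statistical model

A proximity-methylation architecture-capture experiment recruits a GC
methyltransferase to a single genomic locus (the *viewpoint*) through an
operator array, so that accessible DNA that is physically proximal to the
viewpoint — in *cis* or in *trans* — becomes methylated and can be
recovered by methylation-enrichment sequencing. A control strain carries
the free enzyme but no operator array, so its methylation reflects the
background activity alone. Because the enzyme acts almost exclusively in
nucleosome-depleted regions (NDRs), the NDR is the natural quantum of
signal: fragment counts are integrated over each annotated NDR rather
than over fixed-width genomic bins, which would dilute the signal with
flanking nucleosomal DNA.

The per-NDR counts are modeled as negative binomial, the standard model
for overdispersed sequencing counts. For NDR $i$ and sample $j$ with
size factor $s_j$,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
\mu_{ij} = s_j \exp(\beta_{0i} + \beta_{1i} x_j),$$

where $x_j$ indicates the targeted strain and
$\mathrm{Var}(K) = \mu + \alpha \mu^2$. The *signal* of NDR $i$ is the
base-2 fold change $\beta_{1i}/\ln 2$, and an NDR is *called
interacting* when

$$\log_2 \mathrm{FC} > 0.7 \quad\text{and}\quad p_{\mathrm{adj}} < 0.05,$$

with strict inequalities, where $p$ is a two-sided Wald p-value and
$p_{\mathrm{adj}}$ its Benjamini–Hochberg adjustment over all tested
NDRs. NDRs with zero counts in every sample are untestable and are
excluded from testing and from the adjustment universe. NDRs overlapping
the viewpoint insertion itself are excluded from the call set (they are
the viewpoint's own locus).

The engine is a deliberately transparent implementation of this
NB-Wald-plus-BH contract, not a re-implementation of any specific tool:
every step below is specified, unit-tested against independent oracles,
and validated end to end by calibration and recovery on simulated data
with known ground truth.

### Normalization

Size factors use median-of-ratios: over NDRs with positive counts in
every sample, $s_j = \mathrm{median}_i \, K_{ij} / g_i$ with $g_i$ the
geometric mean of NDR $i$ across samples, rescaled so the geometric mean
of the $s_j$ is one. This is robust to the minority of NDRs with strong
differential signal. A unit test cross-checks the factors against an
independent established implementation of the same estimator.

### Dispersion estimation

With two replicates per group — the design this assay uses — per-NDR
dispersion estimates are extremely noisy, and how they are stabilized is
the single most consequential numerical choice in the engine:

1. **Raw estimate.** Method of moments on normalized counts:
   $\hat\alpha_i = (\hat v_i - \bar\mu_i)/\bar\mu_i^2$, with $\hat v_i$
   the pooled within-group variance (2 degrees of freedom at $n = 2 + 2$).
2. **Trend.** A mean-dependent trend
   $\alpha_{\mathrm{tr}}(\mu) = a_0 + a_1/\mu$ is fit by non-negative
   least squares to the *unclipped* raw estimates. Fitting on the raw
   scale matters: least squares on $\log\hat\alpha$ over the positive
   estimates is biased low, both by Jensen's inequality (the log of a
   noisy, nearly chi-square variance estimate is biased downward by
   roughly $\psi(\nu/2)-\log(\nu/2)$) and by the selection on
   $\hat\alpha > 0$. An underestimated trend makes every downstream Wald
   test anticonservative.
3. **Asymmetric shrinkage.** The final dispersion blends raw and trend
   on the log scale with weight $w = 0.5$ on the trend, then is
   **floored at the trend value**. The floor is deliberate: with 2
   degrees of freedom, a raw estimate *below* the trend is almost surely
   sampling noise, and letting it lower the final dispersion would let
   chance within-group agreement inflate the Wald statistic — exactly
   the NDRs that then become false calls. A raw estimate *above* the
   trend may reflect genuine extra variability and is only partially
   shrunk. NDRs whose raw estimate is zero carry no information of their
   own and receive the trend value.

The test suite verifies the consequences rather than the formulas: on a
pure-null simulation at the study design (2,000 NDRs, mean count 50,
dispersion 0.05, two replicates per group) the raw-p rejection rate at
the 0.05 level must fall in $[0.03, 0.07]$ and the double-threshold call
rate must stay below 1%; on data with 50 planted fold-4 contacts the
caller must reach sensitivity $\ge 0.8$ at empirical FDR $\le 0.1$.
During development the symmetric (unfloored) blend failed both checks —
rejection up to 0.077 and empirical FDR up to 0.15 — which is what
motivated the floor.

### The Wald test

At fixed $\alpha_i$ the two-group model factorizes, so each group mean is
fit by Newton iteration on its log scale (score
$\sum_j (K_j-\mu_j)/(1+\alpha\mu_j)$), and the standard error of the
group contrast comes from the Fisher information,
$\mathrm{SE}^2 = 1/\mathcal I_{\mathrm{targeted}} +
1/\mathcal I_{\mathrm{control}}$ with
$\mathcal I = \sum_j \mu_j/(1+\alpha\mu_j)$. A group with all-zero
counts receives a continuity floor of half a count on its fitted total
(flagged in the output); a non-converged fit is reported with $p = 1$ and
flagged, so it can never be called but still counts in the BH universe.
The maximizer is tested against an independent grid-plus-golden-section
profile-likelihood search to $10^{-4}$ in $\log_2\mathrm{FC}$. BH
adjustment delegates to the stock step-up implementation and is tested
against the brute-force definition on exhaustive small vectors.

## Interaction classes and distance decay

Calls are classified relative to the viewpoint: `trans` on a different
chromosome; `far_cis` on the viewpoint chromosome at midpoint distance
strictly greater than 30 kb; `local` otherwise. "Local" is defined as
the complement of far-cis on the same chromosome so that the three
classes are exhaustive and mutually exclusive. Two distance conventions
coexist deliberately: viewpoint-to-NDR and NDR-to-NDR distances use
interval *midpoints* (which makes the 30 kb class boundary unambiguous),
while NDR-to-feature proximity uses *gap* distance (so an NDR touching a
peak is at distance zero). Both are exposed; each function documents
which it uses.

Signal decay with distance is modeled as
$S(d) = A \cdot 2^{-d/h}$, fit by least squares on
$\log_2 S = \log_2 A - d/h$; the base-2 exponent makes $h$ literally the
half-distance in bp. The fit refuses fewer than 4 points, non-positive
signals, zero-variance distances, and non-negative slopes ("no decay
detected").

The profile of signal around called long-range contacts
(`neighbor_decay_profile`) aligns NDRs by the centers of called NDRs,
bins distances (200 bp default, matching the averaged presentation such
profiles are given in practice), and returns both the mean
$\log_2\mathrm{FC}$ and its excess-fold transform $2^{\bar S}-1$, the
natural scale for fitting because the planted enrichment is
multiplicative above a background of fold one. Centers default to local
signal *summits* (a call is a center only if no stronger call lies
within the window on its chromosome): using every call as a center lets
the decaying flank of one contact masquerade as a second center, which
compresses distances and inflated the fitted half-distance by ~25–45% in
development tests. Neighbors are included whether or not they were
themselves called; excluding called neighbors would censor the profile
at the calling threshold.

## Feature association and enrichment

An NDR is feature-associated when it overlaps a peak by at least one
base (half-open adjacency is no overlap), and feature-proximal when its
gap distance to the nearest same-chromosome peak is at most 1 kb — a
default chosen as clearly sub-NDR-spacing scale (mean NDR spacing in
this genome is 2–3 kb); it is a parameter, not a claim about the
original analyses, which did not state a threshold. Enrichment of calls
for a feature uses the pooled two-proportions z-test; call/feature
overlap significance can also be assessed by permutation, drawing
$|{\rm calls}|$ NDRs uniformly without replacement from the annotation
universe, with the add-one p-value convention
$(1 + \#\{{\rm null} \ge {\rm obs}\})/(1 + n_{\rm perm})$ so the
estimate is never exactly zero. The permutation null is exchangeable, so
it is tested against the closed-form hypergeometric tail. Group
comparisons of nearest-feature distances default to the two-sided
rank-sum test, since medians are the reported summary; Welch's t-test is
available behind a flag.

## Multi-viewpoint correlation clustering

With several viewpoints assayed on the same NDR universe, every NDR
called by at least one viewpoint has a complete vector of signals
(its $\log_2\mathrm{FC}$ in every viewpoint's result, called or not).
Pearson correlation of these vectors over NDR pairs measures shared
interaction behavior; the correlation matrix is clustered by Ward's
minimum-variance linkage on Euclidean distances between its *rows* — the
stated object of clustering is the correlation matrix, so each NDR is
represented by its correlation profile. The alternative of treating
$1 - r$ directly as a dissimilarity is available behind a flag. The Ward
implementation is checked, merge by merge, against a naive
$O(n^3)$ minimum-variance oracle on all instance sizes up to 20. The
number of clusters $k$ is a user parameter: the tree carries no
privileged cut, cuts are nested (a smaller $k$ coarsens a larger one),
and labels are numbered by decreasing cluster size for stability.
Zero-variance signal rows have undefined correlation and are dropped
with a warning rather than imputed. When a cluster's NDRs were called
with different interaction classes by different viewpoints, the summary
applies the precedence local over far-cis over trans.

## Bisulfite trace rates

Bisulfite conversion reads an unmethylated C as T; a methylated C stays
C. Given a per-position four-channel intensity table exported from
Sanger trace software (chromatogram parsing is deliberately out of
scope), the methylation rate at each GC-dinucleotide cytosine of the
unconverted reference is $I_C/(I_C+I_T)$, a scale-free ratio, so no
per-position intensity normalization is needed. Sites with
$I_C + I_T = 0$ are skipped with a warning. Only the forward strand is
scored by default (one PCR product is sequenced in one direction);
reverse-strand scoring — which reads the G/A channels at the forward G
of the dinucleotide — is behind a flag.

## The simulator: what it emulates and what it does not

The generator produces every input with known truth. Defaults describe
the study conditions: NDRs of 150 bp at a mean spacing of 2.5 kb
(start-to-start gaps exponential above the width) on five 1 Mb
chromosomes, giving ~2,000 NDRs; mean control depth 50 per NDR; NB
dispersion 0.05; two replicates per group; local enrichment
$1 + f_{\rm local} 2^{-d/400\,{\rm bp}}$ around the viewpoint with
amplitude 8; 50 planted long-range contacts at fold 4; an NPC-like
feature flagging 11.3% of NDRs genome-wide with 6-fold enrichment among
contacts. Per-NDR accessibility weights are lognormal
($\sigma = 0.5$, mean one) to mimic enrichment variability between NDRs;
per-sample depth factors are lognormal ($\sigma = 0.1$). Counts are
emitted per NDR directly, which keeps stage tests orthogonal; a separate
deterministic fragment emitter exercises the counting stage, and a trace
emitter exercises the bisulfite stage. Multi-viewpoint runs share one
genome and one contact set with balanced latent compartment labels;
viewpoints are assigned compartments round-robin, and a contact is
enriched only for viewpoints of its own compartment, which induces the
within-compartment signal correlation the clustering stage assumes. An
optional halo mode adds exponentially decaying enrichment around contact
centers for decay-profile round trips.

Known simplifications: no antibody-efficiency or GC-density differences
between NDRs, no methylation saturation, no read-level error model, no
polymer physics. Passing tests therefore demonstrate the statistical
contract of the pipeline — calibration, recovery, decay and compartment
round trips — under an idealized generative model, not performance on
any particular real dataset.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible
given (configuration, seed). The test suite and the acceptance script
use: 2,000-NDR genomes for calibration and recovery; a denser 500 bp
spacing layout (~4,000 NDRs over four 0.5 Mb chromosomes) for the
neighbor-decay round trip, since at 2.5 kb spacing almost no NDR falls
within two half-distances of a contact; 60 contacts x 8 viewpoints for
compartment recovery; 200 points for direct decay fits; and
100,000 permutations where the permutation test is compared with its
hypergeometric oracle. A full run of the suite takes on the order of a
minute.

## Known limitations

* The engine is not numerically identical to any specific differential
  tool; agreement is at the level of the statistical contract
  (calibration, recovery), which is what downstream stages consume.
* With two replicates per group the dispersion trend dominates; NDRs
  with genuinely atypical dispersion below the trend are tested
  conservatively by design.
* Whether independent filtering should be applied before BH is left
  off: the adjustment universe is all NDRs with any counts, the simpler
  and more reproducible choice; results within a small neighborhood of
  the padj boundary depend on this convention.
* Library sizes count fragments, not reads; if read-level depth is
  wanted for CPM tracks it must be supplied explicitly.
* The classification threshold (30 kb) is measured from the viewpoint
  insertion midpoint; measuring from the insertion edge would shift
  NDRs within half the insertion width of the boundary.
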