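---
title: "Discovering and scoring RBness signatures with rbnsig"
author: "rbnsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and scoring RBness signatures with rbnsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbnsig)
```

## The problem

Loss of the retinoblastoma tumor suppressor RB1 reshapes a tumor's
transcriptome, and some tumors acquire the same transcriptional state
*without* any detectable RB1 lesion — no truncating mutation, no deep
deletion, normal Rb protein.  We call that state **RBness**.  Detecting it
requires (i) a reliable definition of RB1-defective and RB1-proficient
reference samples, (ii) a differential-expression signature that is robust
to the tiny discovery groups such definitions produce, and (iii) a scoring
rule that classifies any new transcriptome against the signature.  `rbnsig`
implements that pipeline end to end, together with the downstream filters
used to nominate synthetic-lethal genes and candidate drugs for
signature-high tumors.

## Status calling

Each sample is called **defective**, **proficient**, or **indeterminate**
from up to five modalities (`callRbStatus`):

* defective iff total Rb protein $\le -0.2$ (TCGA scale; $-0.7$ on the
  CPTAC phase-2/3 scale, where abundances are distributed differently), OR
  median phospho-Rb $\ge 0.3$ with Rb $\le 0.2$ and $\mathrm{pRb} -
  \mathrm{Rb} \ge 0.2$ (hyperphosphorylated, inactive Rb), OR a truncating
  RB1 mutation, OR an RB1 deep deletion (copy-number log2 ratio $< -1$);
* proficient iff none of {truncating mutation, deep deletion}, Rb $> 0$,
  and RB1 mRNA z-score $\ge 0.2$ — the soft mRNA filter guards against
  occult loss in samples with nominally high protein;
* missense mutations force indeterminate: their functional impact is
  unknown, so such samples belong to neither reference group.

The genomic (pan-cancer) variant, for cohorts without proteomics, calls
defective on truncating *or splice* mutations or copy-number deletion, and
balances the groups by taking the top-$M$ non-defective samples by RB1
mRNA z-score as proficient (`selectDiscoveryGroupsGenomic`), requiring
$M \ge 3$.  Ties at the $M$-th z-value break by lexicographic sample id so
runs are reproducible.  Copy-number "deletion" defaults to deep deletion
only; `includeLoss = TRUE` extends it to shallow loss.

All threshold comparisons are implemented exactly as written above
(inclusive/exclusive as printed); the hyperphosphorylation *difference*
comparison carries a $10^{-9}$ tolerance so a printed pair like
pRb $= 0.35$, Rb $= 0.15$ is not rejected by floating-point rounding.

## Robust differential expression

Discovery runs on per-gene z-scored expression (`zscoreByGene`; population
SD, standardised within the analysed cohort — the upstream reference
population of public z-scores is rarely documented, so we standardise
explicitly and say so).  `fitModeratedDE` fits the usual two-group linear
model with empirical-Bayes variance moderation: a scaled inverse-chi-square
prior is fitted to the gene variances by moment matching on
$\log s^2_g$ (prior df via a trigamma inverse), each gene's variance is
shrunk to $\tilde{s}^2_g = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, and the
moderated $t$ is referred to $d + d_0$ degrees of freedom.  Two numerical
conventions matter:

* when the log-variances show no excess spread beyond chi-square sampling
  noise ($d_0 = \infty$), the prior variance is set to the *mean* gene
  variance, so that genes with identical variances yield exactly the
  ordinary pooled $t$;
* `priorDf = 0` disables shrinkage entirely, which is the contract our
  oracle tests check against an independently coded pooled $t$.

The subsampling robustness procedure (`lool`) reruns the moderated fit on
every one of the $n \cdot m$ subsets obtained by deleting one defective and
one proficient sample, restricted to the initially selected candidate genes
(selection: $|\Delta \bar z| \ge 0.585$, BH $q < 0.1$), and counts how
often each gene passes the stricter thresholds $|\Delta \bar z| \ge 1$,
$q < 0.1$.  BH adjustment is performed within the candidate set, matching
the restriction.  The subset loop updates group sums and sums of squares
incrementally — an exact rearrangement, verified against naive re-fitting
in the tests.  Because each subset must retain two samples per group, the
procedure requires $n, m \ge 3$.

The final filter keeps genes with robustness fraction $\ge 0.20$
(proteogenomic) or $\ge 0.50$ when more than 20 genes were initially found
(genomic variant; exactly 20 falls in the lenient branch), absolute mean
defective-group z $\ge 0.2$, and direction consistency $\ge 0.6$ (a z of
exactly 0 never counts as matching).  Fold-change thresholds are applied
to group-mean differences on the z scale, the scale the pipeline ingests;
this is stated rather than hidden because it changes what "1.5-fold"
means for pre-standardised input.  An empty result is returned as a
signature flagged invalid (`isValidSignature`), not as an error: in a
pan-cancer sweep some cancer types legitimately fail to produce a
signature.

## Relevance-network refinement

To generalise a candidate signature beyond its discovery set,
`refineSignature` works at four RB1 expression scales
$\alpha \in \{0.4, 0.6, 0.8, 1.0\}$.  At each scale, samples with RB1 z
$> \alpha$ or $< -\alpha$ (strict inequalities) are selected, the Spearman
correlation matrix of the signature genes over those samples is computed
(average ranks; fewer than three selected samples makes the scale
unusable), and an adjacency $A_{ij} = 1$ iff $i \ne j$ and
$C_{ij} \ge c$ is thresholded over the grid $c \in \{0.10, 0.12, \dots,
0.80\}$.  For each $c$, the genes with degree $\ge 1$ are scored: every
selected sample is classified defective-like when its alignment over the
connected genes exceeds $0.5$ (a tie at exactly $0.5$ counts as
proficient-like), the RB1-low side being the one expected to look
defective-like, since directions are defined on defective samples
(`invertSides` swaps this).  $c^*$ is the smallest grid value achieving
the maximal accuracy — the smallest-$c$ tie-break keeps the most genes
connected.  Constant genes over the selected samples have undefined
correlations and are treated as disconnected.

The cross-scale consensus keeps genes connected at **all** usable scales
(strict) or at $\ge 2$ scales (tolerant); `mode = "auto"` chooses strict
for candidate sets above 50 genes and tolerant otherwise (exactly 50 is
tolerant, the boundary being unassigned by the dichotomy "more than 50 /
less than 50").  When a scale is unusable, strict consensus is impossible
by definition and the run falls back to tolerant with a warning; with a
single usable scale the tolerant membership threshold drops to 1 so small
cohorts can still refine.  Both conventions are deliberate design choices
and are recorded in the refined signature's metadata.

## Alignment scoring

A signature stores one direction per gene, $d_g = \mathrm{sign}(\bar z_g)$
over the defective discovery samples.  The alignment of a sample is the
fraction of its *measured* signature genes whose z-score sign matches
$d_g$; a z of exactly 0 counts as discordant (the sign formalism leaves 0
unassigned, and on continuous data the choice is measure-zero).  Scores
$> 0.55$ classify a sample signature-high, $< 0.45$ low, and the inclusive
band $[0.45, 0.55]$ no-confidence.  Because the score depends only on
signs, it is invariant to any per-gene affine rescaling of the raw data
that precedes z-scoring — a property the tests exercise directly.

`svdSignatureScore` provides the benchmarking alternative used to compare
gene-list signatures on a common footing: genes are standardised, samples
are scored by the first right-singular vector of the standardised matrix,
the sign is oriented to correlate positively with the mean of the
up-regulated genes (SVD signs are arbitrary, so a convention is required
for tertile semantics), and samples are trichotomised by tertiles.

`buildCoreSignature` aggregates per-cancer-type signatures into a core of
genes recurring in at least $\max(3, \lceil 0.2\,n \rceil)$ signatures
(reproducing "3 of 14" and scaling beyond it); core directions are the
majority sign, with tied genes dropped.  Pairwise signature overlap uses
the overlap coefficient $|A \cap B| / \min(|A|, |B|)$ after removing RB1
from both sets, since the anchor gene would otherwise inflate every
pairwise overlap by one.

## Screen gating

Candidate synthetic-lethal genes and drugs are nominated by *gated* Welch
tests: a gene/compound is tested at all only when the group means pass the
screening gates (gene effect: mean in the defective or RBness group
$< -0.5$, mean in the signature-low group $> -0.75$, and the former below
the latter; drugs: mean dr-AUC $\ge 0$ in the low group and $< -0.5$ in
the tested group, with at least three cell lines per group).  Testable
items get a one-sided Welch $t$ (Satterthwaite df, alternative "tested
group lower"), candidates at $p < 0.05$ without multiple-testing
correction — matching the uncorrected convention of the screens this
mirrors; an `fdr` switch exists but is off by default.  Items failing the
gates never receive a p-value, an invariant the tests assert.  The
isogenic knockout-vs-parent filter applies its three printed thresholds
($\Delta < -2$, knockout z $< -2$, parent z $> -4$) verbatim.

Percent genome altered defaults to the length-weighted fraction of the
segmented genome with $|\log_2 \text{ratio}| > 0.2$; `byCount = TRUE`
computes the unweighted segment-count fraction, the literal reading of
"proportion of segmented regions".  Length weighting is the default
because it is invariant to how a run of constant copy number happens to be
split into segments.

Enrichment p-values use the one-sided hypergeometric tail (`phyper`), the
same engine named by the overrepresentation analyses this reproduces; the
gene universe must be supplied explicitly by the caller because no default
universe is defensible.

## The synthetic cohort generator

`generateCohort` emulates the statistical structure of a proteogenomic
discovery cohort — it is the package's study condition, not a tuning knob.
The defaults (2000 genes, 100 samples, 40 signature genes at
$|\log_2 FC| = 1.5$, 20% defective, 10% phenocopy, residual SD 0.5, 10%
missing phospho, per-gene baselines $N(7, 1)$) describe a cohort of
roughly the size and effect magnitude a single-cancer-type discovery
analysis sees.  Each defective sample passes exactly one randomly chosen
defective rule, with the other modalities kept in the proficient range —
this isolates the rules so the round-trip test (every truth-defective
sample called defective, every phenocopy sample never called defective)
is exact.  Hyperphospho samples get Rb in $(-0.2, 0.15]$ and three
phospho-sites in $[0.35, 0.6]$; missing-phospho samples are drawn from the
non-hyperphospho pool so the missingness never contradicts a planted
mechanism.  Phenocopy samples carry the full expression shift (including
low RB1 mRNA) with entirely normal protein, mutation and copy-number
profiles.  The RB1 mRNA row is bimodal (offsets $+1$ / $-3$ around its
baseline), giving the proficiency soft filter and the refinement scale
selection a well-separated axis.

What the generator does *not* emulate: count-level sequencing noise,
batch effects, correlated co-regulation beyond the planted block
(`plantCorrelatedBlock`, a single-factor construction whose monotonicity
makes the induced Spearman correlation track the target $\rho$), partial
lesions, or tumor purity gradients.  Passing the recovery and phenocopy
criteria on these cohorts therefore demonstrates correctness of the
machinery under its stated model, not clinical performance on real data.

Group sizes are `floor(frac * n + 0.5)` (round-half-up), so tests can
assert exact counts.  All generators accept a seed and restore the
caller's RNG state; identical spec and seed give bit-identical output.

## Validation problem sizes

The validation suite and `scripts/acceptance.R` use: planted-signature
recovery and null calibration on the default 2000-gene cohort (10 and 20
replicates; discovery groups of 20 defective vs 25 proficient, the
proficient list truncated to 25 to fix the group geometry); subset-oracle
equivalence on 50 random instances with $n, m \le 6$; refinement on a
300-sample fixture with a 20-gene planted block against 80 uncorrelated
decoys with random fixed directions (decoy directions are fixed *before*
evaluation — fitting them on the evaluation samples would leak concordance
into the accuracy criterion); phenocopy detection on held-out halves of
200-sample cohorts (stratified odd/even split, z-scored cohort-wide as a
validation cohort would be); and screen gating on 200-gene tables with 20
lines per group at margin 0.6.  These sizes keep each study to seconds
while leaving comfortable statistical margins.

## Known limitations

* The moderated fit covers the two-group design only — no covariates, no
  precision weights, no count-level (voom-style) path; inputs must be
  log2 or z-scored, enforced by the `valueKind` tag.
* "Validity" of a signature is purely "non-empty after filtering/
  refinement"; no further quality criterion is imposed.
* The accuracy-driven $c^*$ search is a heuristic: on weakly separated
  cohorts it can retain chance-correlated genes or over-prune, which is
  why the strict consensus is the default for large candidate sets.
* Manual curation steps of cohort assembly (e.g. treatment-ambiguity
  exclusions) have no stated rule and are not implemented.
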