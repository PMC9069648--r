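---
title: "Discovering enhancer–promoter motif pairs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering enhancer–promoter motif pairs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epmotifs)
```

## The question and the model

Physical contact between an enhancer and a promoter is thought to be
stabilised, in part, by direct or bridged interaction of transcription
factors bound on the two elements — CTCF–CTCF and YY1–YY1 are the textbook
homotypic cases. `epmotifs` systematises the search for such signals: given
interacting EP pairs (from a normalized chromatin-contact matrix) and a
motif library, it finds oriented motif pairs (one motif in enhancers, the
other in promoters) whose joint presence across EP pairs exceeds what
independent occurrence would produce.

The statistical skeleton is deliberately simple. Write $N$ for the number
of interacting EP pairs, $a$ for the number of enhancers containing motif
$X$, $b$ for the number of promoters containing motif $Y$, and $k$ for the
number of EP pairs with both. Under region-wise independence the expected
co-occurrence is $\lambda = ab/N$, and the observed $k$ is scored with the
Poisson upper tail $P(\mathrm{Pois}(\lambda) \ge k)$ — the clumping
heuristic for counts of rare joint events. The same tail, with
$\lambda = N\prod_i f_i$ over member marginal frequencies $f_i$, scores a
candidate motif *module* (a set of 2–5 motifs). Modules are enumerated
Apriori-style over presence/absence profiles with anti-monotone pruning at
a minimum support of 30 EP pairs, and oriented pairs are extracted only
from modules that survive Bonferroni correction at 0.01.

Two points deserve emphasis because the upstream literature leaves them
open:

* **The Poisson rate is a reconstruction.** The clumping heuristic is cited
  in the field without its parameterisation; $\lambda = ab/N$ (pairs) and
  $N\prod f_i$ (modules) are this package's explicit choices, and both are
  exposed in the output tables so any alternative can be recomputed.
* **The correction family is Bonferroni** over the hypotheses actually
  evaluated — support-passing candidate modules for the module test, and
  oriented pairs tested for the pair test (a pair and its flip are two
  hypotheses). Benjamini–Hochberg is available via
  `correct_pvalues(method = "BH")`.

## Thresholds and tunable parameters

| parameter | default | meaning |
|---|---|---|
| interaction cutoff | 30 (150 deep) | strict `>` on normalized contact value |
| non-interaction cutoff | 5 | strict `<`, absent bin pairs count as 0 |
| distance window | 2.5 kb – 2 Mb | enhancer-midpoint to TSS, inclusive |
| promoter window | −1000/+100 bp | around the TSS, strand-mirrored |
| scan p-value | 1e-4 | FIMO-style reporting threshold |
| presence p-value | 1e-5 | instance threshold for co-occurrence profiles |
| similarity E-values | 1e-5 / 1e-8 | annotation/dedup vs cross-condition sharing |
| min support | 30 | module and oriented-pair support |
| module size | 2–5 | Apriori levels |
| alpha | 0.01 | on corrected p-values; homogeneous tests use 0.01/K |

The **presence p-value** is stricter than the scan threshold by design. A
permissive scan reports roughly $2Lp$ false instances per sequence of
length $L$; at $p=10^{-4}$ an 1100-bp promoter accrues ≈ 0.22 expected
false instances, which would inflate presence marginals to the point where
the Poisson calibration of the co-occurrence test degrades. Instances at
$p<10^{-5}$ keep the per-region false-presence rate at the percent level
while still accepting consensus-quality sites of any motif of width ≥ 9.
Raw scan hits (1e-4) are still what the classifier counts, where noise is
averaged rather than thresholded.

Promoter windows are mirrored on minus-strand genes so "upstream" is
biological upstream; `make_promoters(ignore_strand = TRUE)` restores the
unstranded reading. EP distance is enhancer midpoint to TSS (configurable
to edge-to-edge); overlap with a contact bin means ≥ 1 bp; when several bin
pairs support one EP pair the maximum contact value is kept; positives and
type-3 negatives are kept disjoint explicitly (`exclude_pairs`), since an
enhancer spanning two bins can otherwise appear in both sets.

## Scanning and numerical choices

Scores are $\sum_j \log_2 (p_{b_j,j}/q_{b_j})$ against an i.i.d.
background (uniform by default). P-values come from the *exact* score
distribution: for widths ≤ 10 by full enumeration of all $4^w$ words
(bit-identical to window scoring, so oracle tests hold to 1e-12); for wider
motifs by dynamic programming on a 1/1000-bit score lattice, with window
scores computed on the same lattice so lookups stay self-consistent
(documented tolerance 1e-3 against enumeration). Windows containing `N`
never match, which makes repeat-masked input safe. Matrices are
regularized with a 0.01 pseudocount at construction; both strands are
scanned, presence/absence collapses strands, feature counts keep them.

Motif similarity is an ungapped alignment of probability columns: all
offsets with ≥ 4 overlapping columns, both orientations. The alignment is
*selected* by the sum of column-wise Pearson correlations — a long
agreeing overlap must beat a short perfect one, as in ungapped
Smith–Waterman-style aligners — while the reported score is the mean
correlation of that alignment, in $[-1, 1]$. Significance is empirical:
within-motif column permutations of the first motif, p = fraction of
shuffles scoring *strictly* better, E-value = p × number of pairs compared.
Strict inequality matters: counting ties would floor every self-comparison
at the probability that a random permutation reconstructs the motif
(≈ 4·10⁻⁴ for a width-8 motif with repeated columns), making the 1e-5
contract unreachable for identical motifs. The converse limitation is that
the E-value resolution is 1/`n_shuffles` × scaling, so very small E-value
cutoffs (1e-8, used for cross-condition sharing) are effectively "no
strictly better shuffle observed" calls.

Tail probabilities (binomial, Poisson, hypergeometric) are computed with
R's log-space distribution functions behind the package's contract
wrappers (`binom_upper_tail()` includes the observed count; all return
exactly 1 at zero counts) and are cross-checked in the test suite against
independent term-by-term summation oracles.

## Negative sets

* **Type 1** permutes each positive pair's enhancer and promoter sequence
  independently (mononucleotide; exact composition conservation). A
  dinucleotide-preserving Eulerian-path shuffle (Altschul–Erickson) is
  available but not the default, which follows the plain "random
  permutation" reading.
* **Type 2** keeps the promoter and substitutes a random genomic region of
  *exactly* the enhancer's length at a TSS distance resampled from the
  empirical positive distances (random side, clipped to the distance window
  and chromosome bounds, rejecting overlaps with enhancers ∪ promoters,
  100 attempts then skip). "Similar length and distance distributions" is
  thus operationalised as exact length copy plus empirical resampling.
* **Type 3** re-runs EP-pair construction on bin pairs with contact < 5.
  The class imbalance this produces is preserved by default; `balance`
  subsamples negatives to the positive count before classification.

## Classification

Each EP pair is a $4n+1$ vector over the $n$ discovered motif pairs:
counts of the E-side and P-side motif in the enhancer and in the promoter,
plus the label. "Lasso" is L1-penalized *logistic* regression (glmnet),
since the reported metrics are classification metrics; stratified 10-fold
cross-validation with the penalty chosen by inner cross-validation on the
training folds, restricted to penalties that keep at least one feature
active — the null model carries no discriminative content, and letting it
win under a flat inner-CV curve would collapse predictions onto the
majority class. Counts are left unscaled (they share units);
standardization is available but changes the selected set. Selected pairs
are those with any nonzero coefficient in a final fit on all rows.
`cross_condition_eval()` scores condition B's EP pairs with condition A's
motif pairs, probing conservation of the mechanism.

## What the generator emulates — and what it does not

`simulate_bundle()` lays each EP pair in its own genomic block: a
strand-random TSS with the −1000/+100 promoter, a 300-bp enhancer at a
sampled distance (2.5–25 kb), one contact record per pair (interacting
values in (60, 200), low-contact values in (0, 4.5) with every other record
left absent), an information-rich width-12 motif library (0.97 consensus
probability), background sites planted at rate 0.05 per region, and the
planted oriented pair inserted jointly in a fraction `q_joint` of positive
pairs. The enhancer:promoter length ratio (300:1100) mirrors the observed
~3× length difference between promoters and enhancers, which keeps the
length-aware preference and homogeneous tests in a realistic regime. Width
12 ensures planted consensus sites (p ≈ 6·10⁻⁸) clear the presence
threshold with a wide margin.

Deliberately *not* modelled: distance-dependent contact decay, GC/isochore
heterogeneity, motif clustering and tandem repeats, overlapping regulatory
elements, cell-type-specific activity calling. Passing tests on these
bundles therefore demonstrate the statistical machinery — calibration
under independence, power against planted signal, exactness of the tails
and the scanner — not performance on real chromatin data, where marginal
frequencies are heterogeneous and contact calling itself is noisy.

Problem sizes used by the test suite and the acceptance script (500 EP
pairs for discovery sweeps, 400 + 400 for classification, 200 × 1000
replicates for calibration) were chosen as the smallest sizes at which the
planted-signal and null regimes separate cleanly.

## Known limitations

* The Poisson rate and correction denominators are reconstructions (above);
  absolute significance levels on real data should be read comparatively.
* The permutation E-value cannot distinguish candidates below the shuffle
  resolution; near-duplicate short motifs (width < 9) may evade the 1e-5
  dedup cutoff when ties are the only evidence.
* The homogeneous tests plug estimated marginals into the binomial null,
  which makes them conservative (measured null exceedance at 0.05 is
  ≈ 0.005–0.01 in the suite's calibration check).
* Type-2 sampling can fail on short chromosomes with dense exclusions; it
  errors when more than 10% of pairs cannot be placed.
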