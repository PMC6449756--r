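---
title: "Detecting split genes with phylogenetic tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting split genes with phylogenetic tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the two tests

Draft assemblies of large genomes routinely leave genes in pieces, and
annotation pipelines emit each piece as a separate gene model. Within a
gene family that also contains full-length homologs from reference
genomes, two fragments of one gene have a characteristic signature: they
occupy disjoint (or nearly disjoint) regions of the family alignment, and
they attach close to the same point of the gene tree — yet they are
almost never inferred as sister leaves, because no alignment column
covers both fragments and the data therefore contain no information about
their relative placement. `phylosplit` turns this signature into two
tests.

**Candidate filter.** Within a family, all pairs of target-genome genes
with ungapped lengths of at least `min_len = 50` amino acids are
screened by the aligned-overlap rule `a12 < 0.1·l1 AND a12 < 0.1·l2`
(strict inequalities; `a12` is the number of residues the two rows share
per column). Fragments shorter than 50 aa carry too little phylogenetic
signal to be worth rescuing, and allowing more than 10% overlap admits
genuine paralog pairs wholesale.

**Test 1 — collapsing weakly supported branches.** Bootstrap supports
are a measure of how much resolution the data actually provide. If every
branch separating the two fragments has support below a threshold
(default 0.95), that separation is phylogenetic noise: collapsing all
weak branches should merge the fragments into a common polytomy. The pair
is called a split when the fragments are sister leaves — children of the
same node — of the collapsed, unrooted tree. Polytomy sisters count:
collapsing is meant to erase insignificant resolution, and after
contraction a multifurcation is precisely the statement that the data
cannot order those children. Supports equal to the threshold survive
("below" is strict), and missing supports default to 1 (never collapsed),
which is the conservative direction.

**Test 2 — likelihood ratio with a bootstrap null.** The null H_s says
the fragments are one gene: the family then has $n-1$ genes and the two
rows are merged into one. The alternative H_p keeps them as $n$ separate
genes. The statistic is $T = 2[\ln L(H_p) - \ln L(H_s)]$ with each
likelihood maximized over topology and branch lengths. H_s is the null
*because it is the smaller model* (the fragments are pinned to one
place), so — unusually — failing to reject is what produces a
prediction: the decision rule is $p_B \ge \alpha$ with $\alpha = 0.01$.
The models are not nested, so no $\chi^2$ asymptotics apply; the null
distribution is estimated by resampling alignment columns with
replacement from the H_s (merged) alignment, recomputing the statistic on
each of $n = 100$ replicates (50 in the scaled-down test suites), and
counting $p_B = \#\{T^*_i \ge T_0\}/n$, ties in the numerator.

To protect against a suboptimal H_s search inflating the statistic
downward, H_p is fitted twice — once de novo and once started from the
H_s tree with the merged leaf replaced by a near-zero-length cherry of
the two fragments — and the better likelihood is used. Because gaps are
missing data, the zero-length cherry reproduces the H_s likelihood
exactly, so $T_0 \ge -2\,\mathrm{tol}$ by construction.

**Combination and ambiguity.** The default combined call is the
intersection: both tests must agree. When a gene appears in several
positive predictions, the partner fragments are compared with the same
overlap rule: mutually non-overlapping partners describe a gene split
into more than two pieces (reported as an ordered chain, unambiguous);
partners competing for the same alignment region make the pairing
unresolvable and the whole conflict component is labelled ambiguous.
Chains of compatible fragments that also touch a conflict are treated as
part of the conflict component — the bookkeeping the sources leave open;
propagating through the conflict graph is the conservative resolution.

## Where the resampling scheme matters

"Splitting the replicate at the same position as in the original
alignment" is the load-bearing detail of the bootstrap. Each replicate
keeps the *original* fragment-membership pattern by column position: the
drawn column that lands at position $j$ belongs to fragment 1 exactly
when position $j$ belonged to fragment 1 originally. Under H_s the
fragments are arbitrary pieces of one sequence, so this reassignment is
distribution-preserving; under a true two-paralog process it scrambles
the association between column content and fragment membership, pushing
the replicate statistics toward the null. The alternative — carrying each
drawn column's own label — preserves the observed signal in every
replicate, makes $T^*$ track $T_0$, and leaves the test with no power at
all; it exists in the API (`resample_merged(..., provenance =
"carried")`) only for mechanical bookkeeping checks. Columns where both
fragments held a residue (allowed below 10% overlap) are routed to the
longer fragment, whose residue the merged row already carries; the
shorter fragment's residues on those columns are unrecoverable after
merging, a documented lossy corner affecting under 10% of its residues.

## Numerical engine

Likelihoods are Felsenstein pruning under the empirical LG model with its
stationary frequencies, one rate category, gaps and `X` as missing data
(all-ones partial likelihoods; an all-gap column contributes exactly
zero). Tree searches start from neighbor joining on maximum-likelihood
pairwise distances and hill-climb with NNI until no rearrangement
improves the log-likelihood; branch lengths live in $[10^{-8}, 10]$ and
the optimizer tolerance is $10^{-4}$ log-likelihood units. The numerics
are delegated to phangorn/ape — the standard R toolchain for exactly
these operations — behind a thin engine surface, and the test suite
cross-checks the pruning likelihood against an independent
exhaustive-enumeration oracle on small trees. A single rate category is
the default deliberately: rate heterogeneity along the sequence is a
known failure mode of split-gene inference (a two-domain protein with one
fast domain can mimic two distinct genes), and the simple baseline makes
that limitation explicit rather than hiding it behind a partially
effective correction.

Two details deserve a note. First, a pair of rows sharing no
residue-bearing column has no defined pairwise distance (and the
underlying distance routine silently returns zero for it, which would
weld the fragments into a spurious zero-length cherry); such entries are
imputed additively through the best shared neighbor,
$d(i,j) = \min_k[d(i,k) + d(k,j)]$. Second, branch supports are
classical Felsenstein bootstrap proportions with replicate trees rebuilt
by NJ on ML distances (a full NNI re-search per replicate is available
via `rebuild = "search"`); FastTree-style SH-like local supports are
accepted on input trees through the adapter, and the threshold semantics
are identical.

## The synthetic benchmark

`simulate_scenario()` reproduces the evaluation design at desk scale.
Families are evolved along a species tree (balanced topology over 8
reference genomes, branch lengths uniform on 0.05–0.3
substitutions/site, the target grafted as sister to a random reference)
under LG, 400-aa genes, no indels — so the true alignment is exact and
the tests are isolated from aligner error. Positives cut the target gene
at a uniform position leaving both pieces at least 50 aa. Negatives
simulate a duplication `dup_depth` substitutions/site before the present:
a duplicate lineage is grafted that far above the target leaf *along the
tree*, the family is evolved on the augmented tree, and complementary
fragments of the two copies replace them. Placing the duplication on the
tree (rather than evolving two copies off the present-day sequence) is
what makes depth a real difficulty dial: a deep duplication attaches the
two copies at different points of the tree, which reference lineages
diverging inside that window can resolve, while `dup_depth = 0` yields
the species-specific close-paralog limit — fragments of two identical
copies, inherently indistinguishable from a true split, where the
false-positive rate is reported rather than bounded.

What a green benchmark does establish: with exact alignments, a correct
model and moderately informative families, the combined test recovers
planted splits at high recall and rejects deep-paralog negatives at high
precision. What it does not establish: robustness to alignment error,
indels, rate heterogeneity along the sequence, annotation noise or family
inference errors — all present in real assemblies, all outside the
generator by design (the mafft/FastTree adapters exist to layer some of
this back in).

## Defaults and tunables

| Parameter | Default | Meaning |
|---|---|---|
| `collapse_threshold` | 0.95 | support below which branches collapse (strict) |
| `alpha` | 0.01 | LRT significance; `p_B >= alpha` predicts a split |
| `n_boot` | 100 | bootstrap replicates for the LRT null |
| `support_reps` | 100 | bootstrap replicates for branch supports |
| `min_len` | 50 aa | minimum fragment length |
| `max_overlap_frac` | 0.1 | aligned-overlap bound (strict, both fragments) |
| `replicate_mode` | `"full"` | per-replicate tree re-search; `"fast"` fixes topologies and refits branch lengths |
| `dup_depth` | 0.4 | benchmark duplication depth (subst/site) |

Raising the collapse threshold or lowering α yields more predictions at
lower confidence; the defaults are the stringent, whole-genome-scan
operating point. `"fast"` replicate mode exists because a full
re-search per replicate costs roughly an order of magnitude more for
little change in $p_B$ on desk-scale families; the mode is recorded in
every result.

## Degenerate inputs and edge cases

Families with fewer than four members are skipped (no informative
unrooted topology exists). Two-row alignments are fitted by direct 1-D
optimization of the single distance (the general optimizer requires at
least three edges). Ties: support exactly at the threshold survives;
`p_B` exactly at α predicts a split; an overlap exactly at 10% of either
fragment rejects the pair. A negative $T_0$ is never clamped — it simply
lands high in the null and produces a split call, the conservative
direction for the null hypothesis. All randomness flows from explicit
integer seeds: replicate $i$ derives seed + i, family $i$ in a scan
derives seed + 10000·i, and pair $j$ within a family adds 100·j, so any
subset of the computation can be reproduced in isolation.
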