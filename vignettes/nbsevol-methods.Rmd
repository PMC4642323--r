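---
title: "Methods: models, estimators and design choices in nbsevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in nbsevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nbsevol` is a desk-scale re-implementation of the standard genome-wide
evolutionary analysis of plant NBS (nucleotide-binding site) disease-resistance
genes: architecture classification, gene-family clustering, Ka/Ks-based
duplication dating, neighbor-joining phylogenetics with species-specific
duplication clade counting, codon site-model tests of positive selection, and
promoter cis-element scanning. This vignette documents the models, the
numerical choices, and the places where the protocol is underdetermined and a
design decision had to be made.

## Architecture classification

A gene is NBS-encoding iff its domain-annotation table contains an NBS
(NB-ARC) hit. The letter code is a pure function of domain presence: TIR
present gives TNL/TN (with/without LRR); otherwise CC gives CNL/CN; otherwise
XNL/XN. Multiple hits of one domain collapse to presence — the classification
protocol uses presence only, and coordinates are kept for reporting and for
slicing out the NBS domain for phylogenetics. Because surveyed RPW8-carrying
genes span TNL, CNL and XNL/XN architectures, RPW8 is an orthogonal boolean
flag (`rnl`), not a seventh code.

The census denominator (genes in the whole genome) is deliberately an explicit
argument: whether it means annotated or expressed genes is a property of the
upstream annotation, not of this package. Percentages are displayed at two
decimals with half-up rounding, matching the usual table conventions.

## Gene families

Two genes are joined when **both** global-alignment coverage and identity
reach the threshold (70/80/90% in the standard protocol); families are
connected components of size >= 2 (single linkage). Choices the criterion
itself does not fix:

* **Alignment**: Needleman–Wunsch global alignment with affine gaps (Gotoh
  algorithm, compiled), BLOSUM62, gap open 10 / extend 0.5, end gaps
  penalized; a length-L gap costs `10 + 0.5 L`. The scoring is recorded in
  the pipeline's settings metadata.
* **Coverage denominator**: the *longer* gene's length. This makes coverage
  symmetric and conservative; the alternative (each gene's own length,
  required in both directions) is stricter only for near-equal lengths.
* **Aligned length** counts columns with a residue in both sequences;
  `identity` is identical residue pairs over aligned length, with `X` never
  counting as identical.
* **Linkage**: single linkage via connected components — the weakest
  assumption consistent with "grouped by pairwise criteria".

Multiple alignments (for codon back-translation and the NBS-domain tree) use
a center-star progressive strategy over the same pairwise engine: the center
is the sequence with the greatest summed pairwise score, and pairwise
alignments are merged under once-a-gap-always-a-gap.

## Ka/Ks

Nei–Gojobori (1986) counting with Jukes–Cantor correction — the method behind
the usual "Ka/Ks in MEGA" default:

* synonymous site fractions per codon come from exhaustive enumeration of the
  nine single-nucleotide changes, with changes to stop codons excluded from
  the possible-change count; `S + N = 3 x codons` holds identically;
* site counts are averaged over the two sequences; gapped columns are removed
  pairwise (pairwise deletion);
* for codons differing at k positions, differences are averaged over the k!
  orderings of minimal mutational pathways, excluding pathways through stop
  codons (if every pathway is blocked — not observed in practice — all
  pathways are used with stop-involving steps counted as nonsynonymous);
* `d = -(3/4) ln(1 - (4/3) p)`; `p >= 3/4` raises a typed "saturated" error
  rather than returning a number.

Family-level Ka, Ks are arithmetic means over within-family pairs and the
family ratio is `mean(Ka)/mean(Ks)` rather than the mean of ratios: the mean
of ratios is undefined whenever any pair has Ks = 0 and is dominated by
near-zero-Ks pairs otherwise. Pairs with undefined ratios thus still
contribute their Ka and Ks. The Ks profile bins pairwise Ks into half-open
`[lo, hi)` bins of width 0.1 over [0, 1), tallying Ks >= 1 separately, with
the mean Ka/Ks of each bin alongside — the standard duplication-age profile.

## Phylogeny and duplication clades

Distances are pairwise-deletion protein p-distances, Poisson-corrected by
default (`d = -ln(1-p)`); the raw p-distance is available by flag. The tree is
Saitou–Nei neighbor joining with the Q-criterion. Determinism matters more
than speed here, so ties in Q are broken by the lexicographically smallest
pair of subtree representative labels, and bipartition keys are canonical
sorted leaf sets; trees are reproducible bit for bit. Negative NJ branch
lengths are clamped to zero with the deficit moved to the sibling branch
(standard practice); raw values are kept in an attribute.

Bootstrap supports resample alignment columns with replacement, rebuild the
NJ tree, and report the percentage of replicates containing each internal-edge
bipartition of the full-data tree (default 1000 replicates, seeded).

Species-specific duplication clades are evaluated on the midpoint-rooted
tree: maximal clades (no counted clade nested in another) with >= 2 leaves,
all of one species, and support strictly greater than the threshold (default
50). Midpoint rooting and the maximal-clade rule are design choices — the
protocol this follows does not state its rooting or nesting rule; maximality
prevents double counting of genes, and the conservation property (clade sizes
sum to the reported gene count) is enforced by construction. Monophyly of a
marked gene set (e.g. RPW8-flagged genes) is an exact bipartition test on the
unrooted tree, reporting that edge's support.

## Codon site models

Selection tests use GY94 codon models over the 61 sense codons:
`q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for
single-nucleotide changes. The likelihood is computed by Felsenstein pruning
with per-node rescaling and log-space accumulation; transition matrices come
from the symmetrized eigendecomposition of the reversible generator. Codon
frequencies default to F3x4 estimated from the alignment (with a 0.5
pseudocount per nucleotide so no sense codon has probability zero); equal
frequencies are available.

* **M0**: a single omega; kappa, omega and all branch lengths are estimated
  jointly by Nelder–Mead on log-transformed parameters.
* **M7**: omega ~ Beta(p, q) on (0,1), discretized into K = 10
  equal-probability categories at their quantile medians (the PAML
  convention).
* **M8**: the M7 beta component with weight p0 plus one class at
  omega_s >= 1 with weight 1 - p0.

For the mixtures, the generator of each class is scaled by a common factor so
the *weighted mean* substitution rate is 1; branch lengths and kappa are
held fixed at their M0 estimates — an approximation to joint optimization
chosen for desk-scale runtime, applied identically to M7 and M8 so the
likelihood-ratio test compares like with like. Site-class parameters are
maximized by bounded derivative-free search (Nelder–Mead on transformed
parameters) with seeded random restarts; the M8 search additionally starts
from the fitted M7 solution at the `p0 -> 1` boundary, which guarantees
`lnL(M8) >= lnL(M7)` up to optimizer tolerance. The LRT statistic
`2(lnL_M8 - lnL_M7)` is compared with chi-square critical values at df = 2
(5.991 at 5%, 9.210 at 1%); negative statistics within 1e-4 are clamped to
zero.

Positively selected sites are identified by *naive* empirical Bayes: the
posterior probability of the omega_s class at the MLEs,
`P(k|site) ∝ w_k L_k(site)`, starred at 0.95 and 0.99. Full Bayes empirical
Bayes — integrating over parameter uncertainty — is out of scope, and outputs
label the method accordingly; at desk-scale alignment sizes NEB posteriors
are the dominant term of BEB.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with a
ground-truth manifest for validation:

* One ancestral codon sequence per dataset; every family root and singleton
  descends from it along a deep branch (default 1.0 expected substitutions
  per codon site per lineage, under omega 0.3, kappa 2). All genes are
  therefore homologous — as real NBS superfamily members are — while
  between-family amino-acid identity (roughly 35–50%) stays far below the
  70% clustering threshold and far from distance saturation.
* Within a family, members evolve independently from the family root on a
  star topology, each branch half the pairwise divergence calibrated to the
  target Ks. The calibration converts target Ks to branch length through the
  model's stationary synonymous rate fraction and the expected Nei–Gojobori
  synonymous site count, so the estimator applied downstream is unbiased for
  the planted value up to Monte-Carlo error. A star is the simplest genealogy
  satisfying a single pairwise Ks target; no indels, recombination or gene
  conversion are simulated.
* Domain architectures are emitted as annotation rows (the pipeline consumes
  domain tables, mirroring upstream Pfam/SMART-style scanners), not as
  sequence motifs.
* Promoters are authored in promoter orientation and written into the genome
  strand-aware, so extraction round-trips exactly. When provable planted
  counts are requested (the default), the background is drawn from the
  3-letter alphabet A/C/T: a motif containing G then cannot occur on the
  forward strand by chance, making the planted forward-strand count exactly
  recoverable. Otherwise the background is uniform A/C/G/T.
* Exon counts are planted per gene (1–6) and emitted as contiguous exon
  features subdividing the gene span; intron structure and realistic
  intergenic sequence are not simulated.

The default configuration is a two-species survey scaled to desk size: nine
families (sizes 6,5,4,4,3,3,3,4,2; one TIR family of four and one TIR pair;
one RPW8-flagged family; one family in the second species), Ks targets
clustered on the 0.4–0.5 duplication peak with a recent-duplication minority
at 0.06–0.16, omegas mostly 0.2–0.5 with one mildly positive family
(omega 1.2, Ks 0.10), 8 singletons, 1000-bp promoters, and a genome total of
2000 genes as census denominator. Strongly positive families (omega >= 2)
are deliberately absent from the default: at the divergence needed to show
power in an M7/M8 test they erode amino-acid identity below the 70% family
criterion, so they would never appear as families — a real tension of the
protocol, not of the simulator.

What passing tests on this generator do **not** show: robustness to indels
and alignment error, to domain-annotation noise, to intron-containing gene
structures, or to the scale of real genomes (hundreds of genes, thousands of
promoters). The generator validates the estimators and the plumbing, not the
upstream annotation steps, which are inputs here.

## Problem sizes and numerical settings

Test and validation runs use sizes chosen to exercise every code path while
completing in minutes on one core: oracle cross-checks on 5–8 taxon trees,
3–4 taxon codon likelihoods of 2–3 codons against exhaustive ancestral-state
summation, 200 random codon pairs against brute-force pathway enumeration,
50 random 1-kb promoters against a naive scanner; parameter-recovery runs use
pairs of 2000 codons (10 replicates) and M0 fits on 4 taxa x 500 codons
(5 replicates); pipeline runs use the default synthetic dataset with 40–200
bootstrap replicates. Optimizer settings: Nelder–Mead relative tolerance
1e-9, convergence reported per fit; beta shape parameters are bounded to
[0.02, 50] (the likelihood is flat beyond, and extreme shapes only degrade
quantile accuracy in the discretization); pruning rescales partial likelihoods per
internal node; eigendecompositions are clamped at tiny negative transition
probabilities and rows renormalized.

## Known limitations

* NEB rather than full BEB site posteriors (flagged in outputs).
* Branch lengths and kappa fixed at M0 estimates for M7/M8.
* Center-star multiple alignment is adequate for the low-gap families the
  clustering step produces, but is not a substitute for a modern MSA tool on
  gappy data.
* The "branch model" of the original protocol beyond a single-ratio M0 is
  treated as M0: its published description ("model = 0" with "NS site = 0")
  describes the one-ratio model.
* Bootstrap supports near the midpoint root can attach to either child edge
  of the root; clade counting uses the support stored on each clade's own
  edge.
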