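---
title: "Detecting, dating and characterizing a whole-genome duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, dating and characterizing a whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdkit)
```

## The analysis this package implements

An ancient whole-genome duplication (WGD) leaves two genomic signatures
that survive tens of millions of years of rediploidization. First, most
regions of a non-duplicated outgroup genome are collinear with *two*
regions of the descendant genome, so a dotplot of homologous gene pairs
shows a 2:1 pattern. Second, the surviving duplicate pairs all date to
the same event, so their synonymous divergence (Ks) piles up in a single
peak rather than the decaying curve produced by continuous small-scale
duplication. `wgdkit` implements the full chain of computations that
turns gene positions, coding sequences, homology hits, per-family MCMC
age traces, expression labels and resequencing summaries into those two
signatures plus three follow-up analyses: an absolute age for the event,
a test of which gene classes were preferentially retained in duplicate,
and population-genetic summaries of the descendant species.

The package is organized as an analysis workflow: each numbered script
under `analysis/` is a thin driver over exported functions, and every
computation is unit-tested against an independent oracle (brute-force
enumeration, closed forms, or simulation) in `tests/testthat/`.

## Codon alignment and cleaning

Ka/Ks estimation requires in-frame codon alignments. Protein pairs are
aligned globally (`global_protein_align`; Needleman–Wunsch with affine
gaps, BLOSUM62 by default, gap of length $k$ costing
$\mathrm{open} + k\cdot\mathrm{extend}$) and back-translated onto their
coding sequences (`backtranslate_alignment`), so each amino-acid column
becomes one codon column. Traceback ties are broken deterministically
(diagonal, then gap in the second sequence, then gap in the first), so
alignments are reproducible.

Columns near gaps are unreliable, so `clean_alignment_columns` retains a
column only if it is gap-free and every existing column within three
positions on each side is also gap-free. At the alignment ends the
window is *clipped* by default: a gap-free alignment passes through
unchanged, which is what a reader of "remove positions near gaps"
expects. The stricter variant that also discards the first and last
three columns of every alignment (`drop_ends = TRUE`) is provided
because the convention is genuinely ambiguous; the two variants differ
by at most six columns per alignment. Cleaned alignments then face two gates
(`alignment_passes_filters`): strictly more than 150 aa of cleaned
columns, and the cleaned length must cover at least half of the ungapped
length of *both* proteins.

## NG86 Ka/Ks

`estimate_ka_ks` implements the Nei–Gojobori (1986) counting estimator
with Jukes–Cantor correction:

* Each codon contributes synonymous sites equal to the fraction of its
  nine single-nucleotide changes that preserve the amino acid, averaged
  over the two sequences. Changes creating a stop codon are counted as
  nonsynonymous, which keeps $S + N = 3\,\times$ codons exactly.
* Differences between two codons are resolved over all minimal
  mutational paths with equal weights; paths passing through a stop
  codon are excluded, and a codon pair whose every path is blocked is
  skipped and counted in `n_skipped`.
* $K_s = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p_S)$ and likewise $K_a$. When
  $p_S \ge 3/4$ or $p_N \ge 3/4$ the pair is flagged `saturated` instead
  of raising; flagged pairs are excluded from distribution summaries.

The per-codon site counts and the path-averaged difference counts for
all 61×61 sense-codon pairs are precomputed once per session, which
makes the estimator a table lookup; the test suite checks every cell of
those tables against an independent recursive path enumerator.

We chose NG86 over a maximum-likelihood codon model deliberately: it is
transparent, exactly oracle-checkable, and the downstream uses — window
filters and distribution shapes — are insensitive to the few-percent
differences from ML estimates. All Ks windows are configurable so users
calibrating against an ML tool can compensate, and externally computed
Ks tables can be fed to every downstream function (they all accept
plain data frames).

`cluster_duplication_events` deduplicates pairwise Ks into one estimate
per duplication event: genes sharing any pair with Ks ≤ 5 form a family
(connected components), and average-linkage clustering inside each
family emits one event per merge, at the merge height — a family of
$n$ genes yields exactly $n-1$ events. Average linkage is the
convention of the deduplication literature this follows; the linkage
and the 5.0 threshold are both arguments.

`ks_distribution_mode` estimates the peak as the argmax of a Gaussian
KDE (Silverman's rule-of-thumb bandwidth, 512-point grid on
$[0, \max + 3\,\mathrm{bw}]$), matching the default of R's `density`.

## Synteny and retention calls

`find_homolog_anchors` keeps hits at e-value ≤ 1e-10 and, by default,
only the best hit per query gene. `chain_collinear_blocks` finds
maximal-scoring chains of anchors per scaffold pair and orientation by
dynamic programming over rank-sorted anchors: ranks must be strictly
monotone on both genomes (increasing focal ranks for `same`
orientation, decreasing for `inverted`), consecutive anchors may skip
at most 25 intervening gene ranks, chains score
$(\text{anchors}) - 0.05\times(\text{total rank gap})$, and blocks
below 5 anchors are discarded. The 5-anchor/25-gap defaults are the
documented conventions of the standard collinearity scanner; both are
exposed. Chains are extracted greedily by score and never share
anchors; the test suite proves optimality of the extracted chain
against exhaustive enumeration on instances up to 12 anchors.

`classify_orthology` turns blocks into orthology groups: an outgroup
gene anchored in one block is a 1:1 group and its focal partner a
*non-retained* gene; anchored in two blocks with two distinct partners
it is a 1:2 group and both partners are *WGD-retained duplicates*; in
three or more blocks (possible with decoy hits or tandem arrays) it is
excluded and logged rather than guessed. Focal genes are categorized
A (syntenic), B (homologous only) or C (no homology).
`detect_tandem_duplicates` flags runs of adjacent genes on one scaffold
whose best hits point at the same outgroup gene, provided at least one
member is syntenic.

## Consensus dating

The age of the WGD is estimated as a meta-analysis over per-family
Bayesian node-age estimates; running the MCMC itself is out of scope —
traces are inputs (`read_mcmc_trace` reads the common tab-separated log
dialect). `assemble_dating_families` applies the window rules that
define a datable family: duplicate pairs with Ks 0.2–0.6, an outgroup
ortholog at Ks 0.5–1.2, and one ortholog per additional clade at Ks
0.05–0.30, with ties among candidates broken by lowest Ka and then gene
id; a cleaned alignment of at least 100 aa is required when lengths are
supplied. Each trace is summarized by its post-burn-in medians
(burn-in 1000 samples of 10,000) after screening: every statistic must
reach an effective sample size of 200, with ESS = $N/\mathrm{ACT}$ and
the autocorrelation time summed to the first negative autocorrelation
(the usual trace-analyzer convention; the threshold, not the estimator
bit pattern, is what matters, and it is configurable).

`consensus_age` is the KDE mode of the per-family medians.
`bootstrap_ci` resamples families with replacement 1000 times, takes
the KDE mode of each resample, ranks the modes, and reports the 26th
and 974th as the 95% CI. For general $B$ we use ranks
$\lceil 0.025B\rceil + 1$ and $B - \lceil 0.025B\rceil - 1$, the rule
that reproduces 26/974 at $B = 1000$. Under the generator's conditions
(true age 66 Ma, between-family sd 3 Ma, 204 families) the acceptance
suite measures a mean consensus within 1 Ma of truth and CI coverage
statistically consistent with 95% over 200 replicates.

## Enrichment

`fisher_exact_one_sided` computes the exact hypergeometric right tail
$P(X \ge a)$ with log-factorials. The direction question deserves
honesty: the published contingency values we benchmark against are
reproduced *only* by the one-sided (enrichment) test with a Bonferroni
factor of 2 — the two-sided test does not round to the same numbers —
so one-sided-greater with $m = 2$ is the default and a two-sided flag
is provided. This is an inference from the arithmetic, not a claim
about authorial intent, and it is surfaced here rather than buried.

`go_enrichment_elim` implements the elim decorrelation: terms are
tested children-before-parents; when a term is significant at the elim
threshold (default 0.05, configurable — the reporting cutoff is the
natural choice where none is stated), its study genes are removed from
all ancestors before those are tested. With threshold 0 the procedure
reduces exactly to classic Fisher, which the tests assert. Classic
p-values and their Benjamini–Hochberg adjustment are reported
alongside. The gene universe is the annotated, retention-called gene
set, recorded in the output.

## Population-genetic summaries

For a haplotype matrix (0/1, optional missing), `nucleotide_diversity`
averages per-pair differences per site with pairwise deletion (each
pair uses its own effective length; whole-site deletion is a flag),
`wattersons_theta` is $S/(a_1 L)$, and `tajimas_d` uses the standard
constants ($b_1, b_2, c_1, c_2, e_1, e_2$). D is undefined at $S = 0$
and degenerate at $n = 2$; both are flagged, not raised.
`gene_presence_filter` applies the conservation rule: a gene is present
in a sample iff strictly less than 30% of its positions are ambiguous
(missing or below 5× depth), and conserved iff present in every
sample.

## The synthetic data generator

The generator exists so every pipeline stage can be exercised and its
parameter recovery measured against truth tables. It emulates, at
reduced scale, the structure the analysis assumes:

* a diploid outgroup genome (10 chromosomes, 500 ancestral genes by
  default) and a focal genome descended through one WGD; both
  subgenomes inherit the ancestral gene order and losses delete their
  slot with ranks re-indexed, producing a clean 2:1 dotplot when
  nothing is lost;
* codon evolution by a discrete-event process with equal nucleotide
  exchange rates: proposals creating stops are rejected, synonymous
  proposals always accepted, nonsynonymous ones accepted with
  probability $\omega$, and the process stops after a Poisson number of
  synonymous substitutions with mean `target_ks` × (synonymous sites).
  This matches the NG86 assumptions, so recovery tests are exact in
  expectation: duplicates evolve `wgd_ks`/2 on each branch (0.3 total),
  orthologs `outgroup_ks` in total (1.0);
* class-dependent retention with classes `drought_up` (8%) and
  `background` (92%). The retention probabilities (0.65 / 0.43) were
  fixed once so that the expected fraction of syntenic focal genes in
  retained pairs, $2r/(1+r)$, is about 62% — the regime the analysis is
  designed for — while keeping a 0.22 class gap for power studies;
* tandem copies at rate 0.03 with Ks 0.05 to their source, sharing the
  source's best hit; decoy hits at 1% of true hits with passing
  e-values but lower bitscores, to exercise anchor filtering;
* DE labels per class (up: 30% for `drought_up`, 4% false-positive for
  `background`); per-gene per-sample ambiguity fractions
  Beta(0.5, 10.3), fixed once so that presence in all 19 samples is
  expected for about 87% of genes — the conserved-fraction regime of
  the analysis;
* per-family node ages Normal(66, 3) Ma truncated at zero, 204
  families; neutral coalescent haplotypes (infinite sites, n = 20,
  θ = 5 per 2-kb locus).

One top-level seed drives everything through deterministically derived
child streams; the same seed reproduces every output byte for byte.

What the generator does *not* emulate — and therefore what green tests
do not certify about real data: rate variation across sites and genes,
transition/transversion bias and unequal codon frequencies (NG86 and
the evolver share their absence, which is exactly why recovery is
clean), indels within coding sequence, segmental duplications and
rearrangements beyond whole-genome doubling, recombination within
genes, population structure or demography in the coalescent, and
MCMC pathologies richer than the sticky/stuck traces used in the
screening tests.

## Problem sizes and numerical choices

Default runs use 500 ancestral genes, 150–300 codons per gene, 204
dated families, 1000-replicate bootstraps, and 200–2000 simulation
replicates in the calibration tests; these sizes give stable
distributional checks (binomial/CLT tolerances of three standard
errors) while keeping a full run in minutes on one core. Degenerate
inputs are handled by flags rather than exceptions wherever a flag is
meaningful (saturation, undefined D, constant traces, zero margins);
KDE of a constant vector returns the constant; empty anchor sets,
empty hit tables and empty Ks inputs return empty typed frames.

## Known limitations

Absolute Ks from NG86 deviates from ML codon models by a few percent at
the divergences involved; window edges are configurable for that
reason. The chaining score is a simplification of the full
collinearity score of the standard tool (anchors minus a linear gap
penalty); it reproduces block structure on clean data but is not a
reimplementation of that tool's scoring. The elim implementation
removes study genes of significant children from ancestor annotation
sets, the variant that matches its published description; other
implementations remove all annotated genes. Dating consumes traces; it
cannot diagnose model misspecification upstream of them.
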