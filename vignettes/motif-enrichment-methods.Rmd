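---
title: "Methods: windowed motif scoring and gene-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed motif scoring and gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cisenrich identifies candidate transcriptional regulators of a gene set by
asking, for every transcription factor motif (or ChIP profile) in a
collection, whether the genes carrying the strongest genome-wide binding
evidence for that factor overlap the user's gene set more than chance. This
vignette documents the model, its knobs, and the numerical and design
decisions, in the order the pipeline applies them.

## Window scoring

The genome is tiled into fixed windows — 500 bp every 250 bp by default —
so that every position (except a sub-window chromosome-terminal remainder)
is covered by one or two windows. Fixed-length windows are the atomic
scoring unit; trailing bases that cannot host a full window are left
uncovered rather than creating a ragged short window, because the scoring
model's likelihood is only comparable across windows of identical length.
Chromosomes shorter than one window length become a single short-flagged
window.

Each window is scored for a motif with a generative block model in the
Stubb family. The window sequence is parsed left-to-right as a mixture of
single background letters (probability $1-p$, emitted by an order-$k$
Markov background) and motif blocks of width $W$ (probability $p$, emitted
by the motif's position weight matrix as an equal mixture of the forward
and reverse-complement orientation). The forward dynamic program

$$F(i) = F(i-1)\,(1-p)\,b(x_i) + [i \ge W]\,F(i-W)\,p\,\tfrac{1}{2}\left(\theta_{\mathrm{fwd}} + \theta_{\mathrm{rev}}\right)$$

sums over all parses, so the score integrates weak sites as well as strong
ones instead of counting threshold matches. The reported score is
$\log_2$ of the likelihood ratio against pure background ($p = 0$), with
$p$ maximised over $[0, 0.5]$; it is therefore non-negative, and zero for
windows shorter than the motif.

Numerical and algorithmic choices:

* **Odds-space DP.** The recurrence is computed on
  $R(i) = F(i)/\prod_{j \le i} b(x_j)$, so the final value is the
  likelihood ratio directly and stays in double range for ordinary
  windows; a window whose ratio exceeds $10^{200}$ is re-evaluated in log
  space.
* **Optimising $p$.** Expectation–maximisation with
  $p \leftarrow \mathbb{E}[\#\text{blocks}] / \mathbb{E}[\#\text{segments}]$
  from a forward–backward pass, initialised at $p = 0.01$, tolerance
  $10^{-6}$ on $p$, at most 200 iterations, clamped to $[0, 0.5]$. If the
  likelihood ever decreases (or overflows), the maximisation falls back to
  golden-section search on the log likelihood ratio.
* **Screening.** The derivative of the likelihood ratio at $p = 0$ is
  $\sum_i O_i - L$, where $O_i$ is the block/background odds of the block
  ending at position $i$. When it is non-positive — the case for the vast
  majority of genomic windows — the optimum EM converges to from its small
  starting value is $p = 0$ and the score is 0 without iterating. This
  makes genome-scale scoring practical without changing any score.
* **Strand symmetry.** Block emissions are strand-symmetric by
  construction, but a Markov background of order $\ge 1$ is not
  reverse-complement invariant, so the raw likelihood ratio of a window
  and of its reverse complement differ slightly. The reported score is
  therefore the mean of the two orientations' scores, which makes
  score(seq) = score(revcomp(seq)) exact.
* **Background model.** Order 2 by default, trained genome-wide with
  add-one smoothing (per-window training at 500 bp is far too unstable).
  A window is scored standalone, so its first $k$ positions fall back to
  the longest available lower-order context. `N` bases emit probability 1
  under both models (they are uninformative), and any block overlapping an
  `N` has emission 0; all-`N` windows are flagged unscorable.
* **Motif regularisation.** A pseudocount of 0.5 is added to every count
  cell before normalising; motif width is capped at 30 by default.

ChIP profiles take a different route to the same representation: the
per-window value is the length-weighted mean of the bedGraph signal over
the window, with uncovered bases counting as zero (read-count semantics).

## Normalisation, conservation and accessibility

Raw profiles are only meaningful as ranks, so each profile is
rank-normalised: the $r$-th best of $N$ scorable windows receives $r/N$,
ties receiving their mean rank (this preserves the rank sum exactly, which
the test suite checks), unscorable windows exactly 1. A window in the top
1% genome-wide thus gets 0.01, and smaller is better everywhere
downstream.

Because a G/C-rich motif scores well in G/C-rich sequence for composition
alone, the G/C variant first splits scorable windows into 20
equal-population bins of G/C fraction (computed over non-`N` bases) and
rank-normalises within each bin. Equal-population rather than equal-width
bins keep the within-bin rank denominators comparable; bin sizes differ by
at most one window, larger bins taking the lower G/C values, and windows
tied on G/C are ordered by window index so the partition is deterministic.
With one bin the procedure is bit-identical to standard normalisation.
Both normalisations apply to motif and ChIP profiles alike.

When orthologous window scores from related species are available, the
reference profile can be replaced by a weighted average across species
before normalisation, so conserved motif presence outranks
reference-specific signal. Weights default to each species' root-to-leaf
path length in the supplied Newick tree, normalised to sum to one (a
degenerate all-zero-length tree falls back to equal weights), and explicit
weights are accepted — the scheme is deliberately pluggable since several
weighting conventions are in use. Species lacking an ortholog for a window
are dropped for that window and the remaining weights renormalised. The
cross-species window mapping itself is the caller's responsibility.

An accessibility track (DNase/ATAC) can then mask the normalised profile:
the threshold is the value at the $\lceil 0.10 N \rceil$-th highest
accessibility rank, windows at or above it keep their value, and all
others are set to exactly 1 ("no binding"). Ties at the threshold are
retained, so the kept fraction can slightly exceed 10%. The percentile is
taken on raw accessibility values, not on their ranks.

## From windows to genes

Regulatory regions come in three flavours: fixed strand-aware spans around
the TSS (defaults 5 kb upstream / 2 kb downstream); nearest-TSS, the 1-D
Voronoi partition of each chromosome by TSS position (exact-midpoint ties
go to the lower-coordinate TSS); and gene territory, the gene body
extended halfway across the gap to the nearest non-overlapping neighbour
on each side. For territories the left extension takes the floor and the
right the ceiling of the half-gap, so adjacent territories tile exactly;
with no neighbour the territory runs to the chromosome end, the natural
no-competitor limit of the half-gap rule. Overlapping neighbours are
skipped when measuring gaps.

A window belongs to a region iff its midpoint falls inside it. With the 2×
overlapping tiling, overlap-based membership would double-count windows;
the midpoint gives each window one location, and makes nearest-TSS
assignments a strict partition.

Per gene, $P_g$ is the best (minimum) normalised score among its $w_g$
region windows and

$$S_g = 1 - (1 - P_g)^{w_g},$$

the probability that the minimum of $w_g$ independent uniform draws would
beat $P_g$ — i.e. a small-region hit is worth more than the same hit found
in a large region. $w_g$ counts all windows in the region, including
accessibility-masked ones: carrying value 1 they can never supply $P_g$,
but they still describe the searched extent. (The alternative reading, in
which only windows still in play count toward $w_g$, is available via
`score_genes(count_masked = FALSE)`; the default counts them.) Genes with no windows get $S_g = 1$ and can never enter a
target set.

The feature's target gene set is the $K$ genes with the best $S_g$
(default $K = 500$), ties broken lexicographically by gene id, after
restriction to the gene universe.

## The enrichment test

Overlap between a target set (size $K'$ after universe restriction) and a
user set (size $n$) drawn from a universe of $N$ genes is tested with the
upper hypergeometric tail

$$p = \sum_{i=a}^{\min(K', n)} \frac{\binom{K'}{i}\binom{N-K'}{n-i}}{\binom{N}{n}},$$

a one-sided Fisher's exact test for enrichment only. User genes absent
from the universe are dropped with a warning — the universe defines the
sampling frame — and the universe defaults to every annotated gene.
Results are ranked by raw p-value with a display threshold (default
0.05); no multiple-testing correction is applied in the canonical output,
matching the method's convention of ranking by raw p, but `tidy()` adds a
clearly non-canonical Benjamini–Hochberg column for convenience. The
implementation uses `stats::phyper`; the test suite cross-checks it
against an independent explicit tail enumeration to $10^{-12}$.

Configurations (normalisation, conservation, accessibility, region mode,
$K$) are fingerprinted by hashing the canonicalised option list, and a
shared cache lets a batch of configurations reuse window tilings,
background models and raw profiles, so scoring runs once per feature no
matter how many region modes or $K$ values are explored.

## The synthetic benchmark

`make_benchmark_case()` builds a fully synthetic study: an i.i.d. random
genome (default one chromosome of 1 Mb, G+C 0.41 — a typical metazoan
bulk composition), 200 non-overlapping genes of 1 kb with at least 2 kb
spacing on random strands, one sharp random motif of width 8 (85% of
counts on the consensus base per position), and 19 decoys formed by
permuting the planted motif's rows — identical per-column information
content, different sequence — so recovery measures discrimination, not
motif strength. A quarter of the genes receive three consensus copies at
random positions and strands within 2 kb upstream of their TSS, avoiding
gene bodies; a gamma-noise accessibility track covers the planted spans at
roughly ten times background. All randomness flows from one master seed
through named substreams, so every component regenerates bit-identically.

What this emulates is the *logic* of the method: signal planted in
regulatory space, information-matched negative controls, accessibility
aligned with true sites. What it does not emulate is real genome
composition — isochores, repeats, CpG islands, motif clustering in real
enhancers, annotation ambiguity — so passing the recovery benchmark shows
the pipeline's machinery is sound, not that any particular biological
dataset would yield a given enrichment.

The recovery check itself: across 20 master seeds, scoring the 20 motifs
genome-wide, building top-100 target sets over 5 kb-upstream regions and
testing the planted gene set, the planted motif must rank first with a
p-value at least $10^6$-fold smaller than the median decoy p-value in at
least 18 of 20 seeds. At these problem sizes (about 4,000 windows × 20
motifs per seed) a seed takes a few seconds, which keeps the whole suite
comfortably interactive; the margin is typically many orders of magnitude
wider than required.

## Degenerate inputs and edge behaviour

* All-`N` windows: unscorable, normalised value exactly 1, excluded from
  G/C binning.
* A profile with no scorable windows, a G/C binning with fewer scorable
  windows than bins, an empty universe, or an empty intersected user set:
  errors, not silent results.
* A uniform accessibility track retains everything, with a warning.
* Fixed regions with zero extent on both sides are rejected.
* Report p-values are printed in scientific notation with 3 significant
  digits; re-reading a detail file reproduces counts and p-values at
  printed precision.

## Limitations

The scorer is a single-motif model: no joint multi-motif architecture, no
position-specific priors, no dinucleotide dependencies. One TSS per gene
id is assumed — isoform disagreement must be resolved upstream. Ortholog
window mapping is an input, not something the package infers; and the
phylogenetic weighting is one defensible convention among several, which
is why it is pluggable.
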