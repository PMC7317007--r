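---
title: "Plastome structure and the phylogenetic marker survey: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structure and the phylogenetic marker survey: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomarker)
```

## What the package computes

plastomarker operationalizes the comparative half of a plastome
(chloroplast genome) study at the genus scale: given one annotated
reference plastome and a whole-plastome multiple alignment of related
taxa (typically 15--20, the scale of a subfamily survey), it

1. determines the quadripartite architecture of the reference — large
   single copy (LSC), small single copy (SSC) and the two inverted
   repeats (IRa/IRb) — and summarizes composition per region;
2. screens coding sequences for pseudogene symptoms;
3. cuts the alignment into three marker classes — protein-coding
   sequences (cpCDS, pseudogenes included), non-coding genic regions
   (cpNCDS: tRNA/rRNA genes and the full exon+intron spans of
   intron-containing genes) and intergenic spacers (cpIGS);
4. computes per-marker diversity and tree-based informativeness
   metrics, ranks markers by a weighted mean of relative values, and
   assembles top-*k* concatenated datasets;
5. profiles nucleotide diversity in sliding windows; and
6. proposes PCR primer pairs for markers short enough for single-pass
   Sanger sequencing.

Everything is testable offline because the package ships a sequence
simulator that evolves marker-structured alignments along a known tree
with known per-marker rates — the ground truth every pipeline stage is
checked against.

## Inverted-repeat detection

Plastome IRs are two exact reverse-complement copies of one block,
typically tens of kb. `find_inverted_repeat()` finds the
maximal-length pair of disjoint intervals `I`, `J` on the circle with
`seq(I) = revcomp(seq(J))` by seed-and-extend: 21-mer matches between
the sequence and its reverse complement are grouped by anti-diagonal
(`i + j` constant along a reverse-complement repeat), chained into
runs, and extended base-by-base to maximality. Exact identity is
required — no mismatches — which matches how IR boundaries behave in
plastomes whose two copies are kept identical by gene conversion;
detecting small *diverged* repeats (sub-kb, mismatch-tolerant) is out
of scope. The longer gap between the two copies is labelled LSC, the
shorter SSC. Ties between equally long candidate pairs are broken by
minimal SSC length, then smallest start coordinate, so results are
deterministic and rotation of the circular input only shifts
coordinates. The default `min_len = 1000` bp sits far below real IR
lengths and far above chance repeats at plastome size. With no
qualifying repeat a degenerate partition (LSC = whole genome) is
returned with a warning rather than an error, since IR-free plastomes
exist.

The brute-force cross-check (an all-pairs anti-diagonal scan) is
quadratic and only feasible on small genomes; the test suite runs it
on planted quadripartite circles of 2--4 kb, and the planting routine
guards its region boundaries so the planted repeat is *exactly*
maximal.

## Site statistics and distances

Gap handling is **pairwise deletion** throughout: a site drops out of
a comparison only for the sequence pairs where it is gapped or
ambiguous. This keeps ragged plastome alignments comparable across
windows and markers, but note that tools defaulting to complete
deletion (dropping a column for all pairs if any sequence is gapped)
will report different absolute values of nucleotide diversity on gappy
alignments. Ambiguity codes are treated as missing, never fractionally
expanded.

* A column is *variable* if at least two distinct unambiguous states
  remain after exclusion, and *parsimony-informative* (PIS) if at
  least two states are each carried by at least two taxa.
* The Kimura two-parameter (K80) distance between two rows is
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` and `Q` the
  transition and transversion proportions over compared sites. When
  the logarithm's argument is non-positive the pair is *saturated*:
  `k80_distance()` raises a typed condition, means drop the pair, and
  the distance matrix feeding tree building imputes twice the maximum
  defined entry (with a warning) so that inference can proceed on
  alignments containing a few runaway pairs.
* Nucleotide diversity is the mean over unordered pairs of
  (differences / compared sites); the sliding-window profile uses
  800-column windows every 200 columns by default, the window
  geometry of standard plastome hotspot scans. Windows are laid on
  alignment columns; when a column map is available each window also
  reports the reference coordinate of its start. The final partial
  window is dropped; an alignment narrower than one window falls back
  to a single whole-alignment window with a warning.

## Alignment masking and marker partition

Before cutting markers, columns whose gap-plus-ambiguity fraction
*exceeds* the threshold (default 0.8, i.e. "more than 80% of taxa")
are stripped; removed indices are returned so coordinates can be
audited. Marker intervals are defined **after** masking. The column
map sends each ungapped reference position to its alignment column;
a contiguous reference interval maps to the full column span between
the images of its endpoints, so insertion columns relative to the
reference stay inside the enclosing marker and re-extracting the
reference row from a cpCDS marker reproduces the annotated CDS
exactly (a tested invariant).

Design choices where annotation conventions leave room:

* cpIGS boundaries come from **gene spans** (min start to max end of
  all of a gene's parts), not CDS-only spans; spacers are named
  `upstream-downstream` in reference orientation.
* A cpNCDS span may contain a nested CDS (the classic trnK intron
  hosting matK): both markers are emitted, so columns can be shared
  *across* classes but never within one.
* On a circular reference the wrap-around spacer is emitted last as a
  single marker with two column intervals; the reference is otherwise
  linearized at position 0 (the usual convention after stripping one
  IR copy to avoid double-counting duplicated genes).
* Markers retaining fewer than 4 taxa with data are flagged unusable
  for tree metrics — trees on fewer than 4 leaves have no internal
  edges, so bootstrap support and RF distance are undefined.

## Tree engine, supports, RF distance

The built-in engine is neighbor joining over K80 distances, with
nonparametric bootstrap: columns are resampled with replacement to the
original width, the tree is rebuilt per replicate, and the support of
each internal edge of the point-estimate tree is the percentage of
replicates containing the same bipartition. Replicate `r` draws from a
substream derived from `(seed, r)`, so runs are reproducible and
replicates are stable under code reordering. Internally, resampling is
implemented as column *reweighting* — pair counts are one weighted
cross-product of stacked base indicators — which is algebraically
identical and much faster at survey scale. Occasional negative NJ
branch lengths are clamped to zero with the deficit moved to the
sibling edge.

This deliberately replaces maximum-likelihood inference: NJ is fast
enough to bootstrap hundreds of markers in a test suite, and every
consumer of trees also accepts externally computed newick files (with
support as internal node labels), so users wanting ML can feed their
own trees into the same metrics and ranking.

Robinson–Foulds distance is the size of the symmetric difference of
internal bipartition sets; operating on bipartition sets means
polytomies need no special casing. When a marker has dropped taxa, the
full-plastome comparison tree is pruned to the marker's leaf set before
the RF computation.

## Marker ranking

The informativeness score is a weighted mean of min-max-rescaled
("relative") metrics: variable sites (weight 1), mean bootstrap
support (weight 2), and RF distance to the full-plastome tree
(weight 3, *inverted* so that agreeing with the genome-scale tree
scores high):

    score = (1*r_var + 2*r_bs + 3*r_dist) / 6,  each r in [0, 1].

Min-max normalization over the ranked set is the package's
operationalization of "relative values"; the bounds may also be
supplied explicitly, which matters when ranking a printed subset of a
larger survey whose global ranges are known. Ranks are dense in
descending score; ties break by raw variable sites, then name. If a
metric is constant across markers its relative value is 0 for all —
with all metrics constant, all markers share rank 1 (with a warning).
The ranking is scale-invariant in each raw metric and monotone in each
metric holding the others fixed (both tested).

The size filter for primer design keeps markers whose **mean ungapped
length** is below the threshold (default 900 bp, a practical single-
pass Sanger amplicon bound); aligned length would overstate gappy
markers.

## Primer picking

The picker is a documented simplification, not a thermodynamic design
tool: all 18–24-nt substrings of the 200 bp flanks are screened with
hard constraints (GC 40–60%, Tm 57–63 °C by
`Tm = 64.9 + 41*(GC - 16.4)/len`, no homopolymer of 5+, product
≤ 1100 bp containing the whole target), and the feasible pair
minimizing `|Tm - 60| + |GC - 50|/10` summed over both primers wins.
There is no nearest-neighbor Tm model and no dimer check; published
primer tables are used as *data* for amplicon-location tests
(`locate_amplicon()` requires unique binding sites and counts both
primers in the product), not as outputs to reproduce.

## The simulator and what passing tests mean

`simulate_alignment()` draws a root sequence marker-by-marker and
evolves it along a known tree under the exact K2P transition
probabilities per branch (closed-form matrix exponential, not event
simulation), with a per-marker rate multiplier scaling all branch
lengths; `kappa` defaults to 2 and base composition to equal. Trees
come from sequential random attachment with exponential branch lengths
(mean 0.05 substitutions/site). Optional indels (Poisson per branch,
geometric lengths of mean 3, insertion/deletion equiprobable) are
applied on the tree and inherited by descendants, so gap patterns are
phylogenetically coherent. The first taxon doubles as the annotated
reference; with `indel_rate = 0` its row is ungapped.

The default marker plan emulates a 17-taxon survey with twenty markers
of the three classes, one strongly accelerated 1,800 bp "hot" marker
(rate ×4) against a 300–1,500 bp background at rates 0.2–1 — the
ground-truth best marker for recovery tests.

What the simulator does **not** emulate: within-marker rate variation
(no gamma), compositional heterogeneity, inversions/translocations,
alignment error (rows are generated aligned), or sequencing error.
Passing recovery tests therefore shows the pipeline's statistics and
ranking behave correctly under their own model assumptions, not that
they are robust to misalignment or model violation in real data.

Two recovery properties in the acceptance battery are worth an honest
caveat, and the test suite reports their actual rates rather than
papering over them. First, a several-fold-accelerated marker need not
rank first when the background markers are themselves informative: at
these tree depths a ×4 marker pushes pairwise divergences into the
K80 saturation region, which degrades its own tree (and hence the
weight-2 and weight-3 terms), while many background markers already
agree perfectly with the full-genome tree. Second, exponential branch
lengths occasionally produce internal edges expecting only a handful
of substitutions across the whole alignment; no distance method can
recover those reliably. Both are properties of the study conditions,
not tunables, so the corresponding checks are left to fail where they
fail.

## Problem sizes and determinism

The shipped tests run entirely on simulated or hand-built data: unit
fixtures of 2–17 taxa and up to a few kb, oracle batteries of a few
hundred random alignments at toy size, planted-IR genomes of 2–12 kb,
and the recovery batteries at the default 17-taxon/20-marker scale
with bootstrap B = 100 over 20 seeds — sizes chosen so the whole suite
exercises every code path at survey-realistic shape while staying
desk-scale. Pipeline defaults (mask 0.8, windows 800/200, B = 1000
full / 100 per marker, weights 1/2/3, top-5/top-10 subsets, 900 bp
primer cutoff) mirror common practice for genus-level plastome
surveys. All randomness flows from one master seed through named
substreams; two runs with the same config and seed produce
byte-identical report files, and the manifest records config, seed,
package version and collected warnings.

## Known limitations

* IR detection requires exact copies; diverged or sub-kb IRs are not
  found (by design).
* K80 only; no GTR/gamma distances or ML/Bayesian engines (external
  trees are accepted instead).
* Pairwise deletion makes absolute diversity values differ from
  complete-deletion tools on gappy alignments.
* The pseudogene screen is structural (stops, frame, start/stop
  codons, optional expected-length check at 50%); it does not model
  sequencing error or RNA editing.
* The primer picker is a screen, not a replacement for dedicated
  design software.
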