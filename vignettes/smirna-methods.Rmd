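---
title: "Models and methods behind the smirna pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the smirna pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smirna)
```

`smirna` reimplements, as one tested R package, the analysis chain used in
plant small RNA sequencing studies of stress response: read filtering,
priority-based annotation, known-miRNA quantification with isomiR
profiling, hairpin-based novel miRNA discovery with miRNA* validation,
exact-test differential expression across genotypes and tissues,
complementarity-based target prediction with degradome confirmation, and
Livak 2^-ddCt qPCR analysis. This vignette describes the models and the
choices behind them; the worked example lives in the README.

## The synthetic study and what it emulates

Every stage is exercised against a self-consistent synthetic study built by
`generate_genome()` and `simulate_libraries()`. The study design mirrors a
drought experiment on three rice varieties: two drought-tolerant and one
drought-susceptible genotype, two tissues (leaf, stem), and two conditions
(control, drought), giving 12 single-replicate libraries. Single replicates
are the default deliberately: the exact test below is designed for exactly
this replicate-free regime.

The generator plants, into a random 100 kb genome:

* **Known miRNA loci** (default 16), each a hairpin of a 21 nt GC-rich
  mature arm, an 8-15 nt loop and the reverse-complement star arm, with
  mature and precursor sequences exported as reference sets. Baseline
  expression means span the high (TPM > 10,000), moderate (100-10,000) and
  low (< 100) bands so that expression classification is exercised at both
  band edges.
* **Novel miRNA loci** (default 10) absent from every reference, so they
  surface as unannotated tags. Construction is never trusted: each planted
  locus is excised and folded through the discovery module itself and must
  pass all five candidate conditions, otherwise it is redrawn. Two loci
  additionally receive reads from the opposite genomic strand, emulating
  hairpins transcribed from both strands of one locus.
* **ncRNA loci** (rRNA, tRNA, snRNA, snoRNA) from alternating GenBank-like
  and Rfam-like sources, repeat intervals, and three-exon gene models, which
  donate degradation fragments in sense and antisense orientation.
* **A synthetic transcriptome** (not embedded in the genome — target
  prediction and genomic annotation are deliberately decoupled so neither
  interferes with the other) carrying miRNA target sites with designed
  expectation scores, plus a fabricated GO-style annotation table.

Libraries contain, per their configured fractions of depth: miRNA reads with
negative-binomial counts (dispersion 0.01 by default; 0 gives Poisson)
around the planted means scaled by the planted fold multipliers; isomiR
end-variants of known matures drawn from the precursor context with ±1-2 nt
shifts (the annotated mature carries 70% of the mass); ncRNA, repeat, exon
and intron fragments; unannotated background tags; and all six junk
classes, each read 50 nt with the 3' adapter. The census the simulator
writes is the exact emitted composition, which makes it an oracle for the
filter report and the annotation distribution.

The planted differential design: four known loci carry the
tolerant-down/susceptible-up contrast motif in leaf (x8 both ways), three
are drought-induced x8 everywhere, one repressed x8 everywhere. The x8
magnitude is chosen once so the motif survives the compositional shift of
TPM normalisation: planting strong fold changes into a finite library
changes the library total itself, which deflates observed fold changes by
up to ~0.2 log2 units in the susceptible libraries; at x8 (3 log2 units)
the |log2FC| >= 2 call threshold retains a comfortable margin under the
count noise, while weaker plantings (for example x5, only 0.3 log2 units of
margin) would make end-to-end detection a coin toss. Real tolerant versus
susceptible contrasts are often weaker on the susceptible side, which is
exactly what the relaxed (>1.5-fold, sub-threshold) contrast rule is for;
the strict motif is planted so that recovery is a sharp, reproducible test.

On the noise-free discovery fixture (planted hairpins and their stars
only), recovery is exact. On the full noisy study, regions densely tiled by
degradation fragments — introns especially — can occasionally assemble a
chance hairpin whose "star" support is just another fragment, so the
star-gated novel set can rarely contain one such extra locus. This is a
property of hairpin-based discovery on fragment-rich input, not of the
synthetic data; real pipelines inherit it too.

What passing on this synthetic study does *not* show: the generator has no
sequencing errors, no multi-mapping beyond the planted palindromes, no
RNA editing, and genome-scale realism is not attempted. Results on real
libraries depend on reference completeness and sequencing quality in ways
the synthetic study cannot probe.

## Preprocessing

Reads are assigned to exactly one class, in a fixed order: low quality
(mean Phred < 20 or more than 10% of bases below Phred 10), no 3' adapter
(no exact match of the adapter's first 8 nt), no insert (adapter at
position 1), 5' adapter contamination (5' adapter seed inside the trimmed
insert), post-trim length outside 18-30 nt, and poly(A) (insert at least
80% A or containing an 8 nt A run). Survivors are trimmed and collapsed to
unique tags with summed counts. The quality, adapter-seed and poly(A)
thresholds are conventional defaults — the protocol this mirrors names the
classes but not the thresholds — and all are configurable through
`preprocess_params()`.

## Annotation priority and known-miRNA counting

Each tag receives exactly one category by the priority rRNA > snRNA >
snoRNA > tRNA (within a class, a GenBank-like source outranks an Rfam-like
one) > known miRNA > repeat > exon > intron, with sense outranking
antisense within exon and intron (the ordering of sense versus antisense is
a declared choice; the priority source does not specify it). A tag counts
toward a known mature miRNA when it is an exact substring of a precursor
and overlaps the annotated mature interval by at least 16 nt, overhangs
permitted — this single rule is also what groups ±1-2 nt isomiRs with
their annotated mature. TPM is count x 10^6 / library clean-read total, and
the 10,000 and 100 TPM band edges are read inclusively into the moderate
band.

## The folding model and the five candidate conditions

Novel candidates come from unannotated, intronic and exon-antisense tags
with at least 5 supporting reads. Tag hits are clustered into loci (30 nt
gap), and each locus is excised in both registers (tag on the 5' or the 3'
arm) over several precursor extents (40, 70, 110, 150 nt on the star side,
bounded by the 150 nt flank limit); the best-scoring draft is kept.
Scanning extents rather than folding one fixed 300 nt window matters
because the folding model is a Nussinov-style maximal pairing with per-pair
pseudo-energies G:C = -3, A:U = -2, G:U = -1 kcal/mol and a minimum hairpin
loop of 3 nt: in a long window the optimiser will pair essentially
everything, and a genuine but modest hairpin can be buried by its context.
The model is deliberately self-contained and deterministic — exact dynamic
programming with a reproducible traceback — so every stability threshold in
the package is testable without external folding binaries. It is *not* a
thermodynamic nearest-neighbour model: loops cost nothing, stacking earns
nothing, and energies are on a pseudo-kcal/mol scale that only supports
comparisons within the model.

The five conditions on an evaluated draft:

1. *Arm placement* — the mature lies wholly on one arm and does not run
   into the terminal loop of its own hairpin.
2. *Star duplex geometry* — the pairing partner of the mature, offset to
   give the 2 nt 3' overhangs of a Dicer duplex on both strands, fits
   inside the window and does not overlap the mature.
3. *Loops and bulges* — no internal loop or bulge larger than 4 nt inside
   the mature:star duplex, and at least 60% of mature bases paired. The
   4 nt and 60% values quantify a qualitative "lacks large internal loops
   or bulges" criterion and are configurable.
4. *Stability* — the duplex hybridisation energy (the summed pair energies
   of mature-involving pairs) at or below -18 kcal/mol. The hybridisation
   reading is used rather than the whole-window fold energy because under
   maximal pairing any 300 nt window folds far below -18, which would make
   the condition vacuous.
5. *Support* — at least 5 reads at the mature anchor, summed across
   libraries, counted with at most 3 nt terminal overhang and no internal
   mismatch.

Candidates passing all five in at least two libraries are *putative*;
detection of a star-arm read under the same counting tolerance promotes
them to *novel*. Candidates at one locus are merged (a perfectly
complementary stem makes the mature map to both strands, so one hairpin can
surface as several mirror candidates, and 1 nt-shifted matures from one
precursor are collapsed to the higher-count variant). A locus is called
bistranded only on an exact antisense mature tag: within the ±3 nt counting
tolerance the star arm itself is indistinguishable from antisense mature
reads, so the conservative exact rule avoids calling every palindrome
bistranded.

One structural fact about this energy model is worth recording because it
shapes the test fixtures: a hairpin that violates *only* the stability
condition cannot exist. Any duplex energy in (-18, 0] with at least 60% of
an 18+ nt mature paired forces G:U wobbles into the stem, which puts both
G and U into the window; every remaining base then has a pairing partner
available, and a maximal-pairing optimiser will pair it and push the energy
past -18. The stability ablation fixture is therefore a composition-capped
locus (one C, one G, seven U inside poly(A) islands) whose excised window
provably folds to exactly -17 kcal/mol; its energy flag fails and the locus
is removed, but the pairing-fraction condition unavoidably fails with it.

## Differential expression

For each miRNA within a (variety, tissue) cell the control and drought
libraries are compared with the conditional exact test for digital counts:
given `x` reads in a library of `N1`, the second count under equal
expression follows
`P(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`, a negative
binomial with size `x+1` and probability `N1/(N1+N2)`, computed in log
space. The two-sided p doubles the smaller tail and caps at 1. This law is
not symmetric in which library is conditioned on — swapping labels can move
a doubled p by several percent — so the reported p-value is the more
conservative of the two conditionings, making the test invariant under
exchanging control and drought labels while remaining a valid p-value.

A miRNA is drought-responsive when |log2FC| >= 2 and p <= 0.05, after a
prefilter requiring TPM >= 1 in at least one member of the pair. Zero
counts receive a 0.5 pseudocount for the displayed fold change only; the
test always sees the true zeros. No multiple-testing correction enters the
calls (matching the criteria this reproduces); a Benjamini-Hochberg column
is emitted for information. Venn-style grouping keys on the mature
sequence, so identical matures from different loci occupy one region, and
cross-tissue flags record common and opposite regulation. Contrast
detection returns miRNAs significantly down in every tolerant variety and
up in the susceptible one (plus the mirror pattern); with `relax = TRUE`
the minority side may be sub-threshold (above 1.5-fold in the right
direction), mirroring how such contrasts present in real data.

## Target prediction, degradome confirmation, qPCR

Target scoring is a psRNATarget-style penalty alignment of the miRNA
against the reverse complement of a transcript window: mismatch +1, G:U
wobble +0.5, gap +2, all doubled within seed positions 2-13 (1-based from
the miRNA 5' end); the expectation is the minimal total penalty over a
gapped dynamic program, scanned over all windows of the miRNA length and
one extra nucleotide. Sites at or below the cutoff (default 3.5; the
served default range is 3.0-3.5) are reported. Note that every achievable
score is a multiple of 0.5 under these weights. The penalty weights
reconstruct the classic served defaults and are configurable, since the
exact server version behind them is not pinned.

A site is degradome-confirmed when a tag's 5' end sits exactly at the
transcript coordinate opposite miRNA position 10 — the canonical slicing
position between positions 10 and 11; tags offset by even ±2 nt never
confirm. qPCR tables are analysed with the Livak method: per replicate,
dCt against the reference gene in each condition, ddCt across conditions
and fold change 2^-ddCt; replicates are averaged *after* the per-replicate
fold change (the mean-of-triplicate-folds convention), not by averaging Ct
first. Adding any constant to every Ct leaves all folds unchanged.

## Numerical and scale choices

Coordinates are 0-based half-open internally and 1-based inclusive in GFF3
I/O. Ties are broken deterministically throughout: the folding traceback
prefers leaving a base unpaired and then the smallest pairing partner;
dominant isomiRs and merged candidates prefer higher counts, then the
lexicographically smaller sequence; known-miRNA assignment prefers maximal
overlap, then the lexicographically smaller id. Degenerate inputs (empty
libraries, empty references, zero planted loci, tags at contig edges)
return empty results or truncated windows rather than failing.

The default test-suite and acceptance scale — a 100 kb genome and 12
libraries of 50,000 reads, with smaller 60 kb / 12,000-read studies for
module tests — was chosen so the full pipeline runs in minutes while every
count-based oracle still has enough mass to be exact; all sizes are
ordinary function arguments.

## Known limitations

The folding model ranks hairpins differently from a thermodynamic folder,
so absolute energies are not comparable to RNAfold outputs (a full folder
could be slotted behind `fold_rna()`'s contract). Exact substring matching
is used for genome mapping and degradome alignment; mismatch-tolerant
mapping is out of scope. tRNA-derived fragments are annotated as tRNA but
not analysed further. GO terms are consumed from a user-supplied table,
never retrieved. The exact test assumes no biological replication;
with replicates a dispersion-based model (edgeR, DESeq2) is preferable.
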