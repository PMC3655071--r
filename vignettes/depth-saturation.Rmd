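---
title: "Read-depth saturation analysis for de novo transcriptome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth saturation analysis for de novo transcriptome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthsat)
```

## The question

For organisms without a reference genome, RNA-seq plus de novo assembly is
often the only route to gene sequences. Unlike genomic coverage,
transcriptome coverage spans several orders of magnitude across genes, so
"how many reads are enough?" has no closed-form answer: it must be measured.
The standard design is a *saturation analysis*: randomize the read library,
cut nested subsets of increasing size (every smaller subset contained in the
larger, so curves differ only by the added reads), assemble each subset
identically, and track assembly statistics and the recovery of conserved
single-copy orthologs as a function of read count. `depthsat` implements
that design end to end, together with a synthetic-data generator that makes
the whole pipeline testable without any sequencing data.

## Read filtration

Whole reads are removed (never trimmed), by three rules applied in a fixed
order; the first failing rule is the recorded reason:

1. **Low quality** — mean Phred score strictly below `min_mean_phred`
   (default 28, so a read averaging exactly 28 passes).
2. **Adapter** — any configured adapter (default: the Illumina TruSeq
   read-1/read-2 adapters) as an exact substring, or a read 3'-suffix
   matching an adapter prefix of at least 12 nt with at most one mismatch.
   The suffix rule targets read-through of short inserts, the dominant
   adapter artifact in paired-end libraries; requiring it at the 3' end
   keeps the chance of a false positive on random sequence negligible
   (~1e-6 per 100 nt read).
3. **Low complexity** — "mostly repeated bases" has no unique definition, so
   we use two conditions, either sufficient: the most frequent single base
   accounts for at least `low_complexity_fraction` (default 0.9) of non-N
   positions, or a homopolymer run covers at least 0.8 of the read. This
   catches polyT-tract artifacts without flagging AT-rich biological
   sequence. Reads with more than 10% N are also rejected here.

Pairs are then resolved: both mates good, keep the pair; both bad, drop
both; mixed, either keep the good mate as an unpaired read
(`salvage_singletons = TRUE`, the choice appropriate for a largest, most
sensitive assembly) or drop it, counting the good mate as a broken pair.
The report's categories always sum to the input read count.

The pipeline randomizes the raw pool first, then filters, then cuts
subsets. Because filtering is pointwise per pair unit, it commutes with
prefix selection, so this is equivalent to subsampling a pre-filtered pool;
cutting from the filtered pool means every requested depth is a count of
*usable* reads. Depths are counted in reads; mates always travel together,
so a subset can exceed a requested depth by one read if the boundary falls
inside a pair.

## The stand-in assembler

Real saturation studies use a production assembler. For a self-contained,
desk-scale pipeline `depthsat` ships a minimal de Bruijn assembler: count
canonical k-mers (strands collapsed, N excluded), delete those observed
fewer than `coverage_cutoff` times, and emit the maximal non-branching
paths (unitigs) of the remaining bidirected graph, discarding contigs
shorter than `min_contig_length` (default 100 nt). The static coverage
cutoff is the parameter of scientific interest: a permissive cutoff (3)
assembles more, noisier sequence; a strict cutoff (10) fewer, longer, and
cleaner contigs — the C3-versus-C10 contrast. Defaults are k = 21 and
cutoff 3.

Loci — an assembler's gene-level grouping of transcripts — are approximated
as connected components of contigs sharing at least one canonical k-mer.

Deliberate limitations: single k only (no multi-k merging), no bubble
resolution, no paired-end scaffolding, no isoform traversal. Consequently
"transcripts per locus" here measures unitig fragmentation, not splice
variation, and the assembler is a stand-in for pipeline shape, not a
competitor to production tools. Externally assembled contigs can enter
anywhere an assembly is consumed via `as_assembly()`.

Determinism everywhere: contigs are emitted in the lexicographically
smaller orientation, sorted by length then sequence, and identical inputs
produce identical assemblies.

## Assembly metrics

`assembly_metrics()` reports transcript and locus counts, total length,
mean, median (even counts: mean of the central pair), N50 (descending-sort
cumulative-sum convention: the length at which the cumulative sum first
reaches half the total), per-million-read rates, and GC. Two GC views are
emitted because they answer different questions: the scalar is pooled over
bases (total G+C over total unambiguous bases), while `gc_histogram()` is
per sequence, computed identically for reads and contigs. The read
histogram is expression-weighted by construction — an abundant gene
contributes many reads but only one contig — so a GC offset between read
and contig distributions is the signature of high-expression genes with
atypical GC.

## Conserved-gene completeness

The completeness scorer asks, for each reference ortholog cluster (one
conserved gene, one protein per reference species), whether the assembly
contains it, and whether full-length:

1. **Translated search.** Every member protein is locally aligned
   (Smith–Waterman, BLOSUM62, gap open 11 / extend 1 — the aligner is
   Biostrings' `pairwiseAlignment`) against all six reading frames of every
   contig. Significance uses the Karlin–Altschul form
   E = K·m·n·exp(−λS) with the published gapped-BLOSUM62 constants
   (λ = 0.267, K = 0.041), m the query length and n the summed residue
   count of all frames; the detection gate is E ≤ 1e-6. The E-value here is
   a detection gate, not a BLAST replica: no length or composition
   corrections are applied, and the cutoff is configurable. A BLAST-style
   exact 5-mer word prescreen skips frames sharing no word with any member;
   at the divergence levels of conserved orthologs a true hit essentially
   always shares an exact 5-mer, and the screen removes ~98% of unrelated
   frame alignments. It can be disabled (`seed_filter = FALSE`), and the
   test suite validates scores against an independent brute-force
   dynamic-programming oracle.
2. **ORF extraction.** A hit is only usable if its coding sequence has both
   a start and a stop codon: from the aligned span, scan 5' in frame for
   the nearest ATG (failing if an in-frame stop intervenes or the contig
   ends first), then translate from that Met to the first downstream
   in-frame stop. Scanning for the *first* stop after the start — rather
   than a stop beyond the aligned span — is deliberate: a mis-assembly that
   introduces a premature stop inside the span then yields a short protein,
   the situation the fifth length class exists to flag.
3. **Best alignment.** Among passing alignments with an extractable CDS,
   the highest score wins; ties break by higher percent identity, longer
   aligned length, then lexicographic contig id (the ordering is a
   documented choice; scores rarely tie in practice).
4. **Size classification.** Member lengths vary, so "full-length" is a
   window, not a point. With S1 ≤ S2 the two shortest members and
   L1 ≥ L2 the two longest, the window is
   [floor(S1·S1/S2), ceiling(L1·L1/L2)] — the spread between the extreme
   members extrapolated one step, admitting proteins that could plausibly
   become the new shortest or longest member (shortest members 80 and
   100 aa give a lower bound of 64 aa). Flooring the lower bound and
   ceiling the upper keeps non-integer bounds permissive symmetrically.
   The extracted protein (stop excluded from the length) is then assigned
   exactly one of five classes: within range with the alignment covering
   at least 90% of the protein (the only class counted as full-length);
   within range with a shorter alignment; longer than the window; shorter
   than the window; or shorter than the window *and* shorter than the
   alignment, the signature of a bridged stop codon. The 90% rule is
   measured in query (reference-protein) residues of the best alignment.
5. Optionally, extracted proteins are compared against a canonical
   proteome, counting a protein only if it matches a canonical entry
   verbatim.

Per depth, the saturation table reports `n_detected` (any passing
alignment), `n_within_length` (classes 1–2) and `n_full_length` (class 1),
which nest by construction.

## The synthetic-data generator

The generator is the ground truth the pipeline is validated against. It
emulates: expression spanning a configurable number of decades
(log-uniform; the true distribution of any real library is unknown, and
log-normal would serve equally behind the same interface), paired-end
~100 nt reads with ~180 nt inserts from a non-strand-specific protocol,
i.i.d. per-base substitution errors, baseline qualities Normal(38, 2)
clamped to [2, 41], and three planted artifact categories — adapter
read-through (the read's 3' end is the adapter, verbatim), polyT tracts
(97% T), and low-quality reads (qualities Normal(20, 3), straddling the
mean-28 threshold from below). Planted artifacts are never corrupted by the
error model, so the filter's recall on them is exactly measurable.
Ortholog clusters are built by copying an ancestral protein per species
with i.i.d. substitutions (default rate 0.05) and terminal
truncation/extension tuned so the longest-to-shortest length spread
averages ~11.8%, matching the variability typical of curated ortholog
sets; one member per cluster is back-translated (uniform synonymous
codons) and embedded between random UTRs as a transcript.

What it does **not** emulate: splice variants, paralogy, strand-specific
protocols, PCR duplicates, quality-by-cycle decay, indel errors, or
coverage bias. Passing tests therefore demonstrate the pipeline's internal
correctness and the qualitative saturation behavior, not performance on
real libraries.

Everything is deterministic given its seed; sub-seeds for stages are
derived from the master seed.

## Problem sizes and numerical choices

The shipped validation workloads are sized for a single desk CPU: the
saturation study uses 60 genes (50 carrying conserved CDSs), 12,000 read
pairs and a 1,200 / 6,000 / 24,000-read ladder — about 2.5×, 12× and 50×
per-gene coverage, chosen so per-gene k-mer coverage crosses the assembler
cutoff between the bottom and top rungs. At those sizes the full-length
count rises from 0 at the bottom rung to all 50 clusters at the top.
Degenerate inputs are handled explicitly: empty assemblies score zero
everywhere with NA means; an all-N sequence has no defined GC; subset
depths beyond the filtered pool abort naming the shortfall; clusters need
at least two members for size bounds.

## Known limitations

* The unitig assembler understates transcripts-per-locus trends of real
  assemblers and cannot reproduce isoform-level behavior.
* The E-value model is uncorrected Karlin–Altschul; absolute E-values
  differ from BLAST's, which matters only near the detection gate.
* The word prescreen is a heuristic; for very divergent clusters
  (substitution rates far above those of conserved orthologs) disable it.
* Saturation depths measured on synthetic libraries transfer to real data
  only qualitatively; real libraries saturate at tens of millions of reads.
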