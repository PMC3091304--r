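---
title: "Methods: fusion-gene detection from paired-end RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion-gene detection from paired-end RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: what the pipeline
assumes, which knobs matter, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open.

## The detection model

A fusion transcript contributes two distinguishable signals to a paired-end
RNA-seq library: *bridging pairs*, whose mates align uniquely inside exons
of two different genes, and *junction-spanning reads*, which align to
neither the genome nor any normal splice junction because they cross the
novel exon–exon boundary. The pipeline uses the first signal to nominate
gene pairs cheaply and the second to resolve the exact junction and — via
the tiling pattern — to decide whether the junction is real.

The central empirical observation behind the tiling filter is that cDNA
fragmentation places genuine junction reads at essentially uniform start
positions across the breakpoint, whereas reads that are systematically
*misaligned* onto a junction sequence pile up at a single position (give or
take 1–2 bp) and anchor almost entirely within one of the two exons.
Misalignment, not PCR duplication, is the operative failure mode: the
mates of stacked junction reads do not themselves stack.

### Alignment contract

Alignment is ungapped, end-to-end, both strands, reporting *all* placements
with Hamming distance ≤ `max_mismatches` (default 3 on 50 bp reads); `N`
counts as a mismatch; qualities are ignored. This is the behaviour of the
short-read aligners of the 50 bp era and makes every downstream count
reproducible to the base. Internally the search is seed-and-verify: a read
with at most *k* mismatches must contain one of *k*+1 exact non-overlapping
seeds (pigeonhole), so seeds of width ⌊L/(k+1)⌋ are matched exactly
(`Biostrings::matchPDict`) and candidate placements verified with
`neditStartingAt`. The test suite holds this implementation to exact
agreement with a naive sliding-window Hamming scan. Reads with indels
simply fail to map; they are not rescued.

A read placing once on the genome and once on a splice-junction sequence
covering the *same* transcript region is one locus, not two — junction
references overlap exon ends, and without this collapse every exon-end read
would be spuriously "multi". Non-spanning junction placements are therefore
projected back to genomic coordinates before loci are counted.

### Filters at the candidate stage

* **Adjacency.** Two genes are adjacent unless a third gene (any biotype)
  lies with both endpoints strictly inside the gap between them. Adjacent
  and overlapping pairs are discarded as probable readthrough. This
  knowingly sacrifices true fusions between neighbours (tandem
  duplications, local inversions) for specificity.
* **Paralogy.** Paralog pairs are supplied as a two-column table (they come
  from curated homology databases in practice); candidates between them are
  discarded as probable mapping errors.
* **Support.** `min_pair_support` defaults to 2 discordant pairs. For
  deeply sequenced libraries (rule of thumb: more than ~8M filtered pairs)
  raising it to 3 keeps the false-positive proportion comparable across
  samples. The choice is never automatic; it is a logged parameter.

### Junction resolution and the tiling rule

For each candidate pair the junction database contains every exon–exon
combination in both orientations (A→B and B→A), each sequence up to
`flank` = 49 bp from each exon (read length − 1, so every spanning
placement is representable). Only reads that aligned *nowhere* are given to
this stage; uniquely aligned reads are never reused as junction evidence.
Hits must span the breakpoint with `min_anchor` = 10 bp on **both** sides.
The published rule says "at least 10 bp to one exon", which a 50 bp read
satisfies trivially on one side; the two-sided reading is the only
interpretation that constrains anything, and it is what we implement. A
read hitting several junction sequences keeps only its minimum-mismatch
hits. Calls need `min_junction_reads` = 2 distinct spanning reads.

The tiling classifier formalizes the qualitative pattern with three
sub-criteria, each logged per call. A junction is an **artifact** iff

1. span of start positions ≤ `artifact_span` (2 bp — "shifted by one to two
   base pairs"), or
2. distinct start positions < `min_distinct_starts` (3 — the smallest count
   distinguishable from a jittered stack), or
3. reads anchored ≥ `min_anchor` on both sides < `min_two_sided_anchor_reads`
   (1 — "almost exclusively aligned to one of the exons").

Inside the default pipeline criterion 3 cannot fire, because the junction
aligner already enforces two-sided anchors; it is retained because the
classifier is usable standalone on hits admitted at a 1 bp spanning
threshold. Calls are prioritized genuine-first, then by distinct starts,
junction reads, pair support, and finally gene ids (a deterministic total
order). Reciprocal A→B/B→A support is reported and flagged, not merged.

### Characterization

*Frame.* A fusion is in-frame if **any** combination of a 5′-partner
transcript containing the fused 5′ exon and a 3′-partner transcript
containing the fused 3′ exon preserves cumulative CDS length mod 3 across
the junction. A junction upstream of the 3′ CDS leaves the whole ORF
intact (promoter swap) and counts as in-frame; a junction past either
coding region, or into a 3′ CDS with no 5′ coding contribution, does not.
"Potential splice variants" is operationalized as skipping any single
internal exon on either side (`splice_variants = TRUE`, off by default,
since no enumeration rule is given). Out-of-frame calls are reported, not
suppressed.

*Expression.* RPKM = uniquely mapped reads / (merged exonic kb × million
mapped reads). Fusion expression is the raw junction-read count plus an
RPKM-style normalization by junction sequence length; both are reported.

*Copy number.* From a segmented log2-ratio profile: `at_cn_transition` if a
boundary with |Δlog2| ≥ 0.3 falls within `transition_window` = 100 kb of
either gene; `amplified` if either gene overlaps a segment with
log2 ≥ 1.0. The original calls were made by visual inspection of 1M-probe
aCGH profiles, so these thresholds are parameters mirroring common aCGH
practice, not claims. The flag is monotone in the window by construction.

## The synthetic-data generator

The generator emulates the data regime the method was built for: a small
multi-chromosome genome (default 4 × 30 kb) with 24 non-overlapping
multi-exon genes (4–6 exons of 80–200 bp, introns 100–300 bp), 56 bp
paired-end reads trimmed to 50 bp, fragment lengths from a truncated normal
around a median of 200 nt (σ = 10; the study's libraries had medians of 100
and 200), independent per-base substitution errors at 0.5%, and an exact
5% of pairs copied from rRNA-like contaminant sequences. All sampling is
driven by one seed; outputs are byte-identical across runs.

Planted structure:

* **Fusions** are specified by partner class (intra/inter), fused exon
  indices, frame target, read counts and junction-read mode. CDS starts are
  placed so the frame target holds *exactly* (verified by an independent
  per-base phase oracle in the tests). Promoter-swap events put both
  partners' CDS downstream of the junction, so the 3′ ORF is intact, and
  silence the 3′ partner's wild-type expression — reproducing the
  exclusive-expression coverage signature.
* **Readthrough decoys** are chimeric transcripts across *adjacent* gene
  pairs, so the adjacency filter is exercised by construction.
* **Paralog decoys** duplicate a gene elsewhere with one substitution every
  12 bp (~92% identity, evenly spaced). The spacing is chosen so that every
  50 bp window differs from the source by ≥ 4 bases: at 95%+ identity a
  window can sit within the 3-mismatch bound, the mates go "multi", no
  candidate forms, and the paralog filter would never be tested. Evenly
  spaced divergence is the package's choice of the weakest decoy that still
  produces uniquely assignable reads.
* **Artifact stacks** are junction reads genuinely copied from a fusion
  junction sequence at near-identical offsets (one draw, ± 1 bp jitter) —
  the observable the filter sees — rather than a simulation of the
  upstream misalignment mechanism itself.
* **Tiling-mode** junction reads draw start offsets uniformly over
  positions with ≥ `min_anchor` overhang on both sides. Offsets with ≤ 3 bp
  on one side would align end-to-end to the genome within the mismatch
  bound and never reach the junction pass, so they are not valid junction
  evidence by construction.
* An exact intergenic duplication between two chromosomes provides
  multi-mapping reads; an overlapping gene pair sharing an exon provides
  ambiguous assignments.

What the generator does **not** emulate: indels, quality-score structure,
GC and positional bias, PCR duplication, intron signal from unspliced
pre-mRNA, breakpoints inside exons, and real genome repeat structure. A
clean pass on synthetic data therefore demonstrates the logic of the
pipeline — coordinate arithmetic, filters, classifier, bookkeeping — not
robustness to every artifact of real libraries.

## Numerical and design choices

* Internal coordinates are 1-based closed (the GRanges convention); GTF I/O
  is 1-based inclusive, the copy-number TSV 0-based half-open (BED-like).
* Adjacency/overlap ignore strand (readthrough and mapping artifacts are
  strand-agnostic at that stage) and are evaluated on gene spans, not
  transcript spans.
* Contaminant filtering removes whole pairs (one contaminated mate
  invalidates the fragment); the mate-level alternative would retain
  half-fragments of rRNA inserts.
* A biotype whitelist for candidates exists but defaults to all biotypes
  eligible — the source procedure records biotype without stating a
  wholesale exclusion.
* Junction reads never rescue candidates below the pair-support threshold.
* Duplicate reads are not removed; the tiling filter addresses the
  identical-start pathology where it matters.
* Ties everywhere break on identifiers, so every output is a deterministic
  total order.

## Problem sizes

The flagship test universe uses 24 genes on 4 × 30 kb chromosomes, five
genuine fusions (two interchromosomal, one out-of-frame, one promoter
swap, two amplified), two readthrough decoys, two paralog decoys, two
artifact stacks, one overlapping pair and ~1,200 read pairs — small enough
to run the complete pipeline in about a minute on one core while exercising
every filter. Oracle suites use 1,000 random reads against ~20 kb of
reference for the aligner and 200 randomized CDS pairs for the frame
predictor; the tiling classifier is measured over 500 seeded replicates.

## Known limitations

Only exon-boundary breakpoints are modelled (the junction database is
exon–exon); gapped/spliced alignment, genomic (DNA-seq) breakpoints and
trans-splicing discrimination are out of scope. The aligner is a
desk-scale reimplementation of the bounded-mismatch contract, not an
FM-index engine; inputs beyond a few megabases belong in an external
aligner, whose SAM output could be adapted upstream of the candidate
stage. Frame prediction trusts the annotated CDS and does not model stop
codons introduced by the junction sequence itself, nonsense-mediated
decay, or novel splice sites.
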