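---
title: "Protein-evidence annotation with prohintr: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-evidence annotation with prohintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prohintr)
```

## Scope and pipeline shape

`prohintr` implements the computational middle of a protein-based genome
annotation pipeline: everything between "a spliced aligner produced
protein-to-genome alignments" and "a gene predictor consumed hints and a
training set". The external binaries themselves (aligner, `etraining`-style
trainer, predictor, metaparameter optimizer) are reached through adapter
hooks and are out of scope; the package ships a deterministic hint-driven
`mock_predictor()` so that every stage, including chunked execution, can be
exercised and verified offline.

The stage order in `run_pipeline()` is: load alignments → score and
classify intron evidence → select round-1 training genes and excise them
with flanks → (trainer hook) → plan chunks → predict per chunk with hints →
merge → evaluate evidence support of the predictions → build the round-2
training set from fully supported predictions with decontaminated flanks →
(trainer/optimizer hooks) → final chunked prediction → merge → summary.
Each stage writes plain-text checkpoints; a rerun resumes after the last
complete stage, and identical inputs give byte-identical outputs.

## The intron evidence model

A spliced alignment chain contributes one candidate intron per pair of
consecutive blocks. Two complementary signals decide its fate:

**Intron border alignment (IBA).** Misplaced splice junctions tend to show
degraded alignment quality immediately next to the junction, so IBA scores
the conservation of the flanking exonic columns with weights decaying away
from the junction. Column k from the junction (k = 1 adjacent) gets weight
$q^{k-1}$; identical columns credit 1, conservative substitutions
`substitution_credit`, mismatches 0. The two sides' weighted means are
averaged, multiplied by `event_penalty` once per frameshift or in-frame
stop codon within the window (both are hallmarks of spurious homology),
and clamped to $[0,1]$. A side with no aligned columns scores 0, which
correctly damps terminal-block artifacts.

**Intron mapping coverage (IMC).** Independent evidence: the number of
*distinct* donor proteins whose alignments map the byte-identical intron
interval (a protein aligned twice to the same locus counts once). Exact
interval agreement between independent donors is very unlikely by chance,
so even two concordant donors are strong support.

Evidence is discarded unless IBA ≥ `iba_min_keep` *or* IMC ≥
`imc_min_keep`, and is high-confidence when IBA ≥ `iba_min_high` *or*
IMC ≥ `imc_min_high`. The OR-combination reflects that the two signals are
independent routes to credibility: deep conservation from a single close
donor, or exact replication across donors. The published description of
this classification names the two scores and the penalty terms but not the
functional form or the thresholds; the exponential-decay credit form and
the defaults below are this package's own concrete choices, and all of
them are exposed in `scoring_config()`.

| parameter | default | units | rationale |
|---|---|---|---|
| `window` (W) | 15 | residue columns/side | ~1 exon's worth of context; junction-proximal columns dominate anyway |
| `decay` (q) | 0.8 | — | weight halves every ~3 columns; column 15 still contributes ~4% |
| `substitution_credit` | 0.5 | — | conservative substitutions are weaker but real evidence of homology |
| `event_penalty` | 0.5 | per event | one frameshift/stop near a junction halves trust, two quarter it |
| `iba_min_keep` / `iba_min_high` | 0.1 / 0.25 | — | keep almost anything with residual conservation; demand a quarter of maximal credit for enforcement |
| `imc_min_keep` / `imc_min_high` | 2 / 2 | proteins | exact replication by two independent donors is sufficient on both counts |
| `cdspart_shrink` | 9 | bp | CDSpart hints are trimmed so approximate block ends do not over-constrain exon boundaries |

Hints derived from the classification follow the predictor's extrinsic
format: intron hints carry `mult` = IMC and source tag `M` (enforced) when
high-confidence, `P` otherwise; CDSpart hints (one per distinct block,
shrunk, 1 bp floor) and start/stop hints (where the chain covers the
protein's terminal residues) are always low-confidence. Column 9 is
exactly `src=<M|P>;mult=<n>;pri=4`.

## Training genes

Round 1 selects, per locus, the best chain whose every intron is
high-confidence, with a clean ORF (length a multiple of 3, no frameshift
or in-frame-stop event) and full terminal coverage, so that the implied
gene structure (blocks plus the downstream stop codon) is a complete,
translatable model. A *locus* is a connected component of same-strand span
overlap — deterministic and cheap, at the cost of occasionally fusing
adjacent genes bridged by a bad chain (such chains rarely survive the
intron filter). Ties on alignment score break by longer CDS, then
lexicographic protein id, making selection order-independent.
Single-exon candidates are admitted (`min_exons = 1`) but reported, since
protein evidence overcalls single-exon genes; excluding them is one flag
away.

Flanking regions should be intergenic: the flank is half the mean training
gene span, clamped to [500, 10000] bp — scale-aware (gene-dense genomes
get short flanks) without letting a few huge genes blow up excision
windows. No published rule exists for this size; the clamp bounds are
conventional gene-finder training practice and configurable.

Round 2 ("iterative training") keeps predictions with *full evidence
support*, operationalized as: every intron matched exactly by an intron
hint, CDS coverage by CDSpart hints ≥ `coverage_threshold` (default 0.8),
and a complete model. The 0.8 default tolerates the deliberate 9 bp
CDSpart shrinkage and modest boundary slack while still demanding that the
bulk of the CDS is evidence-backed. Other predictions are not discarded —
they only *delimit* flanks: `refine_flanks()` shrinks each training gene's
window so it contains no base of any other predicted gene, collapsing to
the gene span (with a logged conflict) when a neighbor overlaps the gene
itself. The round-2 flank is re-derived from the round-2 gene set rather
than reused, keeping the rule self-consistent as the set changes.

## Chunked prediction

`plan_chunks()` tiles sequences longer than `chunk_size` (default 5 Mb)
with stride `chunk_size − overlap` (overlap default 1 Mb); the final
window is clamped to the sequence end and pulled back to full size so
boundary genes see maximal context. Sequences at most `chunk_size` long
are greedily packed, in seq\_id order, into batches of total length ≤
`batch_target` — one predictor invocation per batch keeps file counts low
on fragmented assemblies. The overlap should exceed twice the intron cap
`max_intron_size(G) = floor(3.6·√G)` (a warning is issued otherwise) so
that no plausible gene can span more than one window boundary.

Duplicate removal is the subtle part. Responsibility intervals partition
each sequence (overlaps split at their midpoints); a transcript is kept
from the chunk whose responsibility contains its midpoint provided that
chunk's window fully contains the transcript, else from the lowest-indexed
emitting chunk that fully contains it, else once (lowest emitter) and
flagged truncated. The midpoint rule is deterministic and
order-independent, and makes merged-chunked output *identical* to an
unchunked run whenever every gene span is shorter than the overlap — the
property the test suite verifies against the mock predictor on a ~2 Mb
fixture (500 kb chunks, 100 kb overlap, 100 genes) and that motivated the
whole construction.

## Accuracy evaluation

Matching is CDS-only and coordinate-exact: exon TP over distinct
(sequence, strand, start, end) exons; transcript TP when the ordered CDS
exon lists agree; a gene matches when any of its transcripts does
(reference side for sensitivity, prediction side for specificity), each
item matching at most once. Both readers canonicalize to stop-included CDS
(GTF `stop_codon` features are merged back into the terminal exon), so
dialect differences cannot create 3 bp phantom mismatches.
F1 = 2·Sn·Sp/(Sn+Sp), defined 0 when both are 0. Cross-species summary
tables use the unweighted arithmetic mean rounded half-up to 2 decimals;
applied to the bundled 14-species benchmark table this reproduces the
published average cells for the gene and exon levels (the published
transcript-level average of the multi-donor row is 0.07 off the mean of
its own per-species values, which the package does not attempt to match).
The mono:mult ratio counts only each gene's first isoform (smallest
transcript id), is `Inf` when no multi-exon first isoform exists, and is
reported with the transcript/gene/incomplete counts by
`summarize_gene_set()`.

## What the fixtures emulate — and what they do not

`make_genome_with_genes()` plants genes with canonical structure (ATG,
GT..AG introns, one terminal in-frame stop, exon lengths multiples of 3 so
codons never straddle introns), spread over the whole sequence with
intergenic gaps ≥ 200 bp, on both strands; emitted proteins are exact
translations. `diverge_proteins()` applies flat per-residue substitution
(half conservative within similarity groups, half arbitrary, never
self-hitting, so expected identity is exactly 1 − divergence), and
`induce_alignments()` reconstructs the chains a spliced aligner would
report, with per-block frameshift/stop corruption at configured rates. A
single seeded generator threads through all fixture operations; the same
seed gives byte-identical files.

These fixtures deliberately do **not** model repeats, GC heterogeneity,
alternative splicing, non-canonical splice sites, codon-spanning introns,
alignment boundary errors, or phylogenetically structured divergence.
Passing tests therefore demonstrate correctness of the *computational
stages* (scoring, selection, chunking, merging, evaluation) under clean
conditions, not annotation accuracy on real genomes — the latter depends
on the external aligner and predictor, which are out of scope by design.

## Numerical and degenerate-case choices

* Coordinates are 0-based half-open internally; GFF/GTF/GenBank I/O
  converts to 1-based inclusive at exactly one boundary. The compact
  alignment dialect keeps the internal convention (documented in
  `write_alignments_compact()`); it is this package's own format, standing
  in for aligner-specific residue-level output, and the standard
  miniprot-style GFF is accepted as well (without residue detail, such
  chains contribute to IMC only).
* IBA ties across supporting junctions take the maximum; value-identical
  ties need no break. Evidence tables, hints, plans and merged outputs are
  always sorted by (seq\_id, start, end, feature/strand) so outputs are
  reproducible byte-for-byte.
* Rounding for table summaries is half-up (`floor(x·100 + 0.5)/100` with a
  1e-7 guard against representation error), matching how printed tables
  round, not banker's rounding.
* Degenerate inputs: empty hint sets write a header-only file; an empty
  candidate set aborts training-gene selection with a hard error
  (a pipeline without training genes cannot proceed); windows reaching
  outside a sequence clamp with a logged message; `mult` < 1, inverted
  intervals, mixed-strand transcripts and unknown column classes are hard
  errors at construction.
* Problem sizes in the shipped tests are the package's verification scale:
  fixtures of 30–100 kb with 5–50 genes for unit and recovery tests, one
  ~2 Mb / 100-gene fixture for the chunking oracle, 200 random instances
  for the IMC brute-force comparison and 1000 random geometries for the
  responsibility-partition property.

## Known limitations

* The locus definition (span overlap) can merge genes nested on the same
  strand; splice-graph clustering would be finer but nondeterministic
  under evidence noise.
* Support evaluation treats CDSpart coverage as a proxy for exon-level
  agreement; a prediction can reach 80% coverage with wrong exon
  boundaries if its introns happen to match.
* `compare_gene_sets()` counts exon TP over distinct exon coordinates, not
  per-transcript occurrences; with heavy isoform duplication the two
  conventions differ.
* The GenBank reader only parses records this package writes; it is not a
  general flat-file parser.
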