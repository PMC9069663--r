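---
title: "Exon-centric spliced alignment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-centric spliced alignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonalign)
```

## The problem

Homology-based gene annotation often starts from a protein whose
exon/intron structure is already known and asks where each exon lies on a
genomic target that harbours a single homolog. Conventional spliced
aligners optimise a global alignment of the whole protein and only
implicitly commit to splice sites; when the goal is an exon-by-exon
comparison — for instance to build one profile HMM per exon, or to use
exon architecture to tell paralogs apart — the exon boundaries themselves
are the quantity of interest, and they should be placed where a credible
splice signal exists, in a way that preserves the reading frame.

`exonalign` implements that exon-centric strategy. The query is a protein
*annotated by exon boundaries* (amino-acid spans plus the codon phase at
each internal boundary); the output is a gene model with refined genomic
exon spans, the complete predicted protein, and one peptide per exon with
junction-split residues excluded — exactly the shape downstream exon-wise
MSA/HMM construction needs. Genes with very large introns and genes
scattered across several assembly fragments are first-class inputs.

## Pipeline stages

1. **Seeding.** Each exon peptide is aligned locally (BLOSUM62, affine
   gaps 11/1) against the three forward frame translations of each target
   region — and of its reverse complement, so contigs of unknown strand
   are reoriented automatically. Within each region the best-scoring
   chain of hits consistent with exon order is kept; chain-adjacent hits
   may be at most `max_intron` (20,000 nt) apart. This mirrors the
   behaviour of fast k-mer seeders whose intron cap makes exons across
   oversized introns invisible at this stage — deliberately so, since the
   rescue stage recovers them.
2. **Truncation filter.** A hit that misses more than 12 residues at the
   start or more than 10 at the end of its exon (strict inequalities) is
   discarded as spurious.
3. **Rescue.** For every run of missing exons a temporary target is cut
   from the region between the flanking retained hits (extending to the
   region ends for missing terminal exons). Each missing exon is searched
   *only inside its own synteny window* with the same local aligner; the
   short target makes the search sensitive. Hits are converted to bit
   scores with ungapped Karlin–Altschul parameters for BLOSUM62
   (`lambda = 0.3176`, `K = 0.134`) and kept only above 50.0 bits
   (strict). No intron-size cap applies here, which is what makes a
   25 kb intron recoverable.
4. **Gap classification.** Consecutive hits separated by fewer than 5 nt
   are one exon split by alignment imprecision (reported as two records
   with the merge annotated); gaps of at least 21 nt are introns; gaps in
   between are readthroughs, i.e. kept as coding sequence and flagged.
5. **Junction refinement.** For each intron-like gap, donor candidates
   (GT, and the minor GC form) are enumerated within ±35 nt of the seeded
   exon end and acceptor candidates (AG) within ±35 nt of the next exon's
   start. Candidates are scored by a pluggable splice-site model. With
   `n` the signed distance from the end of the upstream exon's last full
   codon to a donor candidate and `n'` the signed distance from an
   acceptor candidate to the start of the downstream exon's first full
   codon, a pair preserves the reading frame iff `(n + n') mod 3 == 0`.
   Among frame-preserving pairs whose sites each score above −10 and
   whose implied intron is at least 21 nt, the pair with the highest
   combined score wins. If no admissible pair exists the window is
   widened once by 18 nt; if that also fails, an exon is rejected with a
   warning (manual-curation territory).
6. **Terminal refinement.** The in-frame ATG nearest the seeded start of
   the first exon (ties upstream) becomes the start codon; the first
   in-frame stop at/after the last exon's end becomes the stop, excluded
   from CDS and protein. A first exon with no ATG in the extended window
   is omitted from the model — a deliberate bias: for HMM building, a
   missing exon is cheaper than an erroneous one.
7. **Assembly and output.** The CDS is spliced from the refined spans,
   translated, and cut into per-exon peptides; a residue whose codon
   spans a junction appears in the protein but in neither flanking exon
   record. Outputs are protein FASTA, exon-wise FASTA, GFF3 in
   source-contig coordinates, and a per-exon TSV report that always has
   one row per query exon (rejected and missing exons keep their row and
   status).

## Splice-site scoring

The scorer is a contract, not a fixed model: anything that maps a 9-mer
donor context (3 exonic + 6 intronic nt) and a 23-mer acceptor context
(20 intronic + 3 exonic nt) to a log-odds score can be plugged in via a
TSV table (`kind`, `position`, `base`, `log_odds`). The bundled default
is a position weight matrix over canonical mammalian donor/acceptor base
frequencies, expressed as log2-odds against a uniform background. Its
consensus contexts score far above the reliability cutoff of 3.0
(donor ≈ 12.7, GC-donor ≈ 6.3, acceptor ≈ 22.7), and any context
containing N scores −∞ and can never be selected. The pipeline's logic is
independent of which admissible scorer is used; thresholds (−10
admissible, 3 reliable) follow the conventions established for
maximum-entropy splice models. Minor-spliceosome AT–AC introns and other
non-canonical edges are out of scope: only G[T|C]...AG is considered.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `max_intron` | 20,000 | nt | seeding-stage chain gap cap |
| `trunc_start_aa` / `trunc_end_aa` | 12 / 10 | aa | truncation filter (strict `>`) |
| `rescue_min_bits` | 50.0 | bits | rescue acceptance (strict `>`) |
| `merge_gap_nt` | 5 | nt | below: merge |
| `min_intron_nt` | 21 | nt | at/above: intron; between: readthrough |
| `search_radius_nt` | 35 | nt | splice/terminal search radius (symmetric) |
| `radius_extension_nt` | 18 | nt | one-time widening on failure |
| `reliable_score` / `min_score` | 3 / −10 | log2-odds | site score semantics |

## Design choices where the design was open

* **Per-site score threshold.** The −10 cutoff is applied to donor and
  acceptor separately, not to their sum; a junction is only as credible
  as its weaker site.
* **Tie-breaking.** Equal combined scores fall to least displacement from
  the seed estimate (`|n| + |n'|`), then GT over GC, then the upstream
  pair — least surprise relative to the homology evidence.
* **Symmetric radius.** The 35 nt search radius is read as ±35 around the
  estimate, and the 18 nt extension re-enumerates the full ±53 window of
  the failing junction only.
* **Rejection cascade.** When a junction fails even after extension, the
  flanking exon with the weaker seed bit score is rejected (tie:
  downstream) and the new neighbour pair is retried; homology evidence
  arbitrates which side was wrong.
* **Frame checking is per junction**, matching the offset arithmetic; a
  whole-model length-mod-3 check at assembly catches pathological
  cascades and downgrades the model with a warning instead of
  re-optimising.
* **Phase conventions.** Internally all intervals are 0-based half-open
  (which keeps the `n`/`n'` arithmetic sign-safe); GFF3 output is 1-based
  closed through a single audited converter. A junction-split residue
  belongs to the upstream exon's query span, phase recorded. The
  per-exon-FASTA query dialect carries no phase information, so phases
  default to 0 there; the FASTA + span-table dialect is authoritative.
* **GC donors** are admitted with no prior penalty beyond their model
  score; the scorer already penalises the non-consensus +2 position.
* **Inter-contig junctions** (consecutive exons on different regions)
  are refined on both sides with the same frame arithmetic but without
  the minimum-intron constraint, which is not measurable across contigs.
* **Readthrough segments** extend the upstream exon's record, flagged in
  both the FASTA header and GFF3 attributes.

## The synthetic-fixture generator

`simulate_gene()` is first-class, tested code, and its defaults define
the study conditions used throughout the test suite and the acceptance
script: 3–12 exons of 20–60 aa, introns of 60–5,000 nt (single introns up
to 25,000 nt for the rescue stress), GC-donor probability 0.69% (the
mammalian minor-donor rate), flanks of 200–500 nt, and query amino-acid
substitution rates of 0 or 0.1 applied to the query copy only (the genome
stays ground truth). A stop-free CDS of random sense codons is cut into
exons at phase-consistent boundaries; donor/acceptor contexts are sampled
from the bundled model's own frequencies and rejection-sampled until they
score above the reliability cutoff; the whole junction is then verified
to be the admissible argmax in the windows the pipeline will actually
search (including the one-codon shift of the donor-side estimate that a
phase>0 junction can produce), with accidental stronger competitors
resampled away. Fixture difficulty is therefore controlled by explicitly
planted decoys (`n_decoys`), never by accidental look-alike sites.
`fragment_gene()` splits the genome at intron/intergenic breakpoints and
can hand fragments over reverse-complemented with no strand declaration,
exercising the automatic strand detection.

What the generator deliberately does **not** emulate: repeats and
paralogous gene families, GC-content heterogeneity, indels between query
and target (substitutions only by default — indels near junctions
interact with the offset arithmetic and deserve targeted stress tests),
sequencing gaps (N runs), and non-canonical splicing. Passing the fixture
suite therefore demonstrates the correctness of the pipeline's logic
under its stated assumptions, not performance on diverged real genomes;
like any seed-based method, sensitivity will degrade once local
alignment no longer retrieves homologous exons reliably.

## Numerical and degenerate-input choices

* Alignment raw scores convert to bits with ungapped Karlin–Altschul
  parameters; local alignments with non-positive raw score are treated
  as no hit.
* Regions shorter than 3 nt are skipped with a warning; N bases never
  form part of a splice motif and translate as X.
* Negative estimated gaps (overlapping seed hits) classify as merges and
  the overlap is clipped at the downstream hit's start.
* An empty model (no surviving exon) is a distinct error condition
  carrying the full warning log, and a distinct exit code (2) in the CLI.
* Determinism: identical inputs and configuration give byte-identical
  outputs; all fixture randomness flows through a single integer seed.

## Problem sizes used in the checks

The bundled verification suites use 30 genes per condition (pristine and
mutated), 500 random instances for the junction-selection brute-force
cross-check, a five-exon gene with one 25,000 nt intron for the rescue
stress, and a six-exon gene cut into three fragments (one
reverse-complemented) for the fragmentation stress. These sizes keep a
full run in the low minutes on a single core while exercising every
stage; all recovery percentages they report are computed, not assumed.

## Known limitations

* One homolog per target set is assumed; multi-copy resolution
  (paralog-to-contig assignment) belongs to upstream tooling.
* No local re-alignment of exon flanks is integrated with junction
  scoring; the seed estimate plus site scores decide alone.
* Only the standard genetic code is supported.
* The published maximum-entropy splice model files are not bundled; the
  pluggable TSV scorer table is the supported exchange format.
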