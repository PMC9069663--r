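# exonalign

Exon-centric spliced alignment of an exon-annotated protein query to
genomic DNA.

## The problem

Building exon-wise multiple alignments and per-exon profile HMMs — for
example to tell the members of a large paralog family apart by their
exon/intron architecture — needs a spliced aligner whose primary output is
the *exon boundaries themselves*, placed where a credible splice signal
exists and constrained to preserve the reading frame. Conventional
protein-to-genome aligners optimise a global alignment, report only the
full protein, and attach no score to the splice sites they imply; genes
with very long introns and genes scattered over several assembly
fragments make this worse.

`exonalign` aligns one exon at a time. Given a protein with known
amino-acid exon spans and boundary phases, plus one or more target
regions assumed to contain a single homolog, it:

1. seeds each exon by local alignment (BLOSUM62, affine gaps) against
   frame translations of both strands of each region, chaining hits
   collinearly with a 20 kb intron cap;
2. drops truncated hits (more than 12 residues missing at the exon start
   or more than 10 at the end);
3. rescues missing exons by a sensitive search inside the region between
   the flanking retained exons only, keeping hits above 50 bits
   (Karlin–Altschul, ungapped BLOSUM62 parameters) — no intron cap, so
   oversized introns are bridged here;
4. classifies inter-exon gaps: `< 5` nt merge, `>= 21` nt intron,
   readthrough in between;
5. refines each intron junction by enumerating GT/GC donor and AG
   acceptor candidates within ±35 nt of the seeded boundaries and scoring
   them with a pluggable splice-site model (bundled: a log2-odds PWM over
   canonical mammalian splice frequencies). With `n` the signed offset of
   a donor from the upstream exon's last full codon and `n'` the signed
   offset of the downstream exon's first full codon from an acceptor, a
   pair is admissible iff `(n + n') mod 3 == 0`, both sites score
   `> -10`, and the intron is at least 21 nt; the admissible pair with
   the highest combined score is chosen. On failure the window widens
   once by 18 nt, then the weaker flanking exon is rejected with a
   warning;
6. refines the start codon (nearest in-frame ATG) and stop codon (first
   in-frame TAA/TAG/TGA), and assembles the gene model: spliced CDS,
   translated protein, and per-exon peptides in which residues whose
   codons span a junction are excluded (they appear only in the complete
   protein).

Outputs are protein FASTA, exon-wise FASTA, GFF3 (1-based, source-contig
coordinates, merge/readthrough annotations), and a per-exon TSV report
with one row per query exon — rejected or missing exons keep their row
and status.

## Worked example

Simulate a gene with known structure, align its query back, and inspect
the model:

```r
library(exonalign)

gene <- simulate_gene(n_exons = 4, seed = 7)     # planted ground truth
regions <- target_region("contig1", gene$genome)
res <- align_exons(gene$query, regions)

res$model
#> <gene_model> synq: 4/4 exon(s) placed, CDS 579 nt, protein 193 aa
#>   start codon: yes; stop codon: yes

tidy(res$model)[, c("exon_index", "start", "end", "status",
                    "left_phase", "right_phase", "donor_score", "s")]
#> # A tibble: 4 × 8
#>   exon_index start   end status left_phase right_phase donor_score     s
#> 1          1   242   354 seeded          0           1        8.88     3
#> 2          2  1480  1631 seeded          1           2        8.27     3
#> 3          3  5254  5394 seeded          2           1       10.5      3
#> 4          4  6896  7072 seeded          1           0       NA       NA

identical(res$model$protein, gene$true_protein)
#> [1] TRUE
```

Each row is one exon: the refined genomic span (0-based half-open), its
fate (`seeded`, `rescued`, `merged_with_next`, `rejected`, `missing`),
the codon phases at its boundaries, the chosen donor site's log2-odds
score, and the frame sum `s = n + n'` of the junction following it
(divisible by 3 by construction). `glance(res$model)` gives a one-row
summary, `autoplot(res$model)` a structure sketch, and
`write_gene_model(res$model, "out/run", res$regions)` the four output
files. A thin command-line front end lives at
`inst/scripts/exonalign.R` (`align` and `fixtures` subcommands).

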