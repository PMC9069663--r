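cfg <- pipeline_config()
model <- splice_score_model()

test_that("generation is deterministic for a fixed seed", {
  g1 <- simulate_gene(n_exons = 4, seed = 42)
  g2 <- simulate_gene(n_exons = 4, seed = 42)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$query$protein_seq, g2$query$protein_seq)
  g3 <- simulate_gene(n_exons = 4, seed = 43)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("forcing the GC-donor probability to 1 plants only GC donors", {
  gene <- simulate_gene(n_exons = 5, gc_donor_prob = 1, seed = 44)
  donors <- substring(gene$genome, gene$true_exons$end[-5] + 1L,
                      gene$true_exons$end[-5] + 2L)
  expect_equal(donors, rep("GC", 4))
  # and by default donors are overwhelmingly GT
  gt <- simulate_gene(n_exons = 5, gc_donor_prob = 0, seed = 45)
  expect_equal(substring(gt$genome, gt$true_exons$end[-5] + 1L,
                         gt$true_exons$end[-5] + 2L), rep("GT", 4))
})

test_that("planted junction contexts score above the reliability cutoff", {
  n_checked <- 0L
  for (seed in 601:610) {
    gene <- simulate_gene(n_exons = 6, seed = seed)
    for (i in 1:5) {
      d <- gene$true_exons$end[i]
      a <- gene$true_exons$start[i + 1]
      dctx <- substring(gene$genome, d - 2L, d + 6L)
      actx <- substring(gene$genome, a - 19L, a + 3L)
      expect_gt(score_splice_sites(dctx, "donor", model), cfg$reliable_score)
      expect_gt(score_splice_sites(actx, "acceptor", model),
                cfg$reliable_score)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 50L)
})

test_that("the planted CDS translates to the recorded protein and introns are legal", {
  gene <- simulate_gene(n_exons = 5, seed = 46)
  pieces <- substring(gene$genome, gene$true_exons$start + 1L,
                      gene$true_exons$end)
  cds <- paste(pieces, collapse = "")
  expect_equal(
    as.character(Biostrings::translate(Biostrings::DNAString(cds))),
    gene$true_protein)
  expect_false(grepl("\\*", gene$true_protein))
  intron_len <- gene$true_exons$start[-1] - gene$true_exons$end[-5]
  expect_true(all(intron_len >= cfg$min_intron_nt))
  # the stop codon sits immediately after the last exon
  stopc <- substring(gene$genome, gene$stop_pos + 1L, gene$stop_pos + 3L)
  expect_true(stopc %in% c("TAA", "TAG", "TGA"))
})

test_that("infeasible generator parameters are validation errors", {
  expect_error(simulate_gene(n_exons = 0), class = "exonalign_fixture_error")
  expect_error(simulate_gene(exon_aa = c(0, 5)),
               class = "exonalign_fixture_error")
  expect_error(simulate_gene(intron_nt = c(10, 20)),
               class = "exonalign_fixture_error")
  expect_error(simulate_gene(n_exons = 3, intron_lengths = c(100)),
               class = "exonalign_fixture_error")
})

test_that("fragmentation keeps truth well-defined and rejects exonic breakpoints", {
  gene <- simulate_gene(n_exons = 3, seed = 47)
  # no breakpoints: one region equal to the genome
  whole <- fragment_gene(gene)
  expect_equal(nrow(whole$regions), 1L)
  expect_equal(whole$regions$dna, gene$genome)

  mid <- floor((gene$true_exons$end[1] + gene$true_exons$start[2]) / 2)
  frag <- fragment_gene(gene, breakpoints = mid, revcomp = c(FALSE, TRUE))
  expect_equal(nrow(frag$regions), 2L)
  expect_equal(sum(nchar(frag$regions$dna)), nchar(gene$genome))
  # the reverse-complemented fragment is handed over as-is (strand unknown)
  expect_equal(frag$regions$orientation, c("+", "+"))
  expect_true(all(frag$truth$strand[frag$truth$contig == "frag2"] == "-"))

  inside <- gene$true_exons$start[2] + 3L
  expect_error(fragment_gene(gene, breakpoints = inside),
               class = "exonalign_fixture_error")
})

test_that("fixture files round-trip through the package readers", {
  gene <- simulate_gene(n_exons = 3, seed = 48)
  dir <- withr::local_tempdir()
  write_planted_gene(gene, dir, name = "fix")
  q <- read_exon_query(file.path(dir, "fix_query.fa"),
                       file.path(dir, "fix_query_exons.tsv"))
  expect_equal(q$protein_seq, gene$query$protein_seq)
  expect_equal(q$boundary_phases, gene$query$boundary_phases)
  regions <- read_target_regions(file.path(dir, "fix_genome.fa"))
  expect_equal(regions$dna, gene$genome)
  truth <- rtracklayer::import(file.path(dir, "fix_truth.gff3"),
                               format = "gff3")
  expect_equal(GenomicRanges::start(truth) - 1L, gene$true_exons$start)
  expect_equal(GenomicRanges::end(truth), gene$true_exons$end)
})

test_that("decoy motifs are planted without displacing the true junction", {
  gene <- simulate_gene(n_exons = 4, n_decoys = 2, intron_nt = c(150, 800),
                        seed = 49)
  res <- align_exons(gene$query, target_region("t", gene$genome))
  td <- tidy(res$model)
  expect_equal(td$start, gene$true_exons$start)
  expect_equal(td$end, gene$true_exons$end)
})
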