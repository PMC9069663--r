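cfg <- pipeline_config()

test_that("exact-match exons seed with identity 1 at the planted full-codon spans", {
  gene <- simulate_gene(n_exons = 4, seed = 301)
  hits <- seed_exons(gene$query, target_region("t", gene$genome), cfg)
  expect_equal(nrow(hits), 4L)
  expect_equal(hits$identity, rep(1, 4))
  expect_equal(hits$origin, rep("seed", 4))
  # the seed estimate covers the exon's full codons: boundaries shrink by
  # the split-codon phase on each side (the aligner may recruit one extra
  # residue when the junction-spanning codon happens to translate to the
  # split residue, shifting the end estimate by a full codon)
  p_prev <- c(0L, gene$true_phases)
  p_next <- c(gene$true_phases, 0L)
  expect_equal(hits$t_start, gene$true_exons$start + (3L - p_prev) %% 3L)
  end_est <- gene$true_exons$end - p_next
  expect_true(all(hits$t_end == end_est |
                    (p_next > 0L & hits$t_end == end_est + 3L)))
  expect_true(all(hits$score > 0))
})

test_that("interior substitutions lower identity without moving the span", {
  gene <- hand_gene(exon_aa = 30)
  q <- gene$query
  aa <- strsplit(q$protein_seq, "")[[1]]
  for (i in c(10, 15, 20)) aa[i] <- if (aa[i] == "H") "W" else "H"
  qmut <- exon_query(paste(aa, collapse = ""), cbind(0L, 30L),
                     integer(), "mut")
  hits <- seed_exons(qmut, target_region("t", gene$genome), cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 27 / 30)
  expect_equal(hits$t_start, gene$true_exons$start)
  expect_equal(hits$t_end, gene$true_exons$end)
})

test_that("exons across a gap beyond max_intron are not chained at seeding", {
  gene <- simulate_gene(n_exons = 2, intron_lengths = 25000, seed = 302)
  hits <- seed_exons(gene$query, target_region("t", gene$genome), cfg)
  expect_equal(nrow(hits), 1L)
  # a wider cap keeps both
  wide <- seed_exons(gene$query, target_region("t", gene$genome),
                     pipeline_config(max_intron = 30000))
  expect_equal(nrow(wide), 2L)
})

test_that("seeding finds genes on the reverse strand and reorients the region", {
  gene <- simulate_gene(n_exons = 3, seed = 303)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene$genome)))
  hits <- seed_exons(gene$query, target_region("t", rc), cfg)
  regions <- attr(hits, "regions")
  expect_equal(regions$orientation, "-")
  expect_equal(nrow(hits), 3L)
  # spans are in gene orientation of the flipped region = original genome
  p_prev <- c(0L, gene$true_phases)
  expect_equal(hits$t_start, gene$true_exons$start + (3L - p_prev) %% 3L)
})

test_that("collinearity chaining keeps the best order-consistent subset", {
  hits <- tibble::tibble(
    exon_index = c(1L, 2L, 3L),
    region_id = "r",
    t_start = c(100L, 5000L, 2000L),  # exon 3 placed before exon 2
    t_end = c(190L, 5090L, 2090L),
    q_aa_start = c(0L, 30L, 60L), q_aa_end = c(30L, 60L, 90L),
    score = c(60, 55, 40), identity = c(1, 1, 0.9), origin = "seed"
  )
  chained <- exonalign:::chain_hits(hits, max_gap = 20000)
  # the low-scoring out-of-order hit is dropped
  expect_equal(chained$exon_index, c(1L, 2L))
})

test_that("truncation filtering applies strict >12 / >10 missing-residue rules", {
  q <- exon_query(strrep("A", 60), cbind(0L, 60L), integer(), "q")
  mk <- function(miss_start, miss_end) tibble::tibble(
    exon_index = 1L, region_id = "r",
    t_start = 0L, t_end = 3L,
    q_aa_start = miss_start, q_aa_end = 60L - miss_end,
    score = 50, identity = 1, origin = "seed")
  expect_false(exonalign:::is_truncated(mk(12L, 10L), q, cfg)) # boundary keeps
  expect_true(exonalign:::is_truncated(mk(13L, 0L), q, cfg))
  expect_true(exonalign:::is_truncated(mk(0L, 11L), q, cfg))
  kept <- filter_truncated(mk(13L, 0L), q, cfg)
  expect_equal(nrow(kept), 0L)
  expect_equal(nrow(attr(kept, "dropped")), 1L)
})

test_that("a kept hit implies any hit covering more of the query is kept", {
  set.seed(41)
  q <- exon_query(strrep("A", 50), cbind(0L, 50L), integer(), "q")
  for (i in 1:50) {
    a <- sort(sample(0:50, 2))
    b <- c(max(0, a[1] - sample(0:5, 1)), min(50, a[2] + sample(0:5, 1)))
    mk <- function(span) tibble::tibble(
      exon_index = 1L, region_id = "r", t_start = 0L, t_end = 3L,
      q_aa_start = span[1], q_aa_end = span[2],
      score = 50, identity = 1, origin = "seed")
    if (!exonalign:::is_truncated(mk(a), q, cfg)) {
      expect_false(exonalign:::is_truncated(mk(b), q, cfg))
    }
  }
})
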