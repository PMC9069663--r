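cfg <- pipeline_config()

test_that("intervening targets span the gaps implied by missing exons", {
  q <- exon_query(strrep("ARNDCEQGHI", 9), cbind(c(0L, 30L, 60L),
                                                 c(30L, 60L, 90L)),
                  c(0L, 0L), "q")
  regions <- target_region("r", strrep("A", 10000))
  mk_hit <- function(e, s, en) tibble::tibble(
    exon_index = e, region_id = "r", t_start = s, t_end = en,
    q_aa_start = q$exons$aa_start[e], q_aa_end = q$exons$aa_end[e],
    score = 60, identity = 1, origin = "seed")

  # middle exon missing: one target between the flanking hits
  ret <- rbind(mk_hit(1L, 100L, 190L), mk_hit(3L, 5000L, 5090L))
  tg <- build_intervening_targets(ret, regions, q)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$start, 190L)
  expect_equal(tg$end, 5000L)
  expect_equal(tg$expected_exons[[1]], 2L)
  expect_false(tg$ambiguous)

  # first exon missing: target extends to the region start
  tg2 <- build_intervening_targets(rbind(mk_hit(2L, 3000L, 3090L),
                                         mk_hit(3L, 5000L, 5090L)),
                                   regions, q)
  expect_equal(tg2$start, 0L)
  expect_equal(tg2$end, 3000L)

  # last exon missing: target extends to the region end
  tg3 <- build_intervening_targets(rbind(mk_hit(1L, 100L, 190L),
                                         mk_hit(2L, 3000L, 3090L)),
                                   regions, q)
  expect_equal(tg3$end, 10000L)

  # everything retained: no targets
  all3 <- rbind(mk_hit(1L, 100L, 190L), mk_hit(2L, 3000L, 3090L),
                mk_hit(3L, 5000L, 5090L))
  expect_equal(nrow(build_intervening_targets(all3, regions, q)), 0L)
})

test_that("flanking hits on different regions yield two ambiguous targets", {
  q <- exon_query(strrep("ARNDCEQGHI", 9), cbind(c(0L, 30L, 60L),
                                                 c(30L, 60L, 90L)),
                  c(0L, 0L), "q")
  regions <- rbind(target_region("rA", strrep("A", 4000)),
                   target_region("rB", strrep("A", 4000)))
  ret <- tibble::tibble(
    exon_index = c(1L, 3L), region_id = c("rA", "rB"),
    t_start = c(100L, 2000L), t_end = c(190L, 2090L),
    q_aa_start = c(0L, 60L), q_aa_end = c(30L, 90L),
    score = 60, identity = 1, origin = "seed")
  tg <- build_intervening_targets(ret, regions, q)
  expect_equal(nrow(tg), 2L)
  expect_true(all(tg$ambiguous))
  expect_equal(tg$region_id, c("rA", "rB"))
  expect_equal(tg$start, c(190L, 0L))
  expect_equal(tg$end, c(4000L, 2000L))
})

test_that("an exact planted exon is rescued with a bit score matching the closed form", {
  gene <- hand_gene(exon_aa = 41)  # 40 informative residues + Met
  pep <- exon_peptides(gene$query)
  # plant the exon in a 2 kb window and search it as an intervening target
  regions <- target_region("r", gene$genome)
  targets <- tibble::tibble(region_id = "r", start = 0L,
                            end = nchar(gene$genome),
                            expected_exons = list(1L), ambiguous = FALSE)
  hits <- rescue_missing(gene$query, targets, regions, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$origin, "rescue")
  expect_equal(hits$t_start, gene$true_exons$start)
  expect_equal(hits$t_end, gene$true_exons$end)
  expect_gt(hits$score, 50)
  # closed-form oracle: raw = sum of BLOSUM62 diagonal over the peptide,
  # bits = (lambda * raw - ln K) / ln 2 with the ungapped parameters
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aa <- strsplit(pep, "")[[1]]
  raw <- sum(BLOSUM62[cbind(aa, aa)])
  bits <- (0.3176 * raw - log(0.134)) / log(2)
  expect_equal(hits$score, bits, tolerance = 1e-9)
})

test_that("the rescue bit-score threshold is strict", {
  gene <- hand_gene(exon_aa = 41)
  regions <- target_region("r", gene$genome)
  targets <- tibble::tibble(region_id = "r", start = 0L,
                            end = nchar(gene$genome),
                            expected_exons = list(1L), ambiguous = FALSE)
  bits <- rescue_missing(gene$query, targets, regions, cfg)$score
  # a hit exactly at the cutoff is discarded; just below the cutoff it is kept
  at_cutoff <- pipeline_config(rescue_min_bits = bits)
  expect_equal(nrow(rescue_missing(gene$query, targets, regions, at_cutoff)),
               0L)
  below <- pipeline_config(rescue_min_bits = bits - 0.1)
  expect_equal(nrow(rescue_missing(gene$query, targets, regions, below)), 1L)
})

test_that("random targets never reach the rescue threshold by chance", {
  set.seed(53)
  pep <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      40, replace = TRUE), collapse = "")
  q <- exon_query(pep, cbind(0L, 40L), integer(), "rand")
  worst <- -Inf
  for (i in 1:100) {
    dna <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
    hit <- exonalign:::align_peptide_dna(pep, dna, cfg)
    if (!is.null(hit)) worst <- max(worst, hit$bits)
  }
  expect_lt(worst, cfg$rescue_min_bits)
})

test_that("rescue is confined to the exon's own synteny window", {
  gene <- simulate_gene(n_exons = 3, seed = 311)
  regions <- target_region("t", gene$genome)
  # expect exon 2 only in a window that does not contain it: no hit
  off_window <- tibble::tibble(
    region_id = "t", start = 0L, end = gene$true_exons$start[1],
    expected_exons = list(2L), ambiguous = FALSE)
  expect_equal(nrow(rescue_missing(gene$query, off_window, regions, cfg)), 0L)
})
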