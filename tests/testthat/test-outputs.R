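cfg <- pipeline_config()

test_that("written models round-trip spans, phases, status and sequences", {
  gene <- simulate_gene(n_exons = 4, seed = 501)
  res <- align_exons(gene$query, target_region("t", gene$genome))
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "out")
  paths <- write_gene_model(res$model, prefix, res$regions)
  expect_true(all(file.exists(paths)))
  back <- read_gene_model(prefix)
  expect_equal(back$protein, res$model$protein)
  expect_equal(back$exons$start, res$model$exons$start)
  expect_equal(back$exons$end, res$model$exons$end)
  expect_equal(back$exons$left_phase, res$model$exons$left_phase)
  expect_equal(back$exons$right_phase, res$model$exons$right_phase)
  expect_equal(back$exons$status, res$model$exons$status)
  expect_equal(unname(back$peptides),
               res$model$exons$peptide[!is.na(res$model$exons$start)])
})

test_that("for a phase-0 model the exon records concatenate to the protein record", {
  gene <- hand_gene(exon_aa = c(15, 20), phases = 0L)
  res <- align_exons(gene$query, target_region("t", gene$genome))
  dir <- withr::local_tempdir()
  write_gene_model(res$model, file.path(dir, "m"), res$regions)
  back <- read_gene_model(file.path(dir, "m"))
  expect_equal(paste(back$peptides, collapse = ""), back$protein)
})

test_that("GFF3 output maps back to the internal spans through the coordinate layer", {
  gene <- simulate_gene(n_exons = 3, seed = 502)
  frag <- fragment_gene(gene,
                        breakpoints = floor((gene$true_exons$end[1] +
                                               gene$true_exons$start[2]) / 2),
                        revcomp = c(FALSE, TRUE))
  res <- align_exons(gene$query, frag$regions)
  dir <- withr::local_tempdir()
  write_gene_model(res$model, file.path(dir, "g"), res$regions)
  gff <- rtracklayer::import(file.path(dir, "g.gff3"), format = "gff3")
  cds <- gff[gff$type == "CDS"]
  placed <- res$model$exons[!is.na(res$model$exons$start), ]
  for (i in seq_along(cds)) {
    idx <- as.integer(cds$exon_index[i])
    row <- placed[placed$exon_index == idx, ]
    iv <- from_gff3_interval(GenomicRanges::start(cds)[i],
                             GenomicRanges::end(cds)[i])
    back <- from_source_coords(res$regions,
                               region_id = row$region_id,
                               iv$start, iv$end)
    expect_equal(back$start, row$start)
    expect_equal(back$end, row$end)
  }
})

test_that("merged exon pairs stay separate records sharing a merged_with attribute", {
  # two query exons lying contiguously on the genome (gap 0 nt)
  gene <- hand_gene(exon_aa = c(18, 16), phases = 0L, intron_interior = -1L)
  res <- align_exons(gene$query, target_region("t", gene$genome))
  m <- res$model
  expect_equal(nrow(m$merges), 1L)
  expect_equal(m$exons$status[1], "merged_with_next")
  expect_equal(m$protein, gene$true_protein)
  dir <- withr::local_tempdir()
  write_gene_model(m, file.path(dir, "mg"), res$regions)
  back <- read_gene_model(file.path(dir, "mg"))
  expect_equal(length(back$peptides), 2L)
  expect_true(all(grepl("merged_with=", names(back$peptides))))
  cds <- back$gff[back$gff$type == "CDS"]
  expect_equal(sort(as.integer(cds$merged_with)), c(1L, 2L))
})

test_that("short inter-exon gaps are carried as readthrough coding sequence", {
  gene <- hand_gene(exon_aa = c(18, 16), phases = 0L, intron_interior = -13L)
  res <- align_exons(gene$query, target_region("t", gene$genome))
  m <- res$model
  expect_equal(nrow(m$readthroughs), 1L)
  expect_equal(m$readthroughs$end - m$readthroughs$start, 12L)
  # the 12 nt gap is part of the CDS: four extra residues
  expect_equal(nchar(m$protein), nchar(gene$true_protein) + 4L)
  # the gap is absorbed into the upstream exon's record
  placed <- m$exons[!is.na(m$exons$start), ]
  expect_equal(placed$end[1], placed$start[2])
  dir <- withr::local_tempdir()
  write_gene_model(m, file.path(dir, "rt"), res$regions)
  back <- read_gene_model(file.path(dir, "rt"))
  expect_true(any(grepl("readthrough=yes", names(back$peptides))))
})

test_that("an unwritable output path errors before any partial file exists", {
  gene <- hand_gene(exon_aa = 20)
  res <- align_exons(gene$query, target_region("t", gene$genome))
  bad <- file.path(tempdir(), "no_such_dir_xyz", "out")
  expect_error(write_gene_model(res$model, bad, res$regions),
               class = "exonalign_io_error")
  expect_false(any(file.exists(paste0(bad, c(".protein.fa", ".exons.fa",
                                             ".gff3", ".report.tsv")))))
})
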