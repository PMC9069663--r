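# Output writers: complete protein FASTA, exon-wise peptide FASTA (split
# codons excluded), GFF3 in source-contig coordinates, and a
# machine-readable per-exon report. One row/record per query exon always:
# dropped or rejected exons appear with their status, never silently
# vanish.

#' Write a gene model to files
#'
#' Writes `<prefix>.protein.fa` (complete predicted protein),
#' `<prefix>.exons.fa` (one record per placed exon, junction-split
#' residues excluded, header carrying status/phases/source coordinates),
#' `<prefix>.gff3` (gene/mRNA/CDS features, 1-based closed, source-contig
#' coordinates, merge and readthrough annotations as attributes) and
#' `<prefix>.report.tsv` (one row per query exon with status, identity,
#' junction scores and offsets, and warnings).
#'
#' @param model A `gene_model`.
#' @param out_prefix Output path prefix.
#' @param regions The target-regions tibble the model was built against
#'   (needed to map spans to source coordinates).
#' @return Character vector of the four paths, invisibly.
#' @export
write_gene_model <- function(model, out_prefix, regions) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir) || file.access(dir, 2) != 0L) {
    abort(sprintf("output directory '%s' is not writable", dir),
          class = "exonalign_io_error")
  }
  paths <- paste0(out_prefix, c(".protein.fa", ".exons.fa", ".gff3",
                                ".report.tsv"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)

  ex <- model$exons
  placed <- ex[!is.na(ex$start), ]
  src <- to_source_coords(regions, placed$region_id, placed$start,
                          placed$end)

  # protein
  prot <- Biostrings::AAStringSet(model$protein)
  names(prot) <- model$query_id
  Biostrings::writeXStringSet(prot, paths[1])

  # exon-wise peptides
  merged_with <- rep(NA_integer_, nrow(placed))
  if (nrow(model$merges)) {
    m <- match(placed$exon_index, model$merges$upstream_exon)
    merged_with[!is.na(m)] <-
      model$merges$downstream_exon[m[!is.na(m)]]
    m2 <- match(placed$exon_index, model$merges$downstream_exon)
    merged_with[!is.na(m2)] <-
      model$merges$upstream_exon[m2[!is.na(m2)]]
  }
  rt <- rep(FALSE, nrow(placed))
  if (nrow(model$readthroughs)) {
    # readthrough gaps are absorbed into the upstream exon's record
    rt[placed$exon_index %in% model$readthroughs$upstream_exon] <- TRUE
  }
  headers <- sprintf(
    "%s_exon%d status=%s left_phase=%d right_phase=%d loc=%s:%d-%d(%s)%s%s",
    model$query_id, placed$exon_index, placed$status,
    placed$left_phase, placed$right_phase,
    src$contig, gff3_interval(src$start, src$end)$start, src$end,
    src$strand,
    ifelse(is.na(merged_with), "", sprintf(" merged_with=%d", merged_with)),
    ifelse(rt, " readthrough=yes", "")
  )
  pep <- Biostrings::AAStringSet(placed$peptide)
  names(pep) <- headers
  Biostrings::writeXStringSet(pep, paths[2])

  # GFF3
  gr_list <- list()
  for (ctg in unique(src$contig)) {
    sel <- src$contig == ctg
    g <- gff3_interval(min(src$start[sel]), max(src$end[sel]))
    gid <- sprintf("gene:%s:%s", model$query_id, ctg)
    mid <- sprintf("mRNA:%s:%s", model$query_id, ctg)
    strand <- src$strand[sel][1]
    gr_list[[length(gr_list) + 1L]] <- GenomicRanges::GRanges(
      seqnames = ctg,
      ranges = IRanges::IRanges(start = rep(g$start, 2), end = rep(g$end, 2)),
      strand = strand,
      type = c("gene", "mRNA"),
      ID = c(gid, mid),
      Parent = c(NA_character_, gid),
      exon_index = NA_integer_, status = NA_character_,
      merged_with = NA_integer_, readthrough = NA_character_,
      phase = NA_integer_
    )
  }
  cds_iv <- gff3_interval(src$start, src$end)
  gr_list[[length(gr_list) + 1L]] <- GenomicRanges::GRanges(
    seqnames = src$contig,
    ranges = IRanges::IRanges(start = cds_iv$start, end = cds_iv$end),
    strand = src$strand,
    type = "CDS",
    ID = sprintf("cds:%s:exon%d", model$query_id, placed$exon_index),
    Parent = sprintf("mRNA:%s:%s", model$query_id, src$contig),
    exon_index = placed$exon_index,
    status = placed$status,
    merged_with = merged_with,
    readthrough = ifelse(rt, "yes", NA_character_),
    phase = (3L - placed$left_phase) %% 3L
  )
  gr <- suppressWarnings(do.call(c, gr_list))
  rtracklayer::export(gr, paths[3], format = "gff3")

  # per-exon report
  report <- ex
  report$contig <- NA_character_
  report$contig_start <- NA_integer_
  report$contig_end <- NA_integer_
  report$strand <- NA_character_
  pi <- match(placed$exon_index, report$exon_index)
  report$contig[pi] <- src$contig
  report$contig_start[pi] <- src$start
  report$contig_end[pi] <- src$end
  report$strand[pi] <- src$strand
  report$query_id <- model$query_id
  readr::write_tsv(report, paths[4])

  ok <- TRUE
  invisible(paths)
}

#' Read back a written gene model
#'
#' Reconstructs spans, phases, statuses and sequences from the four files
#' written by [write_gene_model()]; used for round-trip verification.
#'
#' @param out_prefix The prefix passed to [write_gene_model()].
#' @return List with `exons` (the report tibble), `protein`, `peptides`
#'   (named character), and `gff` (the imported GFF3 as a GRanges).
#' @export
read_gene_model <- function(out_prefix) {
  report <- readr::read_tsv(paste0(out_prefix, ".report.tsv"),
                            show_col_types = FALSE)
  prot <- Biostrings::readAAStringSet(paste0(out_prefix, ".protein.fa"))
  pep <- Biostrings::readAAStringSet(paste0(out_prefix, ".exons.fa"))
  gff <- rtracklayer::import(paste0(out_prefix, ".gff3"), format = "gff3")
  list(
    exons = report,
    protein = as.character(prot[[1]]),
    peptides = setNames(as.character(pep), names(pep)),
    gff = gff
  )
}
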