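#' Construct a target region
#'
#' A target region is one genomic sequence (or sub-sequence) assumed to
#' harbour (part of) a single homolog of the query. The stored sequence is
#' kept in gene orientation; `orientation` records the strand of the
#' footprint `[source_offset, source_offset + length)` on the source contig
#' that the stored sequence corresponds to (for `-`, the stored sequence is
#' the reverse complement of that footprint).
#'
#' @param region_id Identifier.
#' @param dna Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param source_contig Source contig name (defaults to `region_id`).
#' @param source_offset 0-based position of the footprint start on the
#'   source contig.
#' @param orientation `"+"` or `"-"`.
#' @return A one-row target-regions tibble.
#' @export
target_region <- function(region_id, dna, source_contig = region_id,
                          source_offset = 0L, orientation = "+") {
  dna <- toupper(as.character(dna))
  if (!nzchar(dna)) {
    abort("region dna must be non-empty", class = "exonalign_region_error")
  }
  if (grepl("[^ACGTN]", dna)) {
    abort("region dna may only contain A, C, G, T, N",
          class = "exonalign_region_error")
  }
  if (source_offset < 0) {
    abort("source_offset must be >= 0", class = "exonalign_region_error")
  }
  if (!orientation %in% c("+", "-")) {
    abort('orientation must be "+" or "-"', class = "exonalign_region_error")
  }
  tibble(
    region_id = as.character(region_id),
    dna = dna,
    source_contig = as.character(source_contig),
    source_offset = as.integer(source_offset),
    orientation = orientation
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read target regions from a (multi-)FASTA
#'
#' Optional `key=value` tokens in the FASTA header are honoured:
#' `contig=`, `offset=` (0-based footprint start) and `strand=`. Records
#' declared `strand=-` are reverse complemented at ingestion so that the
#' stored sequence is in gene orientation, with the original coordinates
#' recoverable through [to_source_coords()]. A BED file may restrict the
#' search to sub-regions of the input contigs; each BED interval becomes
#' one region with its offset bookkeeping set accordingly.
#'
#' @param fasta_path Path to the target FASTA.
#' @param bed_path Optional BED file of sub-regions.
#' @return A target-regions tibble.
#' @export
read_target_regions <- function(fasta_path, bed_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  parse_tok <- function(h, key, default) {
    m <- regmatches(h, regexec(paste0(key, "=(\\S+)"), h))[[1]]
    if (length(m) == 2L) m[2] else default
  }
  regions <- map(seq_along(seqs), function(i) {
    h <- headers[i]
    id <- sub("\\s.*$", "", h)
    strand <- parse_tok(h, "strand", "+")
    dna <- toupper(as.character(seqs[[i]]))
    if (strand == "-") dna <- revcomp(dna)
    target_region(
      region_id = id,
      dna = dna,
      source_contig = parse_tok(h, "contig", id),
      source_offset = as.integer(parse_tok(h, "offset", "0")),
      orientation = strand
    )
  })
  regions <- bind_rows(regions)
  if (!is.null(bed_path)) {
    bed <- rtracklayer::import(bed_path, format = "BED")
    sub <- map(seq_along(bed), function(i) {
      contig <- as.character(GenomicRanges::seqnames(bed)[i])
      j <- match(contig, regions$region_id)
      if (is.na(j)) {
        abort(sprintf("BED interval names unknown contig '%s'", contig),
              class = "exonalign_region_error")
      }
      s <- GenomicRanges::start(bed)[i] - 1L  # BED import is 1-based closed
      e <- GenomicRanges::end(bed)[i]
      target_region(
        region_id = sprintf("%s:%d-%d", contig, s, e),
        dna = substring(regions$dna[j], s + 1L, e),
        source_contig = regions$source_contig[j],
        source_offset = regions$source_offset[j] + s,
        orientation = regions$orientation[j]
      )
    })
    regions <- bind_rows(sub)
  }
  regions
}

#' Write target regions to FASTA
#'
#' Header tokens record contig, offset and orientation so the file
#' round-trips through [read_target_regions()]. Minus-orientation regions
#' are written as the original contig-strand sequence.
#'
#' @param regions Target-regions tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_target_regions <- function(regions, path) {
  seqs <- map_chr(seq_len(nrow(regions)), function(i) {
    if (regions$orientation[i] == "-") revcomp(regions$dna[i]) else regions$dna[i]
  })
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- sprintf("%s contig=%s offset=%d strand=%s",
                        regions$region_id, regions$source_contig,
                        regions$source_offset, regions$orientation)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

flip_region <- function(regions, i) {
  regions$dna[i] <- revcomp(regions$dna[i])
  regions$orientation[i] <- ifelse(regions$orientation[i] == "+", "-", "+")
  regions
}
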