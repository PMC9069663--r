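#' Exon-annotated protein query
#'
#' The unit the whole pipeline is organised around: a protein sequence plus
#' the amino-acid span of each exon and the codon phase at each internal
#' exon boundary. Phases count the nucleotides of the boundary codon
#' contributed by the upstream exon (0, 1 or 2); a residue whose codon is
#' split across a junction is assigned to the upstream exon's span.
#'
#' @param protein_seq Amino-acid string (standard 20 letters plus X).
#' @param exon_spans A two-column matrix/data frame of 0-based half-open
#'   amino-acid intervals `[start, end)`, one row per exon, sorted and
#'   exactly tiling the protein.
#' @param boundary_phases Integer vector in `{0,1,2}` of length
#'   `n_exons - 1`.
#' @param query_id Identifier.
#' @return An object of class `exon_query`.
#' @examples
#' q <- exon_query("MKLVNNAGITRD", rbind(c(0, 5), c(5, 12)), 1, "q1")
#' exon_peptides(q)
#' @export
exon_query <- function(protein_seq, exon_spans, boundary_phases = integer(),
                       query_id = "query") {
  protein_seq <- toupper(as.character(protein_seq))
  spans <- as.matrix(exon_spans)
  if (ncol(spans) != 2) {
    abort("exon_spans must have two columns (aa_start, aa_end)",
          class = "exonalign_query_error")
  }
  storage.mode(spans) <- "integer"
  n <- nrow(spans)
  phases <- as.integer(boundary_phases)
  if (n < 1L) abort("query must have at least one exon",
                    class = "exonalign_query_error")
  if (length(phases) != n - 1L) {
    abort("boundary_phases must have length n_exons - 1",
          class = "exonalign_query_error")
  }
  if (length(phases) && !all(phases %in% 0:2)) {
    abort("boundary_phases must be in {0, 1, 2}",
          class = "exonalign_query_error")
  }
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", protein_seq)) {
    abort("protein_seq may only contain the 20 standard amino acids plus X",
          class = "exonalign_query_error")
  }
  # spans must exactly tile [0, len)
  if (spans[1, 1] != 0L || spans[n, 2] != nchar(protein_seq) ||
      any(spans[, 2] <= spans[, 1]) ||
      (n > 1L && any(spans[-1, 1] != spans[-n, 2]))) {
    abort("exon_spans must be sorted, non-overlapping and tile the protein",
          class = "exonalign_query_error")
  }
  structure(
    list(
      query_id = as.character(query_id),
      protein_seq = protein_seq,
      exons = tibble(
        exon_index = seq_len(n),
        aa_start = spans[, 1],
        aa_end = spans[, 2]
      ),
      boundary_phases = phases
    ),
    class = "exon_query"
  )
}

#' @export
print.exon_query <- function(x, ...) {
  cat(sprintf("<exon_query> %s: %d aa, %d exon(s)\n",
              x$query_id, nchar(x$protein_seq), nrow(x$exons)))
  print(x$exons, n = 10)
  invisible(x)
}

n_exons <- function(query) nrow(query$exons)

#' Per-exon peptides of a query
#'
#' @param query An [exon_query()] object.
#' @return Character vector of amino-acid strings, one per exon (the
#'   junction-split residue, when present, sits at the end of the upstream
#'   exon's peptide, per the span convention).
#' @export
exon_peptides <- function(query) {
  substring(query$protein_seq, query$exons$aa_start + 1L, query$exons$aa_end)
}

#' Read an exon-annotated query from FASTA
#'
#' Two input dialects are accepted. With `exons_path`, `fasta_path` must
#' hold a single protein record and `exons_path` a TSV with columns
#' `exon_index`, `aa_start`, `aa_end` (0-based half-open) and `phase` (the
#' phase of the boundary following the exon; the last exon's phase is
#' ignored and may be NA). Without `exons_path`, `fasta_path` must be a
#' multi-record FASTA with headers `<queryID>_exon<N>`; spans are derived
#' from record lengths and all boundary phases default to 0 (that dialect
#' carries no phase information).
#'
#' @param fasta_path Path to the protein FASTA.
#' @param exons_path Optional path to the exon-span TSV.
#' @return An [exon_query()] object.
#' @export
read_exon_query <- function(fasta_path, exons_path = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (!is.null(exons_path)) {
    if (length(seqs) != 1L) {
      abort("FASTA + exon table dialect expects a single protein record",
            class = "exonalign_query_error")
    }
    tab <- readr::read_tsv(exons_path, show_col_types = FALSE)
    need <- c("exon_index", "aa_start", "aa_end", "phase")
    if (!all(need %in% names(tab))) {
      abort(paste("exon table must have columns:", paste(need, collapse = ", ")),
            class = "exonalign_query_error")
    }
    tab <- tab[order(tab$exon_index), ]
    phases <- as.integer(tab$phase[-nrow(tab)])
    phases[is.na(phases)] <- 0L
    exon_query(as.character(seqs[[1]]),
               cbind(tab$aa_start, tab$aa_end),
               phases,
               query_id = sub("\\s.*$", "", names(seqs)[1]))
  } else {
    ids <- sub("\\s.*$", "", names(seqs))
    m <- regmatches(ids, regexec("^(.*)_exon(\\d+)$", ids))
    if (any(lengths(m) != 3L)) {
      abort("per-exon FASTA headers must look like <queryID>_exon<N>",
            class = "exonalign_query_error")
    }
    qid <- unique(map_chr(m, 2))
    if (length(qid) != 1L) {
      abort("per-exon FASTA mixes multiple query ids",
            class = "exonalign_query_error")
    }
    ord <- order(as.integer(map_chr(m, 3)))
    seqs <- seqs[ord]
    lens <- Biostrings::width(seqs)
    ends <- cumsum(lens)
    starts <- c(0L, head(ends, -1L))
    exon_query(paste(as.character(seqs), collapse = ""),
               cbind(starts, ends),
               rep(0L, length(seqs) - 1L),
               query_id = qid)
  }
}

#' Write a query's exon table (companion TSV dialect)
#'
#' @param query An [exon_query()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_exon_table <- function(query, path) {
  tab <- query$exons
  tab$phase <- c(query$boundary_phases, NA_integer_)
  readr::write_tsv(tab, path)
  invisible(path)
}
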