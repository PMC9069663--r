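# Adapters for externally computed seed alignments: PSL (blat dialect,
# 21 columns) and 12-column tabular ("outfmt 6" style). Both produce seed
# hits under the same contract as the built-in seeder.

psl_cols <- c("matches", "misMatches", "repMatches", "nCount",
              "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
              "strand", "qName", "qSize", "qStart", "qEnd",
              "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

parse_exon_suffix <- function(ids, what) {
  m <- regmatches(ids, regexec("^(.*)_exon(\\d+)$", ids))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) {
    abort(sprintf("%s: query name '%s' lacks the _exon<N> suffix",
                  what, ids[bad[1]]), class = "exonalign_parse_error")
  }
  as.integer(map_chr(m, 3))
}

#' Read seed hits from a PSL file
#'
#' Accepts blat's 21-column PSL with or without its 5-line header. Query
#' names must carry the `_exon<N>` suffix so each line maps to one query
#' exon. For minus-strand lines the target span is reflected into gene
#' orientation and the affected region is recorded in the `"minus_regions"`
#' attribute (the pipeline reorients those regions before refinement).
#'
#' @param path PSL file path.
#' @param query Optional [exon_query()]; when given, per-exon query
#'   coordinates are lifted to absolute protein coordinates.
#' @return Seed-hit tibble (`origin = "seed"`); the PSL `matches` count is
#'   used as the hit score surrogate.
#' @export
read_psl <- function(path, query = NULL) {
  lines <- readLines(path)
  is_data <- grepl("^\\d", lines)
  if (any(!is_data & nzchar(lines)) && !all(is_data[nzchar(lines)])) {
    # header present: data starts at the first numeric line
    first <- which(is_data)[1]
    if (is.na(first)) lines <- character() else lines <- lines[first:length(lines)]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  rows <- list()
  minus_regions <- character()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L) {
      abort(sprintf("PSL parse error at line %d: expected 21 fields, got %d",
                    k, length(f)), class = "exonalign_parse_error")
    }
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (anyNA(num)) {
      abort(sprintf("PSL parse error at line %d: non-numeric field", k),
            class = "exonalign_parse_error")
    }
    rec <- setNames(as.list(f), psl_cols)
    t_strand <- substring(rec$strand, nchar(rec$strand))  # target strand
    t_size <- as.integer(rec$tSize)
    t_start <- as.integer(rec$tStart)
    t_end <- as.integer(rec$tEnd)
    if (t_strand == "-") {
      tmp <- t_start
      t_start <- t_size - t_end
      t_end <- t_size - tmp
      minus_regions <- union(minus_regions, rec$tName)
    }
    exon <- parse_exon_suffix(rec$qName, "read_psl")
    matches <- as.integer(rec$matches)
    mism <- as.integer(rec$misMatches)
    q_start <- as.integer(rec$qStart)
    q_end <- as.integer(rec$qEnd)
    if (!is.null(query)) {
      q_start <- query$exons$aa_start[exon] + q_start
      q_end <- query$exons$aa_start[exon] + q_end
    }
    rows[[k]] <- tibble(
      exon_index = exon, region_id = rec$tName,
      t_start = t_start, t_end = t_end,
      q_aa_start = q_start, q_aa_end = q_end,
      score = as.numeric(matches),
      identity = if (matches + mism > 0) matches / (matches + mism) else 0,
      origin = "seed"
    )
  }
  structure(bind_rows(rows), minus_regions = minus_regions)
}

#' Read seed hits from 12-column tabular alignment output
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore (1-based inclusive subject coordinates;
#' `sstart > send` marks a minus-strand hit, which is reflected into gene
#' orientation using the region length).
#'
#' @param path Tabular file path.
#' @param regions Target-regions tibble (needed to reflect minus hits).
#' @param query Optional [exon_query()] for absolute query coordinates.
#' @return Seed-hit tibble (`origin = "seed"`, score in bits).
#' @export
read_tabular_hits <- function(path, regions, query = NULL) {
  tab <- readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd"
  )
  if (!nrow(tab)) return(empty_hits())
  exon <- parse_exon_suffix(tab$qseqid, "read_tabular_hits")
  minus <- tab$sstart > tab$send
  len <- nchar(regions$dna)[match(tab$sseqid, regions$region_id)]
  if (anyNA(len)) {
    abort("tabular hit names a subject absent from the regions",
          class = "exonalign_parse_error")
  }
  s0 <- ifelse(minus, tab$send - 1L, tab$sstart - 1L)
  e0 <- ifelse(minus, tab$sstart, tab$send)
  t_start <- as.integer(ifelse(minus, len - e0, s0))
  t_end <- as.integer(ifelse(minus, len - s0, e0))
  q_start <- tab$qstart - 1L
  q_end <- tab$qend
  if (!is.null(query)) {
    q_start <- query$exons$aa_start[exon] + q_start
    q_end <- query$exons$aa_start[exon] + q_end
  }
  structure(
    tibble(
      exon_index = exon, region_id = tab$sseqid,
      t_start = t_start, t_end = t_end,
      q_aa_start = as.integer(q_start), q_aa_end = as.integer(q_end),
      score = tab$bitscore, identity = tab$pident / 100, origin = "seed"
    ),
    minus_regions = unique(tab$sseqid[minus])
  )
}
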