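# Terminal refinement: start codon in the first exon, stop codon in the
# last exon. Both reuse the splice-site search radius and its one-time
# extension.

#' Refine the start codon of the first exon
#'
#' Searches for the in-frame ATG nearest the seed estimate of the exon
#' start within the search radius (extended once on failure). Ties go to
#' the upstream candidate. Absence of any in-frame ATG is reported as
#' `NULL` (the caller flags and drops the exon).
#'
#' @param first_hit One-row hit tibble for the first placed exon.
#' @param region_dna Sequence of the exon's region (gene orientation).
#' @param cfg A [pipeline_config()].
#' @return 0-based start position of the chosen ATG, or `NULL`.
#' @export
refine_start <- function(first_hit, region_dna, cfg = pipeline_config()) {
  est <- first_hit$t_start
  L <- nchar(region_dna)
  for (radius in c(cfg$search_radius_nt,
                   cfg$search_radius_nt + cfg$radius_extension_nt)) {
    lo <- max(0L, est - radius)
    hi <- min(L - 3L, est + radius)
    if (hi < lo) next
    pos <- lo:hi
    pos <- pos[(pos - est) %% 3L == 0L]
    if (!length(pos)) next
    codons <- substring(region_dna, pos + 1L, pos + 3L)
    pos <- pos[codons == "ATG"]
    if (length(pos)) {
      # nearest to the estimate; tie: upstream (smaller coordinate)
      pos <- pos[order(abs(pos - est), pos)]
      return(pos[1])
    }
  }
  NULL
}

#' Refine the stop codon after the last exon
#'
#' Scans in-frame codons from the end of the last aligned codon forward
#' within the search radius (extended once on failure) for the first stop
#' (TAA, TAG or TGA). The CDS ends immediately before the stop; the stop
#' codon itself is excluded from the reported protein.
#'
#' @param last_hit One-row hit tibble for the last placed exon.
#' @param region_dna Sequence of the exon's region (gene orientation).
#' @param cfg A [pipeline_config()].
#' @return 0-based position of the stop codon (equals the CDS end), or
#'   `NULL` when no in-frame stop exists in the extended window.
#' @export
refine_stop <- function(last_hit, region_dna, cfg = pipeline_config()) {
  est <- last_hit$t_end
  L <- nchar(region_dna)
  stops <- c("TAA", "TAG", "TGA")
  for (radius in c(cfg$search_radius_nt,
                   cfg$search_radius_nt + cfg$radius_extension_nt)) {
    pos <- seq.int(est, min(L - 3L, est + radius), by = 3L)
    pos <- pos[pos >= 0L]
    if (!length(pos)) next
    codons <- substring(region_dna, pos + 1L, pos + 3L)
    hit <- which(codons %in% stops)
    if (length(hit)) return(pos[hit[1]])
  }
  NULL
}
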