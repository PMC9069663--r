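# Splice-site candidate enumeration. Only the canonical GT (and minor GC)
# donor and AG acceptor intron edges are considered; candidates are
# collected in a symmetric window around the seed estimate of the exon
# boundary.

#' Enumerate splice-site candidates around a boundary estimate
#'
#' Scans every position in `[estimate - radius, estimate + radius]` (nt,
#' 0-based boundary convention: a donor boundary is the first intronic
#' base, an acceptor boundary the first exonic base after the intron).
#' Positions whose intron-edge dinucleotide matches (`GT`/`GC` for donors,
#' `AG` for acceptors) yield one candidate each with its scoring context
#' (donor: 3 exonic + 6 intronic nt; acceptor: 20 intronic + 3 exonic nt).
#' Candidates whose context would run off the region are dropped; windows
#' are silently clipped at region ends.
#'
#' @param dna Region sequence (gene orientation).
#' @param kind `"donor"` or `"acceptor"`.
#' @param estimate 0-based boundary estimate.
#' @param radius Search radius in nt.
#' @param model Optional [splice_score_model()]; when given, candidates are
#'   scored.
#' @param cfg A [pipeline_config()] (unused thresholds are applied later,
#'   at pair selection).
#' @return Tibble (`kind`, `boundary`, `motif`, `context`, `score`) sorted
#'   by position.
#' @export
enumerate_candidates <- function(dna, kind = c("donor", "acceptor"),
                                 estimate, radius,
                                 model = NULL, cfg = pipeline_config()) {
  kind <- match.arg(kind)
  L <- nchar(dna)
  lo <- max(0L, as.integer(estimate) - as.integer(radius))
  hi <- min(L, as.integer(estimate) + as.integer(radius))
  if (hi < lo) {
    return(tibble(kind = character(), boundary = integer(),
                  motif = character(), context = character(),
                  score = numeric()))
  }
  pos <- lo:hi
  substr0 <- function(first, last) {
    if (!length(first)) character() else substring(dna, first, last)
  }
  if (kind == "donor") {
    # context [p - 3, p + 6); motif at [p, p + 2)
    ok <- pos >= DONOR_EXONIC & pos + (DONOR_WIDTH - DONOR_EXONIC) <= L
    pos <- pos[ok]
    motif <- substr0(pos + 1L, pos + 2L)
    keep <- motif %in% c("GT", "GC")
    pos <- pos[keep]
    motif <- motif[keep]
    context <- substr0(pos - DONOR_EXONIC + 1L,
                       pos + DONOR_WIDTH - DONOR_EXONIC)
  } else {
    # context [b - 20, b + 3); motif at [b - 2, b)
    ok <- pos >= ACCEPTOR_INTRONIC &
      pos + (ACCEPTOR_WIDTH - ACCEPTOR_INTRONIC) <= L
    pos <- pos[ok]
    motif <- substr0(pos - 1L, pos)
    keep <- motif == "AG"
    pos <- pos[keep]
    motif <- motif[keep]
    context <- substr0(pos - ACCEPTOR_INTRONIC + 1L,
                       pos + ACCEPTOR_WIDTH - ACCEPTOR_INTRONIC)
  }
  out <- tibble(
    kind = rep(kind, length(pos)),
    boundary = as.integer(pos),
    motif = motif,
    context = context,
    score = rep(NA_real_, length(pos))
  )
  if (!is.null(model) && nrow(out)) {
    out$score <- score_splice_sites(out$context, kind, model)
  }
  out[order(out$boundary), ]
}
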