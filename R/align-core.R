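# Built-in translated local alignment used by seeding and rescue.
# Protein exon vs frame-wise translation of the target, local affine
# alignment under BLOSUM62 (gap open 11 / extend 1, the de facto defaults
# of protein-vs-DNA search tools), with Karlin-Altschul conversion of raw
# scores to bits.

.align_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_env$BLOSUM62 <- e$BLOSUM62
  }
  .align_env$BLOSUM62
}

#' Convert a raw local-alignment score to bits
#'
#' Karlin-Altschul normalisation `(lambda * S - ln K) / ln 2` with the
#' ungapped BLOSUM62 parameters carried in the configuration.
#'
#' @param raw Raw alignment score(s).
#' @param cfg A [pipeline_config()].
#' @return Numeric bit score(s).
#' @export
ka_bits <- function(raw, cfg = pipeline_config()) {
  (cfg$ka_lambda * raw - log(cfg$ka_k)) / log(2)
}

# Translate a DNA string (length a multiple of 3). N-containing codons
# yield X; the fuzzy-codon machinery is only engaged when N is present.
translate_dna <- function(dna) {
  x <- Biostrings::DNAString(dna)
  if (grepl("N", dna, fixed = TRUE)) {
    as.character(Biostrings::translate(x, if.fuzzy.codon = "X"))
  } else {
    as.character(Biostrings::translate(x))
  }
}

# Three forward-frame translations of a DNA string; list of
# list(aa = character, frame = 0:2). Frames shorter than one codon are
# dropped.
translate_frames <- function(dna) {
  L <- nchar(dna)
  out <- list()
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < 1L) next
    aa <- translate_dna(substring(dna, f + 1L, f + 3L * n_codons))
    out[[length(out) + 1L]] <- list(aa = aa, frame = f)
  }
  out
}

# Best local alignment of one peptide against the frame translations of a
# DNA string. Returns NULL when nothing aligns (or the dna is shorter than
# a codon), else a one-row tibble with nt/aa spans (0-based half-open on
# the dna / peptide), raw score, bits and identity.
align_peptide_dna <- function(peptide, dna, cfg) {
  frames <- translate_frames(dna)
  if (!length(frames) || !nzchar(peptide)) return(NULL)
  best <- NULL
  pat <- Biostrings::AAString(peptide)
  for (fr in frames) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = pat,
      subject = Biostrings::AAString(fr$aa),
      type = "local",
      substitutionMatrix = blosum62(),
      gapOpening = cfg$gap_opening,
      gapExtension = cfg$gap_extension
    )
    sc <- Biostrings::score(pa)
    if (is.null(best) || sc > best$raw) {
      p <- Biostrings::pattern(pa)
      s <- Biostrings::subject(pa)
      ss <- Biostrings::start(s)
      se <- Biostrings::end(s)
      best <- tibble(
        nt_start = fr$frame + 3L * (ss - 1L),
        nt_end = fr$frame + 3L * se,
        q_start = Biostrings::start(p) - 1L,
        q_end = Biostrings::end(p),
        raw = sc,
        identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      )
    }
  }
  if (is.null(best) || best$raw <= 0) return(NULL)
  best$bits <- ka_bits(best$raw, cfg)
  best
}
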