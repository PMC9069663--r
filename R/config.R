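#' Pipeline configuration
#'
#' Bundles every tunable threshold of the exon-centric alignment pipeline.
#' Defaults follow the conventions of homology-based annotation practice:
#' seeding refuses to chain exons across gaps larger than `max_intron`;
#' seed hits missing more than `trunc_start_aa` residues at the start or
#' `trunc_end_aa` at the end of their exon are discarded; rescue hits must
#' exceed `rescue_min_bits` bits; inter-exon gaps below `merge_gap_nt` are
#' merges, gaps below `min_intron_nt` are readthroughs, anything larger is
#' treated as an intron; splice-site search scans `search_radius_nt` around
#' the seed estimate and is widened once by `radius_extension_nt` on
#' failure; candidate sites must score above `min_score` (log2-odds) and
#' sites above `reliable_score` are considered reliable.
#'
#' @param max_intron Maximum intron length (nt) bridged during seed chaining.
#' @param trunc_start_aa,trunc_end_aa Truncation-filter thresholds
#'   (amino acids missing at the exon start / end; strict inequalities).
#' @param rescue_min_bits Minimum bit score for a rescued exon hit (strict).
#' @param merge_gap_nt Gaps below this are annotated as exon merges.
#' @param min_intron_nt Minimum length (nt) for a gap to be an intron;
#'   shorter gaps (above `merge_gap_nt`) are readthroughs.
#' @param search_radius_nt Splice-site search radius around the seed
#'   estimate (symmetric, nt).
#' @param radius_extension_nt One-time widening of the radius when no
#'   admissible junction is found.
#' @param reliable_score,min_score Log2-odds cutoffs for reliable and
#'   minimally admissible splice-site scores.
#' @param gap_opening,gap_extension Affine gap penalties of the built-in
#'   protein-vs-translated-DNA aligner (BLOSUM62).
#' @param ka_lambda,ka_k Karlin-Altschul parameters used to convert raw
#'   alignment scores to bit scores (ungapped BLOSUM62 defaults).
#' @param translation_table NCBI translation table id (only 1 supported).
#' @param random_seed Optional integer seed, used by fixture generation only.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(max_intron = 10000)
#' cfg$max_intron
#' @export
pipeline_config <- function(max_intron = 20000L,
                            trunc_start_aa = 12L,
                            trunc_end_aa = 10L,
                            rescue_min_bits = 50,
                            merge_gap_nt = 5L,
                            min_intron_nt = 21L,
                            search_radius_nt = 35L,
                            radius_extension_nt = 18L,
                            reliable_score = 3,
                            min_score = -10,
                            gap_opening = 11,
                            gap_extension = 1,
                            ka_lambda = 0.3176,
                            ka_k = 0.134,
                            translation_table = 1L,
                            random_seed = NULL) {
  cfg <- list(
    max_intron = as.integer(max_intron),
    trunc_start_aa = as.integer(trunc_start_aa),
    trunc_end_aa = as.integer(trunc_end_aa),
    rescue_min_bits = as.numeric(rescue_min_bits),
    merge_gap_nt = as.integer(merge_gap_nt),
    min_intron_nt = as.integer(min_intron_nt),
    search_radius_nt = as.integer(search_radius_nt),
    radius_extension_nt = as.integer(radius_extension_nt),
    reliable_score = as.numeric(reliable_score),
    min_score = as.numeric(min_score),
    gap_opening = as.numeric(gap_opening),
    gap_extension = as.numeric(gap_extension),
    ka_lambda = as.numeric(ka_lambda),
    ka_k = as.numeric(ka_k),
    translation_table = as.integer(translation_table),
    random_seed = if (is.null(random_seed)) NULL else as.integer(random_seed)
  )
  lens <- c("max_intron", "trunc_start_aa", "trunc_end_aa", "merge_gap_nt",
            "min_intron_nt", "search_radius_nt", "radius_extension_nt")
  for (nm in lens) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      abort(sprintf("pipeline_config: `%s` must be a positive length", nm),
            class = "exonalign_config_error")
    }
  }
  if (!cfg$min_score < cfg$reliable_score) {
    abort("pipeline_config: `min_score` must be below `reliable_score`",
          class = "exonalign_config_error")
  }
  if (!cfg$merge_gap_nt < cfg$min_intron_nt) {
    abort("pipeline_config: `merge_gap_nt` must be below `min_intron_nt`",
          class = "exonalign_config_error")
  }
  if (cfg$translation_table != 1L) {
    abort("pipeline_config: only the standard translation table (1) is supported",
          class = "exonalign_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

as_pipeline_config <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) return(cfg)
  do.call(pipeline_config, cfg)
}
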