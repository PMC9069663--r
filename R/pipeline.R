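# Pipeline orchestration: seeding -> truncation filter -> intervening
# targets -> rescue -> gap classification -> junction refinement (with
# extension/rejection) -> terminal refinement -> assembly -> outputs,
# with a run manifest recording configuration and per-stage counts.

#' Align an exon-annotated query to target regions
#'
#' Runs the full exon-centric spliced alignment pipeline and returns the
#' assembled gene model together with a run manifest (configuration
#' snapshot, per-stage counts and wall-clock timings). Externally computed
#' seed alignments (from [read_psl()] or [read_tabular_hits()]) may be
#' supplied in place of the built-in seeder; they pass through the same
#' truncation filter, chaining and rescue stages.
#'
#' @param query An [exon_query()].
#' @param regions Target-regions tibble.
#' @param cfg A [pipeline_config()].
#' @param model A [splice_score_model()].
#' @param seeds Optional externally computed seed-hit tibble.
#' @return List with `model` (a `gene_model`), `manifest`, and `regions`
#'   (the regions as used, reoriented where the evidence demanded it).
#' @examples
#' \donttest{
#' gene <- simulate_gene(n_exons = 3, seed = 7)
#' res <- align_exons(gene$query, target_region("t", gene$genome))
#' res$model
#' }
#' @export
align_exons <- function(query, regions, cfg = pipeline_config(),
                        model = splice_score_model(), seeds = NULL) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (is.null(seeds)) {
    raw <- seed_exons(query, regions, cfg)
    regions <- attr(raw, "regions")
  } else {
    minus <- attr(seeds, "minus_regions") %||% character()
    for (id in minus) {
      regions <- flip_region(regions, match(id, regions$region_id))
    }
    raw <- chain_and_dedupe(seeds, max_gap = cfg$max_intron)
  }
  timings["seeding"] <- tic() - t0

  t1 <- tic()
  filtered <- filter_truncated(raw, query, cfg)
  targets <- build_intervening_targets(filtered, regions, query)
  rescued <- rescue_missing(query, targets, regions, cfg)
  combined <- combine_hits(filtered, rescued)
  timings["rescue"] <- tic() - t1

  t2 <- tic()
  ref <- refine_junctions(combined, regions, query, model, cfg)
  term <- refine_terminals(ref, regions, cfg)
  timings["refinement"] <- tic() - t2

  t3 <- tic()
  gm <- assemble_gene_model(term, regions, query, cfg)
  timings["assembly"] <- tic() - t3

  counts <- list(
    seeded = nrow(raw),
    filtered_out = nrow(raw) - nrow(filtered),
    rescued = nrow(rescued),
    collinearity_dropped = nrow(filtered) + nrow(rescued) - nrow(combined),
    entering_refinement = nrow(combined),
    merged = nrow(gm$merges),
    readthroughs = nrow(gm$readthroughs),
    rejected = nrow(term$rejected),
    missing = sum(gm$exons$status == "missing")
  )
  stopifnot(counts$seeded - counts$filtered_out + counts$rescued -
              counts$collinearity_dropped == counts$entering_refinement)
  manifest <- list(
    tool = "exonalign",
    version = as.character(utils::packageVersion("exonalign")),
    config = unclass(cfg),
    splice_model = model$model_id,
    seeder = if (is.null(seeds)) "internal" else "external",
    counts = counts,
    warnings = gm$warnings,
    timings_sec = as.list(round(timings, 3))
  )
  list(model = gm, manifest = manifest, regions = regions)
}

#' Run the pipeline on files
#'
#' Thin file-level wrapper around [align_exons()]: reads the query (FASTA
#' plus exon-span TSV, or per-exon FASTA), the target multi-FASTA
#' (optionally restricted by a BED file), and optional external seed
#' alignments; writes the four output files and a JSON manifest when
#' `out_prefix` is given.
#'
#' @param query_path Protein query FASTA.
#' @param target_path Target multi-FASTA.
#' @param exons_path Optional exon-span TSV (omit for per-exon FASTA).
#' @param bed_path Optional BED restriction of the targets.
#' @param psl_path,tab_path Optional external seed alignments (PSL or
#'   12-column tabular).
#' @param out_prefix Optional output prefix for [write_gene_model()].
#' @param cfg A [pipeline_config()].
#' @param model A [splice_score_model()] (or a path / `"builtin"`).
#' @return The [align_exons()] result, invisibly when writing output.
#' @export
run_pipeline <- function(query_path, target_path, exons_path = NULL,
                         bed_path = NULL, psl_path = NULL, tab_path = NULL,
                         out_prefix = NULL,
                         cfg = pipeline_config(),
                         model = splice_score_model()) {
  if (!inherits(model, "splice_score_model")) {
    model <- splice_score_model(model)
  }
  query <- read_exon_query(query_path, exons_path)
  regions <- read_target_regions(target_path, bed_path)
  seeds <- NULL
  if (!is.null(psl_path)) {
    seeds <- read_psl(psl_path, query)
  } else if (!is.null(tab_path)) {
    seeds <- read_tabular_hits(tab_path, regions, query)
  }
  res <- align_exons(query, regions, cfg, model, seeds = seeds)
  res$manifest$inputs <- list(
    query = unname(tools::md5sum(query_path)),
    target = unname(tools::md5sum(target_path)),
    exons = if (!is.null(exons_path)) unname(tools::md5sum(exons_path))
  )
  if (!is.null(out_prefix)) {
    write_gene_model(res$model, out_prefix, res$regions)
    jsonlite::write_json(res$manifest, paste0(out_prefix, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
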