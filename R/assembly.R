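# Stage 5: terminal refinement bookkeeping and assembly of refined exons
# into a gene model: spliced CDS, translation, per-exon peptides with
# junction-split residues excluded, and aggregated warnings.

#' Refine terminal exon boundaries of a junction-refined chain
#'
#' Applies [refine_start()] to the first surviving exon and
#' [refine_stop()] to the last. A first exon without an in-frame ATG in
#' the extended window is rejected (dropped with a warning, mirroring the
#' treatment of first exons lacking a start codon); a missing stop only
#' flags the model as 3'-incomplete.
#'
#' @param refinement Output of [refine_junctions()].
#' @param regions Target-regions tibble.
#' @param cfg A [pipeline_config()].
#' @return The refinement list extended with `start_pos`, `stop_pos` and
#'   `completeness`.
#' @export
refine_terminals <- function(refinement, regions, cfg = pipeline_config()) {
  ex <- refinement$exons
  jn <- refinement$junctions
  warnings <- refinement$warnings
  rejected <- refinement$rejected
  start_pos <- NULL
  stop_pos <- NULL
  has_start <- FALSE
  has_stop <- FALSE
  if (nrow(ex)) {
    dna1 <- regions$dna[match(ex$region_id[1], regions$region_id)]
    start_pos <- refine_start(ex[1, ], dna1, cfg)
    if (is.null(start_pos)) {
      rej <- ex$exon_index[1]
      warnings <- c(warnings, sprintf(
        "exon %d rejected: no in-frame start codon (ATG) in the extended window",
        rej))
      rejected <- bind_rows(rejected, tibble(
        exon_index = rej, reason = "no start codon"))
      jn <- jn[jn$upstream_exon != rej & jn$downstream_exon != rej, ]
      ex <- ex[-1, ]
    } else {
      has_start <- TRUE
    }
  }
  if (nrow(ex)) {
    nlast <- nrow(ex)
    dnaN <- regions$dna[match(ex$region_id[nlast], regions$region_id)]
    stop_pos <- refine_stop(ex[nlast, ], dnaN, cfg)
    if (is.null(stop_pos)) {
      warnings <- c(warnings, "no in-frame stop codon in the extended window; model is 3'-incomplete")
    } else {
      has_stop <- TRUE
    }
  }
  list(exons = ex, junctions = jn, rejected = rejected,
       warnings = warnings, start_pos = start_pos, stop_pos = stop_pos,
       completeness = list(has_start = has_start, has_stop = has_stop))
}

translate_cds <- function(cds) {
  n <- (nchar(cds) %/% 3L) * 3L
  if (n < 3L) return("")
  translate_dna(substring(cds, 1L, n))
}

#' Assemble a gene model from refined exons
#'
#' Splices the CDS from the refined spans (merged pairs concatenated
#' seamlessly, readthrough gaps included in the CDS and absorbed into the
#' upstream exon's record, introns excised at the chosen junctions),
#' translates it, computes boundary phases, and extracts per-exon peptides
#' with junction-split residues excluded (those residues appear in the
#' complete protein only).
#'
#' @param refinement Output of [refine_terminals()].
#' @param regions Target-regions tibble.
#' @param query The [exon_query()].
#' @param cfg A [pipeline_config()].
#' @return An object of class `gene_model`.
#' @export
assemble_gene_model <- function(refinement, regions, query,
                                cfg = pipeline_config()) {
  ex <- refinement$exons
  jn <- refinement$junctions
  warnings <- refinement$warnings
  comp <- refinement$completeness
  if (!nrow(ex)) {
    abort("no exon survived refinement; cannot assemble a gene model",
          class = "exonalign_empty_model",
          warnings = warnings)
  }
  n <- nrow(ex)
  left <- integer(n)
  right <- integer(n)
  left[1] <- if (comp$has_start) refinement$start_pos else ex$t_start[1]
  merges <- list()
  readthroughs <- list()
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      j <- jn[jn$upstream_exon == ex$exon_index[k] &
                jn$downstream_exon == ex$exon_index[k + 1L], ]
      if (nrow(j) != 1L) {
        abort("internal error: junction table inconsistent with exon chain",
              class = "exonalign_internal_error")
      }
      if (j$type %in% c("intron", "inter_region")) {
        right[k] <- j$donor_boundary
        left[k + 1L] <- j$acceptor_boundary
      } else {
        right[k] <- j$boundary
        left[k + 1L] <- j$boundary
        if (j$type == "merge") {
          merges[[length(merges) + 1L]] <- tibble(
            upstream_exon = j$upstream_exon,
            downstream_exon = j$downstream_exon)
        } else {
          readthroughs[[length(readthroughs) + 1L]] <- tibble(
            region_id = ex$region_id[k],
            start = ex$t_end[k], end = ex$t_start[k + 1L],
            upstream_exon = ex$exon_index[k],
            downstream_exon = ex$exon_index[k + 1L])
        }
      }
    }
  }
  right[n] <- if (comp$has_stop) refinement$stop_pos else ex$t_end[n]
  bad <- right < left
  if (any(bad)) {
    warnings <- c(warnings, sprintf(
      "exon %s has an inverted refined span; clamped",
      paste(ex$exon_index[bad], collapse = ",")))
    right[bad] <- pmax(right[bad], left[bad])
  }
  seqs <- map_chr(seq_len(n), function(k) {
    dna <- regions$dna[match(ex$region_id[k], regions$region_id)]
    substring(dna, left[k] + 1L, right[k])
  })
  span_len <- nchar(seqs)
  cds <- paste(seqs, collapse = "")
  cum <- cumsum(span_len)
  right_phase <- c(as.integer(cum[-n] %% 3L), 0L)
  left_phase <- c(0L, right_phase[-n])
  if (n == 1L) { right_phase <- 0L; left_phase <- 0L }

  protein <- translate_cds(cds)
  if (comp$has_start && comp$has_stop && nchar(cds) %% 3L != 0L) {
    warnings <- c(warnings,
                  "frame anomaly: CDS length is not a multiple of 3 despite resolved termini")
  }
  if (grepl("\\*", protein)) {
    if (length(readthroughs)) {
      warnings <- c(warnings, "internal stop codon inside the predicted protein (readthrough segment present)")
    } else {
      warnings <- c(warnings, "frame anomaly: internal stop codon inside the predicted protein")
    }
  }

  peptides <- character(n)
  for (k in seq_len(n)) {
    lead <- (3L - left_phase[k]) %% 3L
    trail <- right_phase[k]
    mid <- span_len[k] - lead - trail
    peptides[k] <- if (mid >= 3L) {
      translate_cds(substring(seqs[k], lead + 1L, lead + mid))
    } else ""
  }
  split_residues <- map_chr(which(right_phase > 0L), function(k) {
    aa_idx <- (cum[k] - right_phase[k]) %/% 3L  # 0-based index in protein
    substring(protein, aa_idx + 1L, aa_idx + 1L)
  })

  # per-exon junction annotations
  jn_up <- jn[match(ex$exon_index, jn$upstream_exon), ]
  status <- ex$status
  merged_up <- jn$upstream_exon[jn$type == "merge"]
  status[ex$exon_index %in% merged_up] <- "merged_with_next"
  exon_warn <- ifelse(ex$identity < 0.3,
                      "weak identity (< 0.3)", NA_character_)

  exons_out <- tibble(
    exon_index = ex$exon_index,
    region_id = ex$region_id,
    start = left, end = right,
    status = status,
    left_phase = left_phase, right_phase = right_phase,
    peptide = peptides,
    identity = ex$identity, score = ex$score,
    donor_score = jn_up$donor_score,
    acceptor_score = c(NA_real_, jn[match(ex$exon_index[-1], jn$downstream_exon), ]$acceptor_score),
    n = jn_up$n,
    n_prime = c(NA_integer_, jn[match(ex$exon_index[-1], jn$downstream_exon), ]$n_prime),
    s = jn_up$s,
    extended = jn_up$extended,
    warning = exon_warn
  )
  if (n == 1L) {
    exons_out$acceptor_score <- NA_real_
    exons_out$n_prime <- NA_integer_
  }
  # rows for rejected / never-placed exons so nothing silently vanishes
  absent <- setdiff(query$exons$exon_index, ex$exon_index)
  if (length(absent)) {
    rej <- refinement$rejected
    absent_rows <- tibble(
      exon_index = absent,
      region_id = NA_character_,
      start = NA_integer_, end = NA_integer_,
      status = ifelse(absent %in% rej$exon_index, "rejected", "missing"),
      left_phase = NA_integer_, right_phase = NA_integer_,
      peptide = "", identity = NA_real_, score = NA_real_,
      donor_score = NA_real_, acceptor_score = NA_real_,
      n = NA_integer_, n_prime = NA_integer_, s = NA_integer_,
      extended = NA,
      warning = ifelse(absent %in% rej$exon_index,
                       rej$reason[match(absent, rej$exon_index)],
                       "not recovered by seeding or rescue")
    )
    exons_out <- bind_rows(exons_out, absent_rows)
    exons_out <- exons_out[order(exons_out$exon_index), ]
    missing_only <- setdiff(absent, rej$exon_index)
    if (length(missing_only)) {
      warnings <- c(warnings, sprintf(
        "exon %s not recovered by seeding or rescue",
        paste(missing_only, collapse = ",")))
    }
  }
  if (any(!is.na(exons_out$warning) & exons_out$status %in% c("seeded", "rescued", "merged_with_next"))) {
    weak <- exons_out$exon_index[!is.na(exons_out$warning) &
                                   exons_out$warning == "weak identity (< 0.3)"]
    if (length(weak)) {
      warnings <- c(warnings, sprintf("exon %s has weak identity (< 0.3)",
                                      paste(weak, collapse = ",")))
    }
  }

  structure(
    list(
      query_id = query$query_id,
      exons = exons_out,
      junctions = jn,
      cds = cds,
      protein = protein,
      split_residues = split_residues,
      merges = if (length(merges)) bind_rows(merges) else
        tibble(upstream_exon = integer(), downstream_exon = integer()),
      readthroughs = if (length(readthroughs)) bind_rows(readthroughs) else
        tibble(region_id = character(), start = integer(), end = integer(),
               upstream_exon = integer(), downstream_exon = integer()),
      warnings = warnings,
      completeness = comp
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  placed <- sum(x$exons$status %in% c("seeded", "rescued", "merged_with_next"))
  cat(sprintf("<gene_model> %s: %d/%d exon(s) placed, CDS %d nt, protein %d aa\n",
              x$query_id, placed, nrow(x$exons), nchar(x$cds),
              nchar(x$protein)))
  cat(sprintf("  start codon: %s; stop codon: %s\n",
              ifelse(x$completeness$has_start, "yes", "no"),
              ifelse(x$completeness$has_stop, "yes", "no")))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
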