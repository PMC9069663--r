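# Synthetic-fixture generator: genes with known exon/intron structure
# planted in random background sequence, so every stage of the pipeline is
# verifiable against planted truth. Planted splice contexts are sampled
# from the bundled scorer's own frequencies and rejection-sampled so that
# (a) every planted donor/acceptor scores above the reliability cutoff and
# (b) the planted pair is the admissible argmax in its search window -
# fixture difficulty is therefore controlled by explicitly planted decoys,
# never by accidental look-alike sites.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# uniform integer draw on [lo, hi], safe for lo == hi
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

sense_codons <- function() {
  all64 <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  setdiff(all64, STOP_CODONS)
}

# TRUE iff the planted donor/acceptor pair is the admissible argmax for
# every boundary estimate the seeding stage can produce. For a phase > 0
# junction the donor-side estimate may sit one codon downstream of the last
# full codon (the junction-spanning codon can translate to the split
# residue and be recruited into the seed alignment), so dominance is
# checked against both candidate estimates.
planted_pair_dominates <- function(dna, d_true, a_true, phase, model, cfg) {
  est_a <- a_true + (3L - phase) %% 3L
  base_est <- d_true - phase
  ests <- if (phase > 0L) c(base_est, base_est + 3L) else base_est
  acceptors <- enumerate_candidates(dna, "acceptor", est_a,
                                    cfg$search_radius_nt, model, cfg)
  for (est_d in ests) {
    donors <- enumerate_candidates(dna, "donor", est_d,
                                   cfg$search_radius_nt, model, cfg)
    sel <- select_junction(donors, acceptors, est_d, est_a, cfg)
    if (is.null(sel) || sel$donor_boundary != d_true ||
        sel$acceptor_boundary != a_true) {
      return(FALSE)
    }
  }
  TRUE
}

sample_context <- function(probs, force = NULL) {
  ctx <- vapply(seq_len(ncol(probs)), function(j) {
    sample(BASES, 1L, prob = probs[, j])
  }, character(1))
  if (!is.null(force)) {
    for (nm in names(force)) ctx[as.integer(nm)] <- force[[nm]]
  }
  paste(ctx, collapse = "")
}

#' Generate a gene with known exon/intron structure
#'
#' Builds a stop-free CDS of random sense codons, cuts it into exons at
#' phase-consistent boundaries, joins them with introns whose donor
#' (GT, or GC with probability `gc_donor_prob`) and acceptor (AG) contexts
#' are sampled from the scoring model and guaranteed to score above
#' `cfg$reliable_score`, and embeds the gene (start codon first, stop
#' codon planted right after the last exon) in random flanking sequence.
#' Each planted junction is verified to be the best admissible
#' donor/acceptor pair within the pipeline's search window; accidental
#' stronger competitors are resampled away. Deterministic for a fixed
#' `seed`.
#'
#' @param n_exons Number of exons (>= 1).
#' @param exon_aa Length-2 range of exon sizes in amino acids.
#' @param intron_nt Length-2 range of intron lengths in nt
#'   (min >= `cfg$min_intron_nt`; values above `cfg$max_intron` exercise
#'   the rescue path).
#' @param gc_donor_prob Probability that a planted donor is GC rather than
#'   GT (default: the minor-donor rate of mammalian introns, 0.69%).
#' @param substitution_rate Amino-acid substitution rate applied to the
#'   query copy of the protein (the genome stays ground truth).
#' @param n_decoys Decoy GT/AG motifs planted per intron interior to
#'   stress candidate selection.
#' @param intron_lengths Optional exact per-junction intron lengths
#'   (length `n_exons - 1`); overrides `intron_nt`.
#' @param flank_nt Length-2 range of the intergenic flanks.
#' @param seed Integer seed (optional).
#' @param model Scoring model used for rejection sampling.
#' @param cfg A [pipeline_config()].
#' @param query_id Identifier for the derived query.
#' @return An object of class `planted_gene`: `genome`, `true_exons`
#'   (tibble of genomic spans), `true_phases`, `true_protein`, `stop_pos`,
#'   `query` (an [exon_query()], mutated copy when
#'   `substitution_rate > 0`), and `params`.
#' @export
simulate_gene <- function(n_exons = 5L,
                          exon_aa = c(20L, 60L),
                          intron_nt = c(60L, 5000L),
                          gc_donor_prob = 0.0069,
                          substitution_rate = 0,
                          n_decoys = 0L,
                          intron_lengths = NULL,
                          flank_nt = c(200L, 500L),
                          seed = NULL,
                          model = splice_score_model(),
                          cfg = pipeline_config(),
                          query_id = "synq") {
  if (n_exons < 1L) {
    abort("n_exons must be >= 1", class = "exonalign_fixture_error")
  }
  if (exon_aa[1] < 2L) {
    abort("exons must be at least 2 aa", class = "exonalign_fixture_error")
  }
  if (!is.null(intron_lengths)) {
    if (length(intron_lengths) != n_exons - 1L) {
      abort("intron_lengths must have length n_exons - 1",
            class = "exonalign_fixture_error")
    }
    intron_nt <- range(intron_lengths)
  }
  if (intron_nt[1] < max(cfg$min_intron_nt, 26L)) {
    abort("intron range must allow at least min_intron_nt (and the planted contexts)",
          class = "exonalign_fixture_error")
  }
  build <- function() .simulate_gene_impl(
    n_exons, exon_aa, intron_nt, gc_donor_prob, substitution_rate,
    n_decoys, intron_lengths, flank_nt, model, cfg, query_id, seed)
  if (!is.null(seed)) withr::with_seed(as.integer(seed), build()) else build()
}

.simulate_gene_impl <- function(n_exons, exon_aa, intron_nt, gc_donor_prob,
                                substitution_rate, n_decoys, intron_lengths,
                                flank_nt, model, cfg, query_id, seed) {
  for (attempt in 1:5) {
    g <- .try_build_gene(n_exons, exon_aa, intron_nt, gc_donor_prob,
                         n_decoys, intron_lengths, flank_nt, model, cfg)
    if (!is.null(g)) break
  }
  if (is.null(g)) {
    abort("fixture generation failed to satisfy the dominance constraint",
          class = "exonalign_fixture_error")
  }
  prot <- g$true_protein
  query_prot <- prot
  if (substitution_rate > 0) {
    aa <- strsplit(prot, "")[[1]]
    flip <- which(stats::runif(length(aa)) < substitution_rate)
    letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in flip) aa[i] <- sample(setdiff(letters20, aa[i]), 1L)
    query_prot <- paste(aa, collapse = "")
  }
  a <- g$aa_counts
  ends <- cumsum(a)
  spans <- cbind(c(0L, head(ends, -1L)), ends)
  query <- exon_query(query_prot, spans, g$phases, query_id = query_id)
  structure(
    list(
      genome = g$genome,
      true_exons = g$true_exons,
      true_phases = g$phases,
      true_protein = prot,
      stop_pos = g$stop_pos,
      cds = g$cds,
      query = query,
      params = list(n_exons = n_exons, exon_aa = exon_aa,
                    intron_nt = intron_nt, gc_donor_prob = gc_donor_prob,
                    substitution_rate = substitution_rate,
                    n_decoys = n_decoys, flank_nt = flank_nt, seed = seed)
    ),
    class = "planted_gene"
  )
}

.try_build_gene <- function(n_exons, exon_aa, intron_nt, gc_donor_prob,
                            n_decoys, intron_lengths, flank_nt, model, cfg) {
  dp <- model_probs(model, "donor")
  ap <- model_probs(model, "acceptor")
  a <- sample_range(exon_aa[1], exon_aa[2], n_exons)
  phases <- if (n_exons > 1L) sample(0:2, n_exons - 1L, replace = TRUE)
            else integer()
  total_aa <- sum(a)
  codons <- c("ATG", sample(sense_codons(), total_aa - 1L, replace = TRUE))
  cds <- paste(codons, collapse = "")
  p_prev <- c(0L, phases)          # phase entering exon i
  p_next <- c(phases, 0L)          # phase leaving exon i
  lens <- (3L - p_prev) %% 3L + 3L * (a - as.integer(p_next > 0L)) + p_next
  stopifnot(sum(lens) == 3L * total_aa)
  bnd <- c(0L, cumsum(lens))
  pieces <- substring(cds, bnd[-length(bnd)] + 1L, bnd[-1])
  intron_lens <- if (n_exons <= 1L) integer()
  else if (!is.null(intron_lengths)) as.integer(intron_lengths)
  else sample_range(intron_nt[1], intron_nt[2], n_exons - 1L)
  introns <- character(max(0L, n_exons - 1L))

  ok_all <- TRUE
  if (n_exons > 1L) {
    for (i in seq_len(n_exons - 1L)) {
      built <- FALSE
      for (try in 1:60) {
        gc <- stats::runif(1) < gc_donor_prob
        dctx <- sample_context(dp, force = list(`4` = "G",
                                                `5` = if (gc) "C" else "T"))
        actx <- sample_context(ap, force = list(`22` = "A", `23` = "G"))
        # context layout: donor = 3 exonic + 6 intronic;
        # acceptor = 20 intronic + 3 exonic
        if (score_splice_sites(dctx, "donor", model) <= cfg$reliable_score)
          next
        if (score_splice_sites(actx, "acceptor", model) <= cfg$reliable_score)
          next
        new_up <- paste0(substring(pieces[i], 1L, nchar(pieces[i]) - 3L),
                         substring(dctx, 1L, 3L))
        new_down <- paste0(substring(actx, 21L, 23L),
                           substring(pieces[i + 1L], 4L))
        trial <- pieces
        trial[i] <- new_up
        trial[i + 1L] <- new_down
        if (grepl("\\*", translate_cds(paste(trial, collapse = "")))) next
        interior <- random_dna(intron_lens[i] - 26L)
        if (n_decoys > 0L && nchar(interior) > 60L) {
          for (d in seq_len(n_decoys)) {
            dec <- if (d %% 2L == 1L) {
              sample_context(dp, force = list(`4` = "G", `5` = "T"))
            } else {
              sample_context(ap, force = list(`22` = "A", `23` = "G"))
            }
            pos <- sample.int(nchar(interior) - nchar(dec) - 2L, 1L)
            interior <- paste0(substring(interior, 1L, pos),
                               dec,
                               substring(interior, pos + nchar(dec) + 1L))
          }
        }
        intron <- paste0(substring(dctx, 4L, 9L), interior,
                         substring(actx, 1L, 20L))
        # dominance check within the junction's own neighbourhood: the
        # planted pair must be the admissible argmax the pipeline will see
        neigh_up <- paste0(trial[i], intron, trial[i + 1L])
        d_true <- nchar(trial[i])
        a_true <- nchar(trial[i]) + nchar(intron)
        if (!planted_pair_dominates(neigh_up, d_true, a_true, p_next[i],
                                    model, cfg)) next
        pieces <- trial
        introns[i] <- intron
        built <- TRUE
        break
      }
      if (!built) { ok_all <- FALSE; break }
    }
  }
  if (!ok_all) return(NULL)

  flank5 <- random_dna(sample_range(flank_nt[1], flank_nt[2]))
  flank3 <- random_dna(sample_range(flank_nt[1], flank_nt[2]))
  stop_codon <- sample(STOP_CODONS, 1L)
  parts <- character(0)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- nchar(flank5)
  parts <- flank5
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    parts <- paste0(parts, pieces[i])
    pos <- pos + nchar(pieces[i])
    ends[i] <- pos
    if (i < n_exons) {
      parts <- paste0(parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  stop_pos <- pos
  genome <- paste0(parts, stop_codon, flank3)
  # final whole-genome verification of every planted junction
  if (n_exons > 1L) {
    for (i in seq_len(n_exons - 1L)) {
      if (!planted_pair_dominates(genome, ends[i], starts[i + 1L],
                                  p_next[i], model, cfg)) {
        return(NULL)
      }
    }
  }
  list(
    genome = genome,
    true_exons = tibble(exon_index = seq_len(n_exons),
                        start = starts, end = ends),
    phases = phases,
    aa_counts = a,
    true_protein = translate_cds(paste(pieces, collapse = "")),
    cds = paste(pieces, collapse = ""),
    stop_pos = stop_pos
  )
}

#' @export
print.planted_gene <- function(x, ...) {
  cat(sprintf("<planted_gene> %d exon(s), genome %d nt, protein %d aa\n",
              nrow(x$true_exons), nchar(x$genome), nchar(x$true_protein)))
  invisible(x)
}

#' Fragment a planted gene into target regions
#'
#' Splits the genome at the given breakpoints (which must fall in introns
#' or intergenic sequence, never inside a planted exon or the stop codon,
#' so the truth stays well-defined). Fragments flagged in `revcomp` are
#' handed over reverse-complemented with no strand declaration, emulating
#' assembly contigs whose strand the pipeline must work out itself.
#'
#' @param gene A `planted_gene`.
#' @param breakpoints Integer genome positions (0-based).
#' @param revcomp Logical vector (recycled over fragments).
#' @return List with `regions` (target-regions tibble as a user would load
#'   it) and `truth` (tibble of expected per-exon source coordinates:
#'   `exon_index`, `contig`, `start`, `end`, `strand`).
#' @export
fragment_gene <- function(gene, breakpoints = integer(), revcomp = FALSE) {
  bp <- sort(unique(as.integer(breakpoints)))
  L <- nchar(gene$genome)
  if (any(bp <= 0L | bp >= L)) {
    abort("breakpoints must lie strictly inside the genome",
          class = "exonalign_fixture_error")
  }
  forbidden <- rbind(
    cbind(gene$true_exons$start, gene$true_exons$end),
    c(gene$stop_pos, gene$stop_pos + 3L)
  )
  for (b in bp) {
    if (any(b > forbidden[, 1] & b < forbidden[, 2])) {
      abort(sprintf("breakpoint %d falls inside a planted exon", b),
            class = "exonalign_fixture_error")
    }
  }
  cuts <- c(0L, bp, L)
  k <- length(cuts) - 1L
  rc <- rep_len(revcomp, k)
  regions <- list()
  truth <- list()
  for (i in seq_len(k)) {
    s <- cuts[i]
    e <- cuts[i + 1L]
    piece <- substring(gene$genome, s + 1L, e)
    id <- sprintf("frag%d", i)
    dna <- if (rc[i]) revcomp(piece) else piece
    regions[[i]] <- target_region(id, dna, source_contig = id,
                                  source_offset = 0L, orientation = "+")
    in_piece <- gene$true_exons$start >= s & gene$true_exons$end <= e
    if (any(in_piece)) {
      te <- gene$true_exons[in_piece, ]
      plen <- e - s
      truth[[length(truth) + 1L]] <- tibble(
        exon_index = te$exon_index,
        contig = id,
        start = if (rc[i]) plen - (te$end - s) else te$start - s,
        end = if (rc[i]) plen - (te$start - s) else te$end - s,
        strand = if (rc[i]) "-" else "+"
      )
    }
  }
  list(regions = bind_rows(regions), truth = bind_rows(truth))
}

#' Write a planted gene to fixture files
#'
#' Writes the genome (or fragment) FASTA, the query protein FASTA with its
#' exon-span TSV, and a truth GFF3 of the planted exon spans.
#'
#' @param gene A `planted_gene`.
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @param fragments Optional output of [fragment_gene()]; when given the
#'   fragment FASTA is written instead of the single genome record.
#' @return The directory, invisibly.
#' @export
write_planted_gene <- function(gene, dir, name = "gene", fragments = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fragments)) {
    gset <- Biostrings::DNAStringSet(gene$genome)
    names(gset) <- sprintf("%s_genome", name)
    Biostrings::writeXStringSet(gset, file.path(dir, paste0(name, "_genome.fa")))
  } else {
    write_target_regions(fragments$regions,
                         file.path(dir, paste0(name, "_genome.fa")))
  }
  qset <- Biostrings::AAStringSet(gene$query$protein_seq)
  names(qset) <- gene$query$query_id
  Biostrings::writeXStringSet(qset, file.path(dir, paste0(name, "_query.fa")))
  write_exon_table(gene$query, file.path(dir, paste0(name, "_query_exons.tsv")))
  iv <- gff3_interval(gene$true_exons$start, gene$true_exons$end)
  gr <- GenomicRanges::GRanges(
    seqnames = sprintf("%s_genome", name),
    ranges = IRanges::IRanges(start = iv$start, end = iv$end),
    strand = "+",
    type = "CDS",
    ID = sprintf("true_exon%d", gene$true_exons$exon_index),
    exon_index = gene$true_exons$exon_index,
    phase = c(0L, gene$true_phases)
  )
  rtracklayer::export(gr, file.path(dir, paste0(name, "_truth.gff3")),
                      format = "gff3")
  invisible(dir)
}
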