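# Stage 1-2: per-exon translated seeding on the target, truncation
# filtering, construction of intervening temporary targets, and sensitive
# rescue of missing exons inside their synteny windows.

empty_hits <- function() {
  tibble(
    exon_index = integer(), region_id = character(),
    t_start = integer(), t_end = integer(),
    q_aa_start = integer(), q_aa_end = integer(),
    score = numeric(), identity = numeric(), origin = character()
  )
}

# Best-scoring collinear chain of hits within one region: positions must
# increase with exon index, small overlaps tolerated, and chain-adjacent
# hits may be at most `max_gap` nt apart. Score-weighted longest increasing
# subsequence by dynamic programming.
chain_hits <- function(hits, max_gap = Inf, overlap_slop = 15L) {
  if (nrow(hits) <= 1L) return(hits)
  h <- hits[order(hits$t_start, hits$exon_index), ]
  n <- nrow(h)
  best <- h$score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- h$exon_index[j] < h$exon_index[i] &&
        h$t_start[i] >= h$t_end[j] - overlap_slop &&
        (h$t_start[i] - h$t_end[j]) <= max_gap
      if (ok && best[j] + h$score[i] > best[i]) {
        best[i] <- best[j] + h$score[i]
        prev[i] <- j
      }
    }
  }
  # reconstruct; deterministic tie-break: higher identity, then smaller
  # target coordinate
  ord <- order(-best, -h$identity, h$t_start)
  i <- ord[1]
  keep <- integer()
  while (!is.na(i)) {
    keep <- c(i, keep)
    i <- prev[i]
  }
  h[keep, ]
}

#' Seed exons on target regions
#'
#' Aligns each query exon's peptide locally against frame translations of
#' each region (both strands unless `auto_strand = FALSE`), keeps at most
#' one hit per exon, and retains the best-scoring chain of hits consistent
#' with exon order in which chain-adjacent hits are separated by at most
#' `cfg$max_intron` nt. Exons dropped here (for example across an intron
#' longer than `max_intron`) are recovered later by [rescue_missing()].
#'
#' When the best evidence for a region lies on its reverse strand the
#' region is flipped into gene orientation; the (possibly reoriented)
#' regions tibble is attached to the result as attribute `"regions"`.
#'
#' @param query An [exon_query()].
#' @param regions Target-regions tibble.
#' @param cfg A [pipeline_config()].
#' @param auto_strand Also search the reverse strand and reorient regions
#'   whose evidence lies there.
#' @return A seed-hit tibble (`exon_index`, `region_id`, `t_start`,
#'   `t_end`, `q_aa_start`, `q_aa_end`, `score` in bits, `identity`,
#'   `origin = "seed"`), 0-based half-open coordinates in gene orientation.
#' @export
seed_exons <- function(query, regions, cfg = pipeline_config(),
                       auto_strand = TRUE) {
  peptides <- exon_peptides(query)
  aa_start <- query$exons$aa_start
  all_hits <- list()
  for (i in seq_len(nrow(regions))) {
    dna <- regions$dna[i]
    if (nchar(dna) < 3L) {
      warn(sprintf("region '%s' shorter than 3 nt; skipped",
                   regions$region_id[i]))
      next
    }
    hits_for <- function(d) {
      rows <- imap(peptides, function(pep, e) {
        a <- align_peptide_dna(pep, d, cfg)
        if (is.null(a)) return(NULL)
        tibble(
          exon_index = e, region_id = regions$region_id[i],
          t_start = a$nt_start, t_end = a$nt_end,
          q_aa_start = aa_start[e] + a$q_start,
          q_aa_end = aa_start[e] + a$q_end,
          score = a$bits, identity = a$identity, origin = "seed",
          raw = a$raw
        )
      })
      bind_rows(rows)
    }
    fwd <- hits_for(dna)
    use <- fwd
    if (auto_strand) {
      rev <- hits_for(revcomp(dna))
      if (sum(rev$raw) > sum(fwd$raw)) {
        regions <- flip_region(regions, i)
        use <- rev
      }
    }
    if (nrow(use)) all_hits[[length(all_hits) + 1L]] <- use
  }
  hits <- if (length(all_hits)) bind_rows(all_hits) else empty_hits()
  if (nrow(hits)) {
    hits <- chain_and_dedupe(hits, max_gap = cfg$max_intron)
    hits$raw <- NULL
  }
  structure(hits, regions = regions)
}

# chain per region under the gap cap, then keep one hit per exon across
# regions (best score; ties to identity, then smaller coordinate)
chain_and_dedupe <- function(hits, max_gap) {
  hits <- hits |>
    group_by(.data$region_id) |>
    group_modify_chain(max_gap = max_gap)
  hits <- hits[order(-hits$score, -hits$identity, hits$t_start), ]
  hits <- hits[!duplicated(hits$exon_index), ]
  hits[order(hits$exon_index), ]
}

group_modify_chain <- function(grouped, max_gap) {
  out <- dplyr::group_modify(grouped, function(df, key) {
    chain_hits(df, max_gap = max_gap)
  })
  ungroup(out)
}

#' Truncation filter for seed hits
#'
#' A hit is dropped when its alignment misses more than
#' `cfg$trunc_start_aa` residues at the beginning or more than
#' `cfg$trunc_end_aa` at the end of its query exon (strict inequalities:
#' exactly 12 / 10 missing residues are still kept under the defaults).
#'
#' @param hits Seed-hit tibble.
#' @param query The [exon_query()].
#' @param cfg A [pipeline_config()].
#' @return The kept hits; the dropped rows are attached as attribute
#'   `"dropped"`.
#' @export
filter_truncated <- function(hits, query, cfg = pipeline_config()) {
  if (!nrow(hits)) return(structure(hits, dropped = hits))
  drop <- is_truncated(hits, query, cfg)
  structure(hits[!drop, ], dropped = hits[drop, ],
            regions = attr(hits, "regions"))
}

is_truncated <- function(hits, query, cfg) {
  idx <- match(hits$exon_index, query$exons$exon_index)
  miss_start <- hits$q_aa_start - query$exons$aa_start[idx]
  miss_end <- query$exons$aa_end[idx] - hits$q_aa_end
  miss_start > cfg$trunc_start_aa | miss_end > cfg$trunc_end_aa
}

#' Build temporary targets between retained exons
#'
#' One intervening target per maximal run of missing exons, spanning from
#' the end of the previous retained hit to the start of the next. Runs of
#' missing first or last exons extend to the region start or end. When the
#' flanking hits sit on different regions, one target per flanking side is
#' produced and flagged ambiguous. With no retained hits at all, every
#' region becomes a rescue-all target.
#'
#' @param retained Retained seed hits (sorted by `exon_index`).
#' @param regions Target-regions tibble.
#' @param query The [exon_query()].
#' @return Tibble with `region_id`, `start`, `end`, `expected_exons`
#'   (list-column) and `ambiguous`.
#' @export
build_intervening_targets <- function(retained, regions, query) {
  empty <- tibble(region_id = character(), start = integer(),
                  end = integer(), expected_exons = list(),
                  ambiguous = logical())
  missing <- setdiff(query$exons$exon_index, retained$exon_index)
  if (!length(missing)) return(empty)
  region_len <- function(id) nchar(regions$dna[match(id, regions$region_id)])
  if (!nrow(retained)) {
    return(tibble(
      region_id = regions$region_id,
      start = 0L,
      end = map_int(regions$region_id, region_len),
      expected_exons = rep(list(missing), nrow(regions)),
      ambiguous = rep(nrow(regions) > 1L, nrow(regions))
    ))
  }
  runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
  rows <- list()
  for (run in runs) {
    prev <- retained[retained$exon_index < min(run), ]
    prev <- if (nrow(prev)) prev[which.max(prev$exon_index), ] else NULL
    nxt <- retained[retained$exon_index > max(run), ]
    nxt <- if (nrow(nxt)) nxt[which.min(nxt$exon_index), ] else NULL
    add <- function(region_id, start, end, ambiguous) {
      rows[[length(rows) + 1L]] <<- tibble(
        region_id = region_id,
        start = as.integer(max(0L, start)),
        end = as.integer(max(max(0L, start), end)),
        expected_exons = list(run), ambiguous = ambiguous
      )
    }
    if (!is.null(prev) && !is.null(nxt)) {
      if (prev$region_id == nxt$region_id) {
        add(prev$region_id, prev$t_end, nxt$t_start, FALSE)
      } else {
        add(prev$region_id, prev$t_end, region_len(prev$region_id), TRUE)
        add(nxt$region_id, 0L, nxt$t_start, TRUE)
      }
    } else if (is.null(prev)) {
      add(nxt$region_id, 0L, nxt$t_start, FALSE)
    } else {
      add(prev$region_id, prev$t_end, region_len(prev$region_id), FALSE)
    }
  }
  bind_rows(rows)
}

#' Rescue missing exons inside their synteny windows
#'
#' Each missing exon is searched only in the intervening target(s) in
#' which it is expected. The search is the built-in local aligner (more
#' sensitive than seeding because the target is short); hits with a bit
#' score of at most `cfg$rescue_min_bits` are discarded (strict `>`).
#' No intron-size cap applies on this path.
#'
#' @param query The [exon_query()].
#' @param targets Output of [build_intervening_targets()].
#' @param regions Target-regions tibble.
#' @param cfg A [pipeline_config()].
#' @return Seed-hit tibble with `origin = "rescue"`.
#' @export
rescue_missing <- function(query, targets, regions, cfg = pipeline_config()) {
  if (!nrow(targets)) return(empty_hits())
  peptides <- exon_peptides(query)
  aa_start <- query$exons$aa_start
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    j <- match(targets$region_id[i], regions$region_id)
    sub <- substring(regions$dna[j], targets$start[i] + 1L, targets$end[i])
    if (nchar(sub) < 3L) next
    for (e in targets$expected_exons[[i]]) {
      a <- align_peptide_dna(peptides[e], sub, cfg)
      if (is.null(a) || a$bits <= cfg$rescue_min_bits) next
      rows[[length(rows) + 1L]] <- tibble(
        exon_index = e, region_id = targets$region_id[i],
        t_start = targets$start[i] + a$nt_start,
        t_end = targets$start[i] + a$nt_end,
        q_aa_start = aa_start[e] + a$q_start,
        q_aa_end = aa_start[e] + a$q_end,
        score = a$bits, identity = a$identity, origin = "rescue"
      )
    }
  }
  hits <- if (length(rows)) bind_rows(rows) else empty_hits()
  if (nrow(hits)) {
    hits <- hits[order(-hits$score, -hits$identity, hits$t_start), ]
    hits <- hits[!duplicated(hits$exon_index), ]
    hits <- hits[order(hits$exon_index), ]
  }
  hits
}

# Combine seed and rescue hits and enforce collinearity (no intron-size
# cap after rescue): within each region the best-scoring order-consistent
# chain is kept, lowest-scoring violators dropped.
combine_hits <- function(seeded, rescued) {
  hits <- bind_rows(seeded, rescued)
  if (!nrow(hits)) return(empty_hits())
  hits <- hits |>
    group_by(.data$region_id) |>
    group_modify_chain(max_gap = Inf)
  hits[order(hits$exon_index), ]
}
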