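# Stage 3-4: merge/readthrough classification, frame-preserving
# donor-acceptor pairing, and the extension/rejection policy.

#' Classify the gap between two consecutive exon hits
#'
#' Gaps below `merge_gap_nt` (including overlaps) are single exons split by
#' alignment imprecision ("merge": both exons are still reported, only the
#' merge is annotated); gaps of at least `min_intron_nt` are introns;
#' anything in between is treated as a readthrough (coding sequence).
#' Hits on different regions are always intron-like and never
#' merge/readthrough.
#'
#' @param gap_nt Integer gap(s) in nt between consecutive hits.
#' @param cfg A [pipeline_config()].
#' @return Character vector in `{"merge", "readthrough", "intron"}`.
#' @examples
#' classify_gap(c(4, 12, 21))
#' @export
classify_gap <- function(gap_nt, cfg = pipeline_config()) {
  ifelse(gap_nt < cfg$merge_gap_nt, "merge",
         ifelse(gap_nt >= cfg$min_intron_nt, "intron", "readthrough"))
}

#' Reading-frame offsets of a candidate donor/acceptor pair
#'
#' `n` is the signed number of nucleotides between the end of the upstream
#' exon's last predicted full codon and the candidate donor boundary; `n'`
#' the signed count between the candidate acceptor boundary and the start
#' of the downstream exon's first predicted full codon. Both may be
#' negative (candidate inside the predicted exon). Their sum `s` preserves
#' the reading frame iff `s mod 3 == 0` (mathematical modulo, so negative
#' sums are handled correctly).
#'
#' @param donor_boundary,acceptor_boundary Candidate boundaries (0-based;
#'   donor = first intronic base, acceptor = first exonic base).
#' @param exon_end Predicted end (half-open) of the upstream exon's last
#'   full codon.
#' @param next_start Predicted start of the downstream exon's first full
#'   codon.
#' @return Tibble with `n`, `n_prime`, `s`, `frame_ok`.
#' @examples
#' compute_offsets(12, 110, 10, 109) # n = 2, n' = 1, s = 3: frame kept
#' @export
compute_offsets <- function(donor_boundary, acceptor_boundary,
                            exon_end, next_start) {
  n <- as.integer(donor_boundary) - as.integer(exon_end)
  np <- as.integer(next_start) - as.integer(acceptor_boundary)
  s <- n + np
  tibble(n = n, n_prime = np, s = s, frame_ok = s %% 3L == 0L)
}

#' Select the best admissible donor/acceptor pair
#'
#' Every donor candidate is paired with every acceptor candidate. A pair is
#' admissible when it preserves the reading frame (`s mod 3 == 0`), both
#' site scores exceed `cfg$min_score`, and (same-region junctions only) the
#' implied intron is at least `cfg$min_intron_nt` long. Among admissible
#' pairs the one with the highest combined score wins; ties fall to the
#' least displacement from the seed estimate (`|n| + |n'|`), then GT over
#' GC donors, then the upstream (smaller-coordinate) pair.
#'
#' @param donors,acceptors Candidate tibbles from [enumerate_candidates()]
#'   (scored).
#' @param donor_est,acceptor_est Seed estimates of the exon end / next exon
#'   start used for the offset arithmetic.
#' @param cfg A [pipeline_config()].
#' @param require_intron Enforce the minimum intron length (disabled for
#'   junctions whose exons sit on different regions).
#' @return A one-row tibble (donor/acceptor boundaries, motifs, scores,
#'   `n`, `n_prime`, `s`, `combined_score`, `frame_ok`), or `NULL` when no
#'   admissible pair exists.
#' @export
select_junction <- function(donors, acceptors, donor_est, acceptor_est,
                            cfg = pipeline_config(), require_intron = TRUE) {
  if (!nrow(donors) || !nrow(acceptors)) return(NULL)
  grid <- expand.grid(di = seq_len(nrow(donors)),
                      ai = seq_len(nrow(acceptors)))
  d <- donors[grid$di, ]
  a <- acceptors[grid$ai, ]
  off <- compute_offsets(d$boundary, a$boundary, donor_est, acceptor_est)
  intron_len <- a$boundary - d$boundary
  ok <- off$frame_ok &
    is.finite(d$score) & is.finite(a$score) &
    d$score > cfg$min_score & a$score > cfg$min_score
  if (require_intron) ok <- ok & intron_len >= cfg$min_intron_nt
  if (!any(ok)) return(NULL)
  cand <- tibble(
    donor_boundary = d$boundary[ok], donor_motif = d$motif[ok],
    donor_score = d$score[ok],
    acceptor_boundary = a$boundary[ok], acceptor_motif = a$motif[ok],
    acceptor_score = a$score[ok],
    n = off$n[ok], n_prime = off$n_prime[ok], s = off$s[ok],
    combined_score = d$score[ok] + a$score[ok],
    intron_len = intron_len[ok],
    frame_ok = TRUE
  )
  ord <- order(-cand$combined_score,
               abs(cand$n) + abs(cand$n_prime),
               cand$donor_motif != "GT",
               cand$donor_boundary,
               cand$acceptor_boundary)
  cand[ord[1], ]
}

junction_cols <- function() {
  tibble(
    upstream_exon = integer(), downstream_exon = integer(),
    type = character(), boundary = integer(),
    donor_boundary = integer(), donor_motif = character(),
    donor_score = numeric(),
    acceptor_boundary = integer(), acceptor_motif = character(),
    acceptor_score = numeric(),
    n = integer(), n_prime = integer(), s = integer(),
    combined_score = numeric(), extended = logical()
  )
}

# Attempt the junction between two placed exons; applies the one-time
# radius extension. Returns a one-row junction tibble or NULL.
attempt_junction <- function(up, down, regions, model, cfg) {
  same <- up$region_id == down$region_id
  dna_up <- regions$dna[match(up$region_id, regions$region_id)]
  dna_down <- regions$dna[match(down$region_id, regions$region_id)]
  for (radius in c(cfg$search_radius_nt,
                   cfg$search_radius_nt + cfg$radius_extension_nt)) {
    donors <- enumerate_candidates(dna_up, "donor", up$t_end, radius,
                                   model, cfg)
    acceptors <- enumerate_candidates(dna_down, "acceptor", down$t_start,
                                      radius, model, cfg)
    sel <- select_junction(donors, acceptors, up$t_end, down$t_start, cfg,
                           require_intron = same)
    if (!is.null(sel)) {
      return(tibble(
        upstream_exon = up$exon_index, downstream_exon = down$exon_index,
        type = if (same) "intron" else "inter_region",
        boundary = NA_integer_,
        donor_boundary = sel$donor_boundary, donor_motif = sel$donor_motif,
        donor_score = sel$donor_score,
        acceptor_boundary = sel$acceptor_boundary,
        acceptor_motif = sel$acceptor_motif,
        acceptor_score = sel$acceptor_score,
        n = sel$n, n_prime = sel$n_prime, s = sel$s,
        combined_score = sel$combined_score,
        extended = radius > cfg$search_radius_nt
      ))
    }
  }
  NULL
}

#' Refine all junctions of a placed exon chain
#'
#' Consecutive hit pairs are classified (merge / readthrough / intron);
#' intron-like pairs get a splice-junction search with the one-time radius
#' extension. When no admissible pair exists even after extension, the
#' flanking exon with the weaker seed score is rejected with a warning and
#' the new neighbour pair is retried.
#'
#' @param hits Combined, collinear seed/rescue hits (one row per exon).
#' @param regions Target-regions tibble (gene orientation).
#' @param query The [exon_query()].
#' @param model A [splice_score_model()].
#' @param cfg A [pipeline_config()].
#' @return List with `exons` (surviving hits + `status`), `junctions`
#'   (one row per surviving neighbour pair), `rejected` (tibble of
#'   rejected exon indices and reasons) and `warnings`.
#' @export
refine_junctions <- function(hits, regions, query,
                             model = splice_score_model(),
                             cfg = pipeline_config()) {
  current <- hits
  current$status <- ifelse(current$origin == "rescue", "rescued", "seeded")
  rejected <- tibble(exon_index = integer(), reason = character())
  warnings <- character()
  junctions <- junction_cols()
  repeat {
    if (nrow(current) == 0L) break
    junctions <- junction_cols()
    failure <- NULL
    i <- 1L
    while (i < nrow(current)) {
      up <- current[i, ]
      down <- current[i + 1L, ]
      same <- up$region_id == down$region_id
      gap <- down$t_start - up$t_end
      type <- if (same) classify_gap(gap, cfg) else "intron"
      if (same && type %in% c("merge", "readthrough")) {
        junctions <- bind_rows(junctions, tibble(
          upstream_exon = up$exon_index, downstream_exon = down$exon_index,
          type = type, boundary = as.integer(max(down$t_start, up$t_start)),
          extended = FALSE
        ))
      } else {
        j <- attempt_junction(up, down, regions, model, cfg)
        if (is.null(j)) {
          failure <- c(i, i + 1L)
          break
        }
        junctions <- bind_rows(junctions, j)
      }
      i <- i + 1L
    }
    if (is.null(failure)) break
    # reject the weaker flanking exon (tie: downstream) and retry
    pair <- current[failure, ]
    loser <- if (pair$score[1] < pair$score[2]) failure[1] else failure[2]
    rej <- current$exon_index[loser]
    rejected <- bind_rows(rejected, tibble(
      exon_index = rej,
      reason = "no admissible splice junction (even after radius extension)"
    ))
    warnings <- c(warnings, sprintf(
      "exon %d rejected: no splice site pair with score > %g found within the extended radius; may require manual curation",
      rej, cfg$min_score))
    current <- current[-loser, ]
  }
  list(exons = current, junctions = junctions, rejected = rejected,
       warnings = warnings)
}
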