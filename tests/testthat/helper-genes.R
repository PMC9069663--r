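# Hand-crafted deterministic genes for unit tests.
#
# Exon codons are drawn from a G-free alphabet (plus the initial ATG, always
# followed by an A-starting codon), so exons can never contain a GT/GC donor
# or AG acceptor motif; intron interiors are all-T. Every splice-site
# candidate in such a gene is therefore planted explicitly, which makes
# junction selection fully predictable by hand.

GFREE_CODONS <- c("ACT", "ATT", "CTT", "TTC", "AAC", "CCT", "CAT", "TAC",
                  "CAA", "ATC", "CTC", "TCT", "ACC", "AAT", "CAC", "TTA")

# n deterministic, aperiodic codons from the G-free alphabet (Lehmer-style
# index scatter, so exon peptides are never periodic and seed placement is
# unambiguous)
gfree_codons <- function(n, offset = 0L) {
  k <- offset + seq_len(n)
  GFREE_CODONS[((k * 48271L) %% 65537L) %% 16L + 1L]
}

DONOR_CTX_INTRON <- "GTAAGT"                      # consensus intronic 6-mer
ACCEPTOR_CTX_INTRON <- paste0(strrep("T", 17), "CAG") # consensus intronic 20-mer

# Build a gene by hand. exon_aa: amino acids per exon (first exon includes
# the initial Met). phases: codon phase at each internal boundary.
# intron_interior: nt of all-T interior per intron (>= 0; the full intron is
# 6 + interior + 20 nt). A negative interior plants NO intron: the two exons
# sit `gap` nt apart where gap = -interior - 1 (0 => merge, 5..20 =>
# readthrough, filler "ACT"-repeat). broken_acceptor: logical per intron;
# TRUE replaces the acceptor 20-mer by T's so no acceptor candidate exists.
hand_gene <- function(exon_aa, phases = rep(0L, length(exon_aa) - 1L),
                      intron_interior = rep(174L, length(exon_aa) - 1L),
                      broken_acceptor = rep(FALSE, length(exon_aa) - 1L),
                      flank = strrep("C", 120), query_id = "handq",
                      start_codon = "ATG") {
  n <- length(exon_aa)
  total_aa <- sum(exon_aa)
  codons <- c(start_codon, gfree_codons(total_aa - 1L))
  cds <- paste(codons, collapse = "")
  p_prev <- c(0L, phases)
  p_next <- c(phases, 0L)
  lens <- (3L - p_prev) %% 3L + 3L * (exon_aa - as.integer(p_next > 0L)) + p_next
  stopifnot(sum(lens) == 3L * total_aa)
  bnd <- c(0L, cumsum(lens))
  pieces <- substring(cds, bnd[-length(bnd)] + 1L, bnd[-1])

  genome <- flank
  starts <- integer(n)
  ends <- integer(n)
  pos <- nchar(flank)
  for (i in seq_len(n)) {
    starts[i] <- pos
    genome <- paste0(genome, pieces[i])
    pos <- pos + nchar(pieces[i])
    ends[i] <- pos
    if (i < n) {
      if (intron_interior[i] >= 0L) {
        acc <- if (broken_acceptor[i]) strrep("T", 20) else ACCEPTOR_CTX_INTRON
        intr <- paste0(DONOR_CTX_INTRON, strrep("T", intron_interior[i]), acc)
      } else {
        gap <- -intron_interior[i] - 1L
        intr <- substring(strrep("ACT", 7), 1L, gap)
      }
      genome <- paste0(genome, intr)
      pos <- pos + nchar(intr)
    }
  }
  stop_pos <- pos
  genome <- paste0(genome, "TAA", flank)

  prot <- substring(
    as.character(Biostrings::translate(Biostrings::DNAString(cds))),
    1L, total_aa)
  aa_ends <- cumsum(exon_aa)
  spans <- cbind(c(0L, head(aa_ends, -1L)), aa_ends)
  list(
    genome = genome,
    true_exons = tibble::tibble(exon_index = seq_len(n),
                                start = starts, end = ends),
    true_phases = phases,
    true_protein = prot,
    stop_pos = stop_pos,
    query = exon_query(prot, spans, phases, query_id = query_id),
    pieces = pieces
  )
}

# exact per-exon peptide truth for a hand gene (split-codon residues
# excluded), derived independently of the package's assembly code
hand_exon_peptides <- function(gene) {
  phases <- gene$true_phases
  n <- nrow(gene$true_exons)
  p_prev <- c(0L, phases)
  p_next <- c(phases, 0L)
  vapply(seq_len(n), function(i) {
    piece <- gene$pieces[i]
    lead <- (3L - p_prev[i]) %% 3L
    trail <- p_next[i]
    mid <- nchar(piece) - lead - trail
    if (mid < 3L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(
      substring(piece, lead + 1L, lead + mid))))
  }, character(1))
}
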