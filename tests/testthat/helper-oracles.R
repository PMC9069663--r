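# Independent brute-force oracle for donor/acceptor pair selection: plain
# double loop over the cross product, keeping the admissible pair with the
# maximum combined score (random real-valued scores make ties a measure-zero
# event, so the argmax is unique in the property suites that use this).
brute_force_junction <- function(donors, acceptors, donor_est, acceptor_est,
                                 cfg) {
  best <- NULL
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(acceptors))) {
      n <- donors$boundary[i] - donor_est
      np <- acceptor_est - acceptors$boundary[j]
      s <- n + np
      intron <- acceptors$boundary[j] - donors$boundary[i]
      if (s %% 3 != 0) next
      if (!(donors$score[i] > cfg$min_score)) next
      if (!(acceptors$score[j] > cfg$min_score)) next
      if (intron < cfg$min_intron_nt) next
      combined <- donors$score[i] + acceptors$score[j]
      if (is.null(best) || combined > best$combined) {
        best <- list(d = donors$boundary[i], a = acceptors$boundary[j],
                     combined = combined)
      }
    }
  }
  best
}

random_junction_instance <- function(max_each = 6L) {
  nd <- sample(0:max_each, 1)
  na <- sample(0:max_each, 1)
  list(
    donors = tibble::tibble(
      kind = "donor", boundary = as.integer(sample(80:140, nd)),
      motif = sample(c("GT", "GC"), nd, replace = TRUE),
      context = strrep("A", 9), score = runif(nd, -14, 12)),
    acceptors = tibble::tibble(
      kind = "acceptor", boundary = as.integer(sample(130:420, na)),
      motif = "AG", context = strrep("A", 23), score = runif(na, -14, 12)),
    donor_est = 110L, acceptor_est = 400L
  )
}
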