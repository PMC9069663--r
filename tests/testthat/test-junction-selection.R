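cfg <- pipeline_config()

make_cands <- function(kind, boundary, score, motif = NULL) {
  if (is.null(motif)) motif <- if (kind == "donor") "GT" else "AG"
  tibble::tibble(kind = kind, boundary = as.integer(boundary),
                 motif = rep_len(motif, length(boundary)),
                 context = strrep("A", length(boundary)),
                 score = score)
}

test_that("the frame filter precedes score maximisation", {
  # frame-violating pair scores higher but must lose
  donors <- make_cands("donor", c(100, 101), c(5.1, 9.0))
  acceptors <- make_cands("acceptor", c(400, 402), c(4.0, 9.0))
  # est: exon ends at 100, next starts at 400
  # pair (100,400): s = 0 (frame ok), combined 9.1
  # pair (101,402): s = 1 - 2 = -1 (frame broken), combined 18
  sel <- select_junction(donors, acceptors, 100, 400, cfg)
  expect_equal(sel$donor_boundary, 100L)
  expect_equal(sel$acceptor_boundary, 400L)
  expect_true(sel$frame_ok)
})

test_that("the per-site minimum score is a strict inequality", {
  donors <- make_cands("donor", 100, -10)   # exactly at the cutoff
  acceptors <- make_cands("acceptor", 400, 5)
  expect_null(select_junction(donors, acceptors, 100, 400, cfg))
  donors$score <- -9.99
  expect_false(is.null(select_junction(donors, acceptors, 100, 400, cfg)))
})

test_that("the minimum intron length constrains same-region junctions only", {
  donors <- make_cands("donor", 100, 5)
  acceptors <- make_cands("acceptor", 120, 5)  # intron 20 nt < 21
  # s = 0 - 20 + 20 ... est chosen so the pair is frame-ok
  expect_null(select_junction(donors, acceptors, 100, 120, cfg))
  acceptors21 <- make_cands("acceptor", 121, 5)
  sel <- select_junction(donors, acceptors21, 100, 121, cfg)
  expect_equal(sel$intron_len, 21L)
  # across regions the constraint is waived
  inter <- select_junction(donors, acceptors, 100, 120, cfg,
                           require_intron = FALSE)
  expect_false(is.null(inter))
})

test_that("ties fall to least displacement, then GT over GC donors", {
  # two frame-ok pairs with identical combined score
  donors <- make_cands("donor", c(100, 103), c(5, 5))
  acceptors <- make_cands("acceptor", c(400, 403), c(5, 5))
  # est 100/400: pair (100,400) disp 0; pair (103,403) disp 3+3... wait
  # (103,403): n=3, n'=-3, s=0, disp 6 -> (100,400) wins
  sel <- select_junction(donors, acceptors, 100, 400, cfg)
  expect_equal(sel$donor_boundary, 100L)

  # same boundary and score, GC vs GT donor: GT wins
  donors2 <- rbind(make_cands("donor", 100, 5, "GC"),
                   make_cands("donor", 100, 5, "GT"))
  sel2 <- select_junction(donors2, make_cands("acceptor", 400, 5),
                          100, 400, cfg)
  expect_equal(sel2$donor_motif, "GT")
})

test_that("selection equals brute force over the full cross product", {
  set.seed(77)
  for (rep in 1:60) {
    nd <- sample(0:6, 1)
    na <- sample(0:6, 1)
    donors <- make_cands("donor", sample(80:140, nd),
                         runif(nd, -14, 12),
                         sample(c("GT", "GC"), nd, replace = TRUE))
    acceptors <- make_cands("acceptor", sample(130:420, na),
                            runif(na, -14, 12))
    de <- 110
    ae <- 400
    got <- select_junction(donors, acceptors, de, ae, cfg)
    want <- brute_force_junction(donors, acceptors, de, ae, cfg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$donor_boundary, want$d)
      expect_equal(got$acceptor_boundary, want$a)
    }
  }
})

test_that("raising the minimum site score never admits a junction that was rejected", {
  set.seed(99)
  for (rep in 1:30) {
    donors <- make_cands("donor", sample(80:130, 4),
                         round(runif(4, -14, 8), 2))
    acceptors <- make_cands("acceptor", sample(200:400, 4),
                            round(runif(4, -14, 8), 2))
    strict <- pipeline_config(min_score = -5)
    loose <- pipeline_config(min_score = -10)
    got_strict <- select_junction(donors, acceptors, 100, 350, strict)
    got_loose <- select_junction(donors, acceptors, 100, 350, loose)
    if (!is.null(got_strict)) expect_false(is.null(got_loose))
  }
})
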