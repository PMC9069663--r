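# Pluggable splice-site scorer. The bundled default is a position weight
# matrix over the canonical donor (3 exonic + 6 intronic nt, 9-mer) and
# acceptor (20 intronic + 3 exonic nt, 23-mer) contexts, as log2-odds
# against a uniform background. Any scorer over the same context widths can
# be supplied as a TSV table (columns kind, position, base, log_odds).

DONOR_WIDTH <- 9L
ACCEPTOR_WIDTH <- 23L
DONOR_EXONIC <- 3L      # exonic nt preceding the donor boundary
ACCEPTOR_INTRONIC <- 20L # intronic nt preceding the acceptor boundary

#' Load a splice-site scoring model
#'
#' @param source `"builtin"` for the bundled PWM, a path to a TSV scorer
#'   table (columns `kind`, `position`, `base`, `log_odds`; positions
#'   `-3..-1, 1..6` for donors and `-20..-1, 1..3` for acceptors, negative
#'   positions upstream of the splice boundary), or a data frame in the
#'   same layout.
#' @return An object of class `splice_score_model` with 4 x 9 (donor) and
#'   4 x 23 (acceptor) log2-odds matrices.
#' @export
splice_score_model <- function(source = "builtin") {
  if (is.data.frame(source)) {
    tab <- source
    model_id <- "custom"
  } else if (identical(source, "builtin")) {
    path <- system.file("extdata", "splice_pwm_builtin.tsv",
                        package = "exonalign", mustWork = TRUE)
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    model_id <- "builtin_pwm"
  } else {
    tab <- readr::read_tsv(source, show_col_types = FALSE)
    model_id <- basename(source)
  }
  need <- c("kind", "position", "base", "log_odds")
  if (!all(need %in% names(tab))) {
    abort("splice model table must have columns kind, position, base, log_odds",
          class = "exonalign_model_error")
  }
  build <- function(kind, width) {
    t <- tab[tab$kind == kind, ]
    pos <- sort(unique(t$position))
    if (length(pos) != width) {
      abort(sprintf("%s model must cover %d positions", kind, width),
            class = "exonalign_model_error")
    }
    m <- matrix(NA_real_, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(pos)) {
      tj <- t[t$position == pos[j], ]
      m[tj$base, j] <- tj$log_odds
    }
    if (anyNA(m)) {
      abort(sprintf("%s model table is incomplete", kind),
            class = "exonalign_model_error")
    }
    m
  }
  structure(
    list(donor = build("donor", DONOR_WIDTH),
         acceptor = build("acceptor", ACCEPTOR_WIDTH),
         model_id = model_id),
    class = "splice_score_model"
  )
}

#' @export
print.splice_score_model <- function(x, ...) {
  cat(sprintf("<splice_score_model> %s (donor 9-mer, acceptor 23-mer)\n",
              x$model_id))
  invisible(x)
}

#' Score splice-site contexts
#'
#' Deterministic log-odds score of fixed-width context windows; higher is
#' more splice-like. Any context containing a base outside `A,C,G,T`
#' (notably N) scores `-Inf` and can never be selected.
#'
#' @param contexts Character vector of 9-mers (donors) or 23-mers
#'   (acceptors).
#' @param kind `"donor"` or `"acceptor"`.
#' @param model A [splice_score_model()].
#' @return Numeric scores.
#' @export
score_splice_sites <- function(contexts, kind = c("donor", "acceptor"),
                               model = splice_score_model()) {
  kind <- match.arg(kind)
  m <- model[[kind]]
  width <- ncol(m)
  vapply(contexts, function(ctx) {
    if (nchar(ctx) != width) {
      abort(sprintf("%s context must be %d nt, got %d nt",
                    kind, width, nchar(ctx)),
            class = "exonalign_model_error")
    }
    idx <- match(strsplit(ctx, "", fixed = TRUE)[[1]], rownames(m))
    if (anyNA(idx)) return(-Inf)
    sum(m[cbind(idx, seq_len(width))])
  }, numeric(1), USE.NAMES = FALSE)
}

# column-wise base probabilities implied by a log2-odds matrix (uniform
# background); used by the fixture generator to sample realistic contexts
model_probs <- function(model, kind) {
  m <- 0.25 * 2^model[[kind]]
  sweep(m, 2, colSums(m), "/")
}
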