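# broom-style accessors and a ggplot2 view of a gene model.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene model into a per-exon tibble
#'
#' @param x A `gene_model`.
#' @param regions Optional target-regions tibble; when supplied, source
#'   contig coordinates and strand are added.
#' @param ... Unused.
#' @return A tibble with one row per query exon.
#' @method tidy gene_model
#' @export
tidy.gene_model <- function(x, regions = NULL, ...) {
  out <- x$exons
  if (!is.null(regions)) {
    placed <- !is.na(out$start)
    src <- to_source_coords(regions, out$region_id[placed],
                            out$start[placed], out$end[placed])
    out$contig <- NA_character_
    out$contig_start <- NA_integer_
    out$contig_end <- NA_integer_
    out$strand <- NA_character_
    out$contig[placed] <- src$contig
    out$contig_start[placed] <- src$start
    out$contig_end[placed] <- src$end
    out$strand[placed] <- src$strand
  }
  out
}

#' One-row summary of a gene model
#'
#' @param x A `gene_model`.
#' @param ... Unused.
#' @return A one-row tibble: exon counts by fate, CDS/protein lengths,
#'   completeness flags, and whether the assembled CDS is frame-valid.
#' @method glance gene_model
#' @export
glance.gene_model <- function(x, ...) {
  st <- x$exons$status
  tibble(
    query_id = x$query_id,
    n_exons = nrow(x$exons),
    n_placed = sum(st %in% c("seeded", "rescued", "merged_with_next")),
    n_rescued = sum(st == "rescued"),
    n_rejected = sum(st == "rejected"),
    n_missing = sum(st == "missing"),
    cds_nt = nchar(x$cds),
    protein_aa = nchar(x$protein),
    has_start = x$completeness$has_start,
    has_stop = x$completeness$has_stop,
    frame_valid = nchar(x$cds) %% 3L == 0L,
    n_warnings = length(x$warnings)
  )
}

#' Plot the exon structure of a gene model
#'
#' Draws the refined exon spans per region, coloured by exon fate, with
#' the spliced connections between consecutive placed exons.
#'
#' @param object A `gene_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_model
#' @export
autoplot.gene_model <- function(object, ...) {
  ex <- object$exons[!is.na(object$exons$start), ]
  ggplot2::ggplot(ex) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$region_id, yend = .data$region_id,
                   colour = .data$status),
      linewidth = 6
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$region_id,
                   label = .data$exon_index),
      vjust = -1.2, size = 3
    ) +
    ggplot2::labs(x = "position (nt, gene orientation)", y = NULL,
                  colour = "exon fate",
                  title = sprintf("gene model: %s", object$query_id)) +
    ggplot2::theme_minimal()
}
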