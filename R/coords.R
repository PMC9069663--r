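# Coordinate conventions.
#
# All pipeline-internal intervals are 0-based half-open on the stored
# (gene-orientation) sequence of a target region. Emitted GFF3 intervals
# are 1-based closed; `gff3_interval()` / `from_gff3_interval()` are the
# only converters between the two systems.

#' Map region-internal spans to source-contig coordinates
#'
#' Each target region stores its DNA in gene orientation together with the
#' footprint it occupies on its source contig (`source_offset`, length) and
#' the strand of that footprint. For a `-` region the stored sequence is the
#' reverse complement of the contig footprint, so spans are reflected.
#'
#' @param regions A target-regions tibble (see [read_target_regions()]).
#' @param region_id Region identifier(s), recycled against `start`/`end`.
#' @param start,end 0-based half-open span(s) on the stored sequence.
#' @return A tibble with columns `region_id`, `contig`, `start`, `end`
#'   (0-based half-open on the contig) and `strand`.
#' @examples
#' r <- target_region("r1", strrep("A", 50), source_offset = 200,
#'                    orientation = "-")
#' to_source_coords(r, "r1", 0, 10) # contig [240, 250) on "-"
#' @export
to_source_coords <- function(regions, region_id, start, end) {
  idx <- match(region_id, regions$region_id)
  if (anyNA(idx)) {
    abort(paste0("unknown region_id: ",
                 paste(unique(region_id[is.na(idx)]), collapse = ", ")),
          class = "exonalign_coord_error")
  }
  len <- nchar(regions$dna)[idx]
  if (any(start < 0 | end > len | start > end)) {
    abort("span out of bounds for region", class = "exonalign_coord_error")
  }
  minus <- regions$orientation[idx] == "-"
  off <- regions$source_offset[idx]
  out_start <- ifelse(minus, off + len - end, off + start)
  out_end <- ifelse(minus, off + len - start, off + end)
  tibble(
    region_id = region_id,
    contig = regions$source_contig[idx],
    start = as.integer(out_start),
    end = as.integer(out_end),
    strand = ifelse(minus, "-", "+")
  )
}

#' Inverse of [to_source_coords()]
#'
#' @param regions A target-regions tibble.
#' @param region_id Region identifier(s).
#' @param contig_start,contig_end 0-based half-open span(s) on the source
#'   contig, inside the region footprint.
#' @return A tibble with `region_id`, `start`, `end` on the stored sequence.
#' @export
from_source_coords <- function(regions, region_id, contig_start, contig_end) {
  idx <- match(region_id, regions$region_id)
  if (anyNA(idx)) {
    abort("unknown region_id", class = "exonalign_coord_error")
  }
  len <- nchar(regions$dna)[idx]
  off <- regions$source_offset[idx]
  if (any(contig_start < off | contig_end > off + len | contig_start > contig_end)) {
    abort("span out of bounds for region footprint",
          class = "exonalign_coord_error")
  }
  minus <- regions$orientation[idx] == "-"
  out_start <- ifelse(minus, off + len - contig_end, contig_start - off)
  out_end <- ifelse(minus, off + len - contig_start, contig_end - off)
  tibble(region_id = region_id,
         start = as.integer(out_start), end = as.integer(out_end))
}

#' Convert between internal and GFF3 interval conventions
#'
#' Internal intervals are 0-based half-open; GFF3 is 1-based closed. These
#' two functions are the single audited conversion point.
#'
#' @param start,end Interval endpoints in the respective convention.
#' @return A list with `start` and `end` in the other convention.
#' @export
gff3_interval <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname gff3_interval
#' @export
from_gff3_interval <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}
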