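#' Genomic interval (0-based, half-open, plus-strand coordinates)
#'
#' All internal coordinates in this package are 0-based half-open on the
#' plus strand; conversion to 1-based inclusive happens only at I/O
#' boundaries (reports, GenBank features).
#'
#' @param contig Contig/sequence identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end (`start <= end`).
#' @param strand "+" or "-".
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start)
    stop_input("invalid interval: [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop_input("strand must be '+' or '-'")
  structure(list(contig = as.character(contig), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d, %d) %s\n", x$contig, x$start, x$end,
              x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Convert between internal 0-based half-open and 1-based inclusive
#'
#' `to_one_based()` is used when writing human-facing reports and GenBank
#' features; `from_one_based()` when reading them.
#'
#' @param start,end Coordinates in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
to_one_based <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname to_one_based
#' @export
from_one_based <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Blunt double-strand-break coordinate
#'
#' `position` is the plus-strand index of the first base 3' of the break in
#' the 0-based half-open convention: the left fragment is `[.., position)`,
#' the right fragment `[position, ..)`. Breaks are modeled as blunt.
#'
#' @param contig Contig identifier.
#' @param position Break coordinate.
#' @param source `"cas9"` or `"talen"`.
#' @return A `cut_site` object.
#' @export
cut_site <- function(contig, position, source = c("cas9", "talen")) {
  source <- match.arg(source)
  position <- as.integer(position)
  if (is.na(position) || position < 0L)
    stop_input("cut position must be a non-negative integer")
  structure(list(contig = as.character(contig), position = position,
                 source = source),
            class = "cut_site")
}

#' @export
print.cut_site <- function(x, ...) {
  cat(sprintf("<cut_site> %s:%d (%s, blunt)\n", x$contig, x$position,
              x$source))
  invisible(x)
}
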