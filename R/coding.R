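#' Coding context: ordered CDS intervals of one transcript
#'
#' Intervals must be non-overlapping and supplied (or sortable) in
#' transcription direction: ascending plus-strand coordinates for a
#' plus-strand CDS, descending for a minus-strand CDS. A total CDS length
#' that is not a multiple of 3 is allowed (partial annotation) but flagged
#' with a warning.
#'
#' @param cds_intervals List of `genomic_interval`s on one contig.
#' @param cds_strand Strand the CDS is transcribed from.
#' @return A `coding_context` object.
#' @export
coding_context <- function(cds_intervals, cds_strand = "+") {
  stopifnot(length(cds_intervals) >= 1L)
  for (iv in cds_intervals) stopifnot(inherits(iv, "genomic_interval"))
  if (!cds_strand %in% c("+", "-")) stop_input("strand must be '+' or '-'")
  starts <- vapply(cds_intervals, function(iv) iv$start, 1L)
  ord <- order(starts, decreasing = (cds_strand == "-"))
  cds_intervals <- cds_intervals[ord]
  # non-overlap check in plus coordinates
  s <- sort(starts)
  e <- sort(vapply(cds_intervals, function(iv) iv$end, 1L))
  if (length(s) > 1L && any(s[-1L] < e[-length(e)]))
    stop_input("CDS intervals overlap")
  total <- sum(vapply(cds_intervals, interval_width, 1L))
  if (total %% 3L != 0L)
    warning("total CDS length ", total, " is not a multiple of 3 ",
            "(partial annotation?)")
  structure(list(cds_intervals = cds_intervals, cds_strand = cds_strand,
                 total_length = total),
            class = "coding_context")
}

#' Reading-frame phase of a cut site within a CDS
#'
#' Counts coding bases, in transcription direction, from the CDS start to
#' the break and returns the count modulo 3. The break between plus-strand
#' positions `p - 1` and `p` is "inside" an exon `[s, e)` when
#' `s <= p < e` on the plus strand, or `s < p <= e` on the minus strand
#' (so that a cut immediately 5', in transcript direction, of the first
#' coding base has phase 0). The phase is invariant under intron length
#' changes that do not move the cut relative to coding bases.
#'
#' @param cut A `cut_site` inside one of the CDS exons.
#' @param ctx A `coding_context`.
#' @return Integer phase in `{0, 1, 2}`.
#' @export
coding_phase <- function(cut, ctx) {
  stopifnot(inherits(cut, "cut_site"), inherits(ctx, "coding_context"))
  p <- cut$position
  plus <- ctx$cds_strand == "+"
  n_before <- 0L
  for (iv in ctx$cds_intervals) {
    inside <- if (plus) (iv$start <= p && p < iv$end)
              else (iv$start < p && p <= iv$end)
    if (inside) {
      n_before <- n_before + (if (plus) p - iv$start else iv$end - p)
      return(n_before %% 3L)
    }
    n_before <- n_before + interval_width(iv)
  }
  lo <- min(vapply(ctx$cds_intervals, function(iv) iv$start, 1L))
  hi <- max(vapply(ctx$cds_intervals, function(iv) iv$end, 1L))
  if (p >= lo && p <= hi)
    stop_input("cut at ", p, " is intronic (between CDS exons)")
  stop_input("cut at ", p, " lies outside the annotated gene")
}

#' Read CDS features of one transcript from a GFF3 file
#'
#' Thin adapter over `rtracklayer::import()`: keeps `CDS` features,
#' optionally restricted to one contig, converts to the package's 0-based
#' half-open intervals and returns a [coding_context()].
#'
#' @param path GFF3 file.
#' @param contig Optional contig filter.
#' @return A `coding_context`.
#' @export
read_cds_gff3 <- function(path, contig = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_input("rtracklayer is required to read GFF3")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (!is.null(contig))
    gr <- gr[as.character(GenomeInfoDb_seqnames(gr)) == contig]
  if (length(gr) == 0L) stop_input("no CDS features found in ", path)
  strand <- unique(as.character(BiocGenerics::strand(gr)))
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop_input("CDS features must lie on a single strand")
  ivs <- lapply(seq_along(gr), function(i) {
    cc <- from_one_based(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])
    genomic_interval(as.character(GenomeInfoDb_seqnames(gr))[i],
                     cc$start, cc$end, strand)
  })
  coding_context(ivs, strand)
}

# seqnames() lives in GenomicRanges/GenomeInfoDb; resolve lazily so the
# package does not hard-depend on it when GFF3 input is unused
GenomeInfoDb_seqnames <- function(gr) {
  getExportedValue("GenomicRanges", "seqnames")(gr)
}
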