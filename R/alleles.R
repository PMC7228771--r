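# Targeting plans and predicted integrated alleles.

#' Build a targeting plan (single-site or deletion tagging)
#'
#' In single-site mode both arms flank one cut. In deletion-tagging mode
#' the 5' arm flanks the upstream cut and the 3' arm flanks the downstream
#' cut, so integration bridges the two breaks and excises the intervening
#' genomic DNA.
#'
#' @param mode `"single_site"` or `"deletion_tag"`.
#' @param genome Reference genome sequence.
#' @param cut_a Upstream (or only) `cut_site`.
#' @param arm5,arm3 `homology_arm`s.
#' @param vector A `vector_spec`.
#' @param cut_b Downstream `cut_site` (deletion mode only;
#'   `cut_b > cut_a` on the same contig).
#' @return A `targeting_plan`.
#' @export
targeting_plan <- function(mode = c("single_site", "deletion_tag"),
                           genome, cut_a, arm5, arm3, vector,
                           cut_b = NULL) {
  mode <- match.arg(mode)
  genome <- as_nuc(genome)
  stopifnot(inherits(cut_a, "cut_site"), inherits(arm5, "homology_arm"),
            inherits(arm3, "homology_arm"), inherits(vector, "vector_spec"))
  if (arm5$interval$end != cut_a$position)
    stop_input("5' arm does not end at the (upstream) cut")
  if (mode == "single_site") {
    if (!is.null(cut_b)) stop_input("cut_b given in single_site mode")
    if (arm3$interval$start != cut_a$position)
      stop_input("3' arm does not start at the cut")
  } else {
    stopifnot(inherits(cut_b, "cut_site"))
    if (cut_b$contig != cut_a$contig)
      stop_input("deletion-tag cuts must share a contig")
    if (cut_b$position <= cut_a$position)
      stop_input("deletion mode requires cut_b > cut_a (got ",
                 cut_b$position, " <= ", cut_a$position, ")")
    if (arm3$interval$start != cut_b$position)
      stop_input("3' arm does not start at the downstream cut")
  }
  structure(list(mode = mode, genome = genome, cut_a = cut_a,
                 cut_b = cut_b, arm5 = arm5, arm3 = arm3, vector = vector),
            class = "targeting_plan")
}

#' @export
print.targeting_plan <- function(x, ...) {
  cat(sprintf("<targeting_plan> %s at %s:%d%s; arms %d/%d bp; vector %s\n",
              x$mode, x$cut_a$contig, x$cut_a$position,
              if (!is.null(x$cut_b)) sprintf(" + %d", x$cut_b$position)
              else "",
              interval_width(x$arm5$interval),
              interval_width(x$arm3$interval), x$vector$name))
  invisible(x)
}

#' Predict the precisely integrated allele
#'
#' A precise HMEJ integration joins the genome to the payload through the
#' homology arms; since the arms coincide with genomic sequence, the
#' predicted allele is `genome[0, cut_a) + payload + genome[cut_a, )` in
#' single-site mode and `genome[0, cut_a) + payload + genome[cut_b, )` in
#' deletion mode (the intervening `cut_b - cut_a` bp are excised).
#'
#' @param plan A `targeting_plan`.
#' @param payload Integrated cassette between the arms (defaults to the
#'   plan's vector cargo).
#' @return An `expected_allele`: sequence, junction positions, payload
#'   interval, `deleted_span`, and the arm lengths needed to annotate
#'   junction windows.
#' @export
build_expected_allele <- function(plan, payload = NULL) {
  stopifnot(inherits(plan, "targeting_plan"))
  if (is.null(payload)) payload <- plan$vector$cargo
  payload <- as_nuc(payload, allow_n = FALSE)
  g <- plan$genome
  ca <- plan$cut_a$position
  resume <- if (plan$mode == "deletion_tag") plan$cut_b$position else ca
  seq <- paste0(subseq0(g, 0L, ca), payload,
                subseq0(g, resume, nchar(g)))
  deleted <- resume - ca
  stopifnot(nchar(seq) == nchar(g) - deleted + nchar(payload))
  structure(list(sequence = seq,
                 payload_interval = genomic_interval(
                   plan$cut_a$contig, ca, ca + nchar(payload)),
                 junction5_pos = ca,
                 junction3_pos = ca + nchar(payload),
                 deleted_span = as.integer(deleted),
                 arm5_len = interval_width(plan$arm5$interval),
                 arm3_len = interval_width(plan$arm3$interval),
                 contig = plan$cut_a$contig),
            class = "expected_allele")
}

#' @export
print.expected_allele <- function(x, ...) {
  cat(sprintf(
    "<expected_allele> %d bp; junctions at %d / %d; deleted span %d bp\n",
    nchar(x$sequence), x$junction5_pos, x$junction3_pos, x$deleted_span))
  invisible(x)
}

#' Reference window around a predicted integration junction
#'
#' Returns a window of `window` bp centered on the requested junction of
#' the expected allele, annotated with the sub-interval occupied by the
#' homology arm (the genomic side of the junction). This is the reference
#' a junction amplicon read is classified against.
#'
#' @param allele An `expected_allele`.
#' @param side `"five_prime"` or `"three_prime"`.
#' @param window Total window length in bp (centered; clipped with a
#'   warning if it exceeds the allele bounds).
#' @return A `junction_reference`: `seq`, `side`, `junction_offset`,
#'   `arm_start`, `arm_end` (0-based on the window), `clipped`.
#' @export
expected_junction <- function(allele, side = c("five_prime", "three_prime"),
                              window = 120L) {
  stopifnot(inherits(allele, "expected_allele"))
  side <- match.arg(side)
  window <- as.integer(window)
  j <- if (side == "five_prime") allele$junction5_pos
       else allele$junction3_pos
  half <- window %/% 2L
  n <- nchar(allele$sequence)
  start <- j - half
  end <- j + (window - half)
  clipped <- FALSE
  if (start < 0L || end > n) {
    clipped <- TRUE
    warning("junction window exceeds allele bounds; clipped")
    start <- max(0L, start); end <- min(n, end)
  }
  arm_len <- if (side == "five_prime") allele$arm5_len else allele$arm3_len
  arm <- if (side == "five_prime")
    c(max(j - arm_len, start), j) else c(j, min(j + arm_len, end))
  structure(list(seq = subseq0(allele$sequence, start, end),
                 side = side,
                 junction_offset = j - start,
                 arm_start = arm[1L] - start,
                 arm_end = arm[2L] - start,
                 window = end - start,
                 clipped = clipped),
            class = "junction_reference")
}

#' @export
print.junction_reference <- function(x, ...) {
  cat(sprintf(
    "<junction_reference> %s, %d bp, junction at %d, arm [%d, %d)\n",
    x$side, x$window, x$junction_offset, x$arm_start, x$arm_end))
  invisible(x)
}
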