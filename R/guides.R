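# Universal guide (UgRNA): engineered spacer with no genomic target,
# cloned into the donor so Cas9 can liberate the cargo in vivo.

#' Universal guide (UgRNA) constants
#'
#' The 20-nt universal protospacer and its CGG PAM. The full site as it
#' appears in a donor vector is `paste0(UGRNA_PROTOSPACER, UGRNA_PAM)`.
#'
#' @export
UGRNA_PROTOSPACER <- "GGGAGGCGTTCGGGCCACAG"

#' @rdname UGRNA_PROTOSPACER
#' @export
UGRNA_PAM <- "CGG"

#' Nuclease target site for a Cas9 guide
#'
#' @param protospacer 20-nt protospacer as it reads on the target strand.
#' @param pam PAM bases actually present 3' of the protospacer on the
#'   target strand.
#' @param contig Contig identifier.
#' @param start Plus-strand 0-based start of the protospacer interval.
#' @param strand Target strand ("+" or "-").
#' @return A `guide_target` object. `protospacer_interval` is always given
#'   in plus-strand coordinates.
#' @export
guide_target <- function(protospacer, pam, contig, start, strand = "+") {
  protospacer <- as_nuc(protospacer, allow_n = FALSE)
  pam <- as_nuc(pam, allow_n = FALSE)
  start <- as.integer(start)
  iv <- genomic_interval(contig, start, start + nchar(protospacer), strand)
  structure(list(protospacer = protospacer, pam = pam,
                 protospacer_interval = iv, strand = strand),
            class = "guide_target")
}

#' @export
print.guide_target <- function(x, ...) {
  cat(sprintf("<guide_target> %s %s %s:[%d, %d) %s\n", x$protospacer, x$pam,
              x$protospacer_interval$contig, x$protospacer_interval$start,
              x$protospacer_interval$end, x$strand))
  invisible(x)
}

#' Locate all exact occurrences of a protospacer + PAM on both strands
#'
#' Exact protospacer match; the PAM pattern may use IUPAC codes (default
#' NGG). Hits on the minus strand are reported with plus-strand protospacer
#' coordinates and `strand = "-"`. Mismatched search belongs to
#' [ugrna_offtarget_scan()] only.
#'
#' @param genome Genome sequence (character; unambiguous).
#' @param protospacer Protospacer (no N allowed).
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param contig Contig name used in the returned coordinates.
#' @return List of `guide_target` objects (empty if no hit).
#' @export
find_guide_sites <- function(genome, protospacer, pam_pattern = "NGG",
                             contig = "seq") {
  genome <- as_nuc(genome)
  protospacer <- as_nuc(protospacer, allow_n = FALSE)
  pam_pattern <- as_nuc(pam_pattern, ambiguous = TRUE)
  np <- nchar(protospacer); nm <- nchar(pam_pattern)
  subj <- Biostrings::DNAString(genome)
  pat <- Biostrings::DNAString(paste0(protospacer, pam_pattern))

  hits <- list()
  fwd <- Biostrings::matchPattern(pat, subj, fixed = "subject")
  for (s1 in Biostrings::start(fwd)) {       # 1-based starts
    s0 <- s1 - 1L                            # 0-based protospacer start
    hits[[length(hits) + 1L]] <- guide_target(
      protospacer, subseq0(genome, s0 + np, s0 + np + nm),
      contig, s0, "+")
  }
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                  fixed = "subject")
  for (s1 in Biostrings::start(rev)) {
    s0 <- s1 - 1L                      # 0-based start of rc(PAM) on plus
    proto_start <- s0 + nm             # plus-strand start of protospacer
    hits[[length(hits) + 1L]] <- guide_target(
      protospacer, reverse_complement(subseq0(genome, s0, s0 + nm)),
      contig, proto_start, "-")
  }
  hits[order(vapply(hits, function(h) h$protospacer_interval$start, 1L))]
}

#' Cas9 blunt cut site, 3 bp upstream (5') of the PAM
#'
#' The double-strand break is modeled as blunt, falling 3 bp 5' of the PAM
#' on the target strand (between protospacer bases 17 and 18 counted from
#' the PAM-distal end). The returned position uses the plus-strand
#' half-open convention regardless of target strand.
#'
#' @param target A `guide_target`.
#' @return A `cut_site` with `source = "cas9"`.
#' @examples
#' gt <- guide_target(strrep("A", 20), "AGG", "chr", 100, "+")
#' cas9_cut_site(gt)$position  # 117
#' @export
cas9_cut_site <- function(target) {
  stopifnot(inherits(target, "guide_target"))
  iv <- target$protospacer_interval
  pos <- if (target$strand == "+") iv$end - 3L else iv$start + 3L
  cut_site(iv$contig, pos, "cas9")
}

#' TALEN pair: left/right binding sites separated by a spacer
#'
#' @param left_site,spacer,right_site `genomic_interval`s on the same
#'   contig with `left_site$end <= spacer$start` and
#'   `spacer$end <= right_site$start`.
#' @return A `talen_pair` object.
#' @export
talen_pair <- function(left_site, spacer, right_site) {
  for (iv in list(left_site, spacer, right_site))
    stopifnot(inherits(iv, "genomic_interval"))
  if (left_site$contig != spacer$contig ||
      spacer$contig != right_site$contig)
    stop_input("TALEN binding sites and spacer must share a contig")
  if (left_site$end > spacer$start || spacer$end > right_site$start)
    stop_input("TALEN geometry violated: left <= spacer <= right required")
  structure(list(left_site = left_site, spacer = spacer,
                 right_site = right_site),
            class = "talen_pair")
}

#' TALEN blunt cut site at the spacer midpoint
#'
#' The cut position is not dictated by TALEN biochemistry the way the Cas9
#' offset is; the conventional approximation used here is the floor of the
#' spacer midpoint, with an optional signed offset.
#'
#' @param pair A `talen_pair`.
#' @param offset Signed shift in bp applied to the midpoint (default 0).
#' @return A `cut_site` with `source = "talen"`.
#' @export
talen_cut_site <- function(pair, offset = 0L) {
  stopifnot(inherits(pair, "talen_pair"))
  sp <- pair$spacer
  if (interval_width(sp) == 0L)
    stop_input("zero-length TALEN spacer")
  pos <- (sp$start + sp$end) %/% 2L + as.integer(offset)
  cut_site(sp$contig, pos, "talen")
}
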