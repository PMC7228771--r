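#' Scan a genome for (near-)matches of a guide protospacer
#'
#' Reports all protospacer occurrences within a Hamming-mismatch budget on
#' both strands, requiring an exact (IUPAC) PAM match immediately 3' of
#' the protospacer on the hit strand. Used to confirm that the universal
#' guide has no target in a genome of interest; no scoring model is
#' applied, only the mismatch count.
#'
#' @param genome Genome sequence (unambiguous).
#' @param protospacer Protospacer, default the universal guide.
#' @param pam_pattern IUPAC PAM held exact (default NGG).
#' @param max_mismatches Mismatch budget (default 3).
#' @param contig Contig name for reporting.
#' @return data.frame with columns `contig`, `start` (0-based plus-strand
#'   start of the protospacer), `strand`, `mismatches`, `site` (protospacer
#'   bases as read on the hit strand).
#' @export
ugrna_offtarget_scan <- function(genome, protospacer = UGRNA_PROTOSPACER,
                                 pam_pattern = "NGG", max_mismatches = 3L,
                                 contig = "seq") {
  genome <- as_nuc(genome)
  protospacer <- as_nuc(protospacer, allow_n = FALSE)
  pam_pattern <- as_nuc(pam_pattern, ambiguous = TRUE)
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L) stop_input("max_mismatches must be >= 0")
  np <- nchar(protospacer); nm <- nchar(pam_pattern)
  subj <- Biostrings::DNAString(genome)
  out <- list()

  scan_strand <- function(strand) {
    pat <- Biostrings::DNAString(protospacer)
    if (strand == "-") pat <- Biostrings::reverseComplement(pat)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches)
    for (s1 in Biostrings::start(m)) {
      s0 <- s1 - 1L
      if (strand == "+") {
        if (s0 + np + nm > nchar(genome)) next
        pam <- subseq0(genome, s0 + np, s0 + np + nm)
        site <- subseq0(genome, s0, s0 + np)
      } else {
        if (s0 - nm < 0L) next
        pam <- reverse_complement(subseq0(genome, s0 - nm, s0))
        site <- reverse_complement(subseq0(genome, s0, s0 + np))
      }
      if (!iupac_match(pam, pam_pattern)) next
      mm <- sum(strsplit(site, "")[[1L]] != strsplit(protospacer, "")[[1L]])
      out[[length(out) + 1L]] <<- data.frame(
        contig = contig, start = s0, strand = strand,
        mismatches = as.integer(mm), site = site, stringsAsFactors = FALSE)
    }
  }
  scan_strand("+")
  scan_strand("-")
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      site = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), ]
  rownames(res) <- NULL
  res
}
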