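#' @import methods
#' @importFrom utils write.table read.delim packageVersion
#' @importFrom stats setNames
NULL

# IUPAC alphabets. Unambiguous operations accept ACGT(N); pattern positions
# may use the full ambiguity alphabet.
.DNA_STRICT <- c("A", "C", "G", "T", "N")
.DNA_IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

# expansion of each IUPAC code into the concrete bases it stands for
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Normalize and validate a nucleotide sequence
#'
#' Uppercases, converts RNA U to T, and verifies the result contains only
#' IUPAC DNA letters. Most operations additionally require unambiguous
#' sequence (ACGT, optionally N); pass `ambiguous = TRUE` only for pattern
#' strings such as a PAM.
#'
#' @param x Character scalar.
#' @param ambiguous Allow the full IUPAC ambiguity alphabet.
#' @param allow_n Allow N when `ambiguous = FALSE`.
#' @return Normalized character scalar.
#' @export
as_nuc <- function(x, ambiguous = FALSE, allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_input("sequence must be a single character string")
  s <- chartr("u", "t", x)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  letters <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
  alphabet <- if (ambiguous) .DNA_IUPAC else
    if (allow_n) .DNA_STRICT else c("A", "C", "G", "T")
  bad <- setdiff(letters, alphabet)
  if (length(bad))
    stop_input("non-IUPAC (or disallowed) character(s) in sequence: ",
               paste(bad, collapse = ", "))
  s
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; IUPAC ambiguity codes (including N)
#' are complemented to their mirror codes. Involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq Character scalar (IUPAC DNA).
#' @return Character scalar.
#' @examples
#' reverse_complement("AAACGG")  # "CCGTTT"
#' @export
reverse_complement <- function(seq) {
  s <- as_nuc(seq, ambiguous = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# does base (A/C/G/T) satisfy IUPAC pattern letter? vectorized over both
.iupac_base_ok <- function(base, code) {
  mapply(function(b, p) b %in% .IUPAC_SETS[[p]], base, code,
         USE.NAMES = FALSE)
}

#' Test whether a concrete sequence matches an IUPAC pattern
#'
#' Position-wise comparison; `pattern` may use ambiguity codes, `seq` must
#' be concrete (ACGT). Lengths must agree.
#'
#' @param seq Concrete sequence.
#' @param pattern IUPAC pattern of equal length.
#' @return Logical scalar.
#' @export
iupac_match <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  all(.iupac_base_ok(b, p))
}

# 0-based half-open substring of a linear sequence
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# 0-based half-open substring with wrap-around on a circular sequence;
# start may exceed end modulo length
subseq0_circ <- function(seq, start, end) {
  n <- nchar(seq)
  start <- start %% n
  end <- ((end - 1L) %% n) + 1L  # position of last base, 1..n
  if (start < end) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, n), substr(seq, 1L, end))
}

# seeded random unambiguous DNA
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# condition helpers: classed errors so the CLI can map them to exit codes
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("geneweldr_input_error",
                                             "geneweldr_error")))
}
stop_ambiguous <- function(...) {
  stop(errorCondition(paste0(...), class = c("geneweldr_ambiguity_error",
                                             "geneweldr_error")))
}
stop_assembly <- function(...) {
  stop(errorCondition(paste0(...), class = c("geneweldr_assembly_error",
                                             "geneweldr_error")))
}
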