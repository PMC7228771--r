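# Homology-arm extraction, oligo rendering and validation.
#
# Arms are the only user-supplied fragments of a pGTag-style donor: the
# 3-nt buffer and the UgRNA site belong to the vector scaffold, so an
# annealing oligo is exactly (cloning overhang + arm).

#' Arm specification: side and length
#'
#' Default lengths offered by the method are 12, 24 and 48 bp; arbitrary
#' lengths (e.g. 1000) are allowed up to the contig bounds.
#'
#' @param side `"five_prime"` or `"three_prime"`.
#' @param length Arm length in bp (>= 1).
#' @return An `arm_spec` object.
#' @export
arm_spec <- function(side = c("five_prime", "three_prime"), length = 24L) {
  side <- match.arg(side)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop_input("arm length must be >= 1")
  structure(list(side = side, length = length), class = "arm_spec")
}

#' Extract the 5' and 3' homology arms flanking a cut site
#'
#' The 5' arm is the genome slice `[cut - L5, cut)`, the 3' arm
#' `[cut, cut + L3)`, both on the plus strand; their concatenation
#' reproduces `genome[cut - L5, cut + L3)`. Any N inside either slice is a
#' hard error.
#'
#' @param genome Genome sequence.
#' @param cut A `cut_site`.
#' @param spec5,spec3 `arm_spec`s (or integers, taken as lengths).
#' @return List with elements `five_prime` and `three_prime`, each a
#'   `homology_arm`.
#' @examples
#' cut <- cut_site("toy", 8)
#' extract_arms("AAAACCCCGGGGTTTT", cut, 4, 4)$five_prime$sequence  # "CCCC"
#' @export
extract_arms <- function(genome, cut, spec5 = 24L, spec3 = 24L) {
  genome <- as_nuc(genome)
  stopifnot(inherits(cut, "cut_site"))
  if (!inherits(spec5, "arm_spec")) spec5 <- arm_spec("five_prime", spec5)
  if (!inherits(spec3, "arm_spec")) spec3 <- arm_spec("three_prime", spec3)
  n <- nchar(genome); p <- cut$position
  if (p - spec5$length < 0L)
    stop_input("5' arm out of bounds: needs ", spec5$length - p,
               " more bp upstream of the cut")
  if (p + spec3$length > n)
    stop_input("3' arm out of bounds: needs ", p + spec3$length - n,
               " more bp downstream of the cut")
  arm_of <- function(spec) {
    iv <- if (spec$side == "five_prime")
      genomic_interval(cut$contig, p - spec$length, p)
    else genomic_interval(cut$contig, p, p + spec$length)
    seq <- subseq0(genome, iv$start, iv$end)
    if (grepl("N", seq, fixed = TRUE))
      stop_input("genome slice for the ", spec$side, " arm contains N")
    structure(list(side = spec$side, sequence = seq, interval = iv,
                   cut = cut),
              class = "homology_arm")
  }
  list(five_prime = arm_of(spec5), three_prime = arm_of(spec3))
}

#' @export
print.homology_arm <- function(x, ...) {
  cat(sprintf("<homology_arm> %s %d bp %s:[%d, %d)\n  %s\n", x$side,
              interval_width(x$interval), x$interval$contig,
              x$interval$start, x$interval$end, x$sequence))
  invisible(x)
}

#' Render a homology arm as an annealing-oligo pair with sticky ends
#'
#' Two complementary oligos whose annealed duplex core equals the arm, with
#' single-stranded 5' protrusions equal to the vector's cloning-junction
#' overhangs for the arm's side (BfuAI junctions for the 5' arm, BspQI for
#' the 3' arm). `top = left_overhang + arm`;
#' `bottom = right_overhang + reverse_complement(arm)` (both 5' to 3').
#'
#' @param arm A `homology_arm`.
#' @param vector A `vector_spec` declaring `cloning_junctions` for the side.
#' @param name Optional oligo-pair name; default encodes
#'   vector/side/length.
#' @return An `oligo_pair` object.
#' @export
make_arm_oligos <- function(arm, vector, name = NULL) {
  stopifnot(inherits(arm, "homology_arm"), inherits(vector, "vector_spec"))
  jn <- vector$cloning_junctions[[arm$side]]
  if (is.null(jn) || is.null(jn$left_overhang) || is.null(jn$right_overhang) ||
      !nzchar(jn$left_overhang) || !nzchar(jn$right_overhang))
    stop_input("vector '", vector$name, "' declares no cloning overhangs ",
               "for the ", arm$side, " arm")
  if (is.null(name))
    name <- sprintf("%s_%s_%dbp", vector$name, arm$side,
                    nchar(arm$sequence))
  structure(list(name = name,
                 top = paste0(jn$left_overhang, arm$sequence),
                 bottom = paste0(jn$right_overhang,
                                 reverse_complement(arm$sequence)),
                 duplex_region = arm,
                 left_overhang = jn$left_overhang,
                 right_overhang = jn$right_overhang),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair> %s\n  top:    5'-%s-3'\n  bottom: 5'-%s-3'\n",
              x$name, x$top, x$bottom))
  invisible(x)
}

#' Validate a homology arm against cloning and homology-extension pitfalls
#'
#' Report-only checks:
#' * internal BfuAI (ACCTGC) / BspQI (GCTCTTC) recognition sequences on
#'   either strand (such arms would be re-digested during one-pot
#'   assembly);
#' * occurrence of the UgRNA protospacer+PAM inside the arm (the liberation
#'   guide would then also cut the arm);
#' * `effective_homology_extension`: the number of consecutive vector bases
#'   immediately flanking the arm on its cargo-distal side in the
#'   liberated-cargo layout (buffer first, then PAM, then protospacer
#'   remnant, moving away from the arm) that happen to match the genome
#'   continuing beyond the programmed arm. A non-zero value means the real
#'   homology is longer than designed; the vector's 3-nt buffer exists to
#'   keep this at zero for the common case of a PAM match.
#'
#' @param arm A `homology_arm` derived from `genome`.
#' @param vector A `vector_spec`.
#' @param genome The genome the arm was extracted from.
#' @param cut_phase Optional cut phase in `{0,1,2}` to fill `frame_ok`.
#' @return An `arm_validation_report` object.
#' @export
validate_arm <- function(arm, vector, genome, cut_phase = NULL) {
  stopifnot(inherits(arm, "homology_arm"), inherits(vector, "vector_spec"))
  genome <- as_nuc(genome)
  seq <- arm$sequence
  hits <- do.call(rbind, lapply(list(BFUAI, BSPQI), function(enz) {
    find_motif_both_strands(seq, enz$recognition, enz$name)
  }))
  ug_site <- paste0(vector$ugRNA_protospacer, vector$ugRNA_pam)
  ug_in_arm <- grepl(ug_site, seq, fixed = TRUE) ||
    grepl(reverse_complement(ug_site), seq, fixed = TRUE)

  ext <- effective_homology_extension(arm, vector, genome)
  frame_ok <- if (is.null(cut_phase)) NA
    else frame_check(cut_phase, vector)$frame_ok

  warnings <- character()
  if (nrow(hits))
    warnings <- c(warnings, sprintf(
      "internal %s site at arm position %d (%s strand): would be cut during one-pot assembly",
      hits$enzyme, hits$position, hits$strand))
  if (ug_in_arm)
    warnings <- c(warnings,
                  "UgRNA site inside the arm: liberation would cut the arm")
  if (ext > 0L)
    warnings <- c(warnings, sprintf(
      "vector flank matches the genome for %d bp beyond the arm: effective homology is %d bp, not %d bp",
      ext, nchar(seq) + ext, nchar(seq)))
  structure(list(arm_side = arm$side,
                 internal_type_iis_hits = hits,
                 ugRNA_match_in_arm = ug_in_arm,
                 effective_homology_extension = ext,
                 frame_ok = frame_ok,
                 warnings = warnings),
            class = "arm_validation_report")
}

# fixed-string motif scan of both strands; positions 0-based on the given
# sequence's plus strand
find_motif_both_strands <- function(seq, motif, label) {
  out <- data.frame(enzyme = character(), position = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else reverse_complement(motif)
    m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (m[1L] != -1L)
      out <- rbind(out, data.frame(enzyme = label, position = as.integer(m) - 1L,
                                   strand = strand, stringsAsFactors = FALSE))
  }
  out
}

# count of consecutive matching bases walking outward (cargo-distal) from
# the arm, comparing the liberated-cargo vector flank with the genome
effective_homology_extension <- function(arm, vector, genome) {
  proto <- vector$ugRNA_protospacer
  remnant <- substr(proto, nchar(proto) - 2L, nchar(proto))  # 3 nt left by the cut
  if (arm$side == "five_prime") {
    flank <- paste0(remnant, vector$ugRNA_pam, vector$buffer$five_prime)
    vec_out <- rev(strsplit(flank, "", fixed = TRUE)[[1L]])
    n_avail <- arm$interval$start
    gen_out <- if (n_avail > 0L)
      rev(strsplit(subseq0(genome, max(0L, arm$interval$start - length(vec_out)),
                           arm$interval$start), "", fixed = TRUE)[[1L]])
    else character()
  } else {
    flank <- paste0(vector$buffer$three_prime,
                    reverse_complement(vector$ugRNA_pam),
                    reverse_complement(remnant))
    vec_out <- strsplit(flank, "", fixed = TRUE)[[1L]]
    gen_out <- strsplit(subseq0(genome, arm$interval$end,
                                min(nchar(genome),
                                    arm$interval$end + length(vec_out))),
                        "", fixed = TRUE)[[1L]]
  }
  k <- 0L
  while (k < length(gen_out) && k < length(vec_out) &&
         gen_out[k + 1L] == vec_out[k + 1L]) k <- k + 1L
  k
}

#' Check whether a cut phase matches the vector's cargo junction phase
#'
#' A coding cargo (e.g. a 2A-reporter) must be integrated in frame with the
#' targeted ORF for the reporter to be translated. The vector declares the
#' reading-frame offset of its cargo relative to the liberated 5' junction;
#' a promoter-driven cargo declares none and the check is not applicable.
#' The tool never pads arms to fix frame (padding would break homology);
#' this is report-only.
#'
#' @param cut_phase Phase of the genomic cut in `{0,1,2}`.
#' @param vector A `vector_spec`.
#' @return List with `applicable`, `frame_ok` and `required_phase`.
#' @export
frame_check <- function(cut_phase, vector) {
  stopifnot(inherits(vector, "vector_spec"))
  req <- vector$cargo_junction_phase
  if (is.null(req) || is.na(req))
    return(list(applicable = FALSE, frame_ok = NA, required_phase = NA))
  if (!cut_phase %in% 0:2) stop_input("cut_phase must be 0, 1 or 2")
  list(applicable = TRUE, frame_ok = (cut_phase == req),
       required_phase = as.integer(req))
}

#' Write an oligo order sheet
#'
#' One TSV row per oligo strand: `name`, `sequence` (5' to 3'), `length`,
#' `side`, `overhang`.
#'
#' @param pairs A list of `oligo_pair`s (or a single one).
#' @param path Output TSV path.
#' @return The sheet, invisibly, as a data.frame.
#' @export
write_oligo_sheet <- function(pairs, path) {
  if (inherits(pairs, "oligo_pair")) pairs <- list(pairs)
  rows <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      name = paste0(p$name, c("_top", "_bottom")),
      sequence = c(p$top, p$bottom),
      length = c(nchar(p$top), nchar(p$bottom)),
      side = p$duplex_region$side,
      overhang = c(p$left_overhang, p$right_overhang),
      stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
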