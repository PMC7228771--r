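# Type IIS restriction enzymes cut at a fixed distance outside their
# (asymmetric) recognition sequence, leaving user-defined overhangs --
# the basis of one-pot Golden Gate cloning. Geometry constants below are
# standard enzyme definitions shipped as editable data.

#' Define a Type IIS restriction enzyme
#'
#' `cut_offset_top`/`cut_offset_bottom` are distances in bp from the 3' end
#' of the recognition sequence (on the recognition strand) to the cut on
#' the top and bottom strand respectively; `bottom - top` is the overhang
#' length (positive for 5' overhangs).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (unambiguous, as on the
#'   recognition strand).
#' @param cut_offset_top,cut_offset_bottom Cut distances as above.
#' @return A `type_iis_enzyme` object.
#' @export
type_iis_enzyme <- function(name, recognition, cut_offset_top,
                            cut_offset_bottom) {
  recognition <- as_nuc(recognition, allow_n = FALSE)
  top <- as.integer(cut_offset_top); bottom <- as.integer(cut_offset_bottom)
  if (bottom == top)
    stop_input("blunt Type IIS definitions are not supported: ",
               "overhang length must be non-zero")
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = top, cut_offset_bottom = bottom,
                 overhang_length = bottom - top),
            class = "type_iis_enzyme")
}

#' Shipped enzyme definitions: BfuAI ACCTGC(4/8), BspQI GCTCTTC(1/4)
#'
#' BfuAI leaves 4-nt 5' overhangs, BspQI 3-nt 5' overhangs; these are the
#' two cloning enzymes of the pGTag homology-arm junctions.
#'
#' @export
BFUAI <- type_iis_enzyme("BfuAI", "ACCTGC", 4L, 8L)

#' @rdname BFUAI
#' @export
BSPQI <- type_iis_enzyme("BspQI", "GCTCTTC", 1L, 4L)

# All recognition-site occurrences of `enzyme` on both strands, as
# double-strand cut pairs (t = top-strand cut, b = bottom-strand cut,
# 0-based plus coordinates, b = t + overhang for 5' overhangs).
# For circular molecules, sites spanning the origin are found by scanning
# a doubled sequence and coordinates are reduced modulo length.
type_iis_cut_pairs <- function(seq, enzyme, circular = FALSE) {
  n <- nchar(seq)
  scan_seq <- if (circular) paste0(seq, substr(seq, 1L, min(
    n, nchar(enzyme$recognition) + max(abs(enzyme$cut_offset_bottom),
                                       abs(enzyme$cut_offset_top)))))
    else seq
  len <- nchar(enzyme$recognition)
  pairs <- list()
  add <- function(t, b) pairs[[length(pairs) + 1L]] <<- c(t = t, b = b)

  plus <- gregexpr(enzyme$recognition, scan_seq, fixed = TRUE)[[1L]]
  if (plus[1L] != -1L) for (p1 in as.integer(plus)) {
    p0 <- p1 - 1L
    if (p0 >= n) next                       # duplicate from doubling
    t <- p0 + len + enzyme$cut_offset_top
    b <- p0 + len + enzyme$cut_offset_bottom
    if (!circular && (t < 0L || b > n)) next  # cut falls off a linear end
    add(t, b)
  }
  minus <- gregexpr(reverse_complement(enzyme$recognition), scan_seq,
                    fixed = TRUE)[[1L]]
  if (minus[1L] != -1L) for (q1 in as.integer(minus)) {
    q0 <- q1 - 1L
    if (q0 >= n) next
    t <- q0 - enzyme$cut_offset_bottom
    b <- q0 - enzyme$cut_offset_top
    if (!circular && (t < 0L || b > n)) next
    add(t, b)
  }
  if (circular && length(pairs))
    pairs <- lapply(pairs, function(p) c(t = p[["t"]] %% n,
                                         b = p[["b"]] %% n))
  # b may wrap past t on a circle; keep as (t, overhang) to stay unambiguous
  unique(pairs)
}

#' Digest a DNA molecule with a Type IIS enzyme
#'
#' Finds recognition sites on both strands and splits the molecule at the
#' staggered cut positions, returning fragments with explicit 5'-overhang
#' sequences. On a circular molecule n sites yield n fragments; on a
#' linear molecule n sites yield n+1 fragments whose outer ends are blunt.
#' With zero sites the input is returned intact with a notice.
#'
#' Each fragment records its full top-strand sequence (including the bases
#' of its left 5' protrusion), `left_overhang` (single-stranded 5'
#' protrusion of the top strand, 5' to 3') and `right_overhang`
#' (single-stranded 5' protrusion of the bottom strand, 5' to 3').
#'
#' @param seq Molecule sequence (top strand).
#' @param enzyme A `type_iis_enzyme`.
#' @param circular Topology.
#' @return A `digestion` object: list with `fragments`, `n_sites`, `note`.
#' @export
digest_type_iis <- function(seq, enzyme, circular = FALSE) {
  seq <- as_nuc(seq)
  stopifnot(inherits(enzyme, "type_iis_enzyme"))
  n <- nchar(seq)
  pairs <- type_iis_cut_pairs(seq, enzyme, circular)
  if (length(pairs) == 0L) {
    return(structure(list(
      fragments = list(list(seq = seq, left_overhang = "",
                            right_overhang = "", start = 0L)),
      n_sites = 0L, circular = circular,
      note = "no recognition sites; molecule returned intact"),
      class = "digestion"))
  }
  ord <- order(vapply(pairs, function(p) p[["t"]], 1))
  pairs <- pairs[ord]
  ts <- vapply(pairs, function(p) p[["t"]], 1)
  ov <- enzyme$overhang_length

  frag_between <- function(p_from, p_to) {
    t1 <- p_from[["t"]]; b1 <- p_from[["b"]]
    t2 <- p_to[["t"]]; b2 <- p_to[["b"]]
    top <- if (circular) subseq0_circ(seq, t1, if (t2 <= t1) t2 + n else t2)
           else subseq0(seq, t1, t2)
    left <- if (b1 == t1) "" else
      if (circular) subseq0_circ(seq, t1, if (b1 <= t1) b1 + n else b1)
      else subseq0(seq, t1, b1)
    right <- if (b2 == t2) "" else
      reverse_complement(
        if (circular) subseq0_circ(seq, t2, if (b2 <= t2) b2 + n else b2)
        else subseq0(seq, t2, b2))
    list(seq = top, left_overhang = left, right_overhang = right,
         start = t1 %% n)
  }

  frags <- list()
  if (circular) {
    for (i in seq_along(pairs)) {
      nxt <- if (i == length(pairs)) 1L else i + 1L
      frags[[length(frags) + 1L]] <- frag_between(pairs[[i]], pairs[[nxt]])
    }
  } else {
    blunt0 <- c(t = 0L, b = 0L); bluntN <- c(t = n, b = n)
    bounds <- c(list(blunt0), pairs, list(bluntN))
    for (i in seq_len(length(bounds) - 1L))
      frags[[length(frags) + 1L]] <- frag_between(bounds[[i]],
                                                  bounds[[i + 1L]])
  }
  structure(list(fragments = frags, n_sites = length(pairs),
                 circular = circular, note = NULL),
            class = "digestion")
}

#' @export
print.digestion <- function(x, ...) {
  cat(sprintf("<digestion> %d site(s), %d fragment(s)%s\n", x$n_sites,
              length(x$fragments), if (x$circular) " (circular)" else ""))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}
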