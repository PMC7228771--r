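# One-pot Golden Gate assembly and in-silico UgRNA liberation.

#' Assemble homology-arm oligos into a pGTag-style donor (Golden Gate)
#'
#' Ligation is modeled as exact overhang complementarity: each oligo
#' pair's sticky ends must equal the vector's declared cloning-junction
#' overhangs for its side. The product is the circular donor with the arms
#' directly between buffer and cargo; overhang bases are scaffold/cargo
#' bases (they anneal into existing sequence) and add no extra length.
#' Arms containing an internal BfuAI/BspQI recognition site are rejected
#' (they would be re-digested in the one-pot reaction), as is any product
#' in which a ligation junction recreates an intact recognition site --
#' Golden Gate assemblies are only stable once all enzyme sites are gone.
#'
#' @param vector A `vector_spec`.
#' @param oligos5,oligos3 `oligo_pair`s for the 5' and 3' arms.
#' @param allow_internal_sites Override the internal-arm-site error
#'   (escalation flag mirrored by the CLI).
#' @return An `assembled_donor`: circular sequence, feature table, arms.
#' @export
assemble_donor <- function(vector, oligos5, oligos3,
                           allow_internal_sites = FALSE) {
  stopifnot(inherits(vector, "vector_spec"),
            inherits(oligos5, "oligo_pair"),
            inherits(oligos3, "oligo_pair"))
  for (side in c("five_prime", "three_prime")) {
    ol <- if (side == "five_prime") oligos5 else oligos3
    jn <- vector$cloning_junctions[[side]]
    if (!identical(ol$left_overhang, jn$left_overhang) ||
        !identical(ol$right_overhang, jn$right_overhang))
      stop_assembly("overhang mismatch on the ", side, " side: oligo (",
                    ol$left_overhang, ", ", ol$right_overhang,
                    ") vs vector (", jn$left_overhang, ", ",
                    jn$right_overhang, ")")
  }
  arm5 <- oligos5$duplex_region$sequence
  arm3 <- oligos3$duplex_region$sequence
  if (!allow_internal_sites) {
    for (arm in c(five_prime = arm5, three_prime = arm3)) {
      hits <- rbind(find_motif_both_strands(arm, BFUAI$recognition, "BfuAI"),
                    find_motif_both_strands(arm, BSPQI$recognition, "BspQI"))
      if (nrow(hits))
        stop_assembly("internal ", hits$enzyme[1L],
                      " site inside an arm: the insert would be ",
                      "re-digested during one-pot assembly ",
                      "(use allow_internal_sites to override)")
    }
  }

  segs <- c(backbone = vector$backbone,
            ugRNA_5prime = vector$ug5_segment,
            buffer_5prime = vector$buffer$five_prime,
            arm_5prime = arm5,
            cargo = vector$cargo,
            arm_3prime = arm3,
            buffer_3prime = vector$buffer$three_prime,
            ugRNA_3prime = vector$ug3_segment)
  seq <- paste(segs, collapse = "")
  ends <- cumsum(nchar(segs))
  starts <- ends - nchar(segs)
  features <- data.frame(
    label = names(segs), start = as.integer(starts), end = as.integer(ends),
    strand = ifelse(names(segs) == "ugRNA_3prime", "-", "+"),
    stringsAsFactors = FALSE)
  features <- features[order(features$start, features$label), ]
  rownames(features) <- NULL

  for (enz in list(BFUAI, BSPQI)) {
    if (length(type_iis_cut_pairs(seq, enz, circular = TRUE)))
      stop_assembly("assembled product still contains an intact ",
                    enz$name, " recognition site: Golden Gate assembly ",
                    "would re-digest it")
  }
  structure(list(sequence = seq, topology = "circular",
                 features = features, vector = vector,
                 arm5 = oligos5$duplex_region,
                 arm3 = oligos3$duplex_region),
            class = "assembled_donor")
}

#' @export
print.assembled_donor <- function(x, ...) {
  cat(sprintf("<assembled_donor> %s, %d bp circular, %d features\n",
              x$vector$name, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Liberate the cargo from an assembled donor at the UgRNA sites
#'
#' Applies the Cas9 cut rule at both UgRNA sites of the circular donor and
#' returns the cargo-containing fragment with the positions of both arms
#' and the non-homologous residual sequence outside each arm (under the
#' default orientation: 3-nt protospacer remnant + 3-nt PAM + buffer
#' between the cut and the arm).
#'
#' @param donor An `assembled_donor`.
#' @return A `liberated_cargo`: linear sequence, arm intervals (0-based
#'   half-open on the fragment), `residual_ends`, feature table, and the
#'   backbone fragment sequence.
#' @export
liberate_cargo <- function(donor) {
  stopifnot(inherits(donor, "assembled_donor"))
  v <- donor$vector
  hits <- find_guide_sites(donor$sequence, v$ugRNA_protospacer,
                           v$ugRNA_pam, contig = "donor")
  feat <- donor$features
  site_of <- function(label) {
    f <- feat[feat$label == label, ]
    ok <- vapply(hits, function(h) {
      iv <- h$protospacer_interval
      iv$start >= f$start - 3L && iv$end <= f$end + 3L
    }, TRUE)
    if (!any(ok))
      stop_input("UgRNA site missing or damaged on the ",
                 sub("ugRNA_", "", label), " side of the donor")
    hits[[which(ok)[1L]]]
  }
  g5 <- site_of("ugRNA_5prime")
  g3 <- site_of("ugRNA_3prime")
  c5 <- cas9_cut_site(g5)$position
  c3 <- cas9_cut_site(g3)$position
  n <- nchar(donor$sequence)

  # cargo fragment runs from the 5'-side cut to the 3'-side cut
  cargo_seq <- subseq0_circ(donor$sequence, c5, if (c3 <= c5) c3 + n else c3)
  backbone_seq <- subseq0_circ(donor$sequence, c3,
                               if (c5 <= c3) c5 + n else c5)

  to_frag <- function(pos) (pos - c5) %% n
  a5 <- feat[feat$label == "arm_5prime", ]
  a3 <- feat[feat$label == "arm_3prime", ]
  arm5_iv <- genomic_interval("cargo", to_frag(a5$start), to_frag(a5$end))
  arm3_iv <- genomic_interval("cargo", to_frag(a3$start), to_frag(a3$end))

  # translate features to fragment coordinates; the two UgRNA features are
  # truncated by the cuts, so clip each (possibly origin-wrapping) interval
  # against the fragment
  keep <- c("ugRNA_5prime", "buffer_5prime", "arm_5prime", "cargo",
            "arm_3prime", "buffer_3prime", "ugRNA_3prime")
  frag_len <- nchar(cargo_seq)
  rows <- list()
  for (i in which(feat$label %in% keep)) {
    s0 <- (feat$start[i] - c5) %% n
    e0 <- s0 + (feat$end[i] - feat$start[i])
    for (shift in c(0L, -n)) {
      s <- max(s0 + shift, 0L); e <- min(e0 + shift, frag_len)
      if (s < e)
        rows[[length(rows) + 1L]] <- data.frame(
          label = feat$label[i], start = as.integer(s), end = as.integer(e),
          strand = feat$strand[i], stringsAsFactors = FALSE)
    }
  }
  lf <- do.call(rbind, rows)
  lf <- lf[order(lf$start, lf$label), ]
  rownames(lf) <- NULL

  structure(list(sequence = cargo_seq, topology = "linear",
                 arm5_interval = arm5_iv, arm3_interval = arm3_iv,
                 residual_ends = list(
                   five_prime = subseq0(cargo_seq, 0L, arm5_iv$start),
                   three_prime = subseq0(cargo_seq, arm3_iv$end,
                                         nchar(cargo_seq))),
                 features = lf, backbone_fragment = backbone_seq,
                 vector_name = v$name),
            class = "liberated_cargo")
}

#' @export
print.liberated_cargo <- function(x, ...) {
  cat(sprintf(
    "<liberated_cargo> %d bp linear; arms [%d, %d) and [%d, %d); residuals %d/%d bp\n",
    nchar(x$sequence), x$arm5_interval$start, x$arm5_interval$end,
    x$arm3_interval$start, x$arm3_interval$end,
    nchar(x$residual_ends$five_prime), nchar(x$residual_ends$three_prime)))
  invisible(x)
}
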