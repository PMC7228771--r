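# pGTag-style donor vector model.
#
# Scaffold layout around the cloning region (plus strand, default
# orientation with each UgRNA PAM facing the cargo):
#
#   ...backbone | proto+PAM | buffer5 | ARM5 | cargo | ARM3 | buffer3 |
#      rc(PAM)+rc(proto) | backbone...
#
# Cas9 cuts 3 bp inside each protospacer, so liberation leaves a 3-nt
# protospacer remnant + 3-nt PAM + buffer as the non-homologous residual
# outside each arm. Residuals are modeled, not trimmed: end resection is
# biology, not construct sequence.

#' Specify a pGTag-style donor vector
#'
#' The buffer (default "AAA" on both sides) is the short spacer engineered
#' between the UgRNA PAM and the homology arm so that an accidental
#' PAM/genome match cannot silently lengthen the programmed homology.
#' Cloning-junction overhangs are vector data (they are defined by where
#' BfuAI/BspQI cut the stuffer out of the deposited plasmid, not by this
#' package); defaults are derived from the scaffold so that ligating
#' (overhang + arm) oligos reproduces the scaffold with no extra bases.
#'
#' @param name Vector name (e.g. "pGTag-2A-eGFP-SV40").
#' @param backbone Backbone sequence (plasmid minus the cloning region).
#' @param cargo Cargo cassette sequence between the two arms.
#' @param buffer Per-side buffers, list(five_prime=, three_prime=).
#' @param ug_orientation Per-side UgRNA orientation: `"pam_in"` (PAM faces
#'   the cargo; default) or `"pam_out"`.
#' @param cloning_junctions Optional per-side overrides:
#'   `list(five_prime = list(enzyme=, left_overhang=, right_overhang=), ...)`.
#' @param cargo_junction_phase Reading-frame offset in `{0,1,2}` of the
#'   cargo's coding sequence relative to the liberated 5' junction, or `NA`
#'   for promoter-driven (non-coding-fusion) cargos.
#' @param ugRNA_protospacer,ugRNA_pam Liberation guide; defaults to the
#'   universal guide.
#' @return A `vector_spec` object.
#' @export
vector_spec <- function(name, backbone, cargo,
                        buffer = list(five_prime = "AAA",
                                      three_prime = "AAA"),
                        ug_orientation = list(five_prime = "pam_in",
                                              three_prime = "pam_in"),
                        cloning_junctions = NULL,
                        cargo_junction_phase = NA,
                        ugRNA_protospacer = UGRNA_PROTOSPACER,
                        ugRNA_pam = UGRNA_PAM) {
  backbone <- as_nuc(backbone, allow_n = FALSE)
  cargo <- as_nuc(cargo, allow_n = FALSE)
  buffer <- lapply(buffer, as_nuc, allow_n = FALSE)
  ugRNA_protospacer <- as_nuc(ugRNA_protospacer, allow_n = FALSE)
  ugRNA_pam <- as_nuc(ugRNA_pam, allow_n = FALSE)
  stopifnot(all(c("five_prime", "three_prime") %in% names(buffer)),
            all(unlist(ug_orientation) %in% c("pam_in", "pam_out")))

  site <- paste0(ugRNA_protospacer, ugRNA_pam)
  parts <- c(backbone = backbone, cargo = cargo)
  for (pn in names(parts)) {
    if (grepl(site, parts[[pn]], fixed = TRUE) ||
        grepl(reverse_complement(site), parts[[pn]], fixed = TRUE))
      stop_input("UgRNA site occurs inside the ", pn,
                 ": the donor would carry more than two liberation sites")
  }

  ug5 <- if (ug_orientation$five_prime == "pam_in") site
         else reverse_complement(site)
  ug3 <- if (ug_orientation$three_prime == "pam_in")
           reverse_complement(site) else site

  default_jn <- list(
    five_prime = list(
      enzyme = "BfuAI",
      left_overhang = substr_tail(paste0(ug5, buffer$five_prime), 4L),
      right_overhang = reverse_complement(substr(cargo, 1L, 4L))),
    three_prime = list(
      enzyme = "BspQI",
      left_overhang = substr_tail(cargo, 3L),
      right_overhang = reverse_complement(
        substr(paste0(buffer$three_prime, ug3), 1L, 3L))))
  if (!is.null(cloning_junctions))
    default_jn[names(cloning_junctions)] <- cloning_junctions

  structure(list(name = name, backbone = backbone, cargo = cargo,
                 buffer = buffer, ug_orientation = ug_orientation,
                 ug5_segment = ug5, ug3_segment = ug3,
                 cloning_junctions = default_jn,
                 cargo_junction_phase = cargo_junction_phase,
                 ugRNA_protospacer = ugRNA_protospacer,
                 ugRNA_pam = ugRNA_pam),
            class = "vector_spec")
}

substr_tail <- function(x, n) substr(x, max(1L, nchar(x) - n + 1L), nchar(x))

#' @export
print.vector_spec <- function(x, ...) {
  cat(sprintf("<vector_spec> %s\n  backbone %d bp, cargo %d bp, buffers %s/%s\n",
              x$name, nchar(x$backbone), nchar(x$cargo),
              x$buffer$five_prime, x$buffer$three_prime))
  cat(sprintf("  junction phase: %s\n",
              if (is.na(x$cargo_junction_phase)) "not applicable (promoter-driven)"
              else x$cargo_junction_phase))
  invisible(x)
}

#' Load a vector specification from a JSON registry file
#'
#' Registry files (see `inst/extdata/vectors/`) carry name, backbone,
#' cargo, buffers, orientation and junction phase. The shipped files are
#' named after the published pGTag vectors but contain clearly marked
#' synthetic placeholder sequences to be replaced with the deposited maps.
#'
#' @param path JSON file path, or a bare vector name to resolve against the
#'   shipped registry.
#' @return A `vector_spec`.
#' @export
load_vector_spec <- function(path) {
  if (!file.exists(path)) {
    cand <- system.file("extdata", "vectors", paste0(path, ".json"),
                        package = "geneweldr")
    if (nzchar(cand)) path <- cand
  }
  if (!file.exists(path)) stop_input("vector spec not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  vector_spec(
    name = cfg$name, backbone = cfg$backbone, cargo = cfg$cargo,
    buffer = as.list(cfg$buffer),
    ug_orientation = if (!is.null(cfg$ug_orientation))
      as.list(cfg$ug_orientation)
      else list(five_prime = "pam_in", three_prime = "pam_in"),
    cargo_junction_phase = if (is.null(cfg$cargo_junction_phase)) NA
      else cfg$cargo_junction_phase)
}

#' Generate a synthetic vector spec with motif-free random parts
#'
#' Backbone and cargo are random sequences guaranteed to contain no
#' BfuAI/BspQI recognition site and no UgRNA site on either strand, so
#' assembly invariants depend only on the arms under test. Uses the
#' current RNG state; seed outside.
#'
#' @param backbone_len,cargo_len Part lengths in bp.
#' @param name Vector name.
#' @param ... Passed to [vector_spec()].
#' @return A `vector_spec`.
#' @export
synthetic_vector_spec <- function(backbone_len = 600L, cargo_len = 1500L,
                                  name = "synthetic-donor", ...) {
  forbidden <- c(BFUAI$recognition, BSPQI$recognition,
                 paste0(UGRNA_PROTOSPACER, UGRNA_PAM))
  vector_spec(name,
              backbone = random_dna_clean(backbone_len, forbidden),
              cargo = random_dna_clean(cargo_len, forbidden), ...)
}

# random DNA with none of `motifs` on either strand
random_dna_clean <- function(n, motifs) {
  pats <- c(motifs, vapply(motifs, reverse_complement, ""))
  repeat {
    s <- random_dna(n)
    if (!any(vapply(pats, function(p) grepl(p, s, fixed = TRUE), TRUE)))
      return(s)
  }
}
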