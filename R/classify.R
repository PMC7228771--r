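# Junction classification.
#
# A junction is precise when the homology arm contains no mismatch and
# there are no insertions or deletions up- or downstream of the programmed
# homology within the scored window. The published judgement was by Sanger
# inspection; the scoring scheme that operationalizes it here (global
# alignment, match +1 / mismatch -1 / gap open -2 / gap extend -1,
# leftmost tie-break as produced by the aligner) is a package default and
# is overridable.

.default_classify_params <- function() {
  list(min_overlap = 30L,      # shortest read accepted
       identity_floor = 0.6,   # below this the read is unalignable
       dup_threshold = 0.8,    # fraction of the arm required to call a
                               # tandem homology-domain duplication
       dup_adjacency = 3L,     # bp between insertion and arm boundary
       try_revcomp = TRUE,
       match = 1, mismatch = -1, gap_opening = 2, gap_extension = 1)
}

#' Classify an observed junction read as precise or imprecise
#'
#' Globally aligns the read to the expected-junction reference (after an
#' orientation step that also tries the reverse complement and keeps the
#' better alignment) and extracts events:
#' * `mismatch_in_arm` -- substitution inside the homology-arm
#'   sub-interval (breaks precision);
#' * `insertion` / `deletion` -- any indel within the scored window
#'   (breaks precision wherever it falls);
#' * `arm_duplication` -- an insertion adjacent to the arm whose content
#'   is (a rotation of) at least `dup_threshold` of the arm: a tandem
#'   duplication of the homology domain;
#' * `unalignable` -- alignment identity below `identity_floor`.
#'
#' Substitutions outside the arm but inside the window do not break
#' precision; they are reported as warnings.
#'
#' @param observed Read sequence (character).
#' @param reference A `junction_reference` from [expected_junction()].
#' @param params Optional overrides of the classification defaults.
#' @return A `junction_call`: `verdict`, `events` (data.frame type/pos/
#'   len/seq), `side`, `warnings`, `identity`, `orientation`.
#' @export
classify_junction <- function(observed, reference, params = list()) {
  stopifnot(inherits(reference, "junction_reference"))
  p <- utils::modifyList(.default_classify_params(), params)
  observed <- as_nuc(observed, allow_n = FALSE)
  if (nchar(observed) < p$min_overlap)
    stop_input("read shorter than the minimum overlap (", p$min_overlap,
               " nt)")

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = p$match, mismatch = p$mismatch, baseOnly = TRUE)
  align <- function(obs) Biostrings::pairwiseAlignment(
    pattern = obs, subject = reference$seq, type = "global",
    substitutionMatrix = submat, gapOpening = p$gap_opening,
    gapExtension = p$gap_extension)

  aln <- align(observed)
  orientation <- "forward"
  if (isTRUE(p$try_revcomp)) {
    aln_rc <- align(reverse_complement(observed))
    if (Biostrings::score(aln_rc) > Biostrings::score(aln)) {
      aln <- aln_rc
      orientation <- "reverse_complement"
    }
  }

  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ncol_aln <- length(pat)
  identity <- sum(pat == sub & pat != "-") / ncol_aln

  new_call <- function(verdict, events, warnings = character()) {
    structure(list(verdict = verdict, events = events, side = reference$side,
                   warnings = warnings, identity = identity,
                   orientation = orientation),
              class = "junction_call")
  }
  ev_row <- function(type, pos, len, seq = "") {
    data.frame(type = type, pos = as.integer(pos), len = as.integer(len),
               seq = seq, stringsAsFactors = FALSE)
  }
  no_events <- ev_row(character(0), integer(0), integer(0), character(0))

  if (identity < p$identity_floor)
    return(new_call("imprecise", ev_row("unalignable", NA, NA)))

  # walk alignment columns; ref_pos = 0-based reference coordinate of the
  # current column's subject base
  events <- no_events
  warnings <- character()
  arm_lo <- reference$arm_start; arm_hi <- reference$arm_end
  arm_seq <- substr(reference$seq, arm_lo + 1L, arm_hi)
  ref_pos <- 0L
  i <- 1L
  while (i <= ncol_aln) {
    if (sub[i] == "-") {                      # extra bases in the read
      j <- i
      while (j < ncol_aln && sub[j + 1L] == "-") j <- j + 1L
      ins_seq <- paste(pat[i:j], collapse = "")
      len <- j - i + 1L
      is_dup <- len >= ceiling(p$dup_threshold * nchar(arm_seq)) &&
        ref_pos >= arm_lo - p$dup_adjacency &&
        ref_pos <= arm_hi + p$dup_adjacency &&
        grepl(ins_seq, strrep(arm_seq, 2L), fixed = TRUE)
      events <- rbind(events, ev_row(
        if (is_dup) "arm_duplication" else "insertion", ref_pos, len,
        ins_seq))
      i <- j + 1L
    } else if (pat[i] == "-") {               # bases missing from the read
      j <- i
      while (j < ncol_aln && pat[j + 1L] == "-") j <- j + 1L
      events <- rbind(events, ev_row("deletion", ref_pos, j - i + 1L,
                                     paste(sub[i:j], collapse = "")))
      ref_pos <- ref_pos + (j - i + 1L)
      i <- j + 1L
    } else {
      if (pat[i] != sub[i]) {
        if (ref_pos >= arm_lo && ref_pos < arm_hi)
          events <- rbind(events,
                          ev_row("mismatch_in_arm", ref_pos, 1L, pat[i]))
        else
          warnings <- c(warnings, sprintf(
            "substitution outside the arm at reference position %d (%s>%s)",
            ref_pos, sub[i], pat[i]))
      }
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  verdict <- if (nrow(events) == 0L) "precise" else "imprecise"
  new_call(verdict, events, warnings)
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> %s (%s side, identity %.3f, %s)\n",
              x$verdict, x$side, x$identity, x$orientation))
  if (nrow(x$events))
    cat(paste0("  ", x$events$type, " at ", x$events$pos, " (len ",
               x$events$len, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Summarize junction calls into per-side precision counts
#'
#' @param calls List of `junction_call`s.
#' @return data.frame with one row per side: `side`, `precise`, `total`,
#'   `fraction`, and the conventional `display` form (e.g. "19/20").
#' @export
summarize_precision <- function(calls) {
  if (length(calls) == 0L) stop_input("no junction calls to summarize")
  stopifnot(all(vapply(calls, inherits, TRUE, "junction_call")))
  sides <- vapply(calls, function(x) x$side, "")
  precise <- vapply(calls, function(x) x$verdict == "precise", TRUE)
  out <- do.call(rbind, lapply(sort(unique(sides)), function(s) {
    n <- sum(sides == s); k <- sum(precise[sides == s])
    data.frame(side = s, precise = k, total = n, fraction = k / n,
               display = sprintf("%d/%d", k, n), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write junction calls as a TSV (one row per read) plus a JSON summary
#'
#' @param calls Named list of `junction_call`s (names = read ids).
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The per-read table, invisibly.
#' @export
write_junction_calls <- function(calls, tsv_path = NULL, json_path = NULL) {
  rows <- do.call(rbind, lapply(seq_along(calls), function(i) {
    x <- calls[[i]]
    data.frame(
      read = names(calls)[i] %||% as.character(i),
      side = x$side, verdict = x$verdict,
      events = if (nrow(x$events))
        paste(sprintf("%s@%s(len=%s)", x$events$type, x$events$pos,
                      x$events$len), collapse = ";") else "",
      identity = round(x$identity, 4), orientation = x$orientation,
      warnings = paste(x$warnings, collapse = ";"),
      stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv_path))
    write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- summarize_precision(calls)
    jsonlite::write_json(list(summary = summ, n_reads = length(calls)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(rows)
}
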