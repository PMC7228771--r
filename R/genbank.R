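# Minimal GenBank flat-file writer/reader.
#
# Scope: LOCUS (name, length, topology), FEATURES as misc_feature with a
# /label qualifier (1-based inclusive locations, complement() for minus
# strand), ORIGIN sequence. A fixed LOCUS date keeps output byte-stable so
# write -> read -> write is an identity on the file.

.GB_DATE <- "01-JAN-1980"

# normalize any package record to (name, sequence, topology, features)
as_gb_record <- function(x, name = NULL) {
  if (inherits(x, "assembled_donor")) {
    list(name = if (is.null(name)) gsub("[^A-Za-z0-9._-]", "_",
                                        x$vector$name) else name,
         sequence = x$sequence, topology = "circular",
         features = x$features)
  } else if (inherits(x, "liberated_cargo")) {
    list(name = if (is.null(name))
           paste0(gsub("[^A-Za-z0-9._-]", "_", x$vector_name), "_cargo")
         else name,
         sequence = x$sequence, topology = "linear", features = x$features)
  } else if (is.list(x) && !is.null(x$sequence)) {
    list(name = if (is.null(name)) (x$name %||% "record") else name,
         sequence = x$sequence, topology = x$topology %||% "linear",
         features = x$features %||% data.frame(
           label = character(), start = integer(), end = integer(),
           strand = character(), stringsAsFactors = FALSE))
  } else stop_input("cannot interpret object as a GenBank record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an annotated GenBank flat file
#'
#' Emits the record's sequence and its feature table (as `misc_feature`
#' entries with `/label` qualifiers). Features are written sorted by start
#' then label, and the LOCUS date is fixed, so identical records produce
#' byte-identical files.
#'
#' @param x An `assembled_donor`, `liberated_cargo`, or a list with
#'   `sequence`, `topology`, `features`.
#' @param path Output file path.
#' @param name Optional LOCUS name override.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path, name = NULL) {
  rec <- as_gb_record(x, name)
  seq <- as_nuc(rec$sequence)
  n <- nchar(seq)
  lines <- character()
  lines <- c(lines, sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA %s",
                            rec$name, n, rec$topology, .GB_DATE))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  f <- rec$features
  if (!is.null(f) && nrow(f)) {
    f <- f[order(f$start, f$label), ]
    for (i in seq_len(nrow(f))) {
      cc <- to_one_based(f$start[i], f$end[i])
      loc <- sprintf("%d..%d", cc$start, cc$end)
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines,
                 sprintf("     misc_feature    %s", loc),
                 sprintf("                     /label=\"%s\"", f$label[i]))
    }
  }
  lines <- c(lines, "ORIGIN")
  low <- tolower(seq)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(low, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' Parses LOCUS name/length/topology, `misc_feature` locations with
#' `/label` qualifiers (converted back to 0-based half-open intervals),
#' and the ORIGIN sequence.
#'
#' @param path GenBank file path.
#' @return List with `name`, `sequence`, `topology`, `features`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  if (is.na(locus)) stop_input("not a GenBank file (no LOCUS line): ", path)
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1L]]
  name <- toks[1L]
  topology <- if ("circular" %in% toks) "circular" else "linear"

  feat_rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^     misc_feature", ln)) {
      loc <- trimws(sub("^     misc_feature", "", ln))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      loc <- gsub("complement\\(|\\)", "", loc)
      se <- as.integer(strsplit(loc, "\\.\\.")[[1L]])
      label <- NA_character_
      if (i + 1L <= length(lines) &&
          grepl("/label=", lines[i + 1L], fixed = TRUE)) {
        label <- sub('.*?/label="(.*)".*', "\\1", lines[i + 1L])
        i <- i + 1L
      }
      cc <- from_one_based(se[1L], se[2L])
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        label = label, start = cc$start, end = cc$end, strand = strand,
        stringsAsFactors = FALSE)
    }
    i <- i + 1L
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows)
    else data.frame(label = character(), start = integer(),
                    end = integer(), strand = character(),
                    stringsAsFactors = FALSE)

  o <- grep("^ORIGIN", lines)[1L]
  stop_line <- grep("^//", lines)
  stop_line <- stop_line[stop_line > o][1L]
  seq_lines <- lines[(o + 1L):(stop_line - 1L)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(name = name, sequence = seq, topology = topology,
       features = features)
}
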