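# Independent brute-force oracles used to cross-check the package.
# Deliberately share no code with the implementation: plain character
# arithmetic, sliding windows and explicit loops.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1L]]), collapse = "")
}

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# window starts (0-based) where the IUPAC pattern matches, vectorized
# sliding window over the character vector of the genome
oracle_pattern_starts <- function(gchars, pattern) {
  p <- strsplit(pattern, "")[[1L]]
  n <- length(gchars); m <- length(p)
  if (n < m) return(integer(0))
  starts <- seq_len(n - m + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m))
    ok <- ok & gchars[starts + j - 1L] %in% .oracle_iupac[[p[j]]]
  starts[ok] - 1L
}

# exhaustive protospacer+PAM scan, both strands; returns df(start, strand)
# with start = 0-based plus-strand protospacer start
oracle_scan_guides <- function(genome, proto, pam_pattern) {
  g <- strsplit(genome, "")[[1L]]
  nm <- nchar(pam_pattern)
  plus <- oracle_pattern_starts(g, paste0(proto, pam_pattern))
  minus_pat <- oracle_revcomp(paste0(proto, pam_pattern))
  minus <- oracle_pattern_starts(g, minus_pat)
  df <- rbind(
    if (length(plus)) data.frame(start = plus, strand = "+"),
    if (length(minus)) data.frame(start = minus + nm, strand = "-"))
  if (is.null(df)) data.frame(start = integer(), strand = character())
  else df[order(df$start, df$strand), , drop = FALSE]
}

# brute-force Hamming scan with exact IUPAC PAM, both strands;
# df(start, strand, mismatches), start = 0-based plus protospacer start
oracle_hamming_scan <- function(genome, proto, pam_pattern, budget) {
  g <- strsplit(genome, "")[[1L]]
  n <- length(g)
  np <- nchar(proto); nm <- nchar(pam_pattern)
  count_mm <- function(starts, patt) {     # starts 1-based
    mm <- integer(length(starts))
    p <- strsplit(patt, "")[[1L]]
    for (j in seq_len(np))
      mm <- mm + (g[starts + j - 1L] != p[j])
    mm
  }
  pam_ok <- function(starts, patt) {       # starts 1-based
    p <- strsplit(patt, "")[[1L]]
    ok <- rep(TRUE, length(starts))
    for (j in seq_along(p))
      ok <- ok & g[starts + j - 1L] %in% .oracle_iupac[[p[j]]]
    ok
  }
  res <- list()
  # plus strand: proto at [s, s+np), PAM at [s+np, s+np+nm)
  s1 <- seq_len(n - np - nm + 1L)
  if (length(s1)) {
    mm <- count_mm(s1, proto)
    keep <- mm <= budget & pam_ok(s1 + np, pam_pattern)
    if (any(keep))
      res[[1L]] <- data.frame(start = s1[keep] - 1L, strand = "+",
                              mismatches = mm[keep])
  }
  # minus strand: proto plus-window [s, s+np) vs rc(proto); PAM plus-window
  # [s-nm, s) vs rc(IUPAC pattern)
  s1 <- seq(nm + 1L, n - np + 1L)
  if (length(s1) && s1[1L] <= s1[length(s1)]) {
    mm <- count_mm(s1, oracle_revcomp(proto))
    keep <- mm <= budget & pam_ok(s1 - nm, oracle_revcomp(pam_pattern))
    if (any(keep))
      res[[2L]] <- data.frame(start = s1[keep] - 1L, strand = "-",
                              mismatches = mm[keep])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent both-strand scan-and-split digestion oracle: returns the
# sorted multiset of fragment top-strand sequences
oracle_digest_fragments <- function(seq, recognition, cut_top, cut_bottom,
                                    circular) {
  n <- nchar(seq)
  scan <- if (circular) paste0(seq, seq) else seq
  g <- strsplit(scan, "")[[1L]]
  len <- nchar(recognition)
  tops <- integer(0)
  for (p0 in oracle_pattern_starts(g, recognition))
    if (p0 < n) tops <- c(tops, p0 + len + cut_top)
  for (q0 in oracle_pattern_starts(g, oracle_revcomp(recognition)))
    if (q0 < n) tops <- c(tops, q0 - cut_bottom)
  if (circular) tops <- unique(sort(tops %% n))
  else tops <- unique(sort(tops[tops >= 0 & tops + (cut_bottom - cut_top) <= n]))
  if (!length(tops)) return(sort(seq))
  take <- function(a, b) {             # [a, b) with wrap
    idx <- ((seq.int(a, b - 1L)) %% n) + 1L
    paste(strsplit(seq, "")[[1L]][idx], collapse = "")
  }
  frags <- character(0)
  if (circular) {
    for (i in seq_along(tops)) {
      a <- tops[i]
      b <- if (i == length(tops)) tops[1L] + n else tops[i + 1L]
      frags <- c(frags, take(a, b))
    }
  } else {
    bounds <- c(0L, tops, n)
    for (i in seq_len(length(bounds) - 1L))
      if (bounds[i] < bounds[i + 1L])
        frags <- c(frags, substr(seq, bounds[i] + 1L, bounds[i + 1L]))
      else frags <- c(frags, "")
  }
  sort(frags)
}

# annealing oracle: longest suffix of `top` complementary (antiparallel)
# to a suffix of `bottom`; returns the duplex core and both 5' protrusions
oracle_anneal <- function(top, bottom) {
  kmax <- min(nchar(top), nchar(bottom))
  best <- 0L
  for (k in seq_len(kmax)) {
    a <- substr(top, nchar(top) - k + 1L, nchar(top))
    b <- substr(bottom, nchar(bottom) - k + 1L, nchar(bottom))
    if (identical(oracle_revcomp(b), a)) best <- k
  }
  list(core = substr(top, nchar(top) - best + 1L, nchar(top)),
       left_ss = substr(top, 1L, nchar(top) - best),
       right_ss = substr(bottom, 1L, nchar(bottom) - best))
}

# random edit script on a junction-reference window with unambiguous
# truth: 1..3 edits, >= 15 bp apart, margins away from the window ends;
# substitutions always inside the arm; insertion and deletion never mixed
# in one script (a distant ins+del pair can be re-explained as a cheaper
# mismatch run by any affine-gap aligner, so truth would be ill-defined)
gen_edit_script <- function(ref_seq, arm_lo, arm_hi, n_edits = NULL) {
  n <- nchar(ref_seq)
  if (is.null(n_edits)) n_edits <- sample.int(3L, 1L)
  indel_kind <- sample(c("insertion", "deletion"), 1L)
  types <- sample(c("mismatch_in_arm", indel_kind), n_edits,
                  replace = TRUE)
  arm_interior <- seq(arm_lo + 2L, arm_hi - 3L)
  # jointly sample positions (0-based): substitutions inside the arm
  # interior (pairwise distinct, >= 2 bp apart so columns stay separate),
  # indels anywhere with margins; any pair involving an indel must be
  # >= 15 bp apart so the alignment cannot re-explain one edit by another
  repeat {
    pos <- vapply(types, function(ty)
      if (ty == "mismatch_in_arm") sample(arm_interior, 1L)
      else sample(seq(12L, n - 16L), 1L), 1L)
    if (n_edits == 1L) break
    ok <- TRUE
    for (a in seq_len(n_edits - 1L)) for (b in seq(a + 1L, n_edits)) {
      gap <- abs(pos[a] - pos[b])
      need <- if (types[a] == "mismatch_in_arm" &&
                  types[b] == "mismatch_in_arm") 2L else 15L
      if (gap < need) ok <- FALSE
    }
    if (ok) break
  }
  ord <- order(pos, decreasing = TRUE)   # apply right-to-left
  seq <- ref_seq
  truth <- list()
  for (i in ord) {
    p <- pos[i]
    if (types[i] == "mismatch_in_arm") {
      old <- substr(seq, p + 1L, p + 1L)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      seq <- paste0(substr(seq, 1L, p), new,
                    substr(seq, p + 2L, nchar(seq)))
      truth[[length(truth) + 1L]] <- list(type = "mismatch_in_arm",
                                          len = 1L)
    } else if (types[i] == "insertion") {
      len <- sample.int(3L, 1L)
      ins <- rnd_dna(len)
      seq <- paste0(substr(seq, 1L, p), ins,
                    substr(seq, p + 1L, nchar(seq)))
      truth[[length(truth) + 1L]] <- list(type = "insertion", len = len)
    } else {
      len <- sample.int(3L, 1L)
      seq <- paste0(substr(seq, 1L, p),
                    substr(seq, p + len + 1L, nchar(seq)))
      truth[[length(truth) + 1L]] <- list(type = "deletion", len = len)
    }
  }
  truth_df <- do.call(rbind, lapply(truth, function(t)
    data.frame(type = t$type, len = t$len, stringsAsFactors = FALSE)))
  list(seq = seq, truth = truth_df)
}

# canonical multiset form for event comparison
event_multiset <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(character(0))
  sort(sprintf("%s:%d", df$type, df$len))
}
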