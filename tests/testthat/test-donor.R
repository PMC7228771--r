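# Type IIS digestion, Golden Gate assembly, UgRNA liberation, off-target
# scan, GenBank round trips.

make_donor_fixture <- function(genome_len = 400, arm_len = 24,
                               backbone_len = 150, cargo_len = 120, ...) {
  vec <- synthetic_vector_spec(backbone_len, cargo_len, name = "fix", ...)
  forbidden <- c(BFUAI$recognition, BSPQI$recognition)
  repeat {
    g <- rnd_dna(genome_len)
    cutp <- genome_len %/% 2
    arms <- extract_arms(g, cut_site("c", cutp), arm_len, arm_len)
    donor <- tryCatch(
      assemble_donor(vec, make_arm_oligos(arms$five_prime, vec),
                     make_arm_oligos(arms$three_prime, vec)),
      geneweldr_error = function(e) NULL)
    if (!is.null(donor))
      return(list(genome = g, cut = cut_site("c", cutp), arms = arms,
                  vec = vec, donor = donor))
  }
}

test_that("linear digestion honors the shipped enzyme geometries", {
  # one plus-strand BfuAI site: ACCTGC(4/8) -> 4-nt 5' overhangs
  s <- paste0(strrep("A", 20), "ACCTGC", strrep("T", 34))
  d <- digest_type_iis(s, BFUAI)
  expect_identical(d$n_sites, 1L)
  expect_length(d$fragments, 2L)
  # top cut at 20+6+4 = 30, bottom at 34
  expect_identical(nchar(d$fragments[[1]]$seq), 30L)
  expect_identical(d$fragments[[2]]$left_overhang, substr(s, 31, 34))
  expect_identical(nchar(d$fragments[[2]]$left_overhang), 4L)
  expect_identical(d$fragments[[1]]$right_overhang,
                   reverse_complement(substr(s, 31, 34)))

  # one BspQI site: GCTCTTC(1/4) -> 3-nt overhang
  s2 <- paste0(strrep("G", 10), "GCTCTTC", strrep("T", 23))
  d2 <- digest_type_iis(s2, BSPQI)
  expect_identical(nchar(d2$fragments[[2]]$left_overhang), 3L)

  # zero sites: intact with a notice
  d0 <- digest_type_iis(strrep("A", 50), BSPQI)
  expect_identical(d0$n_sites, 0L)
  expect_match(d0$note, "intact")
})

test_that("circular digestion yields n fragments for n sites and matches
           the scan-and-split oracle", {
  set.seed(83)
  for (i in 1:30) {
    enz <- if (i %% 2 == 0) BFUAI else BSPQI
    n_sites <- sample(1:4, 1)
    parts <- replicate(n_sites, rnd_dna(sample(80:200, 1)))
    insert <- vapply(seq_len(n_sites), function(k)
      if (runif(1) < 0.5) enz$recognition
      else reverse_complement(enz$recognition), "")
    s <- paste0(paste0(parts, insert, collapse = ""))
    # discard accidental extra sites so the count is known
    d <- digest_type_iis(s, enz, circular = TRUE)
    frags <- sort(vapply(d$fragments, function(f) f$seq, ""))
    want <- oracle_digest_fragments(s, enz$recognition,
                                    enz$cut_offset_top,
                                    enz$cut_offset_bottom, TRUE)
    expect_identical(frags, want)
    expect_identical(length(d$fragments), d$n_sites)
    # every junction of consecutive fragments has complementary overhangs
    for (k in seq_along(d$fragments)) {
      nxt <- if (k == length(d$fragments)) 1L else k + 1L
      expect_identical(d$fragments[[nxt]]$left_overhang,
                       reverse_complement(
                         d$fragments[[k]]$right_overhang))
    }
  }
})

test_that("assembly places arms between buffer and cargo in order", {
  set.seed(89)
  fx <- make_donor_fixture()
  donor <- fx$donor
  vec <- fx$vec
  expected_core <- paste0(vec$ug5_segment, vec$buffer$five_prime,
                          fx$arms$five_prime$sequence, vec$cargo,
                          fx$arms$three_prime$sequence,
                          vec$buffer$three_prime, vec$ug3_segment)
  expect_true(grepl(expected_core, donor$sequence, fixed = TRUE))
  expect_identical(donor$topology, "circular")
  labs <- donor$features$label[order(donor$features$start)]
  expect_identical(labs, c("backbone", "ugRNA_5prime", "buffer_5prime",
                           "arm_5prime", "cargo", "arm_3prime",
                           "buffer_3prime", "ugRNA_3prime"))
})

test_that("assembly rejects mismatched overhangs naming the side", {
  set.seed(97)
  fx <- make_donor_fixture()
  bad <- make_arm_oligos(fx$arms$three_prime, fx$vec)
  # flip one overhang base
  ov <- bad$left_overhang
  substr(ov, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                              substr(ov, 1, 1))[1]
  bad$left_overhang <- ov
  bad$top <- paste0(ov, fx$arms$three_prime$sequence)
  expect_error(
    assemble_donor(fx$vec, make_arm_oligos(fx$arms$five_prime, fx$vec),
                   bad),
    regexp = "three_prime", class = "geneweldr_assembly_error")
})

test_that("arms carrying a cloning-enzyme site are rejected", {
  set.seed(101)
  vec <- synthetic_vector_spec(150, 120, name = "fix")
  g <- paste0(rnd_dna(40), "GCTCTTC", rnd_dna(13), rnd_dna(60))
  arms <- extract_arms(g, cut_site("c", 60), 24, 24)
  expect_error(
    assemble_donor(vec, make_arm_oligos(arms$five_prime, vec),
                   make_arm_oligos(arms$three_prime, vec)),
    class = "geneweldr_assembly_error")
})

test_that("assembled donors survive re-digestion with zero cuts", {
  set.seed(103)
  for (i in 1:20) {
    fx <- make_donor_fixture(genome_len = sample(200:500, 1),
                             arm_len = sample(c(12, 24, 48), 1))
    for (enz in list(BFUAI, BSPQI)) {
      d <- digest_type_iis(fx$donor$sequence, enz, circular = TRUE)
      expect_identical(d$n_sites, 0L)
    }
  }
})

test_that("liberation exposes both genomic arms with the programmed
           residual geometry", {
  set.seed(107)
  fx <- make_donor_fixture()
  lib <- liberate_cargo(fx$donor)
  expect_identical(substr(lib$sequence, lib$arm5_interval$start + 1,
                          lib$arm5_interval$end),
                   fx$arms$five_prime$sequence)
  expect_identical(substr(lib$sequence, lib$arm3_interval$start + 1,
                          lib$arm3_interval$end),
                   fx$arms$three_prime$sequence)
  # residual = 3-nt protospacer remnant + 3-nt PAM + buffer
  expect_identical(nchar(lib$residual_ends$five_prime),
                   3L + 3L + nchar(fx$vec$buffer$five_prime))
  expect_identical(nchar(lib$residual_ends$three_prime),
                   3L + 3L + nchar(fx$vec$buffer$three_prime))
  # two fragments in total; the other one carries the backbone
  expect_true(grepl(fx$vec$backbone, lib$backbone_fragment, fixed = TRUE))
  expect_identical(nchar(lib$sequence) + nchar(lib$backbone_fragment),
                   nchar(fx$donor$sequence))
})

test_that("liberation is deterministic and detects a damaged site", {
  set.seed(109)
  fx <- make_donor_fixture()
  l1 <- liberate_cargo(fx$donor)
  l2 <- liberate_cargo(fx$donor)
  expect_identical(l1, l2)

  damaged <- fx$donor
  # mutate one base inside the 5' UgRNA protospacer
  f <- damaged$features
  at <- f$start[f$label == "ugRNA_5prime"] + 5L
  s <- damaged$sequence
  substr(s, at + 1, at + 1) <- if (substr(s, at + 1, at + 1) == "A") "C"
                               else "A"
  damaged$sequence <- s
  expect_error(liberate_cargo(damaged), regexp = "5prime side",
               class = "geneweldr_input_error")
})

test_that("off-target scan obeys the mismatch budget on planted sites", {
  set.seed(113)
  g <- rnd_dna(3000)
  exact <- paste0(UGRNA_PROTOSPACER, "TGG")
  two_mm <- UGRNA_PROTOSPACER
  substr(two_mm, 3, 3) <- "T"; substr(two_mm, 12, 12) <- "A"
  g <- paste0(substr(g, 1, 500), exact, substr(g, 524, 1500),
              two_mm, "AGG", substr(g, 1524 + 477, 3000))
  hits0 <- ugrna_offtarget_scan(g, max_mismatches = 0)
  expect_true(any(hits0$mismatches == 0 & hits0$start == 500))
  hits2 <- ugrna_offtarget_scan(g, max_mismatches = 2)
  planted2 <- hits2[hits2$mismatches == 2, ]
  expect_gte(nrow(planted2), 1)
  hits1 <- ugrna_offtarget_scan(g, max_mismatches = 1)
  expect_false(any(hits1$mismatches == 2))
})

test_that("off-target scan equals the brute-force Hamming oracle", {
  set.seed(127)
  g <- rnd_dna(50000)
  # plant near-matches on both strands
  v1 <- UGRNA_PROTOSPACER; substr(v1, 5, 5) <- "A"
  v2 <- UGRNA_PROTOSPACER; substr(v2, 2, 2) <- "T"; substr(v2, 18, 18) <- "C"
  g <- paste0(substr(g, 1, 10000), v1, "CGG",
              substr(g, 10024, 30000),
              reverse_complement(paste0(v2, "GGG")),
              substr(g, 30024, 50000))
  for (budget in c(0, 2, 4)) {
    got <- ugrna_offtarget_scan(g, max_mismatches = budget)
    want <- oracle_hamming_scan(g, UGRNA_PROTOSPACER, "NGG", budget)
    expect_equal(got[, c("start", "strand", "mismatches")], want,
                 ignore_attr = TRUE)
  }
})

test_that("GenBank write/read round-trips sequence, topology, features", {
  set.seed(131)
  fx <- make_donor_fixture()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(fx$donor, path)
  rec <- read_genbank(path)
  expect_identical(rec$sequence, fx$donor$sequence)
  expect_identical(rec$topology, "circular")
  f1 <- fx$donor$features[order(fx$donor$features$start,
                                fx$donor$features$label), ]
  f2 <- rec$features[order(rec$features$start, rec$features$label), ]
  expect_equal(f1, f2, ignore_attr = TRUE)
  # byte-stability: writing the parsed record again is an identity
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(list(name = rec$name, sequence = rec$sequence,
                     topology = rec$topology, features = rec$features),
                path2)
  expect_identical(readLines(path), readLines(path2))

  # slicing at the arm feature returns the arm
  a5 <- rec$features[rec$features$label == "arm_5prime", ]
  expect_identical(substr(rec$sequence, a5$start + 1, a5$end),
                   fx$arms$five_prime$sequence)

  # a liberated cargo writes with linear topology
  lib <- liberate_cargo(fx$donor)
  path3 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(lib, path3)
  expect_match(readLines(path3)[1], "linear")
  rec3 <- read_genbank(path3)
  expect_identical(rec3$sequence, lib$sequence)
})
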