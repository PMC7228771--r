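# Targeting plans, expected alleles, junction classification, simulator.

plan_fixture <- function(genome_len = 2000, arm_len = 24,
                         mode = "single_site", cut_a = NULL,
                         cut_b = NULL) {
  g <- rnd_dna(genome_len)
  vec <- synthetic_vector_spec(120, 300, name = "pf",
                               cargo_junction_phase = 0L)
  if (is.null(cut_a)) cut_a <- genome_len %/% 3
  ca <- cut_site("c", cut_a)
  if (mode == "single_site") {
    arms <- extract_arms(g, ca, arm_len, arm_len)
    plan <- targeting_plan("single_site", g, ca, arms$five_prime,
                           arms$three_prime, vec)
  } else {
    if (is.null(cut_b)) cut_b <- cut_a + 394L
    cb <- cut_site("c", cut_b)
    a5 <- extract_arms(g, ca, arm_len, 1)$five_prime
    a3 <- extract_arms(g, cb, 1, arm_len)$three_prime
    plan <- targeting_plan("deletion_tag", g, ca, a5, a3, vec,
                           cut_b = cb)
  }
  list(genome = g, vec = vec, plan = plan)
}

test_that("expected-allele lengths follow the splice arithmetic", {
  set.seed(139)
  g <- rnd_dna(10000)
  vec <- synthetic_vector_spec(120, 200, name = "t")
  ca <- cut_site("c", 4000)
  arms <- extract_arms(g, ca, 24, 24)
  plan <- targeting_plan("single_site", g, ca, arms$five_prime,
                         arms$three_prime, vec)
  payload <- rnd_dna(1500)
  allele <- build_expected_allele(plan, payload)
  expect_identical(nchar(allele$sequence), 11500L)
  expect_identical(allele$deleted_span, 0L)

  # deletion tagging across cuts 394 bp apart excises that span
  cb <- cut_site("c", 4394)
  a3 <- extract_arms(g, cb, 1, 24)$three_prime
  dplan <- targeting_plan("deletion_tag", g, ca, arms$five_prime, a3, vec,
                          cut_b = cb)
  dallele <- build_expected_allele(dplan, payload)
  expect_identical(nchar(dallele$sequence), 10000L - 394L + 1500L)
  expect_identical(dallele$deleted_span, 394L)
  expect_error(targeting_plan("deletion_tag", g, ca, arms$five_prime, a3,
                              vec, cut_b = cut_site("c", 3000)),
               class = "geneweldr_input_error")
})

test_that("junction windows match an independent splice oracle", {
  set.seed(149)
  for (i in 1:25) {
    mode <- sample(c("single_site", "deletion_tag"), 1)
    fx <- plan_fixture(mode = mode)
    payload <- rnd_dna(sample(200:600, 1))
    allele <- build_expected_allele(fx$plan, payload)
    # splice oracle built from character vectors, not substr
    gc <- strsplit(fx$genome, "")[[1]]
    pc <- strsplit(payload, "")[[1]]
    ca <- fx$plan$cut_a$position
    resume <- if (mode == "deletion_tag") fx$plan$cut_b$position else ca
    oracle <- c(gc[seq_len(ca)], pc, gc[(resume + 1):length(gc)])
    expect_identical(allele$sequence, paste(oracle, collapse = ""))

    # 60 bases spanning junction5 equal genome-then-payload composition
    win <- expected_junction(allele, "five_prime", 60)
    j <- allele$junction5_pos
    expect_identical(win$seq, paste(oracle[(j - 30 + 1):(j + 30)],
                                    collapse = ""))
    expect_identical(win$junction_offset, 30L)
    # arm sub-interval equals the genomic arm suffix
    expect_identical(substr(win$seq, win$arm_start + 1, win$arm_end),
                     fx$plan$arm5$sequence)
    win3 <- expected_junction(allele, "three_prime", 60)
    expect_identical(substr(win3$seq, win3$arm_start + 1, win3$arm_end),
                     fx$plan$arm3$sequence)
  }
})

test_that("windows beyond the allele bounds are clipped with a warning", {
  set.seed(151)
  fx <- plan_fixture(genome_len = 300, cut_a = 100)
  allele <- build_expected_allele(fx$plan, rnd_dna(50))
  expect_warning(win <- expected_junction(allele, "five_prime", 400),
                 regexp = "clipped")
  expect_true(win$clipped)
  expect_lte(win$window, nchar(allele$sequence))
})

test_that("classification recovers the defining imprecision classes", {
  set.seed(157)
  fx <- plan_fixture()
  allele <- build_expected_allele(fx$plan, rnd_dna(400))
  ref <- expected_junction(allele, "five_prime", 128)

  expect_identical(classify_junction(ref$seq, ref)$verdict, "precise")

  # single-base insertion at the arm's cargo-distal boundary (the
  # junction between homology domain and vector-derived sequence)
  at <- ref$arm_start
  base <- substr(ref$seq, at + 1, at + 1)
  ins_read <- paste0(substr(ref$seq, 1, at),
                     setdiff(c("A", "C", "G", "T"), base)[1],
                     substr(ref$seq, at + 1, nchar(ref$seq)))
  call <- classify_junction(ins_read, ref)
  expect_identical(call$verdict, "imprecise")
  expect_true(any(call$events$type == "insertion" & call$events$len == 1))

  # tandem duplication of the homology domain
  dup <- apply_junction_event(ref, "duplication")
  call2 <- classify_junction(dup$seq, ref)
  expect_identical(call2$verdict, "imprecise")
  expect_true(any(call2$events$type == "arm_duplication"))

  # unalignable read
  call3 <- classify_junction(rnd_dna(128), ref)
  expect_identical(call3$verdict, "imprecise")
  expect_identical(call3$events$type, "unalignable")

  # substitution outside the arm does not break precision
  far <- if (ref$side == "five_prime") ref$arm_end + 20 else 5
  base <- substr(ref$seq, far + 1, far + 1)
  mm_out <- ref$seq
  substr(mm_out, far + 1, far + 1) <- setdiff(c("A", "C", "G", "T"),
                                              base)[1]
  call4 <- classify_junction(mm_out, ref)
  expect_identical(call4$verdict, "precise")
  expect_gte(length(call4$warnings), 1)

  # reverse-complement reads are oriented before scoring
  call5 <- classify_junction(reverse_complement(ref$seq), ref)
  expect_identical(call5$verdict, "precise")
  expect_identical(call5$orientation, "reverse_complement")

  expect_error(classify_junction(rnd_dna(10), ref),
               class = "geneweldr_input_error")
})

test_that("classifier agrees with edit-script truth on mutated references", {
  set.seed(163)
  fx <- plan_fixture()
  allele <- build_expected_allele(fx$plan, rnd_dna(400))
  refs <- list(expected_junction(allele, "five_prime", 128),
               expected_junction(allele, "three_prime", 128))
  for (i in 1:100) {
    ref <- refs[[(i %% 2) + 1]]
    ed <- gen_edit_script(ref$seq, ref$arm_start, ref$arm_end)
    call <- classify_junction(ed$seq, ref)
    expect_identical(call$verdict, "imprecise")
    expect_identical(event_multiset(call$events),
                     event_multiset(ed$truth))
  }
})

test_that("summarize_precision tallies per side with n/m display", {
  set.seed(167)
  fx <- plan_fixture()
  allele <- build_expected_allele(fx$plan, rnd_dna(300))
  ref5 <- expected_junction(allele, "five_prime", 100)
  ref3 <- expected_junction(allele, "three_prime", 100)
  mk <- function(ref, precise) {
    if (precise) classify_junction(ref$seq, ref)
    else classify_junction(apply_junction_event(ref, "insertion")$seq, ref)
  }
  calls <- c(lapply(1:19, function(i) mk(ref5, TRUE)), list(mk(ref5, FALSE)),
             lapply(1:5, function(i) mk(ref3, FALSE)))
  s <- summarize_precision(calls)
  r5 <- s[s$side == "five_prime", ]
  expect_identical(r5$display, "19/20")
  expect_equal(r5$fraction, 0.95)
  r3 <- s[s$side == "three_prime", ]
  expect_identical(r3$display, "0/5")
  expect_equal(r3$fraction, 0)
  expect_identical(sum(s$total), length(calls))

  # permutation invariance
  s2 <- summarize_precision(sample(calls))
  expect_equal(s, s2)
  expect_error(summarize_precision(list()),
               class = "geneweldr_input_error")
})

test_that("fixtures are byte-identical under the same seed", {
  f1 <- simulate_fixture(42, list(genome_len = 3000, cargo_len = 300,
                                  backbone_len = 200, n_reads = 10))
  f2 <- simulate_fixture(42, list(genome_len = 3000, cargo_len = 300,
                                  backbone_len = 200, n_reads = 10))
  expect_identical(f1, f2)
  f3 <- simulate_fixture(43, list(genome_len = 3000, cargo_len = 300,
                                  backbone_len = 200, n_reads = 10))
  expect_false(identical(f1$genome, f3$genome))
})

test_that("noise-free all-precise fixtures classify as 100% precise", {
  fx <- simulate_fixture(7, list(genome_len = 3000, cargo_len = 300,
                                 backbone_len = 200, n_reads = 40))
  calls <- lapply(seq_along(fx$reads), function(i)
    classify_junction(fx$reads[[i]], fx$references[[fx$truth$side[i]]]))
  s <- summarize_precision(calls)
  expect_true(all(s$fraction == 1))
})

test_that("classifier recovers planted event fractions exactly at error 0", {
  mix <- c(precise = 0.6, insertion = 0.15, deletion = 0.1,
           mismatch = 0.1, duplication = 0.05)
  fx <- simulate_fixture(11, list(genome_len = 4000, cargo_len = 400,
                                  backbone_len = 200, n_reads = 200,
                                  event_mix = mix))
  type_of <- function(call) {
    if (call$verdict == "precise") return("precise")
    t <- call$events$type
    if (any(t == "arm_duplication")) "duplication"
    else if (any(t == "insertion")) "insertion"
    else if (any(t == "deletion")) "deletion"
    else "mismatch"
  }
  got <- vapply(seq_along(fx$reads), function(i)
    type_of(classify_junction(fx$reads[[i]],
                              fx$references[[fx$truth$side[i]]])), "")
  expect_identical(got, fx$truth$event)
})

test_that("infeasible simulator parameters error out", {
  expect_error(simulate_fixture(1, list(genome_len = 200, arm_len = 100)),
               class = "geneweldr_input_error")
  expect_error(simulate_fixture(NULL), class = "geneweldr_input_error")
})
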