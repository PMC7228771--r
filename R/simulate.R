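# Seeded synthetic fixtures: random genome with a planted guide site, a
# designed single-site plan through assembly and liberation, and junction
# reads drawn from a labelled event mix.

.default_fixture_params <- function() {
  list(genome_len = 10000L, cargo_len = 1500L, arm_len = 24L,
       backbone_len = 600L, n_reads = 100L,
       event_mix = c(precise = 1),    # precise / mismatch / insertion /
                                      # deletion / duplication
       per_base_error = 0,
       window = NULL)                 # default: 2 * (arm_len + 40)
}

#' Apply a single labelled event to a junction reference window
#'
#' The event generator behind the simulator and the classifier truth
#' tests. Edits are placed with margins (>= 8 bp from the window ends,
#' >= 2 bp inside the arm for substitutions) so that the event a read
#' carries is unambiguous.
#'
#' @param reference A `junction_reference`.
#' @param type One of `"precise"`, `"mismatch"`, `"insertion"`,
#'   `"deletion"`, `"duplication"`.
#' @param max_len Maximum indel length (uniform 1..max_len).
#' @return List with `seq` (the mutated window) and `truth`
#'   (type, pos, len).
#' @export
apply_junction_event <- function(reference, type = "precise",
                                 max_len = 3L) {
  stopifnot(inherits(reference, "junction_reference"))
  ref <- reference$seq
  n <- nchar(ref)
  margin <- 8L
  out <- function(seq, pos = NA_integer_, len = 0L)
    list(seq = seq, truth = list(type = type, pos = pos, len = len))
  if (type == "precise") return(out(ref))
  if (type == "mismatch") {
    lo <- max(reference$arm_start + 2L, margin)
    hi <- min(reference$arm_end - 2L, n - margin)
    if (lo > hi) stop_input("arm too short to place an interior mismatch")
    pos <- sample(lo:hi, 1L) - 1L               # 0-based
    base <- substr(ref, pos + 1L, pos + 1L)
    repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    seq <- paste0(substr(ref, 1L, pos), repl, substr(ref, pos + 2L, n))
    return(out(seq, pos, 1L))
  }
  if (type == "insertion") {
    len <- sample.int(max_len, 1L)
    pos <- sample(margin:(n - margin), 1L)      # insert before 0-based pos
    ins <- random_dna(len)
    seq <- paste0(substr(ref, 1L, pos), ins, substr(ref, pos + 1L, n))
    return(out(seq, pos, len))
  }
  if (type == "deletion") {
    len <- sample.int(max_len, 1L)
    pos <- sample(margin:(n - margin - len), 1L)
    seq <- paste0(substr(ref, 1L, pos), substr(ref, pos + len + 1L, n))
    return(out(seq, pos, len))
  }
  if (type == "duplication") {
    # tandem duplication of the full homology domain next to its
    # programmed copy
    arm <- substr(ref, reference$arm_start + 1L, reference$arm_end)
    at <- reference$arm_end
    seq <- paste0(substr(ref, 1L, at), arm, substr(ref, at + 1L, n))
    return(out(seq, at, nchar(arm)))
  }
  stop_input("unknown event type: ", type)
}

# flip each base with probability `rate` to a different random base
add_base_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

#' Generate a reproducible synthetic targeting fixture
#'
#' Builds, under a mandatory seed: a random genome with a unique planted
#' 20-nt protospacer + AGG site, a synthetic motif-free donor vector,
#' homology arms and oligos, the assembled and liberated donor, a
#' single-site targeting plan with its expected allele and junction
#' references, and `n_reads` junction reads drawn from `event_mix` with
#' truth labels (optionally degraded by a per-base error rate). Identical
#' seeds yield byte-identical fixtures.
#'
#' @param seed Integer seed (mandatory).
#' @param params Named overrides of the defaults: `genome_len` (10000),
#'   `cargo_len` (1500), `arm_len` (24), `backbone_len` (600), `n_reads`
#'   (100), `event_mix` (all precise), `per_base_error` (0), `window`.
#' @return A `sim_fixture` list: `genome`, `guide`, `cut`, `vector`,
#'   `oligos`, `donor`, `liberated`, `plan`, `allele`, `references`,
#'   `reads` (named character vector), `truth` (data.frame), `params`.
#' @export
simulate_fixture <- function(seed, params = list()) {
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  p <- utils::modifyList(.default_fixture_params(), params)
  p$event_mix <- p$event_mix / sum(p$event_mix)
  if (is.null(p$window)) p$window <- 2L * (p$arm_len + 40L)
  cut_offset <- 17L   # cut falls after protospacer base 17
  if (p$arm_len > p$genome_len %/% 2L - cut_offset - 23L)
    stop_input("arm_len infeasible for this genome length")
  set.seed(as.integer(seed))

  forbidden <- c(BFUAI$recognition, BSPQI$recognition,
                 paste0(UGRNA_PROTOSPACER, UGRNA_PAM))
  site_pos <- p$genome_len %/% 2L
  repeat {
    genome <- random_dna(p$genome_len)
    proto <- random_dna(20L)
    genome <- paste0(subseq0(genome, 0L, site_pos), proto, "AGG",
                     subseq0(genome, site_pos + 23L, p$genome_len))
    hits <- find_guide_sites(genome, proto, "NGG", contig = "simchr")
    if (length(hits) != 1L) next
    cut <- cas9_cut_site(hits[[1L]])
    ok <- tryCatch({
      vec <- synthetic_vector_spec(p$backbone_len, p$cargo_len,
                                   name = "synthetic-donor",
                                   cargo_junction_phase = 0L)
      arms <- extract_arms(genome, cut, p$arm_len, p$arm_len)
      ol5 <- make_arm_oligos(arms$five_prime, vec)
      ol3 <- make_arm_oligos(arms$three_prime, vec)
      donor <- assemble_donor(vec, ol5, ol3)
      TRUE
    }, geneweldr_error = function(e) FALSE)
    if (ok) break
    # a ligation junction recreated an enzyme site, or the arm drew a
    # forbidden motif from the random genome: redraw
  }
  liberated <- liberate_cargo(donor)
  plan <- targeting_plan("single_site", genome, cut,
                         arms$five_prime, arms$three_prime, vec)
  allele <- build_expected_allele(plan, vec$cargo)
  refs <- list(five_prime = expected_junction(allele, "five_prime",
                                              p$window),
               three_prime = expected_junction(allele, "three_prime",
                                               p$window))

  types <- names(p$event_mix)
  reads <- character(p$n_reads)
  truth <- vector("list", p$n_reads)
  for (i in seq_len(p$n_reads)) {
    side <- if (i %% 2L == 1L) "five_prime" else "three_prime"
    type <- sample(types, 1L, prob = p$event_mix)
    ev <- apply_junction_event(refs[[side]], type)
    reads[i] <- add_base_errors(ev$seq, p$per_base_error)
    truth[[i]] <- data.frame(
      read = sprintf("read_%04d", i), side = side, event = type,
      pos = ev$truth$pos, len = ev$truth$len,
      label = if (type == "precise") "precise" else "imprecise",
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  names(reads) <- truth$read

  structure(list(genome = genome, guide = hits[[1L]], cut = cut,
                 vector = vec, oligos = list(five_prime = ol5,
                                             three_prime = ol3),
                 donor = donor, liberated = liberated, plan = plan,
                 allele = allele, references = refs, reads = reads,
                 truth = truth, params = p, seed = as.integer(seed)),
            class = "sim_fixture")
}

#' @export
print.sim_fixture <- function(x, ...) {
  cat(sprintf(
    "<sim_fixture> seed %d: genome %d bp, arms %d bp, %d reads (%s)\n",
    x$seed, nchar(x$genome), x$params$arm_len, length(x$reads),
    paste(sprintf("%s=%.2f", names(x$params$event_mix),
                  x$params$event_mix), collapse = ", ")))
  invisible(x)
}
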