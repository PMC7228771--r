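---
title: "Designing short-homology knock-ins: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing short-homology knock-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneweldr)
```

## The procedure being modeled

Homology-mediated end joining (HMEJ) knock-in uses remarkably short
homology — typically 24 or 48 bp, down to 12 bp — to direct a donor
cassette into a nuclease-induced double-strand break. Two design elements
make this work in vivo and both are modeled explicitly here:

1. **In-vivo liberation.** The donor carries a *universal* sgRNA site
   (UgRNA; spacer `GGGAGGCGTTCGGGCCACAG`, PAM `CGG`) on each side of the
   cargo. The UgRNA spacer was engineered to have no target in common
   model genomes, so co-delivering it with Cas9 cuts only the donor,
   exposing both homology arms at the moment and place they are needed.
   `ugrna_offtarget_scan()` lets a user re-verify the "no genomic target"
   premise for any genome, as a plain Hamming scan with an exact NGG PAM
   (default budget 3 mismatches; no scoring model is implied).
2. **Golden Gate arm cloning.** Arms are annealed oligo duplexes with
   sticky ends, ligated in one pot through BfuAI (ACCTGC(4/8), 4-nt 5'
   overhangs) on the 5' side and BspQI (GCTCTTC(1/4), 3-nt overhangs) on
   the 3' side. A correct assembly loses every recognition site, which is
   also the package's invariant: `assemble_donor()` refuses any product
   that an enzyme could still cut, including sites recreated by chance
   across a ligation junction.

Cut-site arithmetic is the Cas9 rule — a blunt break 3 bp 5' of the PAM,
between protospacer bases 17|18 — applied in plus-strand, 0-based,
half-open coordinates regardless of target strand. TALEN breaks have no
comparably crisp published rule; the package uses the conventional
approximation, the floor of the spacer midpoint, with a signed
`offset` argument for users who prefer a different convention.

## Vector model and the buffer

The donor is modeled by `vector_spec()` as parts (backbone, cargo,
per-side buffers, per-side UgRNA orientation, cloning-junction overhangs)
rather than as a monolithic sequence, because the arms are the only
user-supplied fragments: an oligo is exactly *overhang + arm*, and the
3-nt buffer belongs to the scaffold. The buffer exists because the UgRNA
PAM (or its remnant) can, by chance, match the genomic bases just beyond
the programmed arm, which would silently lengthen the effective homology;
`validate_arm()` quantifies exactly this as `effective_homology_extension`
by walking outward from the arm and comparing the liberated-cargo layout
(buffer, then PAM, then protospacer remnant) with the genome.

Two points were genuinely open and are settled here as package defaults,
both per-side configurable:

* **UgRNA orientation**: PAM facing the cargo on both sides, so each
  liberated end carries a 9-nt non-homologous residual (3-nt protospacer
  remnant + 3-nt PAM + 3-nt buffer). Residuals are modeled, not trimmed:
  their removal is end resection, i.e. biology, not construct sequence.
* **A 3' buffer symmetric to the 5' one**: the published description of
  the buffer speaks of "the 5' end of the homology arms" and does not pin
  the 3'-side layout; the default places `AAA` on both sides until a
  deposited map says otherwise.

Cloning-junction overhang sequences are vector *data*, not constants of
the method (they are defined by where the enzymes cut the stuffer out of
a particular plasmid). Defaults are derived from the scaffold so that
ligation adds no extra bases; the shipped registry files
(`inst/extdata/vectors/`) are named after the published pGTag vectors but
carry clearly marked synthetic placeholder payloads — replace them with
the deposited maps for real designs. No test depends on the placeholders.

## Expected alleles and junction classification

A precise integration joins genome to payload through the arms, so the
predicted allele is pure splice arithmetic:
`genome[0, cut) + payload + genome[cut, )` for a single site, and
`genome[0, cut_a) + payload + genome[cut_b, )` for deletion tagging
(excising `cut_b − cut_a` bp).

The published precision rule — no mismatch in the homology arm, no
insertion or deletion up- or downstream of the programmed homology — was
applied by eye to Sanger traces. Operationalizing it requires three
choices, which are defaults here, not claims about the original analysis:

* **Scoring scheme.** Global pairwise alignment with match +1,
  mismatch −1, gap open −2, gap extend −1 (Biostrings'
  `pairwiseAlignment`), after an orientation step that also tries the
  reverse complement and keeps the better score. Ties resolve to the
  aligner's leftmost placement.
* **Scored window.** The "up- or downstream" clause is unbounded in
  prose; the package scores the full supplied reference window, default
  40 bp beyond the arm on each side (`expected_junction()` default 120,
  simulator default `2*(arm_len+40)`). The choice is surfaced in the
  call metadata.
* **Duplication calls.** A tandem duplication of the homology domain
  appears in an alignment as a long insertion adjacent to the arm. An
  insertion is relabeled `arm_duplication` when it is at least 80% of the
  arm long, lies within 3 bp of the arm boundary, and its content is a
  substring of the doubled arm (which covers rotations of the tandem
  copy). The 80% threshold is a heuristic to avoid false calls on
  SNP-adjacent repeats and is configurable.

Substitutions outside the arm do not break precision (the rule names
mismatches only inside the arm); they are reported as warnings. Reads
below 60% alignment identity are called `unalignable` rather than
accumulating meaningless events. Reads shorter than 30 nt are rejected.

## What the simulator emulates — and what it does not

`simulate_fixture()` builds, under a mandatory seed: a uniform-random
genome with a single planted protospacer+AGG site, a motif-free synthetic
vector, the full design-assemble-liberate chain, and junction reads drawn
from a labelled event mix (precise / arm mismatch / 1–3 bp insertion /
1–3 bp deletion / tandem arm duplication), optionally degraded by a
per-base substitution error. Defaults — 10-kb genome, 1.5-kb cargo,
24-bp arms, 100 reads, error 0 — mirror the scale of the modeled
experiments (24/48-bp arms, ~2-kb cassettes, Sanger-read-sized junction
amplicons). Tests scale the genome down to 2–4 kb and use 100–1000 reads;
those are the problem sizes the reported checks were run at.

Real amplicon data differ in ways the generator deliberately does not
model: base composition and repeats (uniform random sequence has neither,
so alignment ambiguity is rarer than at repetitive loci), indel spectra
of real repair (events are drawn independently and placed with margins),
chimeric or mixed-template reads, and quality-correlated errors. Passing
the recovery tests therefore demonstrates correctness of the arithmetic
and the classifier on well-posed inputs, not classifier performance on
difficult loci.

One generator constraint deserves its own note: the classifier-vs-truth
suites never place an insertion *and* a deletion in the same read, and
keep any indel at least 15 bp from other edits. A distant
insertion/deletion pair shifts the intervening segment by one, and under
any affine gap scheme a short shifted segment can be re-explained as a
cheaper run of mismatches — at which point "the truth" is genuinely
ill-defined at the alignment level, for this package and for any aligner.
Within these constraints, classifier output and edit-script truth agree
exactly, and that exact agreement is what the test suite asserts.

## Numerical and interface choices

* 0-based half-open plus-strand coordinates everywhere internally;
  1-based inclusive only in reports, GenBank features and error
  messages. Both conversions are exercised by the round-trip tests.
* Cas9 breaks are modeled blunt (no 1-nt staggered ends); the method's
  arithmetic treats the break as a single position.
* N in any genome region used for arms or junctions is a hard error, not
  a warning; guide search requires an exact protospacer (mismatches
  belong to the off-target scan only).
* Ligation is exact overhang complementarity; there is no
  mismatch-tolerant ligation and no kinetics.
* Internal Type IIS sites in an arm are an assembly error (the insert
  would be re-digested) with an explicit override flag; in the
  report-only `validate_arm()` they are warnings.
* Emitted GenBank records sort features by start then label and carry a
  fixed LOCUS date, so identical records are byte-identical files. The
  GenBank writer/parser is intentionally minimal (LOCUS topology,
  `misc_feature` + `/label`, ORIGIN) — enough for plasmid-map round
  trips, not a general GenBank implementation.
* Frame handling is report-only: `frame_check()` compares the cut phase
  with the vector's declared cargo junction phase and never pads arms,
  since padding would break the homology itself. Promoter-driven cargos
  declare no phase and the check returns not-applicable.

## Known limitations

* No guide discovery or activity scoring (site selection is upstream of
  this tool), and no off-target *scoring* model — only exact-budget
  Hamming counting.
* No modeling of concatemer integration, vector-backbone capture, or
  partial HMEJ events beyond the junction window.
* TALEN cut placement is an approximation; if the spacer midpoint is
  wrong for a particular pair, pass `offset`.
* The junction classifier is designed for Sanger-scale amplicon reads,
  not NGS pipelines (no trimming, merging or UMI handling).
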