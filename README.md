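# geneweldr

Design and in-silico validation of **short-homology knock-ins** driven by
homology-mediated end joining (HMEJ), for researchers building reporter or
cassette integrations at CRISPR/Cas9 or TALEN cut sites in zebrafish and
mammalian cells.

The method modeled here is the pGTag-style workflow: homology arms of
24–48 bp (12 bp to ~1 kb supported) directly flanking a genomic
double-strand break are cloned as annealed oligo duplexes into a donor
vector through Type IIS (BfuAI/BspQI) Golden Gate junctions. A *universal*
guide RNA site (UgRNA, spacer `GGGAGGCGTTCGGGCCACAG` with CGG PAM)
engineered on both sides of the cargo lets Cas9 liberate the cassette in
vivo, exposing both homology arms so the cell's MMEJ/SSA-type repair can
seal the cassette into the break.

## The arithmetic at the core

* **Cas9 cut rule.** For a 20-nt protospacer *P* with PAM immediately 3'
  on the target strand, the blunt break falls 3 bp 5' of the PAM, i.e.
  between protospacer bases 17|18. All coordinates are 0-based half-open
  internally; a plus-strand protospacer over `[s, s+20)` cuts at
  `s + 17`, a minus-strand one at `s + 3`.
* **Arms.** The 5' arm is `genome[cut − L5, cut)`, the 3' arm
  `genome[cut, cut + L3)`; an annealing oligo is exactly
  (cloning overhang + arm).
* **Buffer geometry.** A 3-nt buffer (`AAA`) sits between the donor UgRNA
  PAM and the arm so that a chance PAM/genome match cannot silently extend
  the programmed homology; after liberation each cargo end carries a 9-nt
  non-homologous residual (3-nt protospacer remnant + 3-nt PAM + buffer).
* **Deletion tagging.** With two genomic cuts `a < b`, a donor whose 5'
  arm flanks `a` upstream and 3' arm flanks `b` downstream predicts the
  allele `genome[0, a) + payload + genome[b, )`, excising `b − a` bp.
* **Junction precision.** A sequenced junction is *precise* iff the
  homology arm contains no mismatch and no insertion or deletion occurs
  anywhere in the scored window around the programmed homology; detected
  imprecision classes include single-base insertions at the arm boundary
  and tandem duplications of the homology domain.

## Worked example

```r
library(geneweldr)
set.seed(42)

## toy genome with one CRISPR target
protospacer <- "GGACTTCGAGCAAGAGATGG"
genome <- paste0(random_400mer, protospacer, "CGG", random_400mer2)

vec <- load_vector_spec("pGTag-2A-eGFP-SV40")
res <- run_design(genome, protospacer, vec, out_dir = "demo",
                  arm5_len = 24, arm3_len = 24)
res$plan
#> <targeting_plan> single_site at seq:417; arms 24/24 bp; vector pGTag-2A-eGFP-SV40
res$oligos$five_prime
#> <oligo_pair> pGTag-2A-eGFP-SV40_five_prime_24bp
#>   top:    5'-GAAACGCGCGGGGACTTCGAGCAAGAGA-3'
#>   bottom: 5'-AGCTTCTCTTGCTCGAAGTCCCCGCGCG-3'

donor <- run_assemble(res, vec, "demo")       # writes demo/donor.gb
lib   <- run_liberate(donor, "demo")          # writes demo/liberated_cargo.gb
lib
#> <liberated_cargo> 186 bp linear; arms [9, 33) and [153, 177); residuals 9/9 bp
lib$residual_ends$five_prime
#> [1] "CAGCGGAAA"

allele <- build_expected_allele(res$plan, vec$cargo)
ref  <- expected_junction(allele, "five_prime", 128)
classify_junction(ref$seq, ref)
#> <junction_call> precise (five_prime side, identity 1.000, forward)
```

Reading the numbers: the guide resolves to a unique blunt cut at
position 417 (= protospacer start 400 + 17, i.e. 3 bp before the PAM);
the design emits a 4-row oligo sheet (two strands per arm — the 5' top
oligo is the 4-nt BfuAI junction overhang `GAAA` followed by the 24-bp
arm); after in-silico liberation both 24-bp arms sit 9 bp inside the
fragment ends, behind the `CAG` protospacer remnant + `CGG` PAM + `AAA`
buffer residual; and the expected-junction reference classifies against
itself as precise at identity 1.

A command-line wrapper with `design` / `assemble` / `liberate` /
`simulate` / `classify` subcommands ships at
`system.file("cli", "geneweld.R", package = "geneweldr")`.

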