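# amirkit

Design minimal MIR390-based artificial microRNA (amiRNA) precursors and
evaluate their processing from small RNA-seq read sets.

## The problem

Plant amiRNAs are 21-nt small RNAs that redirect the endogenous miRNA
machinery (DCL1 processing, AGO1 slicing) to silence one chosen transcript.
They are conventionally expressed from the 521-nt *AtMIR390a* primary
precursor, whose foldback consists of a ~15–17 bp basal stem (BS), the
21/21-nt guide/star duplex, and a distal stem–loop (DSL, 31 nt in
AtMIR390a, 16 nt in rice OsMIR390). Most of those 521 nt are dispensable:
a shortened chimeric (`shc`) precursor of only 89 nt — AtMIR390a basal
stem (33 nt) + duplex (42 nt) + OsMIR390 DSL with a 2-nt deletion (14 nt)
— is processed just as accurately, can be cloned from one pair of 58-base
annealed oligos instead of 75-base ones, and is small and stable enough to
ride in an RNA virus vector for transgene-free silencing.

`amirkit` provides, for the designer:

- a registry of backbone architectures (`pri`, `AtDSL-D6..D25`, `OsDSL`,
  `OsDSL-D2..D6`, `OsDS-AtL`, `BS`, `BS-D7..D31`, `shc`), with the
  deletion series derived from parents by symmetric stem deletions;
- star-strand design from a declarative duplex template, precursor
  assembly with per-construct compensation of the two backbone
  nucleotides facing guide positions 20/21;
- cloning-oligo design for the BsaI "B/c" vectors (58/75-base pairs with
  4-base 5′ overhangs), including an internal-BsaI-site guard and an
  in-silico digestion/ligation round trip that must reconstruct the
  precursor bit-exactly;
- hairpin validation against the declared pairing layout, with a
  base-pair-maximization (Nussinov) fold as an independent cross-check.

And for the analyst, the sequencing-side statistics used to judge
precursor processing:

- read collapsing (fastx-style `">id-count"` FASTA and plain FASTQ),
  exact ungapped mapping with per-position/length/strand counts and RPM
  (reads per million mapped);
- **processing accuracy**: the proportion of 19–24-nt (+) reads with 5′
  ends within ±4 nt of the guide 5′ end that are the authentic 21-nt
  amiRNA;
- **strand polarity** of a read set against a reference (dsRNA-derived
  populations sit near 50/50; hairpin-derived ones are strongly
  (+)-skewed);
- **phasing registers**: the 21-register table of 21-nt (+) reads
  downstream of the amiRNA cleavage site (between target nucleotides
  opposite guide positions 10/11);
- a seedable read simulator (`simulate_precursor_reads()`,
  `simulate_viral_sirnas()`, `simulate_phased_reads()`) so every metric is
  testable without the deposited libraries.

Bundled backbone segment sequences are synthetic stand-ins that reproduce
the published architecture exactly (lengths, pairing layout, loop sizes);
see the vignette for what does and does not depend on that.

## Worked example

```r
library(amirkit)

g <- guide_rna("TTAGCAGTACCGATTCGATCA", name = "amiR-demo")

# 89-nt minimal precursor: basal stem 1-16/73-89, guide 17-37, star 52-72
p <- build_precursor(g, "shc")
#> <amir_precursor> shc-amiR-demo: 89 nt, guide at 17-37, star at 52-72

# the declared hairpin closes with zero violations
pair_by_layout(p)
#> <structure_report> shc-amiR-demo: basal stem 16 bp, duplex 21 bp,
#>   DSL stem 2 bp, loop 8 nt, 0 violation(s)

# 58-base annealed oligos for the basal-stem B/c vector
design_oligos(g, "BS-AtMIR390a-B/c")
#> <oligo_pair> amiR-demo into BS-AtMIR390a-B/c (58-base oligos, ligation verified)
#>   F: 5'-TGTATTAGCAGTACCGATTCGATCACTAATGGAATAGTGATCGAATCGGTACTGCTAA-3'
#>   R: 5'-TAAGTTAGCAGTACCGATTCGATCACTATTCCATTAGTGATCGAATCGGTACTGCTAA-3'

# simulate a 95%-fidelity library and recover the accuracy
reads  <- simulate_precursor_reads(p, sim_config(seed = 42, depth = 2e4,
                                                 exact_fraction = 0.95))
report <- processing_accuracy(map_exact(reads, p$sequence), p)
report
#> <processing_report> shc-amiR-demo: accuracy 94.9%
#>   (15258 exact guide / 16071 window reads)
```

The accuracy is the fraction of reads in the ±4-nt 5′-end window that are
the exact mature amiRNA — here 15258/16071 = 94.9%, recovering the
simulated 95% fidelity within sampling error. `tidy()`/`glance()` methods
return these results as tibbles, and `autoplot()` draws the per-position
profile, the window breakdown and the phasing-register table.

A thin command-line front end over the same functions ships at
`inst/cli/amirkit.R` (subcommands `precursor`, `star`, `oligos`, `fold`,
`extract`, `map`, `accuracy`, `polarity`, `phasing`, `simulate`).

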