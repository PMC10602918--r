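---
title: "Engineering minimal MIR390-based amiRNA precursors and evaluating their processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering minimal MIR390-based amiRNA precursors and evaluating their processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amirkit)
library(dplyr)
```

## The problem

Artificial microRNAs (amiRNAs) are designed 21-nt small RNAs that co-opt the
plant miRNA pathway to silence a chosen transcript with single-gene
specificity. They are produced in planta by expressing a modified *MIR* gene
whose natural miRNA/miRNA\* duplex has been replaced by the amiRNA/amiRNA\*
duplex. The workhorse backbone for this is the 521-nt *Arabidopsis thaliana*
MIR390a primary transcript, which folds into a hairpin with three functional
blocks:

* a **basal stem (BS)** of roughly 15–17 base pairs below the duplex, the
  landmark for the first DICER-LIKE1 cut (in the full-length primary
  transcript this basal region, including its single-stranded flanks,
  spans 448 nt);
* the 21/21-nt **guide/star duplex**;
* a **distal stem–loop (DSL)** above the duplex — 31 nt in AtMIR390a, and
  only 16 nt in the rice OsMIR390 precursor.

Much of the 521 nt is dispensable. Systematic shortening shows that an
89-nt chimeric precursor — the AtMIR390a basal stem, the amiRNA duplex, and
the OsMIR390 DSL carrying a further 2-nt deletion (the *shc* architecture:
33 + 42 + 14 nt) — is processed as accurately as the full-length backbone,
while being short enough to clone from a single pair of 58-base oligos and
to survive as a stable insert in an RNA virus vector for spray-on,
transgene-free silencing.

This package implements both halves of that workflow:

1. **Design** — a registry of backbone architectures (`pri`, the
   `AtDSL-D*`/`OsDSL-D*`/`BS-D*` deletion series, `shc`), star-strand
   design, precursor assembly, cloning-oligo design with an in-silico
   BsaI ligation check, and layout-based hairpin validation.
2. **Evaluation** — the small RNA-seq computations used to judge precursor
   processing: read collapsing, exact ungapped mapping with per-position
   counts and RPM, the processing-accuracy statistic, strand polarity, and
   21-register phasing tables, plus a seedable simulator that makes every
   metric testable without sequencing data.

## Backbone registry and the synthetic sequence stand-ins

Backbone architectures are loaded from a bundled YAML registry. The segment
*lengths* and the pairing *layout* are the published architecture; the
segment *sequences* are synthetic stand-ins (the file is named
`backbones_synthetic.yaml` for that reason) constructed to satisfy every
declared pairing, with no BsaI site and no repeated 19-mer anywhere in the
constant regions so that exact read mapping is unambiguous. Every length
invariant is re-checked at load time, so a mistyped bundle fails
immediately. Users with the natural sequences can drop them into the same
registry format and work with the authentic backbones.

```{r registry}
purrr::map_dfr(list_backbones(), ~ glance(get_backbone(.x)))
```

The arithmetic identity `total = basal region + 42 + DSL` holds for every
backbone: 448 + 42 + 31 = 521 for `pri` and 33 + 42 + 14 = 89 for `shc`.
Derived backbones are never stored: each `D`-series member is produced from
its parent by a symmetric stem deletion. Even deletions remove the same
number of positions from both arms; an odd remainder is taken from the
unpaired loop-adjacent stem position, which keeps the surviving pairs in
register. DSL deletions trim the duplex-proximal stem ends and preserve the
terminal loop (as the deletion series is drawn); basal-stem deletions trim
the open basal ends and preserve the duplex-adjacent pairs that the first
DCL1 cut measures from.

## Duplex template and compensation rule

The main design decision with no single canonical answer is the exact
guide/star duplex geometry. The default template here is MIR390-like:

* star positions 1–19 are the Watson–Crick complement of guide positions
  19–1 (guide *i* pairs star *20 − i*);
* star 20/21 are fixed template bases, left unpaired as the 2-nt 3′
  overhang of the released duplex;
* guide 20/21 pair with the two duplex-proximal nucleotides of the 3′ DSL
  arm. These two backbone positions are the per-construct **compensation
  positions**: `build_precursor()` rewrites them to the Watson–Crick
  complement of guide 20/21, so the drawn secondary structure is preserved
  for *any* guide.

One consequence supports this geometry: the cloning oligos must span
everything construct-specific — the four-base vector overhang, the guide,
the DSL (whose compensation positions vary per construct) and star 1–19,
with the fixed star 3′ dinucleotide supplied by the vector. That single
formula, 4 + 21 + DSL + 19, yields 75 bases on the full-length `pri` vector
(DSL 31) and 58 bases on the basal-stem vector (DSL 14) — exactly the two
oligo lengths the two vector generations require. The template is data, not
code: `duplex_template()` accepts any pairing declaration, including
intentional mismatches (where the star repeats the facing guide base, which
cannot pair even as a G:U wobble).

```{r design}
g <- guide_rna("TTAGCAGTACCGATTCGATCA", name = "amiR-demo")
p <- build_precursor(g, "shc")
p
tidy(p)
```

## Cloning oligos and the in-silico ligation

`design_oligos()` emits the annealed pair for either vector and refuses
guides that would introduce an internal BsaI recognition site (GGTCTC or
GAGACC), since such an insert would be re-cut during Golden-Gate assembly.
`ligate_oligos()` verifies the two 4-base 5′ overhangs against the vector
and reconstructs the precursor; `design_oligos()` only returns after this
round trip reproduces `build_precursor()` bit-exactly.

```{r oligos}
design_oligos(g, "BS-AtMIR390a-B/c")
```

## Hairpin validation

Two independent routes guard the fold. `pair_by_layout()` checks the
architecture's declared pairs position by position (G:U wobbles count as
paired by default, as plant hairpins rely on them) and reports violations
rather than fixing them. `fold_nussinov()` is a structure-agnostic
base-pair maximization (minimum loop 3 nt, G:U allowed, deterministic
leftmost-partner traceback) used only for pair-count comparisons — it shows
a hairpin of the declared size is attainable, without asserting that the
thermodynamic fold equals the layout. Free-energy folding is deliberately
out of scope.

```{r structure}
pair_by_layout(p)
```

## Small RNA-seq metrics

All read-level functions take and return tibbles. Reads live in DNA space;
mapping is exact and ungapped — a stated feature of the method, not a
shortcut — via `Biostrings` matching. Conventions that matter:

* **Multi-position reads** contribute their count at every position they
  hit but enter the mapped total once. As a consequence the RPM column sums
  to exactly 10^6 only when no read maps at several positions; with
  multi-hits the per-position column intentionally over-counts, mirroring
  the per-position profile definition.
* **Processing accuracy** = counts at exactly (guide start, 21 nt, (+))
  divided by all (+) counts of length 19–24 whose 5′ end lies within ±4 nt
  of the guide start (nine positions). The read's 3′ end is not
  constrained beyond the length range. A zero denominator is flagged
  undefined, never reported as 0/0.
* **RPM** is normalized per reference under analysis (profiles are built
  per precursor); library-wide normalization can be had by mapping against
  a concatenated reference.
* **Cleavage site**: between target nucleotides opposite guide positions
  10/11 (the canonical plant AGO1 rule), reported as the last nucleotide
  retained on the 5′ fragment; phasing register 1 begins at the next
  nucleotide, and registers cycle with period 21.

```{r metrics}
reads <- simulate_precursor_reads(p, sim_config(seed = 42, depth = 2e4, exact_fraction = 0.95))
profile <- map_exact(reads, p$sequence)
report <- processing_accuracy(profile, p)
report
```

## What the simulator does and does not emulate

`simulate_precursor_reads()` draws reads from the precursor (+) strand:
with probability `exact_fraction` the exact mature strand (guide or star,
by `guide_star_ratio`, default 0.8), otherwise a read with a 5′ offset from
a symmetric triangular distribution on ±4 nt and a length from a
distribution peaked at 21 nt with minor 20/22/24-nt mass (the 24-nt class
stands in for transgene-derived siRNAs). The defaults are the study
conditions the metrics were designed around: `exact_fraction = 0.95`
matches the accuracy observed for shc-expressed amiRNAs, `strand_bias =
0.5` is the dsRNA-replication hypothesis for virus-derived siRNAs (0.89
emulates the hairpin-derived alternative), and `phased_fraction = 0`
reflects the absence of phased secondary siRNAs from amiRNA targets. The
offset and size spectra are plausible placeholders, not measured values.

The simulator draws category counts from one multinomial per source, is
fully reproducible from its seed, and emits no sequencing errors, adapter
artifacts or PCR duplication bias. Passing recovery tests therefore shows
the *metrics* are computed correctly at realistic depths — not that real
libraries are this clean; with real data, upstream trimming and quality
filtering remain the user's responsibility.

## Numerical and testing choices

Simulation sizes in the test suite and acceptance script (10^5 reads for
accuracy recovery, 10^4 for polarity, 21,000 for phasing uniformity) were
chosen so that three-sigma binomial/multinomial bounds are tight enough to
be meaningful while each check runs in seconds. Statistical recovery tests
compare against those sampling bounds rather than fixed tolerances. The
Nussinov fold is O(n^3) in plain R — ample for foldback-scale sequences
(hundreds of nt), not meant for genomes. Register assignment, mapping and
collapsing are integer/string exact; the only floating-point quantities
are proportions and RPM.

## Known limitations

* Bundled backbone sequences are synthetic stand-ins (see above); all
  length/pairing conclusions transfer to the natural sequences, but any
  sequence-specific analysis (e.g. folding the authentic AtMIR390a) needs
  the real registry entries.
* Guide selection against a transcriptome (specificity screening,
  off-target prediction, expression-level prediction) is out of scope;
  guides are inputs.
* Mapping is strictly exact: no mismatch tolerance, no gaps, no
  genome-scale alignment.
* Thermodynamic folding is not implemented; `fold_nussinov()` maximizes
  pair counts only.
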