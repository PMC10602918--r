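# Sequence plumbing shared across modules. Precursor-side code works in RNA
# space (A,C,G,U); read/oligo-side code works in DNA space (A,C,G,T).

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Accepts DNA or RNA input, case-insensitive; `T` becomes `U`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector in uppercase RNA alphabet.
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Normalize a nucleotide string to the DNA alphabet
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector in uppercase DNA alphabet.
#' @export
as_dna <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

# TRUE for strings restricted to unambiguous bases (either alphabet)
is_unambiguous <- function(x) {
  !grepl("[^ACGTU]", toupper(x))
}

assert_unambiguous <- function(x, what = "sequence") {
  bad <- which(!is_unambiguous(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains characters outside the unambiguous A/C/G/T/U alphabet (first offender: element %d)",
      what, bad[1]
    ))
  }
  invisible(x)
}

#' Reverse complement
#'
#' Alphabet-preserving reverse complement: RNA input (contains `U`) yields
#' RNA output, otherwise DNA complement rules are used.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    if (grepl("U", s, fixed = TRUE)) {
      comp <- chartr("ACGU", "UGCA", s)
    } else {
      comp <- chartr("ACGT", "TGCA", s)
    }
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# single-base Watson-Crick complement in RNA space
comp_base_rna <- function(b) {
  chartr("ACGU", "UGCA", b)
}

# Watson-Crick or (optionally) G:U wobble pairing in RNA space
bases_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) {
    wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  }
  wc
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
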