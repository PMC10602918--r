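#' Construct a 21-nt amiRNA guide
#'
#' Validates and normalizes an artificial microRNA guide strand. Guides are
#' exactly 21 nt (the canonical plant miRNA length); DNA input is accepted
#' and normalized to RNA.
#'
#' @param sequence A single nucleotide string of length 21 (DNA or RNA,
#'   case-insensitive).
#' @param name Optional label for the guide (e.g. `"amiR-NbSu"`).
#' @return An object of class `amir_guide`: a length-21 RNA string with a
#'   `name` attribute.
#' @examples
#' guide_rna("TTAGCAGTACCGATTCGATCA", name = "amiR-demo")
#' @export
guide_rna <- function(sequence, name = "amiRNA") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    abort("`sequence` must be a single nucleotide string")
  }
  s <- as_rna(sequence)
  if (nchar(s) != 21) {
    abort(sprintf("an amiRNA guide must be exactly 21 nt, got %d nt", nchar(s)))
  }
  assert_unambiguous(s, "guide sequence")
  structure(s, name = as.character(name), class = "amir_guide")
}

is_guide <- function(x) inherits(x, "amir_guide")

#' @export
as.character.amir_guide <- function(x, ...) {
  attributes(x) <- NULL
  x
}

as_guide <- function(x, name = "amiRNA") {
  if (is_guide(x)) x else guide_rna(x, name = name)
}

#' @export
print.amir_guide <- function(x, ...) {
  cat(sprintf("<amir_guide> %s: 5'-%s-3' (21 nt)\n", attr(x, "name"), unclass(x)))
  invisible(x)
}
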