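#' Extract a coordinate-delimited fragment from a reference sequence
#'
#' Coordinates are 1-based and inclusive at both ends, so positions 1004 to
#' 1092 yield an 89-nt fragment. With `orientation = "reverse"` the
#' fragment is reverse-complemented (used e.g. for antisense inserts of
#' target-gene fragments in VIGS vectors).
#'
#' @param reference A nucleotide string (DNA or RNA).
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end <=
#'   nchar(reference)`.
#' @param orientation `"forward"` or `"reverse"`.
#' @return The fragment, in the alphabet of the input; length
#'   `end - start + 1`.
#' @examples
#' extract_fragment("ACGTACGT", 2, 4) # "CGT"
#' extract_fragment("ACGTACGT", 2, 4, "reverse") # "ACG"
#' @export
extract_fragment <- function(reference, start, end,
                             orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (!is.character(reference) || length(reference) != 1) {
    abort("`reference` must be a single nucleotide string")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  n <- nchar(reference)
  if (is.na(start) || is.na(end) || start < 1L || end < start || end > n) {
    abort(sprintf(
      "coordinates out of range: need 1 <= start <= end <= %d, got [%s, %s]",
      n, start, end
    ))
  }
  frag <- substr(reference, start, end)
  if (orientation == "reverse") revcomp(frag) else frag
}
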