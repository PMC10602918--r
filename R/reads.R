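# Read collapsing and exact, ungapped mapping. Reads live in DNA space;
# references are converted to DNA for matching. No mismatches or gaps are
# ever tolerated: exactness is a stated feature of the method, not a
# shortcut.

#' Collapse identical reads into counted records
#'
#' Each distinct sequence appears once with its total count, sorted by
#' descending count then sequence. Records with characters outside the
#' unambiguous DNA alphabet are rejected (their number is reported in a
#' message and in the `n_rejected` attribute).
#'
#' @param raw_reads Character vector of read sequences, or a data frame
#'   with a `sequence` column and optional `count` column.
#' @return A tibble of read records (`sequence`, `count`).
#' @examples
#' collapse_reads(c("AAA", "AAA", "CCC"))
#' @export
collapse_reads <- function(raw_reads) {
  if (is.character(raw_reads)) {
    raw_reads <- tibble(sequence = raw_reads, count = 1L)
  }
  if (!is.data.frame(raw_reads) || !"sequence" %in% names(raw_reads)) {
    abort("`raw_reads` must be a character vector or a data frame with a `sequence` column")
  }
  reads <- as_tibble(raw_reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  reads$sequence <- as_dna(reads$sequence)
  valid <- !grepl("[^ACGT]", reads$sequence) & nchar(reads$sequence) > 0
  n_rejected <- sum(reads$count[!valid])
  if (n_rejected > 0) {
    rlang::inform(sprintf("rejected %d read(s) with non-nucleotide characters", n_rejected))
  }
  out <- reads[valid, ] |>
    group_by(.data$sequence) |>
    summarise(count = sum(as.integer(.data$count)), .groups = "drop") |>
    arrange(desc(.data$count), .data$sequence)
  attr(out, "n_rejected") <- n_rejected
  out
}

# all (overlapping) 1-based start positions of `pattern` in `subject_dna`
exact_starts <- function(pattern, subject) {
  if (nchar(pattern) > length(subject)) {
    return(integer(0))
  }
  Biostrings::start(Biostrings::matchPattern(pattern, subject))
}

#' Map reads exactly against a reference
#'
#' Every exact, ungapped occurrence of each read in the reference (and in
#' its reverse complement when `strands = "both"`) is recorded with the
#' read's count: a read matching at m positions contributes its count at
#' each of the m positions, but enters the mapped total once. Positions are
#' the 1-based reference coordinate of the read's 5' end (for (-) hits this
#' is the rightmost coordinate of the match).
#'
#' @param reads A read tibble (`sequence`, `count`), character vector, or
#'   anything [collapse_reads()] accepts.
#' @param reference Reference nucleotide string (DNA or RNA).
#' @param strands `"plus"` to map only the forward strand (the default, as
#'   used for precursor processing profiles) or `"both"`.
#' @param reference_name Label stored on the profile.
#' @return An `amir_profile` tibble (`position`, `length`, `strand`,
#'   `count`, `rpm`) with attributes `total_mapped`, `reference_name`,
#'   `reference_length`.
#' @examples
#' map_exact(c("ACGT"), "AAACGTTT")
#' @export
map_exact <- function(reads, reference, strands = c("plus", "both"),
                      reference_name = "reference") {
  strands <- match.arg(strands)
  reads <- collapse_reads(reads)
  ref_dna <- as_dna(reference)
  if (nchar(ref_dna) == 0) abort("`reference` must be non-empty")
  subject <- Biostrings::DNAString(ref_dna)

  rows <- purrr::map2(reads$sequence, reads$count, function(s, cnt) {
    L <- nchar(s)
    plus <- exact_starts(s, subject)
    minus <- integer(0)
    if (strands == "both") {
      minus <- exact_starts(as.character(revcomp(s)), subject)
    }
    tibble(
      position = c(plus, minus + L - 1L),
      length = L,
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      count = cnt,
      mapped = length(plus) + length(minus) > 0
    )
  })
  hit_tbl <- dplyr::bind_rows(rows)
  if (nrow(hit_tbl) == 0) {
    hit_tbl <- tibble(
      position = integer(0), length = integer(0), strand = character(0),
      count = integer(0), mapped = logical(0)
    )
  }
  total_mapped <- sum(reads$count[vapply(rows, function(r) any(r$mapped), logical(1))])

  profile <- hit_tbl |>
    dplyr::select(-"mapped") |>
    group_by(.data$position, .data$length, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$position, .data$length, .data$strand)

  attr(profile, "total_mapped") <- total_mapped
  attr(profile, "reference_name") <- reference_name
  attr(profile, "reference_length") <- nchar(ref_dna)
  class(profile) <- c("amir_profile", class(profile))
  rpm_normalize(profile)
}

#' Recompute reads-per-million on a mapping profile
#'
#' `rpm = count / total_mapped * 1e6`, with the mapped total taken from the
#' profile (each mapped read counted once, regardless of how many positions
#' it hit). An empty or unmapped profile gets all-zero RPM and an `empty`
#' attribute.
#'
#' @param profile An `amir_profile`.
#' @return The profile with its `rpm` column recomputed.
#' @export
rpm_normalize <- function(profile) {
  total <- attr(profile, "total_mapped") %||% 0
  if (total > 0) {
    profile$rpm <- profile$count / total * 1e6
    attr(profile, "empty") <- FALSE
  } else {
    profile$rpm <- rep(0, nrow(profile))
    attr(profile, "empty") <- TRUE
  }
  profile
}
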