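# Processing metrics computed from exact-mapping profiles: the
# processing-accuracy statistic, strand polarity, and 21-register phasing
# tables relative to the predicted cleavage site.

#' Precursor processing accuracy
#'
#' The denominator is the summed count of (+)-strand hits of length 19-24
#' whose 5' end lies within +/- 4 nt of the guide 5' end (a 9-position
#' window); the numerator is the count at exactly (`guide_start`, 21 nt,
#' (+)) - under exact ungapped mapping this hit is necessarily the authentic
#' mature amiRNA. Accuracy is their ratio, and is flagged undefined (NA)
#' when no reads fall in the window.
#'
#' @param profile An `amir_profile` computed against the precursor sequence.
#' @param precursor The `amir_precursor` the profile was mapped against (or
#'   a list with a `guide_start` field).
#' @param window Half-width of the 5'-end window (default 4).
#' @param sizes Read lengths admitted to the denominator (default 19:24).
#' @return A `processing_report`: `window_reads`, `exact_guide_reads`,
#'   `accuracy` (proportion in \[0, 1\] or NA), and `size_by_offset`, the
#'   per-offset, per-length breakdown of window counts.
#' @export
processing_accuracy <- function(profile, precursor, window = 4L, sizes = 19:24) {
  gs <- precursor$guide_start
  if (is.null(gs)) abort("`precursor` must carry a guide_start")
  win <- profile |>
    filter(
      .data$strand == "+",
      .data$length %in% sizes,
      .data$position >= gs - window,
      .data$position <= gs + window
    )
  window_reads <- sum(win$count)
  exact_guide_reads <- sum(win$count[win$position == gs & win$length == 21L])
  size_by_offset <- win |>
    mutate(offset = .data$position - gs) |>
    group_by(.data$offset, .data$length) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$offset, .data$length)

  structure(
    list(
      precursor = precursor$name %||% "precursor",
      guide_start = gs,
      window_reads = window_reads,
      exact_guide_reads = exact_guide_reads,
      accuracy = if (window_reads > 0) exact_guide_reads / window_reads else NA_real_,
      undefined = window_reads == 0,
      size_by_offset = size_by_offset
    ),
    class = "processing_report"
  )
}

#' @export
print.processing_report <- function(x, ...) {
  acc <- if (x$undefined) "undefined (no window reads)" else sprintf("%.1f%%", 100 * x$accuracy)
  cat(sprintf(
    "<processing_report> %s: accuracy %s (%d exact guide / %d window reads)\n",
    x$precursor, acc, x$exact_guide_reads, x$window_reads
  ))
  invisible(x)
}

#' Per-offset, per-length window breakdown
#'
#' @param x A `processing_report`.
#' @param ... Unused.
#' @return Tibble of window counts by 5'-end offset and read length.
#' @method tidy processing_report
#' @export
tidy.processing_report <- function(x, ...) x$size_by_offset

#' One-row summary of a processing report
#'
#' @param x A `processing_report`.
#' @param ... Unused.
#' @return One-row tibble (window reads, exact guide reads, accuracy).
#' @method glance processing_report
#' @export
glance.processing_report <- function(x, ...) {
  tibble(
    precursor = x$precursor,
    window_reads = x$window_reads,
    exact_guide_reads = x$exact_guide_reads,
    accuracy = x$accuracy
  )
}

#' Strand polarity of a read set against a reference
#'
#' Maps reads on both strands and returns the fraction of mapped counts of
#' (+) and (-) polarity. A read whose sequence maps to both strands
#' contributes to each; the two fractions always sum to 1 when anything
#' maps. Diagnostic of dsRNA-derived (about 50/50) versus hairpin-derived
#' (strongly (+)-skewed) small RNA populations.
#'
#' @param reads A read tibble or character vector.
#' @param reference Reference nucleotide string (e.g. a viral genome).
#' @return A one-row tibble (`plus_fraction`, `minus_fraction`,
#'   `plus_count`, `minus_count`, `undefined`); fractions are NA when no
#'   read maps.
#' @export
strand_polarity <- function(reads, reference) {
  reads <- collapse_reads(reads)
  ref <- Biostrings::DNAString(as_dna(reference))
  hits <- purrr::map2(reads$sequence, reads$count, function(s, cnt) {
    c(
      plus = if (length(exact_starts(s, ref)) > 0) cnt else 0L,
      minus = if (length(exact_starts(as.character(revcomp(s)), ref)) > 0) cnt else 0L
    )
  })
  plus <- sum(vapply(hits, `[[`, integer(1), "plus"))
  minus <- sum(vapply(hits, `[[`, integer(1), "minus"))
  total <- plus + minus
  tibble(
    plus_fraction = if (total > 0) plus / total else NA_real_,
    minus_fraction = if (total > 0) minus / total else NA_real_,
    plus_count = plus,
    minus_count = minus,
    undefined = total == 0
  )
}

#' Locate the predicted amiRNA cleavage site on a target
#'
#' Requires exactly one perfectly complementary (reverse-complement) site
#' for the guide on the target. Cleavage follows the canonical plant AGO1
#' rule - between the target nucleotides opposite guide positions 10 and 11
#' - so the returned coordinate is the last target nucleotide retained on
#' the 5' cleavage fragment: `site_start + 10` for a site whose 21-nt match
#' begins at `site_start`.
#'
#' @param target Target nucleotide string (mRNA, viral genome, ...).
#' @param guide A 21-nt guide.
#' @return 1-based target coordinate of the last nucleotide 5' of the cut.
#' @export
locate_cleavage_site <- function(target, guide) {
  guide <- as_guide(guide)
  site <- as_dna(revcomp(unclass(guide)))
  starts <- exact_starts(site, Biostrings::DNAString(as_dna(target)))
  if (length(starts) != 1) {
    abort(sprintf(
      "target contains %d perfectly complementary site(s) for the guide; exactly 1 is required",
      length(starts)
    ))
  }
  starts + 10L
}

#' Phasing-register table downstream of a cleavage site
#'
#' Considers 21-nt (+)-strand exact hits whose 5' end lies strictly
#' downstream of the cleavage site and assigns each to one of 21 cyclic
#' registers: register `((pos - (cleavage_site + 1)) mod 21) + 1`, so reads
#' initiating precisely at the cut (and every 21 nt thereafter) fall in
#' register 1. Proportions are over the considered reads.
#'
#' @param reads A read tibble or character vector.
#' @param target Target nucleotide string.
#' @param cleavage_site 1-based coordinate of the last nucleotide 5' of the
#'   cut (see [locate_cleavage_site()]); must lie in
#'   `[1, nchar(target) - 21]`.
#' @return A `phasing_table`: tibble of 21 rows (`register`, `count`,
#'   `proportion`) with attributes `n_reads` and `cleavage_site`.
#' @export
phasing_registers <- function(reads, target, cleavage_site) {
  cleavage_site <- as.integer(cleavage_site)
  n <- nchar(target)
  if (cleavage_site < 1L || cleavage_site > n - 21L) {
    abort(sprintf("cleavage_site must lie in [1, %d]", n - 21L))
  }
  profile <- map_exact(reads, target, strands = "plus")
  hits <- profile |>
    filter(.data$length == 21L, .data$strand == "+", .data$position > cleavage_site) |>
    mutate(register = ((.data$position - (cleavage_site + 1L)) %% 21L) + 1L)
  counts <- hits |>
    group_by(.data$register) |>
    summarise(count = sum(.data$count), .groups = "drop")
  tab <- tibble(register = 1:21) |>
    dplyr::left_join(counts, by = "register") |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  n_reads <- sum(tab$count)
  tab$proportion <- if (n_reads > 0) tab$count / n_reads else rep(0, 21)
  attr(tab, "n_reads") <- n_reads
  attr(tab, "cleavage_site") <- cleavage_site
  attr(tab, "empty") <- n_reads == 0
  class(tab) <- c("phasing_table", class(tab))
  tab
}

#' One-row summary of a phasing table
#'
#' @param x A `phasing_table`.
#' @param ... Unused.
#' @return One-row tibble (reads considered, register-1 proportion, top
#'   register).
#' @method glance phasing_table
#' @export
glance.phasing_table <- function(x, ...) {
  tibble(
    n_reads = attr(x, "n_reads"),
    cleavage_site = attr(x, "cleavage_site"),
    register1_proportion = x$proportion[x$register == 1],
    top_register = x$register[which.max(x$proportion)]
  )
}
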