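#' Assemble an amiRNA precursor from a guide and a backbone
#'
#' Inserts the 21-nt guide into the backbone's guide slot, designs the star
#' strand from the backbone's duplex template, and applies the compensation
#' rule: the duplex-proximal nucleotides of the 3' DSL arm facing guide
#' positions 20/21 are set to their Watson-Crick complements so that the
#' drawn foldback pairing is preserved for any guide.
#'
#' @param guide A 21-nt guide ([guide_rna()] or string; DNA accepted).
#' @param backbone A `backbone_spec` or registered backbone name.
#' @return An `amir_precursor`: the assembled RNA sequence with a 1-based
#'   `segment_map`, `guide_start` and `star_start`. If the guide also occurs
#'   elsewhere in the assembled sequence (which would make downstream read
#'   mapping ambiguous), the precursor is flagged `ambiguous` with a warning.
#' @examples
#' p <- build_precursor("TTAGCAGTACCGATTCGATCA", "shc")
#' nchar(p$sequence) # 89
#' @export
build_precursor <- function(guide, backbone) {
  guide <- as_guide(guide)
  if (is.character(backbone)) backbone <- get_backbone(backbone)
  if (!inherits(backbone, "backbone_spec")) {
    abort("`backbone` must be a backbone_spec or a registered backbone name")
  }

  segs <- backbone$segments
  g <- unclass(guide)
  star <- design_star(guide, backbone$template)
  segs$guide_slot <- g
  segs$star_slot <- star

  # compensation: dsl3_arm[k] faces guide 20, dsl3_arm[k-1] faces guide 21
  k <- nchar(segs$dsl3_arm)
  gch <- seq_chars(g)
  n_comp <- min(2L, k)
  if (n_comp > 0) {
    d3 <- seq_chars(segs$dsl3_arm)
    for (j in seq_len(n_comp)) {
      d3[k - j + 1L] <- comp_base_rna(gch[19L + j])
    }
    segs$dsl3_arm <- paste(d3, collapse = "")
  }

  lens <- vapply(segs, nchar, integer(1))
  starts <- stats::setNames(cumsum(c(1L, utils::head(lens, -1))), names(lens))
  sequence <- paste(unlist(segs, use.names = FALSE), collapse = "")
  segment_map <- tibble(
    role = names(lens),
    start = unname(starts),
    end = unname(starts + lens - 1L)
  ) |> filter(.data$end >= .data$start)

  guide_start <- unname(starts[["guide_slot"]])
  hits <- count_occurrences(sequence, g)
  ambiguous <- hits > 1L
  if (ambiguous) {
    warn(sprintf(
      "guide '%s' occurs %d times in the assembled precursor; read mapping will be ambiguous",
      attr(guide, "name"), hits
    ))
  }

  structure(
    list(
      name = sprintf("%s-%s", backbone$name, attr(guide, "name")),
      sequence = sequence,
      segment_map = segment_map,
      guide_start = guide_start,
      star_start = unname(starts[["star_slot"]]),
      guide = g,
      star = star,
      backbone = backbone,
      ambiguous = ambiguous
    ),
    class = "amir_precursor"
  )
}

count_occurrences <- function(sequence, pattern) {
  length(Biostrings::matchPattern(pattern, Biostrings::RNAString(sequence)))
}

#' @export
print.amir_precursor <- function(x, ...) {
  cat(sprintf(
    "<amir_precursor> %s: %d nt, guide at %d-%d, star at %d-%d%s\n",
    x$name, nchar(x$sequence), x$guide_start, x$guide_start + 20L,
    x$star_start, x$star_start + 20L,
    if (x$ambiguous) " [ambiguous guide placement]" else ""
  ))
  invisible(x)
}

#' Tidy a precursor into its segment coordinate table
#'
#' @param x An `amir_precursor`.
#' @param ... Unused.
#' @return A tibble of segments with 1-based inclusive coordinates and
#'   sequences.
#' @method tidy amir_precursor
#' @export
tidy.amir_precursor <- function(x, ...) {
  x$segment_map |>
    mutate(
      precursor = x$name,
      sequence = substring(x$sequence, .data$start, .data$end),
      length = .data$end - .data$start + 1L,
      .before = 1
    )
}

#' One-row summary of an assembled precursor
#'
#' @param x An `amir_precursor`.
#' @param ... Unused.
#' @return A one-row tibble (name, length, guide/star starts, backbone
#'   architecture lengths, ambiguity flag).
#' @method glance amir_precursor
#' @export
glance.amir_precursor <- function(x, ...) {
  tibble(
    precursor = x$name,
    backbone = x$backbone$name,
    length = nchar(x$sequence),
    guide_start = x$guide_start,
    star_start = x$star_start,
    dsl_length = x$backbone$dsl_length,
    bs_region_length = x$backbone$bs_region_length,
    ambiguous = x$ambiguous
  )
}
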