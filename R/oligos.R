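# Annealed-oligo design for the BsaI ('B/c') cloning vectors.
#
# The two oligos tile the amiRNA-specific window of the precursor:
#
#   forward:  bs5[last 4] + guide(21) + DSL + star(1..19)   (top strand)
#   reverse:  revcomp( guide(21) + DSL + star(21) + bs3[1..2] )
#
# Annealing leaves two 4-base 5' overhangs (the forward oligo's first four
# bases and the reverse oligo's first four bases) that are complementary to
# the BsaI-linearized vector ends; the vector supplies everything else,
# including the fixed star 3'-terminal dinucleotide. Both printed oligo
# lengths follow from one formula, 4 + 21 + dsl_length + 19: 75 bases for
# the full-length pri vector (DSL 31) and 58 for the basal-stem vector
# (DSL 14).

BSAI_SITES <- c("GGTCTC", "GAGACC")

#' Cloning vector specification
#'
#' @param name `"AtMIR390a-B/c"` (full-length pri backbone, 75-base oligos)
#'   or `"BS-AtMIR390a-B/c"` (shc backbone, 58-base oligos).
#' @return A `vector_spec` with the acceptor backbone, expected oligo
#'   length, the two 4-base overhangs, and the fixed upstream/downstream
#'   vector context used by [ligate_oligos()].
#' @export
vector_spec <- function(name = c("AtMIR390a-B/c", "BS-AtMIR390a-B/c")) {
  name <- match.arg(name)
  backbone <- if (name == "AtMIR390a-B/c") "pri" else "shc"
  spec <- get_backbone(backbone)
  # any guide gives the same context: the window below excludes the
  # guide/star/compensation positions
  ref <- suppressWarnings(build_precursor(strrep("A", 21), spec))
  gs <- ref$guide_start
  ss <- ref$star_start
  n <- nchar(ref$sequence)
  structure(
    list(
      name = name,
      backbone = backbone,
      oligo_length = 44L + spec$dsl_length,
      overhang5 = as_dna(substr(ref$sequence, gs - 4L, gs - 1L)),
      overhang3 = as_dna(revcomp(substr(ref$sequence, ss + 19L, ss + 22L))),
      upstream = substr(ref$sequence, 1L, gs - 5L),
      downstream = substr(ref$sequence, ss + 19L, n)
    ),
    class = "vector_spec"
  )
}

#' Design the annealed cloning-oligo pair for a guide
#'
#' Returns the two DNA oligos whose annealed duplex, ligated into the
#' BsaI-linearized vector, reconstructs [build_precursor()] of the same
#' guide exactly. The in-silico ligation check is performed and its result
#' recorded on the returned object.
#'
#' @param guide A 21-nt guide ([guide_rna()] or string).
#' @param vector Vector identifier (see [vector_spec()]).
#' @return An `oligo_pair` with fields `forward`, `reverse` (equal-length
#'   DNA strings), `overhang5`, `overhang3`, `vector`, and `ligation_ok`.
#' @examples
#' op <- design_oligos("TTAGCAGTACCGATTCGATCA", "BS-AtMIR390a-B/c")
#' nchar(op$forward) # 58
#' @export
design_oligos <- function(guide, vector = c("AtMIR390a-B/c", "BS-AtMIR390a-B/c")) {
  guide <- as_guide(guide)
  vec <- if (inherits(vector, "vector_spec")) vector else vector_spec(vector)
  prec <- build_precursor(guide, vec$backbone)
  gs <- prec$guide_start
  ss <- prec$star_start

  forward <- as_dna(substr(prec$sequence, gs - 4L, ss + 18L))
  reverse <- as_dna(revcomp(substr(prec$sequence, gs, ss + 22L)))
  check_bsai(forward, "forward")
  check_bsai(reverse, "reverse")

  pair <- structure(
    list(
      name = attr(guide, "name"),
      vector = vec$name,
      forward = forward,
      reverse = reverse,
      overhang5 = substr(forward, 1L, 4L),
      overhang3 = substr(reverse, 1L, 4L),
      ligation_ok = NA
    ),
    class = "oligo_pair"
  )
  lig <- ligate_oligos(pair, vec)
  pair$ligation_ok <- identical(lig, prec$sequence)
  if (!pair$ligation_ok) {
    abort("internal error: in-silico ligation did not reconstruct the precursor")
  }
  pair
}

check_bsai <- function(oligo, which) {
  for (site in BSAI_SITES) {
    hit <- regexpr(site, oligo, fixed = TRUE)
    if (hit > 0) {
      abort(sprintf(
        "guide creates an internal BsaI site (%s) at position %d of the %s oligo; it would be destroyed on digestion",
        site, as.integer(hit), which
      ))
    }
  }
  invisible(oligo)
}

#' Ligate an annealed oligo pair into its vector in silico
#'
#' Verifies that the two oligos anneal into a duplex with the two 4-base 5'
#' overhangs declared by the vector, then joins the insert with the vector's
#' fixed context.
#'
#' @param pair An `oligo_pair`.
#' @param vector A `vector_spec` (or identifier).
#' @return The reconstructed precursor RNA sequence.
#' @export
ligate_oligos <- function(pair, vector) {
  vec <- if (inherits(vector, "vector_spec")) vector else vector_spec(vector)
  fwd <- toupper(pair$forward)
  rev <- toupper(pair$reverse)
  if (nchar(fwd) != nchar(rev)) {
    abort("forward and reverse oligos must have equal length")
  }
  if (substr(fwd, 1L, 4L) != vec$overhang5) {
    abort(sprintf(
      "forward 5' overhang %s is not compatible with the %s vector (expects %s)",
      substr(fwd, 1L, 4L), vec$name, vec$overhang5
    ))
  }
  if (substr(rev, 1L, 4L) != vec$overhang3) {
    abort(sprintf(
      "reverse 5' overhang %s is not compatible with the %s vector (expects %s)",
      substr(rev, 1L, 4L), vec$name, vec$overhang3
    ))
  }
  # annealing: the double-stranded core is the overlap of the two strands
  top_from_reverse <- revcomp(rev) # top-strand window guide .. bs3[2]
  core_top <- substr(fwd, 5L, nchar(fwd))
  if (substr(top_from_reverse, 1L, nchar(core_top)) != core_top) {
    abort("oligos do not anneal: double-stranded core mismatch")
  }
  paste0(vec$upstream, as_rna(fwd), vec$downstream)
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf(
    "<oligo_pair> %s into %s (%d-base oligos, ligation %s)\n  F: 5'-%s-3'\n  R: 5'-%s-3'\n",
    x$name, x$vector, nchar(x$forward),
    if (isTRUE(x$ligation_ok)) "verified" else "NOT verified",
    x$forward, x$reverse
  ))
  invisible(x)
}

#' Tidy an oligo pair into an ordering sheet
#'
#' @param x An `oligo_pair`.
#' @param ... Unused.
#' @return A two-row tibble (name, vector, strand, sequence, length,
#'   overhang) suitable for [readr::write_tsv()].
#' @method tidy oligo_pair
#' @export
tidy.oligo_pair <- function(x, ...) {
  tibble(
    name = paste0(x$name, c("-F", "-R")),
    vector = x$vector,
    strand = c("forward", "reverse"),
    sequence = c(x$forward, x$reverse),
    length = nchar(.data$sequence),
    overhang = c(x$overhang5, x$overhang3)
  )
}
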