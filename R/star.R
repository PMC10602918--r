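# Star-strand (amiRNA*) design from a declared duplex template.
#
# A duplex template is data, not code: it declares, for each of the 21 star
# positions, either the guide position it pairs with, that the pairing is an
# intentional mismatch, or a fixed base. The default template reproduces the
# MIR390-style duplex used by the precursor layouts in this package: star
# positions 1-19 pair guide positions 19-1 (guide i with star 20 - i), and
# star 20/21 are the fixed, unpaired 3'-terminal dinucleotide that forms the
# 2-nt 3' overhang of the released duplex.

#' Build a guide/star duplex template
#'
#' @param pairs Integer vector of length 21. `pairs[i]` is the guide position
#'   that star position `i` faces, or `NA` for star positions carrying a
#'   fixed base.
#' @param mismatches Integer vector of star positions (subset of the paired
#'   positions) at which the star deliberately does not complement the guide.
#' @param fixed Named character vector of literal RNA bases for star
#'   positions with `NA` in `pairs`; names are the star positions.
#' @return A `duplex_template` object.
#' @export
duplex_template <- function(pairs, mismatches = integer(0), fixed = character(0)) {
  pairs <- as.integer(pairs)
  if (length(pairs) != 21) {
    abort("a duplex template must declare all 21 star positions")
  }
  paired <- which(!is.na(pairs))
  if (any(pairs[paired] < 1 | pairs[paired] > 21)) {
    abort("guide positions in a duplex template must lie in 1..21")
  }
  if (anyDuplicated(pairs[paired])) {
    abort("a guide position cannot face two star positions")
  }
  mismatches <- as.integer(mismatches)
  if (!all(mismatches %in% paired)) {
    abort("mismatch positions must be declared paired star positions")
  }
  need_fixed <- setdiff(seq_len(21), paired)
  fixed_pos <- as.integer(names(fixed))
  if (!setequal(fixed_pos, need_fixed)) {
    abort("every unpaired star position needs exactly one fixed base")
  }
  fixed <- as_rna(unname(fixed))
  if (length(fixed) > 0) assert_unambiguous(fixed, "fixed star bases")
  structure(
    list(pairs = pairs, mismatches = mismatches,
         fixed = stats::setNames(fixed, fixed_pos)),
    class = "duplex_template"
  )
}

#' MIR390-style default duplex template
#'
#' Star 1-19 complement guide 19-1; star 20/21 are fixed (`C`, `U`) and sit
#' as the 2-nt 3' overhang at the base of the duplex.
#'
#' @return A `duplex_template`.
#' @export
template_mir390 <- function() {
  duplex_template(
    pairs = c(19:1, NA, NA),
    fixed = c(`20` = "C", `21` = "U")
  )
}

#' Fully paired (blunt) duplex template
#'
#' Star position `i` complements guide position `22 - i`; the star is the
#' exact reverse complement of the guide. Useful as a reference template:
#' applying [design_star()] twice with it returns the original guide.
#'
#' @param mismatches Optional star positions to deviate at.
#' @return A `duplex_template`.
#' @export
template_all_paired <- function(mismatches = integer(0)) {
  duplex_template(pairs = 22L - 1:21, mismatches = mismatches)
}

#' Design the star (passenger) strand for a guide
#'
#' The star is the reverse complement of the guide at every template-paired
#' position, deviates only at declared mismatch positions (where the star
#' repeats the facing guide base, which can never pair, not even as a G:U
#' wobble), and carries the template's fixed bases elsewhere. Deterministic
#' for a fixed template.
#'
#' @param guide A 21-nt guide ([guide_rna()] object or string).
#' @param template A [duplex_template()]; default [template_mir390()].
#' @return A 21-nt RNA string (the star strand, 5' to 3').
#' @examples
#' design_star("AAAAAAAAAAAAAAAAAAAAA", template_all_paired())
#' @export
design_star <- function(guide, template = template_mir390()) {
  guide <- as_guide(guide)
  if (!inherits(template, "duplex_template")) {
    abort("`template` must be a duplex_template object")
  }
  g <- seq_chars(unclass(guide))
  star <- character(21)
  for (i in seq_len(21)) {
    j <- template$pairs[i]
    if (is.na(j)) {
      star[i] <- template$fixed[[as.character(i)]]
    } else if (i %in% template$mismatches) {
      star[i] <- g[j]
    } else {
      star[i] <- comp_base_rna(g[j])
    }
  }
  paste(star, collapse = "")
}
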