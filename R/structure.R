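# Hairpin validation. Two independent routes are provided: pair_by_layout()
# checks the pairing the backbone architecture declares (basal stem, duplex,
# compensation pairs, DSL stem) position by position, while fold_nussinov()
# is a structure-agnostic base-pair-maximization fold used as a cross-check
# that a hairpin of the declared size is attainable at all.

#' Validate a precursor against its declared pairing layout
#'
#' Pairs positions according to the backbone's architecture (basal-stem arms
#' against each other, guide against star per the duplex template, guide
#' 20/21 against the compensation positions, DSL arms against each other)
#' and verifies Watson-Crick or, optionally, G:U complementarity at each
#' declared pair. Failures are listed as violations, never silently fixed.
#'
#' @param precursor An `amir_precursor`.
#' @param allow_gu Count G:U wobbles as paired (default `TRUE`; plant
#'   hairpins rely on them).
#' @return A `structure_report`: dot-bracket string (same length as the
#'   precursor), pair counts per stem, loop length, and a tibble of
#'   violations.
#' @examples
#' report <- pair_by_layout(build_precursor("TTAGCAGTACCGATTCGATCA", "shc"))
#' nrow(report$violations) # 0
#' @export
pair_by_layout <- function(precursor, allow_gu = TRUE) {
  if (!inherits(precursor, "amir_precursor")) {
    abort("`precursor` must be an amir_precursor")
  }
  need <- c("bs5_arm", "guide_slot", "loop", "star_slot", "bs3_arm")
  missing_roles <- setdiff(need, precursor$segment_map$role)
  if (length(missing_roles) > 0) {
    abort(sprintf("segment map is missing roles: %s", paste(missing_roles, collapse = ", ")))
  }
  layout <- layout_pairs(precursor$backbone)
  ch <- seq_chars(precursor$sequence)
  ok <- bases_pair(ch[layout$pos5], ch[layout$pos3], allow_gu = allow_gu)

  db <- rep(".", nchar(precursor$sequence))
  db[layout$pos5[ok]] <- "("
  db[layout$pos3[ok]] <- ")"

  violations <- layout[!ok, ] |>
    mutate(
      expected_pairing = paste0(ch[.data$pos5], ":", comp_base_rna(ch[.data$pos5])),
      found = paste0(ch[.data$pos5], ":", ch[.data$pos3])
    )
  loop_row <- precursor$segment_map |> filter(.data$role == "loop")

  structure(
    list(
      precursor = precursor$name,
      dotbracket = paste(db, collapse = ""),
      basal_stem_bp = sum(ok & layout$kind == "basal_stem"),
      duplex_paired = sum(ok & layout$kind == "duplex"),
      dsl_stem_bp = sum(ok & layout$kind == "dsl_stem"),
      loop_length = loop_row$end - loop_row$start + 1L,
      violations = violations
    ),
    class = "structure_report"
  )
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf(
    "<structure_report> %s: basal stem %d bp, duplex %d bp, DSL stem %d bp, loop %d nt, %d violation(s)\n",
    x$precursor, x$basal_stem_bp, x$duplex_paired, x$dsl_stem_bp,
    x$loop_length, nrow(x$violations)
  ))
  invisible(x)
}

#' Violations table of a structure report
#'
#' @param x A `structure_report`.
#' @param ... Unused.
#' @return Tibble of declared pairs that failed complementarity.
#' @method tidy structure_report
#' @export
tidy.structure_report <- function(x, ...) x$violations

#' One-row summary of a structure report
#'
#' @param x A `structure_report`.
#' @param ... Unused.
#' @return A one-row tibble of pair counts and the violation count.
#' @method glance structure_report
#' @export
glance.structure_report <- function(x, ...) {
  tibble(
    precursor = x$precursor,
    basal_stem_bp = x$basal_stem_bp,
    duplex_paired = x$duplex_paired,
    dsl_stem_bp = x$dsl_stem_bp,
    loop_length = x$loop_length,
    n_violations = nrow(x$violations)
  )
}

#' Maximum base-pair fold (Nussinov recursion)
#'
#' Classical base-pair maximization with a minimum hairpin loop and G:U
#' wobbles allowed. Intended for foldback-scale sequences as an independent
#' check that the layout-declared hairpin is attainable; it is not a
#' thermodynamic fold.
#'
#' @param sequence RNA or DNA string.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param allow_gu Count G:U wobbles as pairable (default `TRUE`).
#' @return A dot-bracket string with attribute `n_pairs` (the maximal pair
#'   count). Traceback is deterministic: at ties the leftmost pairing
#'   partner is chosen, which keeps stems contiguous.
#' @examples
#' fold_nussinov("GGGAAACCC") # "(((...)))"
#' @export
fold_nussinov <- function(sequence, min_loop = 3, allow_gu = TRUE) {
  s <- as_rna(sequence)
  assert_unambiguous(s)
  n <- nchar(s)
  ch <- seq_chars(s)
  if (n < min_loop + 2) {
    return(structure(strrep(".", n), n_pairs = 0L))
  }

  can_pair <- function(i, j) bases_pair(ch[i], ch[j], allow_gu = allow_gu)
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      ks <- ks[bases_pair(ch[ks], ch[j], allow_gu = allow_gu)]
      if (length(ks) > 0) {
        left <- ifelse(ks > i, M[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- ifelse(ks + 1L <= j - 1L, M[cbind(pmin(ks + 1L, n), j - 1L)], 0L)
        best <- max(best, max(left + 1L + inner))
      }
      M[i, j] <- best
    }
  }

  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]
    j <- ij[2]
    while (j - i > min_loop) {
      target <- M[i, j]
      if (target == 0L) break
      paired <- FALSE
      for (k in i:(j - min_loop - 1L)) {
        if (!can_pair(k, j)) next
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
        if (left + 1L + inner == target) {
          db[k] <- "("
          db[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          i <- k + 1L
          j <- j - 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) j <- j - 1L
    }
  }
  structure(paste(db, collapse = ""), n_pairs = max(M[1, n], 0L))
}
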