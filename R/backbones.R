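# Backbone registry: named precursor architectures of the MIR390 series.
#
# A backbone spec carries the constant segment sequences of a precursor
# (flanks, basal-stem arms, DSL arms, terminal loop) plus 21-nt slots for
# the guide and star strands, the duplex template used to design the star,
# and the compensation rule that re-writes the two duplex-proximal
# nucleotides of the 3' DSL arm to complement guide positions 20/21.
# Delta-series backbones are derived from their parent by symmetric stem
# deletions at load time and are never stored redundantly.

SEGMENT_ROLES <- c(
  "flank5", "bs5_arm", "guide_slot", "dsl5_arm", "loop",
  "dsl3_arm", "star_slot", "bs3_arm", "flank3"
)

GUIDE_SLOT_PLACEHOLDER <- strrep("N", 21)

#' Construct a backbone specification
#'
#' Usually obtained from [get_backbone()]; exposed so user-defined
#' architectures can be validated through the same checks as the registry.
#'
#' @param name Backbone identifier.
#' @param segments Named character vector/list of RNA segment sequences.
#'   Allowed roles, in 5' to 3' order: `flank5`, `bs5_arm`, `dsl5_arm`,
#'   `loop`, `dsl3_arm`, `bs3_arm`, `flank3` (the 21-nt `guide_slot` and
#'   `star_slot` are implicit). `bs5_arm`, `bs3_arm` and `loop` are
#'   mandatory; `dsl5_arm` may be empty.
#' @param template Duplex template used for star design
#'   (default [template_mir390()]).
#' @return A `backbone_spec` object with derived lengths (`dsl_length`,
#'   `bs_stem_length`, `bs_region_length`, `total_length`) as fields.
#' @export
backbone_spec <- function(name, segments, template = template_mir390()) {
  segments <- lapply(segments, as_rna)
  bad_roles <- setdiff(names(segments), setdiff(SEGMENT_ROLES, c("guide_slot", "star_slot")))
  if (length(bad_roles) > 0) {
    abort(sprintf("unknown segment role(s): %s", paste(bad_roles, collapse = ", ")))
  }
  for (role in c("bs5_arm", "bs3_arm", "loop")) {
    if (is.null(segments[[role]])) {
      abort(sprintf("backbone '%s' is missing mandatory segment '%s'", name, role))
    }
  }
  segments$dsl5_arm <- segments$dsl5_arm %||% ""
  segments$dsl3_arm <- segments$dsl3_arm %||% ""
  for (role in names(segments)) {
    if (nzchar(segments[[role]])) assert_unambiguous(segments[[role]], role)
  }
  if (nchar(segments$loop) < 3) {
    abort(sprintf("backbone '%s': terminal loop must be at least 3 nt", name))
  }

  full <- stats::setNames(vector("list", length(SEGMENT_ROLES)), SEGMENT_ROLES)
  for (role in SEGMENT_ROLES) {
    full[[role]] <- if (role %in% c("guide_slot", "star_slot")) {
      GUIDE_SLOT_PLACEHOLDER
    } else {
      segments[[role]] %||% ""
    }
  }
  lens <- vapply(full, nchar, integer(1))
  spec <- structure(
    list(
      name = name,
      segments = full,
      template = template,
      compensation = list(segment = "dsl3_arm", guide_positions = c(20L, 21L)),
      dsl_length = unname(lens[["dsl5_arm"]] + lens[["loop"]] + lens[["dsl3_arm"]]),
      bs_stem_length = unname(lens[["bs5_arm"]] + lens[["bs3_arm"]]),
      bs_region_length = unname(lens[["flank5"]] + lens[["bs5_arm"]] +
        lens[["bs3_arm"]] + lens[["flank3"]]),
      total_length = unname(sum(lens))
    ),
    class = "backbone_spec"
  )
  stopifnot(spec$total_length == spec$bs_region_length + 42L + spec$dsl_length)
  spec
}

segment_lengths <- function(spec) {
  vapply(spec$segments, nchar, integer(1))
}

# --- registry ---------------------------------------------------------------

.registry <- new.env(parent = emptyenv())

registry_path_default <- function() {
  system.file("extdata", "backbones_synthetic.yaml", package = "amirkit")
}

# Symmetric deletion of k nucleotides from one stem of a parent spec,
# preserving the terminal loop and the pairing register of the surviving
# pairs. Even deletions remove floor(k/2) positions from each arm; an odd
# remainder is taken from the unpaired loop-adjacent stem position (the arm
# overhanging the other), so the remaining arms stay in register.
delete_stem <- function(spec, stem = c("dsl", "bs"), k, name) {
  stem <- match.arg(stem)
  segs <- spec$segments
  arms <- if (stem == "dsl") c("dsl5_arm", "dsl3_arm") else c("bs5_arm", "bs3_arm")
  l5 <- nchar(segs[[arms[1]]])
  l3 <- nchar(segs[[arms[2]]])
  if (stem == "dsl") {
    # arms meet the duplex at the start of dsl5_arm and the end of dsl3_arm;
    # two dsl3 positions are compensation slots, the rest pair with dsl5
    per_arm <- floor(k / 2)
    d5_head <- per_arm
    d3_tail <- per_arm
    d5_tail <- 0L
    d3_head <- 0L
    if (k %% 2 == 1) {
      if (l5 > max(l3 - 2L, 0L)) {
        d5_tail <- 1L # unpaired dsl5 position next to the loop
      } else if (l3 - 2L > l5) {
        d3_head <- 1L # unpaired dsl3 position next to the loop
      } else {
        abort(sprintf(
          "cannot delete an odd number of nucleotides (%d) from the fully paired DSL stem of '%s'",
          k, spec$name
        ))
      }
    }
    if (d5_head + d5_tail > l5 || d3_head + d3_tail > l3) {
      abort(sprintf("cannot delete %d nt from the dsl stem of '%s'", k, spec$name))
    }
    segs[[arms[1]]] <- substr(segs[[arms[1]]], d5_head + 1L, l5 - d5_tail)
    segs[[arms[2]]] <- substr(segs[[arms[2]]], 1L + d3_head, l3 - d3_tail)
  } else {
    # basal stem: pairs are anchored at the duplex-proximal ends, so trimming
    # the open basal ends (start of bs5_arm, end of bs3_arm) keeps register;
    # the longer (overhanging) arm loses the odd remainder
    d3 <- if (l3 >= l5) ceiling(k / 2) else floor(k / 2)
    d5 <- k - d3
    if (d5 > l5 || d3 > l3) {
      abort(sprintf("cannot delete %d nt from the bs stem of '%s'", k, spec$name))
    }
    segs[[arms[1]]] <- substr(segs[[arms[1]]], d5 + 1L, l5)
    segs[[arms[2]]] <- substr(segs[[arms[2]]], 1L, l3 - d3)
  }
  keep <- setdiff(names(segs), c("guide_slot", "star_slot"))
  backbone_spec(name, segs[keep][vapply(segs[keep], nzchar, logical(1))],
    template = spec$template
  )
}

#' Load a backbone registry file
#'
#' Parses a YAML registry of segment sequences, base backbone compositions
#' and derived (delta-series) definitions, validates every declared length
#' invariant, and installs the result as the active registry. Called
#' automatically with the bundled synthetic registry on first use.
#'
#' @param path Path to a registry YAML file.
#' @return (Invisibly) a named list of `backbone_spec` objects.
#' @export
load_backbone_registry <- function(path = registry_path_default()) {
  cfg <- yaml::read_yaml(path)
  seqs <- lapply(cfg$segments, as_rna)
  specs <- list()
  for (nm in names(cfg$backbones)) {
    comp <- cfg$backbones[[nm]]
    segs <- lapply(comp, function(ref) {
      if (is.null(seqs[[ref]])) abort(sprintf("registry references unknown segment '%s'", ref))
      seqs[[ref]]
    })
    names(segs) <- names(comp)
    specs[[nm]] <- backbone_spec(nm, segs)
  }
  for (nm in names(cfg$derived)) {
    d <- cfg$derived[[nm]]
    parent <- specs[[d$parent]]
    if (is.null(parent)) abort(sprintf("derived backbone '%s' has unknown parent '%s'", nm, d$parent))
    specs[[nm]] <- delete_stem(parent, d$stem, d$delete, nm)
  }
  validate_registry(specs, cfg$expected)
  .registry$specs <- specs
  .registry$path <- path
  invisible(specs)
}

# enforce the published architecture constants; a mistyped bundle fails fast
validate_registry <- function(specs, expected) {
  for (nm in names(expected)) {
    spec <- specs[[nm]]
    if (is.null(spec)) abort(sprintf("expected-length table names unknown backbone '%s'", nm))
    for (field in names(expected[[nm]])) {
      want <- expected[[nm]][[field]]
      got <- spec[[field]]
      if (!identical(as.integer(got), as.integer(want))) {
        abort(sprintf(
          "registry validation failed: %s of '%s' is %d, declared %d",
          field, nm, got, want
        ))
      }
    }
  }
  invisible(specs)
}

registry_specs <- function() {
  if (is.null(.registry$specs)) load_backbone_registry()
  .registry$specs
}

#' List registered backbone names
#'
#' @return Character vector of backbone identifiers.
#' @export
list_backbones <- function() names(registry_specs())

normalize_backbone_name <- function(name) {
  # accept the Greek-delta spelling of the deletion series
  gsub("Δ", "D", name)
}

#' Look up a backbone by name
#'
#' @param name Backbone identifier (e.g. `"pri"`, `"shc"`, `"OsDSL-D2"`,
#'   `"AtDSL-D25"`; the Greek-delta spelling is accepted).
#' @return A `backbone_spec`.
#' @examples
#' get_backbone("pri")$dsl_length # 31
#' get_backbone("shc")$total_length # 89 once a guide is inserted
#' @export
get_backbone <- function(name) {
  specs <- registry_specs()
  nm <- normalize_backbone_name(name)
  if (!nm %in% names(specs)) {
    abort(sprintf(
      "unknown backbone '%s'; registered backbones: %s",
      name, paste(names(specs), collapse = ", ")
    ))
  }
  specs[[nm]]
}

# --- declared pairing layout ------------------------------------------------

# Absolute (1-based) coordinates of every declared base pair of a backbone's
# hairpin: basal stem, guide/star duplex (per template, intentional
# mismatches excluded), the two guide/compensation pairs, and the DSL stem.
layout_pairs <- function(spec) {
  lens <- segment_lengths(spec)
  starts <- cumsum(c(1L, utils::head(lens, -1)))
  names(starts) <- names(lens)
  pos <- function(role, i) unname(starts[[role]] + i - 1L)
  L5 <- lens[["bs5_arm"]]
  L3 <- lens[["bs3_arm"]]
  a <- lens[["dsl5_arm"]]
  k <- lens[["dsl3_arm"]]

  p1 <- integer(0)
  p2 <- integer(0)
  kind <- character(0)
  add <- function(i, j, what) {
    p1 <<- c(p1, i)
    p2 <<- c(p2, j)
    kind <<- c(kind, what)
  }
  for (j in seq_len(min(L5, L3))) {
    add(pos("bs5_arm", L5 + 1L - j), pos("bs3_arm", j), "basal_stem")
  }
  tpl <- spec$template
  for (s in seq_len(21)) {
    g <- tpl$pairs[s]
    if (!is.na(g) && !(s %in% tpl$mismatches)) {
      add(pos("guide_slot", g), pos("star_slot", s), "duplex")
    }
  }
  n_comp <- min(2L, k)
  for (j in seq_len(n_comp)) {
    # guide 20 faces dsl3[k], guide 21 faces dsl3[k-1]
    add(pos("guide_slot", 19L + j), pos("dsl3_arm", k - j + 1L), "duplex")
  }
  if (k >= 3L && a >= 1L) {
    for (j in seq_len(min(a, k - 2L))) {
      add(pos("dsl5_arm", j), pos("dsl3_arm", k - 1L - j), "dsl_stem")
    }
  }
  tibble(
    pos5 = pmin(p1, p2), pos3 = pmax(p1, p2), kind = kind
  ) |> arrange(.data$pos5)
}

# --- methods ----------------------------------------------------------------

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf(
    "<backbone_spec> %s: total %d nt = basal region %d + duplex 42 + DSL %d\n",
    x$name, x$total_length, x$bs_region_length, x$dsl_length
  ))
  lens <- segment_lengths(x)
  cat("  segments:", paste(sprintf("%s[%d]", names(lens)[lens > 0], lens[lens > 0]),
    collapse = " "
  ), "\n")
  invisible(x)
}

#' Tidy a backbone spec into its segment table
#'
#' @param x A `backbone_spec`.
#' @param ... Unused.
#' @return A tibble with one row per segment (role, sequence, length,
#'   start, end).
#' @method tidy backbone_spec
#' @export
tidy.backbone_spec <- function(x, ...) {
  lens <- segment_lengths(x)
  starts <- stats::setNames(cumsum(c(1L, utils::head(lens, -1))), names(lens))
  tibble(
    backbone = x$name,
    role = names(lens),
    sequence = unlist(x$segments, use.names = FALSE),
    length = unname(lens),
    start = unname(starts),
    end = unname(starts + lens - 1L)
  ) |> filter(.data$length > 0)
}

#' One-row architecture summary of a backbone
#'
#' @param x A `backbone_spec`.
#' @param ... Unused.
#' @return A one-row tibble of the derived architecture lengths.
#' @method glance backbone_spec
#' @export
glance.backbone_spec <- function(x, ...) {
  tibble(
    backbone = x$name,
    total_length = x$total_length,
    bs_region_length = x$bs_region_length,
    bs_stem_length = x$bs_stem_length,
    dsl_length = x$dsl_length,
    loop_length = nchar(x$segments$loop)
  )
}
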