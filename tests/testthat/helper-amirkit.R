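# Shared fixtures and independent oracles. Oracles are deliberately naive
# (sliding windows, exhaustive recursion, plain string assembly) and never
# share code with the implementation paths they check.

random_guide <- function() {
  guide_rna(paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force exact mapper: O(n * m) sliding-window scan
oracle_map <- function(reads, reference, strands = "plus") {
  reads <- collapse_reads(reads)
  ref <- as_dna(reference)
  n <- nchar(ref)
  rows <- list()
  mapped_total <- 0
  for (r in seq_len(nrow(reads))) {
    s <- reads$sequence[r]
    cnt <- reads$count[r]
    L <- nchar(s)
    hit <- FALSE
    if (L <= n) {
      for (i in seq_len(n - L + 1)) {
        if (substr(ref, i, i + L - 1) == s) {
          rows[[length(rows) + 1]] <- list(position = i, length = L, strand = "+", count = cnt)
          hit <- TRUE
        }
        if (strands == "both" && substr(ref, i, i + L - 1) == revcomp(s)) {
          rows[[length(rows) + 1]] <- list(position = i + L - 1, length = L, strand = "-", count = cnt)
          hit <- TRUE
        }
      }
    }
    if (hit) mapped_total <- mapped_total + cnt
  }
  profile <- dplyr::bind_rows(rows)
  if (nrow(profile) == 0) {
    profile <- tibble::tibble(
      position = integer(0), length = integer(0),
      strand = character(0), count = integer(0)
    )
  }
  profile <- profile |>
    dplyr::group_by(position, length, strand) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::arrange(position, length, strand)
  list(profile = profile, total_mapped = mapped_total)
}

# exhaustive maximum-base-pair count by enumeration over all non-crossing
# structures (no DP table; exponential, for short sequences only)
oracle_max_pairs <- function(sequence, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  pairable <- function(a, b) {
    ok <- paste0(a, b) %in% c("AU", "UA", "GC", "CG")
    if (allow_gu) ok <- ok || paste0(a, b) %in% c("GU", "UG")
    ok
  }
  recur <- function(i, j) {
    if (j - i < min_loop + 1) {
      return(0L)
    }
    best <- recur(i + 1, j) # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (pairable(s[i], s[k])) {
        best <- max(best, 1L + recur(i + 1, k - 1) + recur(k + 1, j))
      }
    }
    best
  }
  if (length(s) < min_loop + 2) {
    return(0L)
  }
  recur(1L, length(s))
}

# balanced-bracket check for dot-bracket strings
brackets_balanced <- function(db) {
  depth <- 0
  for (ch in strsplit(db, "")[[1]]) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth < 0) {
      return(FALSE)
    }
  }
  depth == 0
}
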