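# Format readers and writers. Collapsed FASTA follows the fastx_collapser
# dialect: headers are ">id-count" with a mandatory trailing count, so
# read counts survive collapsing. Plain FASTQ is accepted with a count of 1
# per record. gzip is handled transparently by R's connections.

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a FASTA file of named sequences
#'
#' @param path Path to a FASTA file (optionally gzipped); records may be
#'   line-wrapped. Header text after the first whitespace is kept in the
#'   `description` column.
#' @return A tibble with columns `name`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  tibble(
    name = sub("\\s.*$", "", headers),
    sequence = unname(toupper(as.character(set))),
    description = ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  )
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector, or a tibble with `name` and
#'   `sequence` columns (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes single-line records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.data.frame(seqs)) {
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  }
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    body <- if (is.finite(width) && nchar(s) > width) {
      substring(s, seq(1, nchar(s), width), pmin(seq(width, nchar(s) + width - 1, width), nchar(s)))
    } else {
      s
    }
    c(paste0(">", nm), body)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a collapsed-FASTA read set
#'
#' Headers must follow the `">id-count"` convention (count mandatory), e.g.
#' `">1-2843"` for the most abundant sequence seen 2843 times.
#'
#' @param path Path to a collapsed FASTA file (optionally gzipped).
#' @return A tibble of read records (`sequence`, `count`), ordered by
#'   descending count then sequence.
#' @export
read_collapsed_fasta <- function(path) {
  fa <- read_fasta(path)
  ids <- paste0(fa$name, ifelse(nzchar(fa$description), paste0(" ", fa$description), ""))
  m <- regmatches(fa$name, regexec("-(\\d+)$", fa$name))
  counts <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  if (anyNA(counts)) {
    bad <- which(is.na(counts))[1]
    abort(sprintf(
      "collapsed-FASTA header '%s' (record %d) carries no '-count' suffix; for plain per-read FASTA/FASTQ use read_fastq()",
      ids[bad], bad
    ))
  }
  collapse_reads(tibble(sequence = fa$sequence, count = as.integer(counts)))
}

#' Write a read set as collapsed FASTA
#'
#' @param reads A read tibble (`sequence`, `count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  reads <- collapse_reads(reads)
  write_fasta(
    stats::setNames(reads$sequence, paste0(seq_len(nrow(reads)), "-", reads$count)),
    path,
    width = Inf
  )
}

#' Read a FASTQ file into a read tibble
#'
#' A plain 4-line-per-record FASTQ parser (no line wrapping, which sRNA-seq
#' FASTQ never uses); quality strings are checked for length and discarded.
#' Each record enters with a count of 1; collapse with [collapse_reads()].
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A tibble with columns `sequence` and `count` (all 1).
#' @export
read_fastq <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf(
      "truncated FASTQ: record %d is incomplete (%d trailing line(s))",
      length(lines) %/% 4 + 1, length(lines) %% 4
    ))
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(tibble(sequence = character(0), count = integer(0)))
  }
  idx <- 4 * (seq_len(n) - 1)
  heads <- lines[idx + 1]
  seqs <- toupper(lines[idx + 2])
  quals <- lines[idx + 4]
  bad <- which(!startsWith(heads, "@") | !startsWith(lines[idx + 3], "+"))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d (line %d)", bad[1], idx[bad[1]] + 1))
  }
  badq <- which(nchar(quals) != nchar(seqs))
  if (length(badq) > 0) {
    abort(sprintf(
      "malformed FASTQ record %d: quality length %d does not match sequence length %d",
      badq[1], nchar(quals[badq[1]]), nchar(seqs[badq[1]])
    ))
  }
  tibble(sequence = seqs, count = 1L)
}

#' Write a per-position mapping profile as TSV
#'
#' @param profile A mapping profile (see [map_exact()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- profile |>
    mutate(reference = attr(profile, "reference_name") %||% "reference", .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a report object as JSON
#'
#' Serializes processing reports, phasing tables, or any list/tibble to
#' pretty-printed JSON.
#'
#' @param report The object to serialize (`structure_report`,
#'   `processing_report`, `phasing_table`, list, or data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- if (inherits(report, c("processing_report", "structure_report"))) {
    unclass(report)
  } else {
    report
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
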