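# Synthetic sRNA read-set generator. Stands in for deposited sequencing
# libraries so every metric has a testable ground truth: processing
# fidelity, strand bias and phasing are all dialled by the config and fully
# reproducible from the seed.

#' Simulation configuration
#'
#' @param seed Integer seed; identical seed + config gives identical reads.
#' @param depth Total read count to emit.
#' @param exact_fraction Probability that a duplex-derived read is the exact
#'   21-nt mature strand (default 0.95, the processing accuracy observed
#'   for shc-expressed amiRNAs against endogenous targets).
#' @param offset_distribution Named probabilities over 5'-end offsets for
#'   imprecisely processed reads; default symmetric triangular on
#'   `-4..4` excluding 0. Offsets are names, e.g. `"-2"`.
#' @param size_distribution Named probabilities over read lengths 19-24;
#'   default peaked at 21 nt with minor 20/22/24-nt mass (the 24-nt class
#'   emulates transgene-derived siRNAs).
#' @param guide_star_ratio Fraction of duplex reads drawn from the guide
#'   strand rather than the star strand (default 0.8).
#' @param strand_bias (+)-strand probability for [simulate_viral_sirnas()]
#'   (default 0.5, the dsRNA-replication-intermediate hypothesis).
#' @param phased_fraction Fraction of 21-nt target reads initiating in
#'   register 1 for [simulate_phased_reads()] (default 0: no phased
#'   secondary siRNAs, as observed for amiRNA targets).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       depth = 1e5,
                       exact_fraction = 0.95,
                       offset_distribution = NULL,
                       size_distribution = NULL,
                       guide_star_ratio = 0.8,
                       strand_bias = 0.5,
                       phased_fraction = 0) {
  if (is.null(offset_distribution)) {
    offs <- c(-4:-1, 1:4)
    w <- 5 - abs(offs)
    offset_distribution <- stats::setNames(w / sum(w), offs)
  }
  if (is.null(size_distribution)) {
    size_distribution <- c(
      `19` = 0.03, `20` = 0.10, `21` = 0.70, `22` = 0.10, `23` = 0.02, `24` = 0.05
    )
  }
  probs <- c(
    exact_fraction, guide_star_ratio, strand_bias, phased_fraction,
    offset_distribution, size_distribution
  )
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  for (d in list(offset_distribution, size_distribution)) {
    if (abs(sum(d) - 1) > 1e-9) abort("distributions must be normalized")
  }
  structure(
    list(
      seed = as.integer(seed), depth = as.integer(depth),
      exact_fraction = exact_fraction,
      offset_distribution = offset_distribution,
      size_distribution = size_distribution,
      guide_star_ratio = guide_star_ratio,
      strand_bias = strand_bias,
      phased_fraction = phased_fraction
    ),
    class = "sim_config"
  )
}

# multinomial read emission over a category table with columns start, len, prob
emit_reads <- function(ref_dna, categories, depth) {
  counts <- as.integer(stats::rmultinom(1, depth, categories$prob))
  keep <- counts > 0
  collapse_reads(tibble(
    sequence = substring(ref_dna, categories$start[keep], categories$start[keep] + categories$len[keep] - 1L),
    count = counts[keep]
  ))
}

#' Simulate reads from an amiRNA precursor
#'
#' Emits (+)-strand reads from the precursor: with probability
#' `exact_fraction` the exact 21-nt mature strand (guide or star per
#' `guide_star_ratio`), otherwise a read whose 5'-end offset and length are
#' drawn from the configured distributions, mirroring the non-uniform DCL
#' cleavage observed around real processing sites. Draws that would run
#' outside the precursor are redrawn from the remaining admissible
#' offset/length combinations (an error is raised if none exists).
#'
#' @param precursor An `amir_precursor`.
#' @param cfg A [sim_config()].
#' @return A collapsed read tibble (`sequence`, `count`) in DNA space, with
#'   the config stored in the `sim_config` attribute.
#' @export
simulate_precursor_reads <- function(precursor, cfg = sim_config()) {
  ref <- as_dna(precursor$sequence)
  n <- nchar(ref)
  sources <- tibble(
    start = c(precursor$guide_start, precursor$star_start),
    p_source = c(cfg$guide_star_ratio, 1 - cfg$guide_star_ratio)
  )
  cats <- purrr::pmap(sources, function(start, p_source) {
    exact <- tibble(start = start, len = 21L, prob = p_source * cfg$exact_fraction)
    inexact <- tidyr::expand_grid(
      offset = as.integer(names(cfg$offset_distribution)),
      len = as.integer(names(cfg$size_distribution))
    ) |>
      mutate(
        start = start + .data$offset,
        prob = p_source * (1 - cfg$exact_fraction) *
          cfg$offset_distribution[as.character(.data$offset)] *
          cfg$size_distribution[as.character(.data$len)]
      )
    valid <- inexact$start >= 1L & inexact$start + inexact$len - 1L <= n
    if (!all(valid)) {
      if (!any(valid)) {
        abort("no admissible offset/length combination fits inside the precursor")
      }
      lost <- sum(inexact$prob[!valid])
      inexact <- inexact[valid, ]
      inexact$prob <- inexact$prob * (sum(inexact$prob) + lost) / sum(inexact$prob)
    }
    dplyr::bind_rows(exact, inexact[, c("start", "len", "prob")])
  })
  categories <- dplyr::bind_rows(cats)
  out <- with_seed(cfg$seed, emit_reads(ref, categories, cfg$depth))
  attr(out, "sim_config") <- cfg
  out
}

#' Simulate virus-derived small RNAs along a genome
#'
#' Reads of lengths 19-24 are placed uniformly along the genome; each read
#' is assigned to the (+) strand with probability `strand_bias` (0.5
#' emulates dsRNA replication intermediates; values near 1 emulate
#' hairpin-derived populations).
#'
#' @param genome Genome nucleotide string (length >= 24).
#' @param cfg A [sim_config()].
#' @return A collapsed read tibble in DNA space.
#' @export
simulate_viral_sirnas <- function(genome, cfg = sim_config(depth = 1e4)) {
  ref <- as_dna(genome)
  n <- nchar(ref)
  if (n < 24) abort("genome must be at least 24 nt")
  out <- with_seed(cfg$seed, {
    lens <- as.integer(sample(names(cfg$size_distribution), cfg$depth,
      replace = TRUE, prob = cfg$size_distribution
    ))
    starts <- 1L + floor(stats::runif(cfg$depth) * (n - lens + 1L))
    plus <- stats::runif(cfg$depth) < cfg$strand_bias
    seqs <- substring(ref, starts, starts + lens - 1L)
    seqs[!plus] <- revcomp(seqs[!plus])
    collapse_reads(seqs)
  })
  attr(out, "sim_config") <- cfg
  out
}

#' Simulate phased and unphased 21-nt reads downstream of a cleavage site
#'
#' A `phased_fraction` of reads initiate at `cleavage_site + 1 + 21k`
#' (register 1); the remainder initiate uniformly at the downstream
#' positions.
#'
#' @param target Target nucleotide string.
#' @param cleavage_site 1-based coordinate of the last nucleotide 5' of the
#'   cut; must leave room for at least one 21-nt read downstream.
#' @param cfg A [sim_config()].
#' @return A collapsed read tibble in DNA space.
#' @export
simulate_phased_reads <- function(target, cleavage_site, cfg = sim_config(depth = 21000)) {
  ref <- as_dna(target)
  n <- nchar(ref)
  cleavage_site <- as.integer(cleavage_site)
  if (cleavage_site < 1L || cleavage_site > n - 21L) {
    abort(sprintf("cleavage_site must lie in [1, %d]", n - 21L))
  }
  first <- cleavage_site + 1L
  last <- n - 20L
  phased_starts <- seq.int(first, last, by = 21L)
  out <- with_seed(cfg$seed, {
    is_phased <- stats::runif(cfg$depth) < cfg$phased_fraction
    starts <- integer(cfg$depth)
    starts[is_phased] <- sample(rep(phased_starts, 2), sum(is_phased), replace = TRUE)
    starts[!is_phased] <- first + floor(stats::runif(sum(!is_phased)) * (last - first + 1L))
    collapse_reads(substring(ref, starts, starts + 20L))
  })
  attr(out, "sim_config") <- cfg
  out
}
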