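demo_precursor <- function() {
  build_precursor(guide_rna("UUAGCAGUACCGAUUCGAUCA", "amiR-sim"), "shc")
}

test_that("identical seed and config reproduce identical read sets", {
  p <- demo_precursor()
  cfg <- sim_config(seed = 7, depth = 5000)
  expect_identical(
    simulate_precursor_reads(p, cfg),
    simulate_precursor_reads(p, cfg)
  )
  genome <- random_dna(500)
  expect_identical(
    simulate_viral_sirnas(genome, sim_config(seed = 7, depth = 2000)),
    simulate_viral_sirnas(genome, sim_config(seed = 7, depth = 2000))
  )
  # a different seed gives a different draw
  expect_false(identical(
    simulate_precursor_reads(p, cfg),
    simulate_precursor_reads(p, sim_config(seed = 8, depth = 5000))
  ))
})

test_that("every simulated read is an exact substring of its declared source strand", {
  p <- demo_precursor()
  reads <- simulate_precursor_reads(p, sim_config(seed = 9, depth = 5000, exact_fraction = 0.8))
  prof <- map_exact(reads, p$sequence, strands = "plus")
  expect_equal(attr(prof, "total_mapped"), sum(reads$count))

  genome <- random_dna(600)
  vreads <- simulate_viral_sirnas(genome, sim_config(seed = 9, depth = 2000, strand_bias = 0.6))
  vprof <- map_exact(vreads, genome, strands = "both")
  expect_equal(attr(vprof, "total_mapped"), sum(vreads$count))
})

test_that("exact_fraction 1 yields perfect processing accuracy", {
  p <- demo_precursor()
  reads <- simulate_precursor_reads(p, sim_config(seed = 10, depth = 2000, exact_fraction = 1))
  rep <- processing_accuracy(map_exact(reads, p$sequence), p)
  expect_equal(rep$accuracy, 1.0)
})

test_that("simulated processing fidelity is recovered within the binomial bound", {
  p <- demo_precursor()
  for (pexp in c(0.9, 0.95)) {
    reads <- simulate_precursor_reads(
      p, sim_config(seed = 11, depth = 2e4, exact_fraction = pexp)
    )
    rep <- processing_accuracy(map_exact(reads, p$sequence), p)
    sigma <- sqrt(pexp * (1 - pexp) / rep$window_reads)
    expect_lt(abs(rep$accuracy - pexp), 3 * sigma)
  }
})

test_that("strand bias 1 gives pure (+) polarity and 0.5 is recovered", {
  genome <- random_dna(800)
  plus_only <- simulate_viral_sirnas(genome, sim_config(seed = 12, depth = 2000, strand_bias = 1))
  pol <- strand_polarity(plus_only, genome)
  expect_equal(pol$plus_fraction, 1.0)

  mixed <- simulate_viral_sirnas(genome, sim_config(seed = 13, depth = 1e4, strand_bias = 0.5))
  pol2 <- strand_polarity(mixed, genome)
  expect_lt(abs(pol2$plus_fraction - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("phased_fraction 1 puts all reads in register 1 and 0.5 matches the mixture expectation", {
  withr::with_seed(84, target <- random_dna(800))
  cs <- 150L
  phased <- simulate_phased_reads(target, cs, sim_config(seed = 14, depth = 3000, phased_fraction = 1))
  tab <- phasing_registers(phased, target, cs)
  expect_equal(tab$proportion[tab$register == 1], 1.0)

  half <- simulate_phased_reads(target, cs, sim_config(seed = 15, depth = 5e4, phased_fraction = 0.5))
  tab2 <- phasing_registers(half, target, cs)
  expected <- 0.5 + 0.5 / 21
  sigma <- sqrt(expected * (1 - expected) / 5e4)
  expect_lt(abs(tab2$proportion[tab2$register == 1] - expected), 3 * sigma)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(exact_fraction = 1.2), "\\[0, 1\\]")
  expect_error(
    sim_config(size_distribution = c(`21` = 0.5, `22` = 0.4)),
    "normalized"
  )
  expect_error(simulate_viral_sirnas("ACGT", sim_config()), "at least 24 nt")
  expect_error(
    simulate_phased_reads(random_dna(100), 95, sim_config()),
    "must lie in"
  )
})
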