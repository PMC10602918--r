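shc_fixture <- function(guide = "UUAGCAGUACCGAUUCGAUCA") {
  build_precursor(guide_rna(guide, "amiR-fix"), "shc")
}

test_that("processing accuracy on a hand-counted fixture is 8/10", {
  p <- shc_fixture()
  gs <- p$guide_start
  reads <- tibble::tibble(
    sequence = c(
      as_dna(p$guide), # exact 21-nt guide at gs
      as_dna(substr(p$sequence, gs - 1, gs + 20)) # 22-nt read at gs - 1
    ),
    count = c(8L, 2L)
  )
  rep <- processing_accuracy(map_exact(reads, p$sequence), p)
  expect_equal(rep$window_reads, 10)
  expect_equal(rep$exact_guide_reads, 8)
  expect_equal(rep$accuracy, 0.8)
  expect_equal(glance(rep)$accuracy, 0.8)
})

test_that("all-exact window reads give accuracy 1 and the window boundary excludes -5", {
  p <- shc_fixture()
  gs <- p$guide_start
  all_exact <- processing_accuracy(map_exact(as_dna(p$guide), p$sequence), p)
  expect_equal(all_exact$accuracy, 1.0)

  # a 21-nt (+) read with 5' end at gs - 5 contributes to neither term
  outside <- as_dna(substr(p$sequence, gs - 5, gs + 15))
  rep <- processing_accuracy(map_exact(c(as_dna(p$guide), outside), p$sequence), p)
  expect_equal(rep$window_reads, 1)
  expect_equal(rep$accuracy, 1.0)

  # at gs - 4 it enters the denominator only
  inside <- as_dna(substr(p$sequence, gs - 4, gs + 16))
  rep2 <- processing_accuracy(map_exact(c(as_dna(p$guide), inside), p$sequence), p)
  expect_equal(rep2$window_reads, 2)
  expect_equal(rep2$accuracy, 0.5)
})

test_that("accuracy is invariant under count rescaling and undefined on empty windows", {
  p <- shc_fixture()
  gs <- p$guide_start
  reads <- tibble::tibble(
    sequence = c(
      as_dna(p$guide),
      as_dna(substr(p$sequence, gs + 2, gs + 21)),
      as_dna(substr(p$sequence, gs - 3, gs + 19))
    ),
    count = c(17L, 2L, 5L)
  )
  acc1 <- processing_accuracy(map_exact(reads, p$sequence), p)$accuracy
  reads$count <- reads$count * 7L
  acc7 <- processing_accuracy(map_exact(reads, p$sequence), p)$accuracy
  expect_equal(acc1, acc7)

  empty <- processing_accuracy(map_exact("GGGGGGGGGGGGGGGGGGGG", p$sequence), p)
  expect_true(empty$undefined)
  expect_true(is.na(empty$accuracy))
})

test_that("strand polarity splits mapped counts by strand", {
  ref <- "ATTAGCAGTACCGATTCGATCACCGGTTAACCGGAAGGTTCC"
  fwd <- substr(ref, 3, 26)
  rev <- revcomp(substr(ref, 10, 33))
  eq <- strand_polarity(c(fwd, rev), ref)
  expect_equal(eq$plus_fraction, 0.5)
  expect_equal(eq$minus_fraction, 0.5)

  only_fwd <- strand_polarity(fwd, ref)
  expect_equal(only_fwd$plus_fraction, 1.0)
  expect_equal(only_fwd$minus_fraction, 0.0)

  none <- strand_polarity("GGGGGGGGCCCCAAAA", "ATATATATAT")
  expect_true(none$undefined)
  expect_true(is.na(none$plus_fraction))

  # a reverse-complement palindrome counts on both strands it hits
  pal <- strand_polarity("GAATTC", paste0("AAA", "GAATTC", "AAA"))
  expect_equal(pal$plus_fraction, 0.5)
  expect_equal(pal$plus_count + pal$minus_count, 2)
})

test_that("cleavage site sits opposite guide positions 10/11", {
  withr::with_seed(81, {
    g <- random_guide()
    offset <- 101
    target <- paste0(random_dna(offset - 1), as_dna(revcomp(unclass(g))), random_dna(80))
    # guard against accidental second sites in the random context
    site <- tryCatch(locate_cleavage_site(target, g), error = function(e) NA)
    expect_equal(site, offset + 10)

    expect_error(locate_cleavage_site(random_dna(60), g), "0 perfectly complementary")
    two <- paste0(random_dna(20), as_dna(revcomp(unclass(g))), random_dna(20),
                  as_dna(revcomp(unclass(g))), random_dna(20))
    expect_error(locate_cleavage_site(two, g), "2")
  })
})

test_that("phasing registers follow the 21-nt cycle downstream of the cut", {
  withr::with_seed(82, {
    target <- random_dna(400)
    cs <- 100L
    r1 <- substr(target, cs + 1, cs + 21)
    tab <- phasing_registers(r1, target, cs)
    expect_equal(tab$proportion[tab$register == 1], 1.0)
    expect_equal(attr(tab, "n_reads"), 1)

    # a read one full cycle downstream lands in register 1 as well
    r2 <- substr(target, cs + 22, cs + 42)
    tab2 <- phasing_registers(c(r1, r2), target, cs)
    expect_equal(tab2$proportion[tab2$register == 1], 1.0)

    # register 2 read, and proportions always sum to 1
    r3 <- substr(target, cs + 2, cs + 22)
    tab3 <- phasing_registers(c(r1, r1, r3), target, cs)
    expect_equal(tab3$proportion[tab3$register == 1], 2 / 3)
    expect_equal(tab3$proportion[tab3$register == 2], 1 / 3)
    expect_equal(sum(tab3$proportion), 1)

    # reads at or upstream of the cut are excluded
    up <- substr(target, cs - 10, cs + 10)
    tab4 <- phasing_registers(c(r1, up), target, cs)
    expect_equal(attr(tab4, "n_reads"), 1)

    # empty table is flagged, all-zero
    tab5 <- phasing_registers("GGGGGGGGGGGGGGGGGGGGG", target, cs)
    expect_true(attr(tab5, "empty"))
    expect_equal(sum(tab5$proportion), 0)

    expect_error(phasing_registers(r1, target, 395), "must lie in")
  })
})
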