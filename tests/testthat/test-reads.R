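test_that("collapsing sums counts per distinct sequence and orders the result", {
  out <- collapse_reads(c("AAA", "AAA", "CCC"))
  expect_equal(out$sequence, c("AAA", "CCC"))
  expect_equal(out$count, c(2L, 1L))

  distinct <- collapse_reads(c("ACG", "CGT", "GTA"))
  expect_equal(distinct$count, rep(1L, 3))

  # expanding a collapsed set and re-collapsing is idempotent
  expanded <- rep(out$sequence, out$count)
  expect_equal(collapse_reads(expanded), out, ignore_attr = TRUE)

  # U reads are normalized into DNA space
  expect_equal(collapse_reads("ACGU")$sequence, "ACGT")
})

test_that("non-nucleotide records are rejected with their count reported", {
  expect_message(
    out <- collapse_reads(c("ACGT", "ACNT", "ACNT")),
    "rejected 2 read"
  )
  expect_equal(out$sequence, "ACGT")
  expect_equal(attr(out, "n_rejected"), 2)
})

test_that("exact mapping records every occurrence but counts each read once in the total", {
  # read equal to the reference: single (+) hit at position 1
  prof <- map_exact("ACGTACG", "ACGTACG")
  expect_equal(prof$position, 1)
  expect_equal(prof$strand, "+")
  expect_equal(attr(prof, "total_mapped"), 1)

  # a read occurring twice with count 5: two hits of 5, total_mapped 5
  prof2 <- map_exact(
    tibble::tibble(sequence = "ACGT", count = 5L),
    paste0("ACGT", "TTTT", "ACGT")
  )
  expect_equal(nrow(prof2), 2)
  expect_equal(prof2$count, c(5L, 5L))
  expect_equal(attr(prof2, "total_mapped"), 5)
  # multi-position hits inflate the per-position RPM column by design
  expect_equal(prof2$rpm, c(1e6, 1e6))

  # overlapping occurrences are all found
  prof3 <- map_exact("AAA", "AAAAA")
  expect_equal(prof3$position, 1:3)
})

test_that("minus-strand hits record the read 5' end in reference coordinates", {
  # revcomp("TTTACGT") = "ACGTAAA"; reference carries that at 3..9
  prof <- map_exact("TTTACGT", paste0("GG", "ACGTAAA", "CC"), strands = "both")
  expect_equal(prof$strand, "-")
  expect_equal(prof$position, 9) # rightmost coordinate of the match
})

test_that("exact mapping agrees with the sliding-window oracle on random instances", {
  withr::with_seed(71, {
    for (i in 1:60) {
      ref <- random_dna(sample(30:200, 1))
      reads <- tibble::tibble(
        sequence = c(
          # embedded substrings (guaranteed hits)
          vapply(1:3, function(j) {
            L <- sample(5:24, 1)
            s <- sample(nchar(ref) - L, 1)
            substr(ref, s, s + L - 1)
          }, character(1)),
          # random reads (mostly misses)
          vapply(1:3, function(j) random_dna(sample(5:24, 1)), character(1))
        ),
        count = sample(1:50, 6, replace = TRUE)
      )
      strands <- sample(c("plus", "both"), 1)
      got <- map_exact(reads, ref, strands = strands)
      want <- oracle_map(reads, ref, strands = strands)
      expect_equal(as.data.frame(got[, 1:4]), as.data.frame(want$profile), ignore_attr = TRUE)
      expect_equal(attr(got, "total_mapped"), want$total_mapped)
    }
  })
})

test_that("RPM sums to one million on profiles without multi-position reads", {
  withr::with_seed(72, {
    for (i in 1:20) {
      ref <- random_dna(150)
      reads <- tibble::tibble(
        sequence = vapply(1:10, function(j) {
          L <- sample(19:24, 1)
          s <- sample(nchar(ref) - L, 1)
          substr(ref, s, s + L - 1)
        }, character(1)),
        count = sample(1:100, 10, replace = TRUE)
      )
      prof <- map_exact(reads, ref)
      multi <- any(table(prof$position, prof$length) > 1)
      if (!multi && sum(prof$count) == attr(prof, "total_mapped")) {
        expect_equal(sum(prof$rpm), 1e6, tolerance = 1e-12)
      }
    }
  })
})

test_that("rpm_normalize handles the 1/3 split and the empty profile", {
  ref <- paste0("AAAATTTT", "GGGGCCCC")
  prof <- map_exact(
    tibble::tibble(sequence = c("AAAATTTT", "GGGGCCCC"), count = c(1L, 3L)), ref
  )
  expect_equal(sort(prof$rpm), c(250000, 750000))

  empty <- map_exact("TTTTTTTTAC", "GGGG")
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "empty"))
  expect_equal(attr(empty, "total_mapped"), 0)
})
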