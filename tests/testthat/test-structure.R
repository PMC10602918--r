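test_that("every registry backbone folds with zero layout violations for random guides", {
  withr::with_seed(51, {
    for (nm in list_backbones()) {
      for (i in 1:5) {
        p <- suppressWarnings(build_precursor(random_guide(), nm))
        rep <- pair_by_layout(p)
        expect_equal(nrow(rep$violations), 0)
        expect_equal(nchar(rep$dotbracket), nchar(p$sequence))
        expect_true(brackets_balanced(rep$dotbracket))
      }
    }
  })
})

test_that("basal stem of pri and shc sits in the 15-17 bp band and loops are unpaired", {
  for (nm in c("pri", "shc")) {
    p <- build_precursor(guide_rna("UUAGCAGUACCGAUUCGAUCA"), nm)
    rep <- pair_by_layout(p)
    expect_gte(rep$basal_stem_bp, 15)
    expect_lte(rep$basal_stem_bp, 17)
    expect_gte(rep$loop_length, 3)
    loop <- dplyr::filter(p$segment_map, role == "loop")
    loop_db <- substr(rep$dotbracket, loop$start, loop$end)
    expect_equal(loop_db, strrep(".", nchar(loop_db)))
  }
})

test_that("a mutated base is reported at exactly its facing position", {
  g <- guide_rna("UUAGCAGUACCGAUUCGAUCA")
  p <- build_precursor(g, "shc")
  # mutate guide position 5 (C) to A; its partner is star position 15,
  # carrying G, and A:G never pairs
  mutated <- p
  substr(mutated$sequence, p$guide_start + 4, p$guide_start + 4) <- "A"
  rep <- pair_by_layout(mutated)
  expect_equal(nrow(rep$violations), 1)
  expect_equal(rep$violations$pos5, p$guide_start + 4)
  expect_equal(rep$violations$pos3, p$star_start + 14)
})

test_that("pair_by_layout requires a complete segment map", {
  p <- build_precursor(guide_rna("UUAGCAGUACCGAUUCGAUCA"), "shc")
  p$segment_map <- dplyr::filter(p$segment_map, role != "loop")
  expect_error(pair_by_layout(p), "missing roles")
})

test_that("base-pair maximization matches exhaustive enumeration on short sequences", {
  expect_equal(attr(fold_nussinov("GGGAAACCC"), "n_pairs"), oracle_max_pairs("GGGAAACCC"))
  expect_equal(attr(fold_nussinov("GGGAAACCC"), "n_pairs"), 3L)
  expect_equal(attr(fold_nussinov(strrep("A", 12)), "n_pairs"), 0L)
  # palindromic stems close completely over a 3-nt loop
  expect_equal(attr(fold_nussinov("GGGGCAAAGCCCC"), "n_pairs"), 5L)

  withr::with_seed(52, {
    for (i in 1:40) {
      n <- sample(5:12, 1)
      s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
      db <- fold_nussinov(s)
      expect_equal(attr(db, "n_pairs"), oracle_max_pairs(s), info = s)
      expect_equal(nchar(db), n)
      expect_true(brackets_balanced(db))
      # the traceback structure realizes the claimed pair count
      expect_equal(sum(strsplit(db, "")[[1]] == "("), attr(db, "n_pairs"))
    }
  })
})

test_that("the layout-declared hairpin is attainable by unconstrained folding", {
  # pair-count comparison only: the free fold must find at least as many
  # pairs as the declared layout
  p <- build_precursor(guide_rna("UUAGCAGUACCGAUUCGAUCA"), "shc")
  rep <- pair_by_layout(p)
  declared <- rep$basal_stem_bp + rep$duplex_paired + rep$dsl_stem_bp
  free <- attr(fold_nussinov(p$sequence), "n_pairs")
  expect_gte(free, declared)
})
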