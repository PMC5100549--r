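test_that("read_toxins parses FASTA with metadata tags and preserves order", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">AC1 species=Dendroaspis_polylepis subfamily=3FTx",
    strrep("ACDEFGHIKLMNPQRSTVWY", 3),
    ">AC2",
    paste0(strrep("ACDEF", 12), "G")
  ), fa)
  tox <- read_toxins(fa)
  expect_equal(tox$accession, c("AC1", "AC2"))
  expect_equal(tox$length, c(60L, 61L))
  expect_equal(tox$species[1], "Dendroaspis polylepis")
  expect_equal(tox$subfamily[1], "3FTx")
  expect_true(is.na(tox$species[2]))
})

test_that("read_toxins rejects illegal residues naming the accession", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">GOOD", "ACDEFGHIKLMN", ">BADX", "ACDEFGXHIKLM"), fa)
  expect_error(read_toxins(fa), "BADX")
  writeLines(c(">DUP", "ACDEFGHIKLMN", ">DUP", "ACDEFGHIKLMN"), fa)
  expect_error(read_toxins(fa), "duplicate")
})

test_that("read_toxins strips gaps only in ungap mode", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A1", "ACD-EFGHIKLMN"), fa)
  expect_error(read_toxins(fa), "illegal residue")
  expect_equal(read_toxins(fa, ungap = TRUE)$sequence, "ACDEFGHIKLMN")
})

test_that("tile_sequence follows the step-2 grid", {
  t1 <- tile_sequence(strrep("A", 12))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$start, 1L)
  expect_equal(t1$peptide, strrep("A", 12))

  t2 <- tile_sequence("ACDEFGHIKLMNPQ")
  expect_equal(t2$start, c(1L, 3L))
  expect_equal(t2$peptide, c("ACDEFGHIKLMN", "DEFGHIKLMNPQ"))

  # length 13: plain grid stops at start 1 and misses residue 13;
  # the terminal window at start 2 restores full coverage
  s13 <- "ACDEFGHIKLMNP"
  expect_equal(tile_sequence(s13)$start, 1L)
  t13 <- tile_sequence(s13, force_terminal = TRUE)
  expect_equal(t13$start, c(1L, 2L))
  covered <- sort(unique(unlist(lapply(t13$start, function(s) s:(s + 11)))))
  expect_equal(covered, 1:13)
})

test_that("short sequences yield zero tiles with a warning", {
  expect_warning(out <- tile_sequence("ACDEFG"), "shorter than")
  expect_equal(nrow(out), 0L)
})

test_that("terminal-forced tiling covers every residue (brute force)", {
  set.seed(42)
  for (L in sample(12:120, 25)) {
    s <- paste(sample(c("C", "D", "E", "F"), L, replace = TRUE),
               collapse = "")
    tl <- tile_sequence(s, force_terminal = TRUE)
    covered <- logical(L)
    for (i in seq_len(nrow(tl))) {
      covered[tl$start[i]:(tl$start[i] + 11L)] <- TRUE
    }
    expect_true(all(covered), label = paste("coverage at length", L))
  }
})

test_that("build_unique_set pools duplicates and counts redundancy", {
  dup <- tibble::tibble(
    accession = c("A1", "A2"),
    sequence = c("ACDEFGHIKLMN", "ACDEFGHIKLMN")
  )
  u <- build_unique_set(tile_toxins(dup))
  expect_equal(nrow(u$peptides), 1L)
  expect_equal(nrow(u$occurrences), 2L)
  expect_equal(u$redundancy_count, 1L)

  # enumerated by hand: 2 + 2 tiles, all distinct
  two <- tibble::tibble(
    accession = c("B1", "B2"),
    sequence = c("ACDEFGHIKLMNPQ", "CDEFGHIKLMNPQR")
  )
  u2 <- build_unique_set(tile_toxins(two))
  expect_equal(nrow(u2$peptides), 4L)
  expect_equal(u2$redundancy_count, 0L)
})

test_that("build_unique_set is idempotent on already-unique tiles", {
  tiles <- tile_toxins(fixture_toxins()[1:2, ])
  u1 <- build_unique_set(tiles)
  uniq_tiles <- dplyr::distinct(tiles, peptide, .keep_all = TRUE)
  u2 <- build_unique_set(uniq_tiles)
  expect_equal(u2$redundancy_count, 0L)
  expect_equal(sort(u2$peptides$peptide), sort(u1$peptides$peptide))
})

test_that("occurrence spans reconstruct each toxin sequence", {
  tox <- fixture_toxins()
  lib <- design_library(tox, seed = 3)
  for (acc in tox$accession) {
    occ <- dplyr::filter(lib$occurrences, accession == acc)
    L <- nchar(tox$sequence[tox$accession == acc])
    rebuilt <- rep(NA_character_, L)
    for (i in seq_len(nrow(occ))) {
      chars <- strsplit(occ$peptide[i], "")[[1]]
      idx <- occ$start[i]:(occ$start[i] + 11L)
      rebuilt[idx] <- chars
    }
    covered <- !is.na(rebuilt)
    expect_equal(paste(rebuilt[covered], collapse = ""),
                 paste(strsplit(tox$sequence[tox$accession == acc],
                                "")[[1]][covered], collapse = ""))
  }
})

test_that("alanine_variants substitutes every non-alanine position once", {
  expect_equal(nrow(alanine_variants(strrep("A", 12))), 0L)

  one <- alanine_variants(paste0("C", strrep("A", 11)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$peptide, strrep("A", 12))
  expect_equal(one$position, 1L)

  v <- alanine_variants("ACDEFGHIKLMN")
  expect_equal(nrow(v), 11L)  # position 1 is already A
  expect_false(1L %in% v$position)
  for (i in seq_len(nrow(v))) {
    expect_equal(substring(v$peptide[i], v$position[i], v$position[i]), "A")
    diff <- which(strsplit(v$peptide[i], "")[[1]] !=
                    strsplit(v$parent[i], "")[[1]])
    expect_equal(diff, v$position[i])
  }
})

test_that("variant deduplication keeps provenance and collision modes differ", {
  # two parents one substitution apart generate a shared variant
  wt <- c("CCDEFGHIKLMN", "ACDEFGHIKLMN")
  v <- alanine_variants(wt)
  shared <- v[v$peptide == "ACDEFGHIKLMN" |
                (v$parent == "CCDEFGHIKLMN" & v$position == 1L), ]
  expect_true(any(v$parent == "CCDEFGHIKLMN" & v$position == 1L))
  # that variant collides with wt "ACDEFGHIKLMN"
  expect_true("ACDEFGHIKLMN" %in% v$peptide)
  vd <- alanine_variants(wt, drop_wt_collisions = TRUE)
  expect_false("ACDEFGHIKLMN" %in% vd$peptide)
})

test_that("assemble_layout replicates, permutes, and is seed-reproducible", {
  wt <- c("ACDEFGHIKLMN", "CDEFGHIKLMNP")
  va <- c("AADEFGHIKLMN", "ACDAFGHIKLMN", "CDEFGHIKLMNA")
  lay <- assemble_layout(wt, va, seed = 11)
  expect_equal(nrow(lay), 5L * 2L + 3L)
  expect_equal(sort(lay$spot_index), 0:(nrow(lay) - 1L))
  expect_equal(sum(lay$class == "wt"), 10L)

  expect_identical(lay, assemble_layout(wt, va, seed = 11))
  lay2 <- assemble_layout(wt, va, seed = 12)
  expect_false(identical(lay$peptide, lay2$peptide))
  expect_identical(sort(paste(lay$peptide, lay$replicate)),
                   sort(paste(lay2$peptide, lay2$replicate)))
  expect_error(assemble_layout(wt, va, replicates_wt = 0), ">= 1")
})

test_that("design_library spot count identity 5U + V holds", {
  for (seed in 1:3) {
    tox <- synthetic_toxins(6, c(20, 50), seed = seed)
    lib <- suppressWarnings(design_library(tox, seed = seed))
    g <- glance(lib)
    expect_equal(g$n_spots, 5L * g$n_wt + g$n_variants)
    expect_equal(g$n_unique_peptides, g$n_wt + g$n_variants)
  }
})

test_that("library RNG use does not disturb the caller's random stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(design_library(fixture_toxins(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("study metadata table matches the published inventory", {
  meta <- study_toxins()
  expect_equal(nrow(meta), 82L)
  expect_equal(length(unique(meta$accession)), 82L)
  genus <- sub(" .*", "", meta$species)
  expect_equal(sum(genus == "Dendroaspis"), 61L)
  expect_equal(sum(genus == "Naja"), 21L)
  expect_true(all(meta$length >= 30L & meta$length <= 86L))
})

test_that("validate_study_sequences flags length and accession mismatches", {
  meta <- study_toxins()[1:2, ]
  good <- tibble::tibble(
    accession = meta$accession,
    sequence = vapply(meta$length, function(L) strrep("C", L), character(1)),
    length = meta$length
  )
  expect_invisible(validate_study_sequences(good, meta))
  bad <- good
  bad$length[1] <- bad$length[1] + 1L
  expect_error(validate_study_sequences(bad, meta), "length")
  expect_error(validate_study_sequences(good[1, ], meta), "missing")
})
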