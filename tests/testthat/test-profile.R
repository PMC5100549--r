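med_table <- function(peptides, medians, class = "wt") {
  tibble::tibble(peptide = peptides, class = class, median = medians,
                 sd = 0, n = 5L)
}

test_that("binding profile places one point per occurrence at tile starts", {
  tox <- tibble::tibble(accession = "T14", sequence = "ACDEFGHIKLMNPQ")
  tiles <- tile_toxins(tox)
  meds <- med_table(tiles$peptide, c(100, 240))
  prof <- binding_profile("T14", tiles, meds)
  expect_equal(prof$start, c(1L, 3L))
  expect_equal(prof$median, c(100, 240))
  expect_error(binding_profile("NOPE", tiles, meds), "NOPE")
})

test_that("a tile shared by homologs appears in both binding profiles", {
  tox <- tibble::tibble(
    accession = c("H1", "H2"),
    sequence = c("ACDEFGHIKLMNPQ", "WYACDEFGHIKLMNPQ")
  )
  lib <- design_library(tox, seed = 1)
  shared <- "ACDEFGHIKLMN"   # start 1 in H1, start 3 in H2
  meds <- med_table(lib$wt$peptide, seq(100, by = 10,
                                        length.out = nrow(lib$wt)))
  p1 <- binding_profile("H1", lib$occurrences, meds)
  p2 <- binding_profile("H2", lib$occurrences, meds)
  expect_true(shared %in% p1$peptide)
  expect_true(shared %in% p2$peptide)
  m <- meds$median[meds$peptide == shared]
  expect_equal(p1$median[p1$peptide == shared], m)
  expect_equal(p2$median[p2$peptide == shared], m)
})

test_that("residue scores average the medians of spanning tiles", {
  tox <- tibble::tibble(accession = "T14", sequence = "ACDEFGHIKLMNPQ")
  tiles <- tile_toxins(tox)
  m1 <- 100
  m2 <- 240
  meds <- med_table(tiles$peptide, c(m1, m2))
  sc <- residue_scores(tox, tiles, meds)
  expect_equal(sc$residue_score[1:2], rep(m1, 2))        # only tile 1
  expect_equal(sc$residue_score[3:12], rep((m1 + m2) / 2, 10))
  expect_equal(sc$residue_score[13:14], rep(m2, 2))      # only tile 2
  expect_equal(sc$coverage_wt, c(1L, 1L, rep(2L, 10L), 1L, 1L))
})

test_that("residue scores equal the brute-force oracle on random instances", {
  for (seed in 1:5) {
    tox <- synthetic_toxins(3, c(12, 40), seed = seed)
    tiles <- tile_toxins(tox)
    peps <- unique(tiles$peptide)
    set.seed(seed)
    meds <- med_table(peps, stats::runif(length(peps), 10, 500))
    sc <- residue_scores(tox, tiles, meds)
    for (acc in tox$accession) {
      occ <- dplyr::filter(tiles, accession == acc)
      want <- oracle_residue_score(
        tox$sequence[tox$accession == acc], occ$start,
        meds$median[match(occ$peptide, meds$peptide)]
      )
      got <- dplyr::filter(sc, accession == acc)
      expect_equal(got$residue_score, want$score)
      expect_equal(got$coverage_wt, want$coverage)
    }
  }
})

test_that("residue scores stay within the range of covering medians", {
  tox <- synthetic_toxins(2, c(20, 40), seed = 9)
  tiles <- tile_toxins(tox)
  peps <- unique(tiles$peptide)
  set.seed(9)
  meds <- med_table(peps, stats::runif(length(peps), 5, 900))
  sc <- residue_scores(tox, tiles, meds)
  covered <- dplyr::filter(sc, coverage_wt > 0)
  expect_true(all(covered$residue_score >= min(meds$median) - 1e-9))
  expect_true(all(covered$residue_score <= max(meds$median) + 1e-9))
})

test_that("alanine effects follow the log2 variant/wt convention", {
  # one toxin of exactly 12 residues: a single wt tile, fully a binder
  tox <- tibble::tibble(accession = "T12", sequence = "CDEFGHIKLMNP")
  lib <- design_library(tox, seed = 1)
  wt_pep <- "CDEFGHIKLMNP"
  var5 <- paste0("CDEF", "A", "HIKLMNP")  # position 5 (G -> A)
  meds <- dplyr::bind_rows(
    med_table(wt_pep, 400),
    med_table(lib$variants$peptide,
              ifelse(lib$variants$peptide == var5, 50, 400), class = "ala")
  )
  eff <- alanine_effects(tox, lib$occurrences, meds, binders = wt_pep)
  expect_equal(eff$ala_effect[eff$residue == 5], log2(50 / 400))  # -3
  expect_equal(eff$ala_effect[eff$residue == 1], 0, tolerance = 1e-12)
  others <- dplyr::filter(eff, !residue %in% c(5))
  expect_true(all(abs(others$ala_effect) < 1e-12))
  expect_true(all(eff$coverage_binder == 1L))
})

test_that("effects average over covering binder tiles; non-covered are NA", {
  # 14-residue toxin, two tiles, only the first is a binder
  tox <- tibble::tibble(accession = "T14", sequence = "CDEFGHIKLMNPQR")
  lib <- design_library(tox, seed = 1)
  tiles <- tile_sequence(tox$sequence)
  p1 <- tiles$peptide[1]
  p2 <- tiles$peptide[2]
  vars <- lib$variants
  meds <- dplyr::bind_rows(
    med_table(c(p1, p2), c(400, 400)),
    med_table(vars$peptide, 400, class = "ala")
  )
  # substituting residue 4 (offset 4 in p1) halves the signal
  v <- vars$peptide[vars$parent == p1 & vars$position == 4]
  meds$median[meds$peptide == v & meds$class == "ala"] <- 200
  eff <- alanine_effects(tox, lib$occurrences, meds, binders = p1)
  expect_equal(eff$ala_effect[eff$residue == 4], -1)
  # residues 13-14 are covered only by the non-binder tile -> NA
  expect_true(all(is.na(eff$ala_effect[eff$residue %in% 13:14])))
  expect_equal(eff$coverage_binder[eff$residue == 13], 0L)
  # two covering binder tiles: residue 5 sits at offset 5 of p1 and
  # offset 3 of p2; effects -3 and -1 average to -2
  v1 <- vars$peptide[vars$parent == p1 & vars$position == 5]
  v2 <- vars$peptide[vars$parent == p2 & vars$position == 3]
  meds2 <- meds
  meds2$median[meds2$peptide == v1 & meds2$class == "ala"] <- 50   # -3 vs 400
  meds2$median[meds2$peptide == v2 & meds2$class == "ala"] <- 200  # -1 vs 400
  eff2 <- alanine_effects(tox, lib$occurrences, meds2,
                          binders = c(p1, p2))
  expect_equal(eff2$ala_effect[eff2$residue == 5], mean(c(-3, -1)))
})

test_that("medians at or below zero are floored with a warning", {
  tox <- tibble::tibble(accession = "T12", sequence = "CDEFGHIKLMNP")
  lib <- design_library(tox, seed = 1)
  meds <- dplyr::bind_rows(
    med_table("CDEFGHIKLMNP", 400),
    med_table(lib$variants$peptide, 0, class = "ala")
  )
  expect_warning(
    eff <- alanine_effects(tox, lib$occurrences, meds,
                           binders = "CDEFGHIKLMNP", epsilon = 1),
    "floored"
  )
  expect_equal(eff$ala_effect[eff$residue == 2], log2(1 / 400))
})

test_that("null pattern matches classifier output on synthetic data", {
  tox <- synthetic_toxins(5, c(24, 40), seed = 31)
  lib <- design_library(tox, seed = 31)
  noise <- noise_model(50, 8, 4)
  epi <- plant_epitopes(lib, n_epitopes = 2, amplitude = 400, seed = 31)
  sig <- simulate_experiment(lib, epi, noise, seed = 31)
  meds <- replicate_median(sig)
  model <- estimate_background(meds)
  binders <- classify_binders(meds, model)
  eff <- alanine_effects(tox, lib$occurrences, meds, binders)
  cov <- dplyr::filter(eff, coverage_binder > 0)
  uncov <- dplyr::filter(eff, coverage_binder == 0)
  expect_true(all(!is.na(cov$ala_effect)))
  expect_true(all(is.na(uncov$ala_effect)))
  # every covered residue lies within a binder tile span
  bset <- binder_set(binders)
  spans <- dplyr::filter(lib$occurrences, peptide %in% bset)
  for (acc in unique(cov$accession)) {
    s <- dplyr::filter(spans, accession == acc)
    res <- dplyr::filter(cov, accession == acc)$residue
    in_span <- vapply(res, function(i) {
      any(i >= s$start & i <= s$start + 11L)
    }, logical(1))
    expect_true(all(in_span))
  }
})

test_that("alignment projection is lossless and gap-aware", {
  tox <- tibble::tibble(accession = c("X1", "X2"),
                        sequence = c("ACDEF", "ACEF"))
  aln <- tibble::tibble(accession = c("X1", "X2"),
                        aligned = c("ACDEF", "AC-EF"))
  vals <- tibble::tibble(
    accession = rep(c("X1", "X2"), c(5, 4)),
    residue = c(1:5, 1:4),
    value = c(10, 20, 30, 40, 50, 1, 2, 3, 4)
  )
  proj <- project_onto_alignment(vals, aln, toxins = tox)
  x2 <- dplyr::filter(proj, accession == "X2")
  expect_true(is.na(x2$value[x2$column == 3]))
  expect_true(is.na(x2$residue[x2$column == 3]))
  # round trip: drop gap cells and recover the input values
  back <- dplyr::filter(proj, !is.na(residue))
  expect_equal(
    dplyr::arrange(dplyr::select(back, accession, residue, value),
                   accession, residue),
    dplyr::arrange(vals, accession, residue)
  )
  # ungapped alignment projects to the input
  aln0 <- tibble::tibble(accession = "X1", aligned = "ACDEF")
  p0 <- project_onto_alignment(vals[1:5, ], aln0)
  expect_equal(p0$value, vals$value[1:5])

  bad <- tibble::tibble(accession = "X2", aligned = "AC-EG")
  expect_error(project_onto_alignment(vals, bad, toxins = tox), "X2")
})

test_that("random alignments round-trip per-residue values", {
  set.seed(17)
  for (rep in 1:5) {
    L <- sample(8:20, 1)
    seqchars <- sample(c("C", "D", "E", "F"), L, replace = TRUE)
    ngap <- sample(0:4, 1)
    pos <- sort(sample(L + ngap, ngap))
    aligned <- character(L + ngap)
    aligned[pos] <- "-"
    aligned[setdiff(seq_len(L + ngap), pos)] <- seqchars
    tox <- tibble::tibble(accession = "R1",
                          sequence = paste(seqchars, collapse = ""))
    aln <- tibble::tibble(accession = "R1",
                          aligned = paste(aligned, collapse = ""))
    vals <- tibble::tibble(accession = "R1", residue = seq_len(L),
                          value = stats::rnorm(L))
    proj <- project_onto_alignment(vals, aln, toxins = tox)
    back <- dplyr::filter(proj, !is.na(residue))
    expect_equal(back$value, vals$value)
    expect_equal(back$residue, vals$residue)
  }
})
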