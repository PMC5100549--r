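#' Generate random antigen sequences
#'
#' Produces a set of synthetic "toxins": uniform-random amino-acid
#' sequences with lengths drawn from `length_range`. Used to exercise the
#' full design/classify/profile pipeline against a known truth.
#'
#' @param n Number of sequences.
#' @param length_range Inclusive range of sequence lengths.
#' @param seed Integer seed.
#' @return A tibble shaped like [read_toxins()] output.
#' @export
synthetic_toxins <- function(n = 30L, length_range = c(30L, 80L), seed = 1L) {
  with_local_seed(seed, {
    lens <- sample(seq.int(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    tibble(
      accession = sprintf("SYN%03d", seq_len(n)),
      species = "synthetic",
      subfamily = NA_character_,
      sub_subfamily = NA_character_,
      is_fragment = FALSE,
      sequence = seqs,
      length = nchar(seqs)
    )
  })
}

#' Noise model for simulated experiments
#'
#' Parameters of the synthetic signal model, all in the arbitrary
#' fluorescence units (AU) of the scanner. `background_mean` and
#' `background_sd` describe the near-normal population of peptide-level
#' baselines arising from unspecific binding and auto-fluorescence — every
#' peptide (wild-type or variant) draws one baseline offset per experiment.
#' `replicate_sd` is the spot-to-spot noise among replicates of one
#' peptide. Intensities are clipped at `floor` (fluorescence is
#' non-negative).
#'
#' @param background_mean,background_sd Mean and SD of the peptide baseline
#'   population (AU).
#' @param replicate_sd Spot noise SD (AU).
#' @param floor Lower clip for generated intensities.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(background_mean = 50, background_sd = 8,
                        replicate_sd = 8, floor = 0) {
  stopifnot(background_sd >= 0, replicate_sd >= 0)
  structure(
    list(background_mean = background_mean, background_sd = background_sd,
         replicate_sd = replicate_sd, floor = floor),
    class = "noise_model"
  )
}

#' Plant linear epitopes in synthetic antigens
#'
#' Chooses `n_epitopes` distinct antigens and places one epitope core in
#' each: a contiguous stretch of `core_length` residues (linear epitope
#' elements are typically 7-9 residues) positioned inside one of the
#' antigen's actual tiling windows, so that at least one library peptide
#' fully contains it. A random subset of core positions is marked as key
#' residues: substituting one of these with alanine multiplies the epitope
#' signal amplitude by `knockdown`.
#'
#' @param library A `peptide_library` over the synthetic antigens.
#' @param n_epitopes Number of antigens to receive an epitope.
#' @param core_length Candidate core lengths, sampled per epitope.
#' @param n_key Number of key residues per core.
#' @param amplitude Signal added above baseline for peptides containing
#'   the core (AU). Default is 20 background SDs of [noise_model()]'s
#'   default background.
#' @param knockdown Multiplier in `[0, 1)` applied to `amplitude` when a
#'   key residue is substituted.
#' @param seed Integer seed.
#' @return A tibble with columns `accession`, `core_start`, `core_end`,
#'   `key_positions` (list column of integer vectors), `amplitude`,
#'   `knockdown`.
#' @export
plant_epitopes <- function(library, n_epitopes = 10L, core_length = 7:9,
                           n_key = 2L, amplitude = 160, knockdown = 0.25,
                           seed = 1L) {
  occ <- library$occurrences
  k <- library$params$k
  accs <- unique(occ$accession)
  if (n_epitopes > length(accs)) {
    abort("more epitopes requested than antigens with tiles")
  }
  with_local_seed(seed, {
    chosen <- sample(accs, n_epitopes)
    rows <- purrr::map(chosen, function(acc) {
      starts <- filter(occ, .data$accession == acc)$start
      s <- if (length(starts) == 1L) starts else sample(starts, 1L)
      len <- if (length(core_length) == 1L) core_length else
        sample(core_length, 1L)
      len <- min(len, k)
      off <- sample.int(k - len + 1L, 1L) - 1L
      core_start <- s + off
      core_end <- core_start + len - 1L
      keys <- sort(sample(seq.int(core_start, core_end), min(n_key, len)))
      tibble(accession = acc, core_start = core_start, core_end = core_end,
             key_positions = list(as.integer(keys)),
             amplitude = amplitude, knockdown = knockdown)
    })
    bind_rows(rows)
  })
}

# Noise-free mean signal for every peptide in the layout.
# A wild-type peptide whose mapped span fully contains an epitope core is
# elevated by that epitope's amplitude; an alanine variant inherits the
# parent's elevation except that substituting a key residue multiplies the
# amplitude by the knockdown. Peptides qualifying through several
# occurrences or epitopes take the largest contribution.
expected_signal_table <- function(library, epitopes, noise = noise_model()) {
  k <- library$params$k
  wt_amp <- wt_amplitudes(library, epitopes, k)

  peptides <- distinct(library$layout, .data$peptide, .data$class)
  wt_part <- peptides |>
    filter(.data$class == "wt") |>
    left_join(wt_amp$by_peptide, by = "peptide") |>
    mutate(mean = noise$background_mean +
             dplyr::coalesce(.data$amp, 0))

  var_part <- peptides |> filter(.data$class == "ala")
  if (nrow(var_part) > 0L && nrow(wt_amp$by_occurrence) > 0L) {
    contrib <- library$variants |>
      inner_join(wt_amp$by_occurrence,
                 by = c(parent = "peptide"), relationship = "many-to-many") |>
      mutate(
        residue = .data$start + .data$position - 1L,
        hit_key = purrr::map2_lgl(.data$key_positions, .data$residue,
                                  function(kp, r) r %in% kp),
        amp_v = .data$amplitude * ifelse(.data$hit_key, .data$knockdown, 1)
      ) |>
      group_by(.data$peptide) |>
      summarise(amp = max(.data$amp_v), .groups = "drop")
    var_part <- var_part |>
      left_join(contrib, by = "peptide") |>
      mutate(mean = noise$background_mean + dplyr::coalesce(.data$amp, 0))
  } else {
    var_part <- mutate(var_part, amp = NA_real_,
                       mean = noise$background_mean)
  }
  bind_rows(select(wt_part, "peptide", "class", "mean"),
            select(var_part, "peptide", "class", "mean"))
}

# Per-occurrence and per-peptide amplitude of contained epitope cores.
wt_amplitudes <- function(library, epitopes, k) {
  by_occurrence <- library$occurrences |>
    inner_join(epitopes, by = "accession", relationship = "many-to-many") |>
    filter(.data$core_start >= .data$start,
           .data$core_end <= .data$start + k - 1L)
  by_peptide <- if (nrow(by_occurrence) == 0L) {
    tibble(peptide = character(), amp = numeric())
  } else {
    by_occurrence |>
      group_by(.data$peptide) |>
      summarise(amp = max(.data$amplitude), .groups = "drop")
  }
  list(by_occurrence = by_occurrence, by_peptide = by_peptide)
}

#' Noise-free expected signal of a peptide
#'
#' The deterministic mean of the generative model for one or more library
#' peptides: baseline mean plus the epitope amplitude for wild-type
#' peptides fully containing a planted core, with the amplitude knocked
#' down for alanine variants hitting a key residue.
#'
#' @param peptide Character vector of peptide sequences.
#' @param class Matching `"wt"`/`"ala"` class vector (recycled).
#' @param library,epitopes,noise Design, planted truth, [noise_model()].
#' @return Numeric vector of expected mean intensities (AU).
#' @export
expected_signal <- function(peptide, class, library, epitopes,
                            noise = noise_model()) {
  tab <- expected_signal_table(library, epitopes, noise)
  key <- paste(tab$peptide, tab$class)
  idx <- match(paste(peptide, class), key)
  if (anyNA(idx)) {
    abort(paste0("peptide not in library: ",
                 peptide[which(is.na(idx))[1]]))
  }
  tab$mean[idx]
}

#' Derive the expected analysis outcome of a planted design
#'
#' Computes, without any randomness, what a perfect analysis of the
#' simulated data should report: the set of wild-type binder peptides
#' (those with an occurrence fully containing an epitope core) and the
#' expected per-residue alanine-substitution effect — for a key residue,
#' `log2((knockdown * A + bg) / (A + bg))` with `A` the amplitude and `bg`
#' the baseline mean; zero for all other residues of epitope-bearing
#' antigens.
#'
#' @inheritParams expected_signal
#' @return A list of class `synthetic_truth` with `expected_binders`
#'   (character vector of peptide sequences) and `expected_effect` (tibble
#'   `accession`, `residue`, `effect`, `is_key`).
#' @export
derive_truth <- function(library, epitopes, noise = noise_model()) {
  k <- library$params$k
  lens <- tibble(accession = library$toxins$accession,
                 length = nchar(library$toxins$sequence))
  bad <- epitopes |>
    left_join(lens, by = "accession") |>
    filter(is.na(.data$length) | .data$core_start < 1L |
             .data$core_end > .data$length)
  if (nrow(bad) > 0L) {
    abort(paste0("epitope span out of range for accession ",
                 bad$accession[1]))
  }
  amp <- wt_amplitudes(library, epitopes, k)
  expected_binders <- unique(amp$by_peptide$peptide)
  bg <- noise$background_mean
  effect <- epitopes |>
    tidyr::unnest_longer("key_positions", values_to = "residue") |>
    mutate(effect = log2((.data$knockdown * .data$amplitude + bg) /
                           (.data$amplitude + bg)),
           is_key = TRUE) |>
    select("accession", "residue", "effect", "is_key")
  non_key <- epitopes |>
    left_join(lens, by = "accession") |>
    mutate(residue = purrr::map(.data$length, seq_len)) |>
    select("accession", "residue") |>
    tidyr::unnest_longer("residue") |>
    anti_join(effect, by = c("accession", "residue")) |>
    mutate(effect = 0, is_key = FALSE)
  structure(
    list(expected_binders = expected_binders,
         expected_effect = bind_rows(effect, non_key) |>
           arrange(.data$accession, .data$residue)),
    class = "synthetic_truth"
  )
}

#' Simulate one microarray experiment
#'
#' Draws intensities for every spot of the layout under the generative
#' model: each distinct peptide receives a baseline offset drawn from
#' `Normal(0, background_sd)` once per experiment (the near-normal
#' background population of unspecific binding), each spot then draws
#' `Normal(expected mean + offset, replicate_sd)`, and the result is
#' clipped at the floor.
#'
#' @inheritParams expected_signal
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @param experiment_id Label stored in the output.
#' @return A signal tibble with columns `experiment_id`, `peptide`,
#'   `class`, `replicate`, `intensity`, one row per layout spot (layout
#'   order).
#' @export
simulate_experiment <- function(library, epitopes, noise = noise_model(),
                                seed = 1L, experiment_id = "synthetic") {
  means <- expected_signal_table(library, epitopes, noise)
  layout <- library$layout
  peptides <- distinct(layout, .data$peptide)
  with_local_seed(seed, {
    offsets <- tibble(
      peptide = peptides$peptide,
      offset = stats::rnorm(nrow(peptides), 0, noise$background_sd)
    )
    out <- layout |>
      left_join(means, by = c("peptide", "class")) |>
      left_join(offsets, by = "peptide") |>
      mutate(
        intensity = pmax(
          noise$floor,
          stats::rnorm(dplyr::n(), .data$mean + .data$offset,
                       noise$replicate_sd)
        ),
        experiment_id = experiment_id
      ) |>
      select("experiment_id", "peptide", "class", "replicate", "intensity")
    out
  })
}
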