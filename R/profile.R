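#' Binding profile of one antigen
#'
#' The per-position view behind signal-vs-position plots: one point per
#' tile occurrence in the antigen, located at the N-terminal residue of
#' the 12-mer, carrying the peptide's median and replicate SD. A peptide
#' shared by several homologous antigens contributes a point to each of
#' their profiles.
#'
#' @param accession Antigen accession to profile.
#' @param occurrences Occurrence map (`peptide`, `accession`, `start`),
#'   e.g. `library$occurrences`.
#' @param medians A median tibble from [replicate_median()].
#' @param experiment_id Optional label carried into the output.
#' @return A tibble with columns `accession`, `start`, `peptide`,
#'   `median`, `sd`, ascending in `start`.
#' @export
binding_profile <- function(accession, occurrences, medians,
                            experiment_id = NULL) {
  occ <- filter(occurrences, .data$accession == .env$accession)
  if (nrow(occ) == 0L) {
    abort(paste0("no tile occurrences recorded for accession '",
                 accession, "'"))
  }
  wt <- wt_medians(medians)
  out <- occ |>
    inner_join(select(wt, "peptide", "median", "sd"), by = "peptide") |>
    select("accession", "start", "peptide", "median", "sd") |>
    arrange(.data$start)
  if (!is.null(experiment_id)) {
    out <- mutate(out, experiment_id = experiment_id, .before = 1L)
  }
  out
}

wt_medians <- function(medians) {
  if ("class" %in% names(medians)) {
    filter(medians, .data$class == "wt")
  } else {
    medians
  }
}

# Expand occurrences to one row per covered residue:
# (peptide, accession, start, residue, offset) for offset 1..k.
occurrence_residues <- function(occurrences) {
  k <- nchar(occurrences$peptide)
  occurrences |>
    mutate(offset = purrr::map(k, seq_len)) |>
    tidyr::unnest_longer("offset") |>
    mutate(residue = .data$start + .data$offset - 1L)
}

#' Residue scores: average signal of all peptides spanning each residue
#'
#' For every residue of every antigen, the arithmetic mean of the medians
#' of all wild-type tiles whose span contains that residue — binder and
#' non-binder alike. Converts peptide-level binding profiles into a
#' sequence-level score sharing the antigen's own coordinates.
#'
#' @param toxins Antigen tibble (`accession`, `sequence`).
#' @param occurrences Occurrence map (`peptide`, `accession`, `start`).
#' @param medians A median tibble from [replicate_median()].
#' @return A tibble with columns `accession`, `residue`, `residue_letter`,
#'   `residue_score` (NA where no tile covers the residue), `coverage_wt`.
#' @export
residue_scores <- function(toxins, occurrences, medians) {
  wt <- wt_medians(medians)
  per_res <- occurrence_residues(occurrences) |>
    inner_join(select(wt, "peptide", "median"), by = "peptide") |>
    group_by(.data$accession, .data$residue) |>
    summarise(residue_score = mean(.data$median),
              coverage_wt = dplyr::n(), .groups = "drop")
  scaffold_residues(toxins) |>
    left_join(per_res, by = c("accession", "residue")) |>
    mutate(coverage_wt = dplyr::coalesce(.data$coverage_wt, 0L))
}

scaffold_residues <- function(toxins) {
  toxins |>
    transmute(
      accession = .data$accession,
      residue_letter = strsplit(.data$sequence, "")
    ) |>
    tidyr::unnest_longer("residue_letter", indices_to = "residue") |>
    select("accession", "residue", "residue_letter")
}

#' Average alanine-substitution effect per residue
#'
#' For every binder wild-type tile spanning a residue, the effect of
#' substituting that residue is `log2(median(variant) / median(wild-type))`
#' where the variant is the tile with that position replaced by alanine;
#' the residue's value averages these effects over all binder tiles
#' covering it, so the positional context of the residue within each
#' 12-mer is averaged out. Residues that are already alanine contribute 0
#' (self-substitution is the identity). Residues covered by no binder tile
#' get `NA` — non-binding peptides carry no substitution information.
#' Medians at or below zero are floored to `epsilon` before the ratio.
#'
#' @inheritParams residue_scores
#' @param binders Binder peptides: a [classify_binders()] tibble or a
#'   character vector.
#' @param epsilon Floor (AU) applied to medians before the log-ratio.
#' @return A tibble with columns `accession`, `residue`, `residue_letter`,
#'   `ala_effect` (NA where `coverage_binder` is 0), `coverage_binder`.
#' @export
alanine_effects <- function(toxins, occurrences, medians, binders,
                            epsilon = 1) {
  binders <- if (is.data.frame(binders)) binder_set(binders) else
    unique(binders)
  med_wt <- wt_medians(medians)
  med_ala <- if ("class" %in% names(medians)) {
    filter(medians, .data$class == "ala")
  } else medians
  # variants colliding with a wt sequence are measured as variants; fall
  # back to the wt median when only that is available
  var_lookup <- bind_rows(
    select(med_ala, "peptide", "median"),
    anti_join(select(med_wt, "peptide", "median"), med_ala, by = "peptide")
  )

  contrib <- occurrence_residues(
    filter(occurrences, .data$peptide %in% binders)
  ) |>
    inner_join(select(med_wt, "peptide", wt_median = "median"),
               by = "peptide") |>
    mutate(
      letter = substring(.data$peptide, .data$offset, .data$offset),
      variant = purrr::map2_chr(.data$peptide, .data$offset, function(p, j) {
        substring(p, j, j) <- "A"
        p
      })
    ) |>
    left_join(rename(var_lookup, variant_median = "median"),
              by = c(variant = "peptide"))

  missing_var <- filter(contrib, .data$letter != "A",
                        is.na(.data$variant_median))
  if (nrow(missing_var) > 0L) {
    warn(paste0(nrow(missing_var),
                " substitution(s) lack a measured variant median",
                " and are dropped from the average"))
    contrib <- anti_join(contrib, missing_var,
                         by = c("peptide", "offset"))
  }
  floored <- filter(contrib, .data$letter != "A",
                    (.data$wt_median <= 0 | .data$variant_median <= 0))
  if (nrow(floored) > 0L) {
    warn(paste0(nrow(floored), " median(s) <= 0 floored to epsilon = ",
                epsilon, " before the log-ratio"))
  }
  per_res <- contrib |>
    mutate(effect = ifelse(
      .data$letter == "A", 0,
      log2(pmax(.data$variant_median, epsilon) /
             pmax(.data$wt_median, epsilon))
    )) |>
    group_by(.data$accession, .data$residue) |>
    summarise(ala_effect = mean(.data$effect),
              coverage_binder = dplyr::n(), .groups = "drop")
  scaffold_residues(toxins) |>
    left_join(per_res, by = c("accession", "residue")) |>
    mutate(coverage_binder = dplyr::coalesce(.data$coverage_binder, 0L))
}

#' Full residue-level profile of an experiment
#'
#' Joins [residue_scores()] and [alanine_effects()] into the per-residue
#' table used for sequence-level epitope maps: residue score, averaged
#' alanine-substitution effect (NA where no covering peptide passed the
#' binder threshold — the "gray" residues of an epitope map), and both
#' coverage counts.
#'
#' @inheritParams alanine_effects
#' @param library A `peptide_library` (supplies toxins and occurrences).
#' @param experiment_id Optional label carried into the output.
#' @return A tibble with columns `accession`, `residue`, `residue_letter`,
#'   `residue_score`, `ala_effect`, `coverage_wt`, `coverage_binder` (and
#'   `experiment_id` when given).
#' @export
residue_profile <- function(library, medians, binders, epsilon = 1,
                            experiment_id = NULL) {
  scores <- residue_scores(library$toxins, library$occurrences, medians)
  effects <- alanine_effects(library$toxins, library$occurrences, medians,
                             binders, epsilon = epsilon)
  out <- scores |>
    left_join(select(effects, "accession", "residue", "ala_effect",
                     "coverage_binder"),
              by = c("accession", "residue"))
  if (!is.null(experiment_id)) {
    out <- mutate(out, experiment_id = experiment_id, .before = 1L)
  }
  out
}

#' Read a gapped multiple sequence alignment
#'
#' @param path Aligned FASTA with `-` gap characters.
#' @return A tibble with columns `accession`, `aligned`.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort(paste0("no sequences in '", path, "'"))
  widths <- Biostrings::width(aa)
  if (length(unique(widths)) != 1L) {
    abort("alignment rows have unequal widths")
  }
  tibble(accession = sub("\\s.*$", "", names(aa)),
         aligned = as.character(aa))
}

#' Project per-residue values onto alignment columns
#'
#' Places each residue's value at its column in a gapped multiple
#' sequence alignment, so homologous residues of related antigens line up
#' below each other. Gap cells carry no value; ungapping a projected row
#' recovers the input values exactly.
#'
#' @param values A tibble with columns `accession`, `residue`, and one
#'   value column named by `value_col`.
#' @param alignment A tibble from [read_alignment()].
#' @param toxins Optional antigen tibble; when given, each alignment row
#'   is checked to ungap to the antigen's sequence.
#' @param value_col Name of the value column in `values`.
#' @return A tibble with columns `accession`, `column`, `residue` (NA at
#'   gap columns), `value`.
#' @export
project_onto_alignment <- function(values, alignment, toxins = NULL,
                                   value_col = "value") {
  stopifnot(value_col %in% names(values))
  if (!is.null(toxins)) {
    chk <- inner_join(alignment, select(toxins, "accession", "sequence"),
                      by = "accession")
    bad <- filter(chk, gsub("-", "", .data$aligned, fixed = TRUE) !=
                    .data$sequence)
    if (nrow(bad) > 0L) {
      abort(paste0("alignment row does not ungap to the sequence of '",
                   bad$accession[1], "'"))
    }
  }
  vals <- select(values, "accession", "residue", value = all_of(value_col))
  grid <- alignment |>
    transmute(
      accession = .data$accession,
      letter = strsplit(.data$aligned, "")
    ) |>
    tidyr::unnest_longer("letter", indices_to = "column") |>
    group_by(.data$accession) |>
    mutate(residue = ifelse(.data$letter == "-", NA_integer_,
                            cumsum(.data$letter != "-"))) |>
    ungroup()
  grid |>
    left_join(vals, by = c("accession", "residue")) |>
    mutate(value = ifelse(is.na(.data$residue), NA_real_, .data$value)) |>
    select("accession", "column", "residue", "value")
}

#' Write a residue profile table
#'
#' TSV columns: `accession`, `residue_index`, `residue_letter`,
#' `residue_score`, `ala_effect` (empty where no covering binder),
#' `coverage_wt`, `coverage_binder`, `experiment_id`.
#'
#' @param profile A [residue_profile()] tibble.
#' @param path Output path.
#' @return Invisibly, the written tibble.
#' @export
write_residue_profile <- function(profile, path) {
  out <- rename(profile, residue_index = "residue")
  readr::write_tsv(out, path, na = "")
  invisible(out)
}
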