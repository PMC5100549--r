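#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the pipeline into one serializable
#' list. Defaults are the study design values: 12-mers tiled at every
#' second residue, wild-type peptides in five replicates and variants in
#' one, background from the lower 70-percentile of wild-type medians,
#' binder threshold at mean + 10 SD, and a 1 AU floor for log-ratios.
#' The `synthetic` block parameterises [run_simulate()].
#'
#' @param k,step,force_terminal Tiling parameters; see [tile_sequence()].
#' @param replicates_wt,replicates_variant Spots per peptide.
#' @param drop_wt_collisions See [alanine_variants()].
#' @param percentile,k_sd Background percentile and threshold multiplier;
#'   see [estimate_background()].
#' @param min_replicates Replicate count below which [replicate_median()]
#'   warns.
#' @param epsilon Log-ratio floor (AU); see [alanine_effects()].
#' @param effect_orientation `"variant_over_wt"` (loss of binding is
#'   negative) or `"wt_over_variant"`.
#' @param seed Integer seed used by every randomized stage.
#' @param synthetic Named list of generator settings for [run_simulate()]:
#'   `n_toxins`, `length_range`, `n_epitopes`, `core_length`, `n_key`,
#'   `amplitude`, `knockdown`, `background_mean`, `background_sd`,
#'   `replicate_sd`.
#' @return A list of class `pepscan_config`.
#' @export
run_config <- function(k = 12L, step = 2L, force_terminal = FALSE,
                       replicates_wt = 5L, replicates_variant = 1L,
                       drop_wt_collisions = FALSE,
                       percentile = 70, k_sd = 10, min_replicates = 3L,
                       epsilon = 1, effect_orientation = "variant_over_wt",
                       seed = 1L, synthetic = list()) {
  effect_orientation <- match.arg(effect_orientation,
                                  c("variant_over_wt", "wt_over_variant"))
  syn_defaults <- list(
    n_toxins = 30L, length_range = c(30L, 80L), n_epitopes = 10L,
    core_length = 7:9, n_key = 2L, amplitude = 160, knockdown = 0.25,
    background_mean = 50, background_sd = 8, replicate_sd = 8
  )
  synthetic <- utils::modifyList(syn_defaults, synthetic)
  structure(
    list(k = k, step = step, force_terminal = force_terminal,
         replicates_wt = replicates_wt,
         replicates_variant = replicates_variant,
         drop_wt_collisions = drop_wt_collisions,
         percentile = percentile, k_sd = k_sd,
         min_replicates = min_replicates, epsilon = epsilon,
         effect_orientation = effect_orientation, seed = seed,
         synthetic = synthetic),
    class = "pepscan_config"
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as YAML; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `pepscan_config`;
#'   [write_run_config()] returns the path invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `pepscan_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Stable content hash recorded in every stage manifest, so each output
#' table declares the configuration that produced it.
#'
#' @param config A `pepscan_config`.
#' @return A character hash.
#' @export
config_hash <- function(config) {
  # hash the JSON rendering so integer/double storage differences
  # introduced by serialization round-trips do not change the hash
  rlang::hash(as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA)))
}

write_manifest <- function(out_dir, stage, config, inputs, outputs) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    config_hash = config_hash(config),
    config = unclass(config),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(basename(outputs))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Pipeline stage: design the peptide library
#'
#' Reads antigen FASTA, designs the tiling + alanine-scan library, and
#' writes `layout.tsv`, `occurrences.tsv`, `toxins.tsv` and a stage
#' manifest into `out_dir`.
#'
#' @param config A `pepscan_config`.
#' @param fasta_path Antigen FASTA.
#' @param out_dir Output directory (created if needed).
#' @return The `peptide_library`, invisibly.
#' @export
run_design <- function(config, fasta_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toxins <- read_toxins(fasta_path)
  library <- design_library(
    toxins, k = config$k, step = config$step,
    force_terminal = config$force_terminal,
    replicates_wt = config$replicates_wt,
    replicates_variant = config$replicates_variant,
    drop_wt_collisions = config$drop_wt_collisions, seed = config$seed
  )
  g <- glance(library)
  message("design: ", g$n_toxins, " antigens -> ", g$n_tiles, " tiles, ",
          g$redundancy_count, " redundant removed, ", g$n_wt,
          " unique wt, ", g$n_variants, " variants, ", g$n_spots, " spots")
  write_library(library, file.path(out_dir, "layout.tsv"),
                file.path(out_dir, "occurrences.tsv"))
  readr::write_tsv(toxins, file.path(out_dir, "toxins.tsv"))
  write_manifest(out_dir, "design", config, fasta_path,
                 c("layout.tsv", "occurrences.tsv", "toxins.tsv"))
  invisible(library)
}

#' Pipeline stage: simulate a synthetic experiment
#'
#' Generates synthetic antigens, designs their library, plants epitopes,
#' simulates spot intensities, and writes the design files, `signals.tsv`
#' and the `truth.json` sidecar (expected binders and per-residue expected
#' effects) into `out_dir`.
#'
#' @inheritParams run_design
#' @param experiment_id Label for the simulated experiment.
#' @return Invisibly, a list with `library`, `epitopes`, `truth`,
#'   `signals`.
#' @export
run_simulate <- function(config, out_dir, experiment_id = "synthetic") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- config$synthetic
  toxins <- synthetic_toxins(syn$n_toxins, syn$length_range,
                             seed = config$seed)
  library <- design_library(
    toxins, k = config$k, step = config$step,
    force_terminal = config$force_terminal,
    replicates_wt = config$replicates_wt,
    replicates_variant = config$replicates_variant,
    drop_wt_collisions = config$drop_wt_collisions, seed = config$seed
  )
  noise <- noise_model(syn$background_mean, syn$background_sd,
                       syn$replicate_sd)
  epitopes <- plant_epitopes(
    library, n_epitopes = syn$n_epitopes, core_length = syn$core_length,
    n_key = syn$n_key, amplitude = syn$amplitude,
    knockdown = syn$knockdown, seed = config$seed
  )
  truth <- derive_truth(library, epitopes, noise)
  signals <- simulate_experiment(library, epitopes, noise,
                                 seed = config$seed,
                                 experiment_id = experiment_id)
  message("simulate: ", nrow(signals), " spots, ",
          length(truth$expected_binders), " expected binder peptides")
  write_library(library, file.path(out_dir, "layout.tsv"),
                file.path(out_dir, "occurrences.tsv"))
  readr::write_tsv(toxins, file.path(out_dir, "toxins.tsv"))
  readr::write_tsv(rename(signals, peptide_sequence = "peptide"),
                   file.path(out_dir, "signals.tsv"))
  jsonlite::write_json(
    list(expected_binders = truth$expected_binders,
         expected_effect = truth$expected_effect,
         epitopes = mutate(epitopes, key_positions =
                             purrr::map(.data$key_positions, identity))),
    file.path(out_dir, "truth.json"), digits = NA
  )
  write_manifest(out_dir, "simulate", config, character(0),
                 c("layout.tsv", "occurrences.tsv", "toxins.tsv",
                   "signals.tsv", "truth.json"))
  invisible(list(library = library, epitopes = epitopes, truth = truth,
                 signals = signals))
}

#' Pipeline stage: classify antibody-binding peptides
#'
#' Reads a signal table, and per experiment computes replicate medians,
#' fits the background model and classifies wild-type peptides, writing
#' `binders.tsv` (all experiments stacked) and `background.json`.
#'
#' @inheritParams run_design
#' @param signals_path Signal TSV (schema of [read_signals()]).
#' @return Invisibly, a named list per experiment with `medians`,
#'   `model`, `binders`.
#' @export
run_classify <- function(config, signals_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  signals <- read_signals(signals_path)
  by_exp <- split(signals, signals$experiment_id)
  results <- purrr::map(by_exp, function(s) {
    medians <- replicate_median(s)
    model <- estimate_background(medians, percentile = config$percentile,
                                 k = config$k_sd)
    binders <- classify_binders(medians, model,
                                experiment_id = s$experiment_id[1])
    message("classify [", s$experiment_id[1], "]: ",
            sum(binders$is_binder), " / ", nrow(binders),
            " wt peptides above threshold ",
            format(model$threshold, digits = 6))
    list(medians = medians, model = model, binders = binders)
  })
  all_binders <- bind_rows(purrr::map(results, "binders"))
  write_binders(all_binders, file.path(out_dir, "binders.tsv"))
  jsonlite::write_json(
    purrr::map(results, function(r) glance(r$model)),
    file.path(out_dir, "background.json"), digits = NA
  )
  write_manifest(out_dir, "classify", config, signals_path,
                 c("binders.tsv", "background.json"))
  invisible(results)
}

#' Pipeline stage: residue-level profiling
#'
#' Maps peptide medians and binder calls of one experiment back onto the
#' antigen sequences: residue scores, averaged alanine-substitution
#' effects and coverage counts, written as `residue_profile.tsv`.
#'
#' @inheritParams run_design
#' @param signals_path Signal TSV for one experiment.
#' @param binders_path Binder TSV from [run_classify()].
#' @param occurrences_path Occurrence TSV from the design stage.
#' @param toxins_path Antigen TSV from the design stage.
#' @param experiment_id Experiment to profile (default: the only one in
#'   the signal table).
#' @return Invisibly, the residue profile tibble.
#' @export
run_profile <- function(config, signals_path, binders_path,
                        occurrences_path, toxins_path, out_dir,
                        experiment_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  signals <- read_signals(signals_path)
  if (is.null(experiment_id)) {
    experiment_id <- unique(signals$experiment_id)
    if (length(experiment_id) != 1L) {
      abort("signal table holds several experiments; pass experiment_id")
    }
  }
  signals <- filter(signals, .data$experiment_id == .env$experiment_id)
  binders_tab <- readr::read_tsv(binders_path, col_types = readr::cols(),
                                 progress = FALSE) |>
    rename(peptide = "peptide_sequence") |>
    filter(.data$experiment_id == .env$experiment_id)
  occurrences <- readr::read_tsv(occurrences_path,
                                 col_types = readr::cols(),
                                 progress = FALSE) |>
    rename(peptide = "peptide_sequence")
  toxins <- readr::read_tsv(toxins_path, col_types = readr::cols(),
                            progress = FALSE)
  medians <- replicate_median(signals)
  pseudo_library <- list(toxins = toxins, occurrences = occurrences)
  profile <- residue_profile(pseudo_library, medians, binders_tab,
                             epsilon = config$epsilon,
                             experiment_id = experiment_id)
  if (config$effect_orientation == "wt_over_variant") {
    profile <- mutate(profile, ala_effect = -.data$ala_effect)
  }
  write_residue_profile(profile, file.path(out_dir, "residue_profile.tsv"))
  write_manifest(out_dir, "profile", config,
                 c(signals_path, binders_path, occurrences_path,
                   toxins_path),
                 "residue_profile.tsv")
  invisible(profile)
}

#' Pipeline stage: compare binder sets across experiments
#'
#' Reads two or three binder tables, computes the exclusive Venn region
#' counts and pairwise non-shared fractions, and writes
#' `overlap_regions.tsv` plus `overlap_report.json`.
#'
#' @inheritParams run_design
#' @param binder_paths Named character vector of binder TSV paths (names
#'   become the set labels).
#' @return Invisibly, the `overlap_report`.
#' @export
run_compare <- function(config, binder_paths, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sets <- purrr::map(binder_paths, function(p) {
    tab <- readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
    rename(tab, peptide = "peptide_sequence")
  })
  report <- overlap_counts(sets)
  write_overlap_report(report,
                       tsv_path = file.path(out_dir, "overlap_regions.tsv"),
                       json_path = file.path(out_dir, "overlap_report.json"))
  write_manifest(out_dir, "compare", config, unname(binder_paths),
                 c("overlap_regions.tsv", "overlap_report.json"))
  invisible(report)
}

#' Pipeline stage: annotate a structure with residue values
#'
#' Reads a residue profile table, selects one antigen and one value
#' column, and writes the values into the B-factor field of a PDB file.
#'
#' @inheritParams run_design
#' @param pdb_path Input PDB.
#' @param profile_path Residue profile TSV from [run_profile()].
#' @param accession Antigen whose values to map.
#' @param value_col `"residue_score"` or `"ala_effect"`.
#' @param chain Chain identifier in the structure.
#' @param offset Residue-numbering offset; see [annotate_pdb()].
#' @return Invisibly, the annotated-residue tibble from [annotate_pdb()].
#' @export
run_annotate <- function(config, pdb_path, profile_path, accession,
                         out_dir, value_col = "residue_score",
                         chain = "A", offset = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- readr::read_tsv(profile_path, col_types = readr::cols(),
                             progress = FALSE)
  values <- profile |>
    filter(.data$accession == .env$accession) |>
    transmute(residue = .data$residue_index,
              value = .data[[value_col]])
  if (nrow(values) == 0L) {
    abort(paste0("accession '", accession, "' not in the profile table"))
  }
  out_path <- file.path(out_dir, paste0(accession, "_annotated.pdb"))
  res <- annotate_pdb(pdb_path, values, out_path, chain = chain,
                      offset = offset)
  write_manifest(out_dir, "annotate", config,
                 c(pdb_path, profile_path),
                 basename(out_path))
  invisible(res)
}
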