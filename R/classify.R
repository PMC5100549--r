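#' Read a spot-level signal table
#'
#' Reads the flat TSV interchange format for one or more microarray
#' experiments: columns `experiment_id`, `peptide_sequence`, `class`
#' (`wt`/`ala`), `replicate`, `intensity`. Intensities must be finite and
#' non-negative — extraction pipelines that background-subtract must floor
#' their values before handing them over.
#'
#' @param path Path to a TSV file.
#' @return A signal tibble with columns `experiment_id`, `peptide`,
#'   `class`, `replicate`, `intensity`.
#' @export
read_signals <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("experiment_id", "peptide_sequence", "class", "replicate",
                "intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("signal table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- rename(tab, peptide = "peptide_sequence")
  if (!all(tab$class %in% c("wt", "ala"))) {
    abort("class column must be 'wt' or 'ala'")
  }
  if (any(!is.finite(tab$intensity)) || any(tab$intensity < 0)) {
    abort("intensities must be finite and >= 0 (floor negative values upstream)")
  }
  select(tab, "experiment_id", "peptide", "class", "replicate", "intensity")
}

#' Collapse replicate spots to per-peptide medians
#'
#' Computes, for every peptide (wild-type and alanine variant alike), the
#' median of its replicate intensities — the peptide-level statistic all
#' downstream classification and profiling is based on — together with the
#' sample standard deviation (n-1 denominator; 0 when a peptide has a
#' single replicate) and the replicate count.
#'
#' @param signals A signal tibble ([read_signals()] or
#'   [simulate_experiment()] output).
#' @return A median tibble with columns `peptide`, `class`, `median`,
#'   `sd`, `n`. Warns when any wild-type peptide has fewer than 3
#'   replicates.
#' @export
replicate_median <- function(signals) {
  if (nrow(signals) == 0L) abort("empty signal table")
  out <- signals |>
    group_by(.data$peptide, .data$class) |>
    summarise(
      median = stats::median(.data$intensity),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data$intensity), 0),
      n = dplyr::n(),
      .groups = "drop"
    )
  low <- sum(out$n < 3L & out$class == "wt")
  if (low > 0L) {
    warn(paste0(low, " wild-type peptide(s) have fewer than 3 replicates"))
  }
  out
}

#' Fit the background model from wild-type medians
#'
#' Estimates the unspecific-binding background of one experiment under the
#' assumption that the large majority of peptides are not recognised by
#' any antibody: the `floor(percentile/100 * N)` smallest wild-type
#' medians (nearest-rank lower percentile, default the lower
#' 70-percentile) are taken as the background population, whose mean and
#' sample standard deviation define the binder threshold
#' `mean + k * sd` (default `k = 10`).
#'
#' @param medians A median tibble from [replicate_median()], or a bare
#'   numeric vector of wild-type medians.
#' @param percentile Lower percentile (in percent) defining the background
#'   subset.
#' @param k Number of standard deviations above the background mean a
#'   median must exceed to call a binder.
#' @return An object of class `background_model` with fields `percentile`,
#'   `n`, `subset_size`, `mean`, `sd`, `k`, `threshold`.
#' @examples
#' m <- c(8, 9, 10, 10, 10, 10, 11, 12, 500, 600)
#' estimate_background(m)
#' @export
estimate_background <- function(medians, percentile = 70, k = 10) {
  values <- background_input_medians(medians)
  n <- length(values)
  if (n < 10L) {
    abort(paste0("background not estimable from ", n,
                 " wild-type medians (need >= 10)"))
  }
  subset_size <- floor(percentile / 100 * n)
  subset <- sort(values)[seq_len(subset_size)]
  mu <- mean(subset)
  sigma <- stats::sd(subset)
  structure(
    list(percentile = percentile, n = n, subset_size = subset_size,
         mean = mu, sd = sigma, k = k, threshold = mu + k * sigma),
    class = "background_model"
  )
}

background_input_medians <- function(medians) {
  if (is.numeric(medians)) return(medians)
  stopifnot(is.data.frame(medians), "median" %in% names(medians))
  if ("class" %in% names(medians)) {
    medians <- filter(medians, .data$class == "wt")
  }
  medians$median
}

#' @export
print.background_model <- function(x, ...) {
  cat("<background_model> lower ", x$percentile, "% of ", x$n,
      " wt medians (subset ", x$subset_size, ")\n",
      "  mean ", format(x$mean, digits = 6), ", sd ",
      format(x$sd, digits = 6), ", threshold mean + ", x$k, " sd = ",
      format(x$threshold, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @rdname estimate_background
#' @param x A `background_model`.
#' @param ... Unused.
#' @method tidy background_model
#' @export
tidy.background_model <- function(x, ...) {
  tibble(term = c("mean", "sd", "threshold"),
         estimate = c(x$mean, x$sd, x$threshold))
}

#' @rdname estimate_background
#' @method glance background_model
#' @export
glance.background_model <- function(x, ...) {
  tibble(n = x$n, subset_size = x$subset_size, percentile = x$percentile,
         mean = x$mean, sd = x$sd, k = x$k, threshold = x$threshold)
}

#' Classify wild-type peptides as antibody binders
#'
#' A wild-type peptide is called an antibody target when its median
#' replicate intensity lies strictly more than `k` background standard
#' deviations above the background mean, i.e. exceeds the fitted
#' threshold. Alanine variants are never classified (their medians feed
#' the substitution analysis instead); classification is always
#' per-experiment, against a model fitted on the same experiment.
#'
#' @param medians A median tibble from [replicate_median()].
#' @param model A `background_model` fitted on this experiment's wild-type
#'   medians.
#' @param experiment_id Optional label carried into the output.
#' @return A tibble of wild-type peptides with columns `peptide`,
#'   `median`, `threshold`, `is_binder`.
#' @export
classify_binders <- function(medians, model, experiment_id = NULL) {
  wt <- if ("class" %in% names(medians)) {
    filter(medians, .data$class == "wt")
  } else medians
  out <- wt |>
    mutate(threshold = model$threshold,
           is_binder = .data$median > model$threshold) |>
    select("peptide", "median", "threshold", "is_binder")
  if (!is.null(experiment_id)) {
    out <- mutate(out, experiment_id = experiment_id, .before = 1L)
  }
  out
}

#' Extract the binder peptide set
#'
#' @param binders A classification tibble from [classify_binders()].
#' @return Character vector of binder peptide sequences.
#' @export
binder_set <- function(binders) {
  sort(unique(binders$peptide[binders$is_binder]))
}

#' Peptides called in both dilutions of one antivenom
#'
#' The consensus binder set of one antivenom is the intersection of the
#' binder sets of its two dilution experiments — only peptides identified
#' in both experiments are retained for cross-antivenom comparison.
#'
#' @param set_a,set_b Binder sets: character vectors or
#'   [classify_binders()] tibbles.
#' @return Sorted character vector of shared binder peptides.
#' @export
consensus_binders <- function(set_a, set_b) {
  a <- if (is.data.frame(set_a)) binder_set(set_a) else unique(set_a)
  b <- if (is.data.frame(set_b)) binder_set(set_b) else unique(set_b)
  sort(intersect(a, b))
}

#' Write a binder classification table
#'
#' TSV columns: `experiment_id`, `peptide_sequence`, `median`,
#' `threshold`, `is_binder`.
#'
#' @param binders A [classify_binders()] tibble.
#' @param path Output path.
#' @param experiment_id Label to use when the tibble carries none.
#' @return Invisibly, the written tibble.
#' @export
write_binders <- function(binders, path, experiment_id = "experiment") {
  if (!"experiment_id" %in% names(binders)) {
    binders <- mutate(binders, experiment_id = experiment_id, .before = 1L)
  }
  out <- rename(binders, peptide_sequence = "peptide")
  readr::write_tsv(out, path)
  invisible(out)
}
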