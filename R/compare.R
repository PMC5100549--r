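#' Exclusive Venn region counts for 2 or 3 binder sets
#'
#' Computes the exact exclusive-region counts of the Venn decomposition of
#' two or three peptide sets over a common universe (3 regions for a pair,
#' 7 for a triple), plus union and intersection sizes and the pairwise
#' non-shared fractions.
#'
#' @param sets A named list of 2 or 3 binder sets (character vectors or
#'   [classify_binders()] tibbles).
#' @return An object of class `overlap_report`: a list with `labels`,
#'   `regions` (tibble `region`, `count`, one row per exclusive region
#'   named like `"A&B"`), `union_size`, `intersection_size`, and
#'   `non_shared` (tibble of pairwise fractions).
#' @examples
#' overlap_counts(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
#'                     C = "c"))
#' @export
overlap_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    abort("overlap_counts() takes a named list of 2 or 3 sets")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- purrr::map(sets, function(s) {
    if (is.data.frame(s)) binder_set(s) else unique(s)
  })
  labels <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, labels))
  signature <- apply(membership, 1L, function(row) {
    paste(labels[row], collapse = "&")
  })
  all_regions <- unlist(purrr::map(seq_along(labels), function(m) {
    combn(labels, m, paste, collapse = "&")
  }))
  counts <- table(factor(signature, levels = all_regions))
  regions <- tibble(region = all_regions, count = as.integer(counts))
  pairs <- combn(labels, 2L)
  non_shared <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- sets[[pairs[1, i]]]
    b <- sets[[pairs[2, i]]]
    tibble(set_a = pairs[1, i], set_b = pairs[2, i],
           fraction = non_shared_fraction(a, b))
  })
  structure(
    list(labels = labels, regions = regions,
         union_size = length(universe),
         intersection_size = length(purrr::reduce(sets, intersect)),
         non_shared = non_shared),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> sets: ", paste(x$labels, collapse = ", "),
      " (union ", x$union_size, ", intersection ", x$intersection_size,
      ")\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' @rdname overlap_counts
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  x$regions
}

#' Fraction of peptides not shared between two binder sets
#'
#' `(|A union B| - |A intersect B|) / |A union B|`: 0 when the sets are
#' equal (by convention also when both are empty), 1 when they are
#' disjoint but not both empty. This is the disagreement measure used to
#' compare the two dilution experiments of one antivenom.
#'
#' @param a,b Binder sets (character vectors or [classify_binders()]
#'   tibbles).
#' @return A fraction in `[0, 1]`.
#' @export
non_shared_fraction <- function(a, b) {
  a <- if (is.data.frame(a)) binder_set(a) else unique(a)
  b <- if (is.data.frame(b)) binder_set(b) else unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  (u - length(intersect(a, b))) / u
}

#' Antigens recognised through at least one binder peptide
#'
#' Maps a binder peptide set back to the antigens it occurs in: an
#' antigen is recognised when at least one of its tiles is a binder. A
#' peptide shared by several homologs marks all of them.
#'
#' @param binders A binder set (character vector or [classify_binders()]
#'   tibble).
#' @param occurrences Occurrence map (`peptide`, `accession`, `start`).
#' @return Sorted character vector of accessions.
#' @export
toxins_with_binders <- function(binders, occurrences) {
  b <- if (is.data.frame(binders)) binder_set(binders) else unique(binders)
  if (length(b) == 0L) return(character())
  unmatched <- setdiff(b, occurrences$peptide)
  if (length(unmatched) > 0L) {
    abort(paste0("binder peptide(s) missing from the occurrence map: ",
                 unmatched[1]))
  }
  sort(unique(occurrences$accession[occurrences$peptide %in% b]))
}

#' Write an overlap report
#'
#' Writes the exclusive region counts as TSV and the full report
#' (labels, regions, union/intersection sizes, non-shared fractions) as a
#' JSON sidecar.
#'
#' @param report An `overlap_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_overlap_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    readr::write_tsv(report$regions, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(labels = report$labels,
           regions = report$regions,
           union_size = report$union_size,
           intersection_size = report$intersection_size,
           non_shared = report$non_shared),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}
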