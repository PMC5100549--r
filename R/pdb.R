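#' Write per-residue values into the B-factor column of a PDB file
#'
#' Edits the temperature-factor field (columns 61-66) of every `ATOM` and
#' `HETATM` record in place, so residue-level scores (residue scores or
#' averaged alanine-substitution effects) can be rendered as structure
#' colouring in any molecular viewer. All atoms of a mapped residue get
#' the residue's value; residues of the chain without a value get
#' `fill`. Every other byte of the file is left untouched.
#'
#' Raw values are min-max scaled into `scale_range` (default
#' `c(0, 99.99)`) before writing, because raw median intensities can
#' overflow the fixed-width `%6.2f` field; the scaling parameters are
#' written to a JSON sidecar so raw values stay recoverable. Degenerate
#' inputs (all values equal) map to the lower bound. Set
#' `scale_range = NULL` to write raw values, which must then fit the
#' field.
#'
#' @param pdb_path Input PDB file.
#' @param values A tibble with columns `residue` (author residue number
#'   in the file) and `value`; an optional `chain` column restricts rows
#'   to specific chains. Rows with `NA` values are treated as unassigned.
#' @param out_path Output PDB path.
#' @param chain Chain identifier(s) to annotate when `values` has no
#'   `chain` column (default `"A"`).
#' @param fill Value written for atoms of unannotated residues in the
#'   targeted chain(s), on the output (scaled) scale.
#' @param scale_range Numeric length-2 target range for min-max scaling,
#'   or `NULL` for no scaling.
#' @param offset Added to `values$residue` to reconcile sequence
#'   numbering with the structure's author numbering.
#' @param sidecar_path JSON sidecar path for the scaling metadata
#'   (default `out_path` + `".json"`; `NA` disables it).
#' @return Invisibly, a tibble of the annotated residues (`chain`,
#'   `residue`, `value`, `b_factor`).
#' @export
annotate_pdb <- function(pdb_path, values, out_path, chain = "A",
                         fill = 0, scale_range = c(0, 99.99), offset = 0L,
                         sidecar_path = paste0(out_path, ".json")) {
  stopifnot(all(c("residue", "value") %in% names(values)))
  if (!"chain" %in% names(values)) {
    values <- tidyr::expand_grid(chain = chain,
                                 select(values, "residue", "value"))
  }
  values <- values |>
    filter(!is.na(.data$value)) |>
    mutate(residue = .data$residue + offset)
  if (nrow(values) == 0L) abort("no non-missing values to annotate")
  rng <- range(values$value)
  if (is.null(scale_range)) {
    values <- mutate(values, b_factor = .data$value)
  } else {
    span <- rng[2] - rng[1]
    values <- mutate(values, b_factor = if (span == 0) scale_range[1] else
      scale_range[1] + (.data$value - rng[1]) / span *
        (scale_range[2] - scale_range[1]))
  }
  if (any(values$b_factor > 999.99 | values$b_factor < -99.99)) {
    abort("temperature-factor value overflows the fixed-width 6.2 field")
  }

  lines <- readLines(pdb_path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  rec_chain <- substring(lines, 22, 22)
  rec_resno <- suppressWarnings(as.integer(substring(lines, 23, 26)))
  key <- paste(rec_chain, rec_resno)
  idx <- match(key, paste(values$chain, values$residue))

  present <- unique(key[is_atom & !is.na(idx)])
  wanted <- paste(values$chain, values$residue)
  absent <- setdiff(wanted, present)
  if (length(absent) > 0L) {
    abort(paste0("residue(s) absent from the structure: ",
                 paste(utils::head(absent, 3), collapse = ", ")))
  }

  target <- is_atom & rec_chain %in% unique(values$chain)
  new_b <- ifelse(is.na(idx), fill, values$b_factor[idx])
  to_edit <- which(target)
  for (i in to_edit) {
    line <- lines[i]
    if (nchar(line) < 66) line <- formatC(line, width = -66)
    substring(line, 61, 66) <- sprintf("%6.2f", new_b[i])
    lines[i] <- line
  }
  writeLines(lines, out_path)

  if (!is.null(sidecar_path) && !is.na(sidecar_path)) {
    jsonlite::write_json(
      list(source = basename(pdb_path),
           scaled = !is.null(scale_range),
           value_min = rng[1], value_max = rng[2],
           scale_range = scale_range, fill = fill, offset = offset,
           n_residues = nrow(values)),
      sidecar_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(select(values, "chain", "residue", "value", "b_factor"))
}

#' Read back per-residue B-factors from a PDB file
#'
#' Companion reader for [annotate_pdb()]: extracts one B-factor per
#' (chain, residue) from the `ATOM`/`HETATM` records, checking that all
#' atoms of a residue agree.
#'
#' @param pdb_path PDB file.
#' @return A tibble with columns `chain`, `residue`, `b_factor`.
#' @export
read_pdb_bfactors <- function(pdb_path) {
  lines <- readLines(pdb_path)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(lines) == 0L) abort("no ATOM/HETATM records found")
  tab <- tibble(
    chain = substring(lines, 22, 22),
    residue = as.integer(substring(lines, 23, 26)),
    b_factor = as.numeric(substring(lines, 61, 66))
  ) |>
    group_by(.data$chain, .data$residue) |>
    summarise(
      b_factor = {
        if (length(unique(.data$b_factor)) != 1L) {
          warn("atoms of one residue carry different B-factors; using the first")
        }
        .data$b_factor[1]
      },
      .groups = "drop"
    )
  tab
}
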