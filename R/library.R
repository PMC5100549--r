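#' Tile a protein sequence into overlapping k-mers
#'
#' Slides a window of width `k` along the sequence at the given step,
#' mirroring the in-silico design of the microarray: 12-mers tiled at every
#' second residue. With the default `force_terminal = FALSE` the window
#' grid is used as-is, so for odd-length sequences the final residue is not
#' covered — this is the convention under which the study's printed library
#' counts are reproduced. Setting `force_terminal = TRUE` appends one extra
#' window flush with the C-terminus whenever the grid would miss it, so
#' that every residue is covered.
#'
#' @param sequence Amino-acid string (no gaps).
#' @param k Window width in residues.
#' @param step Grid step between window starts.
#' @param force_terminal Append a C-terminal window when the grid misses
#'   the last residue.
#' @return A tibble with columns `start` (1-based) and `peptide`, in
#'   ascending start order. Sequences shorter than `k` yield zero rows and
#'   a warning.
#' @examples
#' tile_sequence("ACDEFGHIKLMNPQ")
#' @export
tile_sequence <- function(sequence, k = 12L, step = 2L, force_terminal = FALSE) {
  len <- nchar(sequence)
  if (len < k) {
    warn(paste0("sequence of length ", len, " is shorter than k = ", k,
                "; no tiles generated"))
    return(tibble(start = integer(), peptide = character()))
  }
  last <- len - k + 1L
  starts <- seq.int(1L, last, by = step)
  if (force_terminal && starts[length(starts)] < last) {
    starts <- c(starts, last)
  }
  tibble(
    start = as.integer(starts),
    peptide = substring(sequence, starts, starts + k - 1L)
  )
}

#' Tile every toxin in a record set
#'
#' Applies [tile_sequence()] to each record, keeping provenance: every row
#' is one window in one antigen. Duplicate peptide sequences (shared between
#' homologous toxins, or repeated within one) appear once per origin.
#'
#' @inheritParams tile_sequence
#' @param toxins A tibble from [read_toxins()] (needs `accession`,
#'   `sequence`).
#' @return A tibble with columns `accession`, `start`, `peptide`.
#' @export
tile_toxins <- function(toxins, k = 12L, step = 2L, force_terminal = FALSE) {
  short <- toxins$accession[nchar(toxins$sequence) < k]
  res <- purrr::map2(toxins$accession, toxins$sequence, function(acc, s) {
    if (nchar(s) < k) return(NULL)
    mutate(tile_sequence(s, k = k, step = step, force_terminal = force_terminal),
           accession = acc, .before = 1L)
  })
  if (length(short) > 0L) {
    warn(paste0(length(short), " sequence(s) shorter than k = ", k,
                " excluded from tiling: ", paste(short, collapse = ", ")))
  }
  bind_rows(res)
}

#' Collapse tiles to the unique peptide set
#'
#' Pools the tiles of all antigens and removes redundant (non-unique)
#' peptide sequences, the deduplication step of the array design. The
#' occurrence map retains every (accession, start) that produced each
#' surviving peptide, so signals measured once per unique peptide can later
#' be mapped back to all homologs carrying it.
#'
#' @param tiles A tibble from [tile_toxins()].
#' @return A list of class `peptide_set` with elements `peptides` (tibble,
#'   one row per unique peptide, first-appearance order), `occurrences`
#'   (tibble `peptide`, `accession`, `start`), and `redundancy_count`
#'   (total tiles minus unique peptides).
#' @export
build_unique_set <- function(tiles) {
  stopifnot(all(c("accession", "start", "peptide") %in% names(tiles)))
  peptides <- distinct(select(tiles, "peptide"))
  out <- list(
    peptides = peptides,
    occurrences = select(tiles, "peptide", "accession", "start"),
    redundancy_count = nrow(tiles) - nrow(peptides)
  )
  class(out) <- "peptide_set"
  out
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("<peptide_set> ", nrow(x$peptides), " unique peptides, ",
      nrow(x$occurrences), " occurrences (",
      x$redundancy_count, " redundant tiles removed)\n", sep = "")
  invisible(x)
}

#' Generate single-alanine substitution variants
#'
#' For each wild-type peptide, produces one variant per position whose
#' residue is not already alanine, substituting that residue with `A`
#' (an alanine scan). Variants are deduplicated on sequence across the
#' whole library; every row of the returned provenance table records one
#' (parent, position) that generates the variant, so a variant arising from
#' several parents keeps all its origins.
#'
#' @param peptides Character vector of wild-type peptide sequences, or a
#'   tibble with a `peptide` column.
#' @param drop_wt_collisions Drop variants whose sequence coincides with a
#'   wild-type peptide (default keeps them in the variant set; they are
#'   still synthesised only once as variants).
#' @return A tibble with columns `peptide` (variant sequence), `parent`,
#'   `position` (1-based within the 12-mer). The unique variant set is
#'   `dplyr::distinct(out, peptide)`.
#' @examples
#' alanine_variants("CAAAAAAAAAAA")
#' @export
alanine_variants <- function(peptides, drop_wt_collisions = FALSE) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  wt <- unique(peptides)
  if (length(wt) == 0L) abort("no wild-type peptides supplied")
  k <- nchar(wt[1])
  rows <- purrr::map(wt, function(p) {
    chars <- strsplit(p, "")[[1]]
    pos <- which(chars != "A")
    if (length(pos) == 0L) return(NULL)
    var <- vapply(pos, function(j) {
      v <- chars
      v[j] <- "A"
      paste(v, collapse = "")
    }, character(1))
    tibble(peptide = var, parent = p, position = as.integer(pos))
  })
  out <- bind_rows(rows)
  # keep one provenance row per distinct (variant, parent, position)
  out <- distinct(out)
  if (drop_wt_collisions) {
    out <- filter(out, !.data$peptide %in% wt)
  }
  out
}

#' Assign peptides to randomized array positions
#'
#' Replicates each wild-type peptide `replicates_wt` times (five on the
#' array) and each alanine variant `replicates_variant` times, then assigns
#' all spots uniformly random positions with one seeded generator, to
#' decouple peptide identity from local intensity biases on the slide.
#'
#' @param wt Character vector (or tibble with `peptide`) of unique
#'   wild-type peptides.
#' @param variants Character vector (or tibble with `peptide`) of unique
#'   variant peptides.
#' @param replicates_wt,replicates_variant Spots per peptide (>= 1).
#' @param seed Integer seed for the layout permutation.
#' @return A tibble with columns `spot_index` (0-based position on the
#'   array, a permutation of `0:(N-1)`), `peptide`, `class`
#'   (`"wt"`/`"ala"`), `replicate` (1-based within peptide), sorted by
#'   `spot_index`.
#' @export
assemble_layout <- function(wt, variants, replicates_wt = 5L,
                            replicates_variant = 1L, seed = 1L) {
  if (is.data.frame(wt)) wt <- wt$peptide
  if (is.data.frame(variants)) variants <- variants$peptide
  wt <- unique(wt)
  variants <- unique(variants)
  if (replicates_wt < 1L || replicates_variant < 1L) {
    abort("replicate counts must be >= 1")
  }
  spots <- bind_rows(
    tibble(peptide = rep(wt, each = replicates_wt), class = "wt",
           replicate = rep(seq_len(replicates_wt), times = length(wt))),
    tibble(peptide = rep(variants, each = replicates_variant), class = "ala",
           replicate = rep(seq_len(replicates_variant), times = length(variants)))
  )
  n <- nrow(spots)
  perm <- with_local_seed(seed, sample.int(n))
  spots$spot_index <- order(perm) - 1L
  arrange(select(spots, "spot_index", "peptide", "class", "replicate"),
          .data$spot_index)
}

# Run code under a temporary RNG state so package functions never disturb
# the caller's random stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Design the full in-silico peptide library
#'
#' Runs the complete array design: tile every antigen into overlapping
#' k-mers, pool and deduplicate the tiles, expand the unique set with all
#' single-alanine substitution variants, and place replicated spots at
#' seeded random array positions. Defaults reproduce the study design:
#' 12-mers at every second residue, wild-type peptides in five replicates,
#' variants in one.
#'
#' @inheritParams tile_toxins
#' @inheritParams assemble_layout
#' @param drop_wt_collisions See [alanine_variants()].
#' @return An object of class `peptide_library`: a list with `toxins`,
#'   `occurrences`, `wt` (unique wild-type peptides), `variants` (variant
#'   provenance), `layout`, `redundancy_count`, and `params`.
#' @examples
#' tox <- tibble::tibble(accession = "T1",
#'                       sequence = "ACDEFGHIKLMNPQRSTVWY")
#' lib <- design_library(tox, seed = 7)
#' glance(lib)
#' @export
design_library <- function(toxins, k = 12L, step = 2L, force_terminal = FALSE,
                           replicates_wt = 5L, replicates_variant = 1L,
                           drop_wt_collisions = FALSE, seed = 1L) {
  tiles <- tile_toxins(toxins, k = k, step = step,
                       force_terminal = force_terminal)
  uniq <- build_unique_set(tiles)
  variants <- alanine_variants(uniq$peptides$peptide,
                               drop_wt_collisions = drop_wt_collisions)
  variant_peptides <- unique(variants$peptide)
  layout <- assemble_layout(uniq$peptides$peptide, variant_peptides,
                            replicates_wt = replicates_wt,
                            replicates_variant = replicates_variant,
                            seed = seed)
  structure(
    list(
      toxins = toxins,
      occurrences = uniq$occurrences,
      wt = uniq$peptides,
      variants = variants,
      layout = layout,
      redundancy_count = uniq$redundancy_count,
      params = list(k = k, step = step, force_terminal = force_terminal,
                    replicates_wt = replicates_wt,
                    replicates_variant = replicates_variant,
                    drop_wt_collisions = drop_wt_collisions, seed = seed)
    ),
    class = "peptide_library"
  )
}

#' @export
print.peptide_library <- function(x, ...) {
  g <- glance(x)
  cat("<peptide_library>\n",
      "  toxins:          ", g$n_toxins, "\n",
      "  tiles generated: ", g$n_tiles, " (", g$redundancy_count,
      " redundant removed)\n",
      "  unique wt:       ", g$n_wt, " x ", x$params$replicates_wt,
      " replicates\n",
      "  ala variants:    ", g$n_variants, " x ",
      x$params$replicates_variant, " replicate\n",
      "  total spots:     ", g$n_spots, "\n", sep = "")
  invisible(x)
}

#' @rdname design_library
#' @param x A `peptide_library`.
#' @param ... Unused.
#' @method glance peptide_library
#' @export
glance.peptide_library <- function(x, ...) {
  tibble(
    n_toxins = nrow(x$toxins),
    n_tiles = nrow(x$occurrences),
    redundancy_count = x$redundancy_count,
    n_wt = nrow(x$wt),
    n_variants = length(unique(x$variants$peptide)),
    n_unique_peptides = nrow(x$wt) + length(unique(x$variants$peptide)),
    n_spots = nrow(x$layout),
    seed = x$params$seed
  )
}

#' @rdname design_library
#' @method tidy peptide_library
#' @export
tidy.peptide_library <- function(x, ...) {
  x$layout
}

#' Write library design files
#'
#' Writes the randomized layout and the peptide occurrence map as TSV.
#' Layout columns: `spot_index`, `peptide_sequence`, `class` (`wt`/`ala`),
#' `parent_sequence` and `substituted_position` (empty for wild-type
#' spots). Occurrence columns: `peptide_sequence`, `accession`, `start`.
#'
#' @param library A `peptide_library`.
#' @param layout_path,occurrences_path Output TSV paths.
#' @return Invisibly, the layout tibble that was written.
#' @export
write_library <- function(library, layout_path, occurrences_path = NULL) {
  prov <- distinct(library$variants, .data$peptide, .keep_all = TRUE)
  out <- library$layout |>
    left_join(rename(prov, parent_sequence = "parent",
                     substituted_position = "position"),
              by = "peptide") |>
    mutate(
      parent_sequence = ifelse(.data$class == "wt", NA, .data$parent_sequence),
      substituted_position = ifelse(.data$class == "wt", NA,
                                    .data$substituted_position)
    ) |>
    rename(peptide_sequence = "peptide")
  readr::write_tsv(out, layout_path, na = "")
  if (!is.null(occurrences_path)) {
    readr::write_tsv(rename(library$occurrences, peptide_sequence = "peptide"),
                     occurrences_path)
  }
  invisible(out)
}
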