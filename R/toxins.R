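#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   distinct left_join inner_join anti_join semi_join bind_rows n n_distinct
#'   row_number rename count across all_of transmute
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @importFrom utils combn head modifyList
#' @importFrom stats median rnorm sd
NULL

#' @export
generics::tidy

#' @export
generics::glance

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read mature toxin sequences from FASTA
#'
#' Parses a (possibly gapped) protein FASTA file into a tibble of antigen
#' records. The first whitespace-delimited token of each header is taken as
#' the accession; optional `key=value` tags in the remainder of the header
#' (e.g. `species=Dendroaspis_polylepis subfamily=3FTx`) populate the
#' metadata columns, with underscores in values read back as spaces.
#'
#' Sequences are expected to be mature chains (signal and pro-peptides
#' already removed) over the 20-letter amino-acid alphabet. Gap characters
#' (`-`) are only tolerated with `ungap = TRUE`, which strips them — use
#' this to recover plain sequences from an alignment FASTA.
#'
#' @param path Path to a FASTA file.
#' @param ungap Strip `-` gap characters (read an alignment as sequences).
#' @return A tibble with columns `accession`, `species`, `subfamily`,
#'   `sub_subfamily`, `is_fragment`, `sequence`, `length`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">T1 species=Example_snake", "ACDEFGHIKLMN"), fa)
#' read_toxins(fa)
#' @export
read_toxins <- function(path, ungap = FALSE) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    abort(paste0("no sequences found in '", path, "'"))
  }
  headers <- names(aa)
  seqs <- unname(as.character(aa))
  acc <- sub("\\s.*$", "", headers)
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    abort(paste0("duplicate accession(s): ", paste(dup, collapse = ", ")))
  }
  tags <- parse_header_tags(headers)
  if (ungap) seqs <- gsub("-", "", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    check_residues(seqs[[i]], acc[[i]])
  }
  tibble(
    accession = acc,
    species = tags$species,
    subfamily = tags$subfamily,
    sub_subfamily = tags$sub_subfamily,
    is_fragment = tags$is_fragment,
    sequence = unname(seqs),
    length = nchar(seqs)
  )
}

parse_header_tags <- function(headers) {
  get_tag <- function(h, key) {
    m <- regmatches(h, regexpr(paste0("\\b", key, "=\\S+"), h))
    if (length(m) == 0L) return(NA_character_)
    gsub("_", " ", sub(paste0("^", key, "="), "", m))
  }
  species <- vapply(headers, get_tag, character(1), key = "species")
  subfamily <- vapply(headers, get_tag, character(1), key = "subfamily")
  sub_sub <- vapply(headers, get_tag, character(1), key = "sub_subfamily")
  frag <- vapply(headers, get_tag, character(1), key = "is_fragment")
  list(
    species = unname(species),
    subfamily = unname(subfamily),
    sub_subfamily = unname(sub_sub),
    is_fragment = !is.na(frag) & toupper(frag) %in% c("TRUE", "T", "1", "YES")
  )
}

check_residues <- function(sequence, accession) {
  if (nchar(sequence) == 0L) {
    abort(paste0("empty sequence for accession '", accession, "'"))
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(paste0(
      "illegal residue '", chars[bad[1]], "' at position ", bad[1],
      " in accession '", accession, "'"
    ))
  }
  invisible(TRUE)
}

#' Study antigen metadata: mamba and cobra venom toxins
#'
#' Returns the annotation table for the 82 manually curated Dendroaspis
#' (mamba) and African Naja (cobra) venom toxins profiled on the microarray:
#' UniProtKB accession, species, mature-sequence length, protein subfamily
#' and sub-subfamily, and whether the database entry is a fragment.
#' Sequences themselves are not bundled; pair this table with a FASTA of the
#' corresponding mature sequences via [read_toxins()] and
#' [validate_study_sequences()].
#'
#' @return A tibble with columns `species`, `accession`, `length`,
#'   `subfamily`, `sub_subfamily`, `is_fragment`.
#' @examples
#' dplyr::count(study_toxins(), genus = sub(" .*", "", species))
#' @export
study_toxins <- function() {
  path <- system.file("extdata", "study_toxins.tsv", package = "pepscan")
  readr::read_tsv(
    path,
    col_types = readr::cols(
      species = readr::col_character(),
      accession = readr::col_character(),
      length = readr::col_integer(),
      subfamily = readr::col_character(),
      sub_subfamily = readr::col_character(),
      is_fragment = readr::col_logical()
    ),
    progress = FALSE
  )
}

#' Check a sequence set against the study metadata
#'
#' Verifies that a toxin tibble (from [read_toxins()]) carries exactly the
#' accessions of the study table and that every mature-sequence length
#' matches the annotated length. Use after fetching the UniProtKB mature
#' chains to confirm the pro-peptide trimming matches the study's.
#'
#' @param toxins A tibble from [read_toxins()].
#' @param metadata The study table; defaults to [study_toxins()].
#' @return `toxins`, invisibly, if consistent; otherwise an error listing
#'   the first mismatches.
#' @export
validate_study_sequences <- function(toxins, metadata = study_toxins()) {
  missing <- setdiff(metadata$accession, toxins$accession)
  extra <- setdiff(toxins$accession, metadata$accession)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "accession mismatch with study table: ",
      length(missing), " missing, ", length(extra), " unexpected",
      if (length(missing)) paste0(" (first missing: ", missing[1], ")") else ""
    ))
  }
  chk <- inner_join(
    select(toxins, "accession", observed = "length"),
    select(metadata, "accession", expected = "length"),
    by = "accession"
  )
  bad <- filter(chk, .data$observed != .data$expected)
  if (nrow(bad) > 0L) {
    abort(paste0(
      nrow(bad), " sequence length(s) disagree with the study table; first: ",
      bad$accession[1], " observed ", bad$observed[1],
      ", expected ", bad$expected[1]
    ))
  }
  invisible(toxins)
}
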