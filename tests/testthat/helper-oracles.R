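# Independent brute-force oracles and tiny fixture builders. These are kept
# deliberately naive (nested loops, no joins) so they share no code path
# with the implementation they check.

# background threshold recomputed from first principles
oracle_background <- function(medians, percentile = 70, k = 10) {
  m <- sort(medians)
  subset <- m[seq_len(floor(percentile / 100 * length(m)))]
  mu <- sum(subset) / length(subset)
  sigma <- sqrt(sum((subset - mu)^2) / (length(subset) - 1))
  list(mean = mu, sd = sigma, threshold = mu + k * sigma)
}

# residue score by explicit window membership
oracle_residue_score <- function(sequence, occ_starts, occ_medians, k = 12) {
  L <- nchar(sequence)
  scores <- rep(NA_real_, L)
  coverage <- integer(L)
  for (i in seq_len(L)) {
    vals <- c()
    for (j in seq_along(occ_starts)) {
      s <- occ_starts[j]
      if (i >= s && i <= s + k - 1) vals <- c(vals, occ_medians[j])
    }
    coverage[i] <- length(vals)
    if (length(vals) > 0) scores[i] <- mean(vals)
  }
  list(score = scores, coverage = coverage)
}

# exclusive Venn regions by direct enumeration over the universe
oracle_venn3 <- function(a, b, c) {
  u <- unique(c(a, b, c))
  sig <- sapply(u, function(x) {
    paste0(ifelse(x %in% a, "A", ""), ifelse(x %in% b, "B", ""),
           ifelse(x %in% c, "C", ""))
  })
  table(sig)
}

# small fixed toxin set used across tests
fixture_toxins <- function() {
  tibble::tibble(
    accession = c("TX1", "TX2", "TX3"),
    species = "test",
    subfamily = NA_character_,
    sub_subfamily = NA_character_,
    is_fragment = FALSE,
    sequence = c(
      "ACDEFGHIKLMNPQRSTVWYCDEFGHIKLMN",  # 31 aa
      "MNPQRSTVWYACDEFGHIKLMNPQ",         # 24 aa
      "ACDEFGHIKLMNPQRSTVWYCDEFGHIKLMN"   # duplicate of TX1
    ),
    length = c(31L, 24L, 31L)
  )
}

# write a FASTA file for a toxin tibble, returning the path
write_fixture_fasta <- function(toxins, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(mapply(function(acc, s) c(paste0(">", acc), s),
                         toxins$accession, toxins$sequence,
                         SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# noiseless signal table: every replicate equals the peptide's given mean
noiseless_signals <- function(layout, means, experiment_id = "exp") {
  idx <- match(paste(layout$peptide, layout$class),
               paste(means$peptide, means$class))
  tibble::tibble(
    experiment_id = experiment_id,
    peptide = layout$peptide,
    class = layout$class,
    replicate = layout$replicate,
    intensity = means$mean[idx]
  )
}

# a minimal but well-formed PDB text: CA+CB atoms for `n` residues, chain A
fixture_pdb_lines <- function(n = 8, chain = "A", b = 10) {
  lines <- c("HEADER    TEST STRUCTURE", "REMARK    synthetic fixture")
  serial <- 0L
  for (r in seq_len(n)) {
    for (atom in c("CA", "CB")) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, atom, chain, r, r * 1.5, r * 0.5, 0, 1.00, b
      ))
    }
  }
  c(lines, "END")
}
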