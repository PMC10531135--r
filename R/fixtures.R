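# Community-simulator stand-in: synthetic 16S-like references and error-free community
# amplicon reads, so the simulator and trainer are testable with no downloads.

#' Mock-community abundance profiles
#'
#' Relative abundances of the eight bacterial species of a standard
#' mock community, as used for read simulation (computed from mapped real
#' data rather than the supplier's nominal proportions).
#'
#' @param lot One of `"v1"`, `"v2"` (default) or `"v2_filtered"` (a
#'   length-filtered v2 run with markedly different observed abundances).
#' @return A tibble with columns `taxon` and `abundance` (fractions summing
#'   to 1).
#' @export
mock_community_profile <- function(lot = c("v2", "v1", "v2_filtered")) {
  lot <- match.arg(lot)
  taxa <- c("Lactobacillus_fermentum", "Listeria_monocytogenes",
            "Bacillus_subtilis", "Staphylococcus_aureus",
            "Salmonella_enterica", "Enterococcus_faecalis",
            "Escherichia_coli", "Pseudomonas_aeruginosa")
  ab <- switch(lot,
    v1 = c(0.08, 0.14, 0.21, 0.18, 0.16, 0.10, 0.12, 0.01),
    v2 = c(0.10, 0.13, 0.18, 0.18, 0.15, 0.08, 0.16, 0.02),
    v2_filtered = c(0.05, 0.07, 0.13, 0.09, 0.30, 0.05, 0.30, 0.01))
  tibble(taxon = taxa, abundance = ab)
}

validate_abundances <- function(abundances) {
  if (!is.data.frame(abundances) ||
      !all(c("taxon", "abundance") %in% names(abundances)))
    rlang::abort("`abundances` must be a tibble with columns taxon and abundance.")
  if (any(abundances$abundance < 0))
    rlang::abort("Abundances must be non-negative.")
  if (abs(sum(abundances$abundance) - 1) > 1e-9)
    rlang::abort("Abundances must sum to 1 (within 1e-9).")
  if (anyDuplicated(abundances$taxon))
    rlang::abort("Duplicate taxon in abundance profile.")
  invisible(abundances)
}

#' Generate synthetic full-length marker reference sequences
#'
#' One random ancestor sequence is mutated independently per taxon at the
#' given per-site substitution fraction, giving a set of ~16S-length
#' references whose pairwise identity stays below a configurable ceiling so
#' species remain distinguishable.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param length Reference length in bases (default 1500, full-length 16S).
#' @param divergence Per-site substitution fraction in (0, 0.5) applied
#'   independently to each taxon's copy of the ancestor.
#' @param seed Integer seed; the same seed reproduces the references exactly.
#' @param taxa Optional character vector of taxon ids (default
#'   `taxon_01`, ...).
#' @param max_identity Pairwise-identity ceiling (default 0.97). If 100
#'   mutation attempts cannot satisfy it, an error is thrown.
#' @return A tibble with columns `id` and `sequence`.
#' @export
generate_references <- function(n_taxa, length = 1500L, divergence = 0.05,
                                seed = NULL, taxa = NULL, max_identity = 0.97) {
  assert_count(n_taxa, "n_taxa")
  assert_count(length, "length")
  if (!is.numeric(divergence) || divergence <= 0 || divergence >= 0.5)
    rlang::abort("`divergence` must be in (0, 0.5).")
  if (is.null(taxa)) taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  if (base::length(taxa) != n_taxa) rlang::abort("`taxa` must have length n_taxa.")

  with_seed(seed, {
    ancestor <- sample(DNA_BASES, length, replace = TRUE)
    if (n_taxa == 1L)
      return(tibble(id = taxa, sequence = paste(ancestor, collapse = "")))
    for (attempt in seq_len(100L)) {
      mat <- vapply(seq_len(n_taxa), function(i) {
        s <- ancestor
        hit <- runif(length) < divergence
        k <- sum(hit)
        if (k) {
          shift <- sample.int(3L, k, replace = TRUE)
          cur <- match(s[hit], DNA_BASES)
          s[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
        }
        s
      }, character(length))
      ok <- TRUE
      for (i in seq_len(n_taxa - 1L)) {
        ident <- colMeans(mat[, i] == mat[, (i + 1L):n_taxa, drop = FALSE])
        if (any(ident > max_identity)) { ok <- FALSE; break }
      }
      if (ok)
        return(tibble(id = taxa,
                      sequence = apply(mat, 2L, paste, collapse = "")))
    }
    rlang::abort("Could not satisfy the pairwise-identity ceiling in 100 attempts; increase `divergence`.")
  })
}

#' Generate error-free amplicon reads from references and abundances
#'
#' Emulates community amplicon simulation with length bias, copy bias and
#' truncation all disabled: each read is the full, unmutated reference
#' sequence of a taxon drawn i.i.d. from the abundance profile.
#'
#' @param refs Reference tibble (`id`, `sequence`), e.g. from
#'   [generate_references()].
#' @param abundances Tibble (`taxon`, `abundance`); taxa must be a subset of
#'   the reference ids.
#' @param n_reads Number of reads to generate (> 0).
#' @param seed Integer seed for the multinomial taxon draw.
#' @return A tibble of error-free reads: `id`, `sequence`, `taxon`, and
#'   zeroed annotation columns `n_ins`, `n_del`, `n_sub` (`category` is `NA`
#'   until the length model runs).
#' @export
generate_amplicons <- function(refs, abundances, n_reads, seed = NULL) {
  assert_reads_tbl(refs)
  validate_abundances(abundances)
  assert_count(n_reads, "n_reads")
  missing <- setdiff(abundances$taxon, refs$id)
  if (length(missing))
    rlang::abort(paste0("Abundance taxa absent from references: ",
                        paste(missing, collapse = ", ")))
  with_seed(seed, {
    taxa <- sample(abundances$taxon, n_reads, replace = TRUE,
                   prob = abundances$abundance)
    tibble(
      id = sprintf("read_%06d", seq_len(n_reads)),
      sequence = refs$sequence[match(taxa, refs$id)],
      taxon = taxa,
      n_ins = 0L, n_del = 0L, n_sub = 0L,
      category = NA_character_)
  })
}

#' Write the read-to-taxon truth table
#'
#' @param reads Read tibble with `id` and `taxon` columns.
#' @param path Output TSV path (two columns, `read_id` and `taxon`, with a
#'   header line).
#' @export
write_truth_table <- function(reads, path) {
  assert_reads_tbl(reads, need = c("id", "taxon"))
  utils::write.table(
    data.frame(read_id = reads$id, taxon = reads$taxon),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "character"))
}
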