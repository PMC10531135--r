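# Validation metrics: error rate, percent unmapped, identity, species-level
# precision/recall, length summaries.

#' Overall sequencing error rate from alignments
#'
#' `100 * sum(mismatch + ins + del) / sum(match + mismatch + ins + del)` over
#' mapped primary alignments.
#'
#' @param alignments Alignment-summary tibble ([parse_sam()]).
#' @return Error rate in percent.
#' @export
error_rate <- function(alignments) {
  m <- dplyr::filter(alignments, .data$mapped)
  if (nrow(m) == 0L) rlang::abort("No mapped alignments.")
  err <- sum(m$n_mismatch) + sum(m$n_ins) + sum(m$n_del)
  cols <- sum(m$n_match) + err
  100 * err / cols
}

#' Percentage of unmapped reads
#'
#' @param alignments Alignment-summary tibble.
#' @return `100 * #unmapped primary / #primary`.
#' @export
pct_unmapped <- function(alignments) {
  if (nrow(alignments) == 0L) rlang::abort("No alignment records.")
  100 * sum(!alignments$mapped) / nrow(alignments)
}

#' Per-read identity mean and SD
#'
#' Identity is `100 * match / (match + mismatch + ins + del)` per mapped
#' read.
#'
#' @param alignments Alignment-summary tibble.
#' @param sd_type `"population"` (default, matching typical read-stat
#'   reporting) or `"sample"`.
#' @return A one-row tibble with `identity_mean` and `identity_sd`.
#' @export
identity_summary <- function(alignments, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- dplyr::filter(alignments, .data$mapped)
  if (nrow(m) == 0L) rlang::abort("No mapped alignments.")
  identity <- 100 * m$n_match / (m$n_match + m$n_mismatch + m$n_ins + m$n_del)
  tibble(identity_mean = mean(identity),
         identity_sd = pop_or_sample_sd(identity, sd_type))
}

pop_or_sample_sd <- function(x, sd_type) {
  if (length(x) < 2L) rlang::abort("At least 2 values are needed for an SD.")
  if (sd_type == "population")
    sqrt(mean((x - mean(x))^2))
  else
    sd(x)
}

#' Species-level precision and recall
#'
#' With true positives being reads assigned to one of the community's
#' species: precision = TP / #assigned reads, recall = TP / #reads.
#' Precision is always >= recall since assigned reads are a subset of all
#' reads.
#'
#' @param assignments Tibble with columns `read_id` and `species` (`NA` =
#'   unassigned), e.g. from [assign_species()].
#' @param truth_species Character vector of the community's species.
#' @return A one-row tibble with `precision`, `recall`, `tp`, `n_assigned`,
#'   `n_reads`. Errors when no read is assigned (precision undefined).
#' @export
precision_recall <- function(assignments, truth_species) {
  if (!is.data.frame(assignments) ||
      !all(c("read_id", "species") %in% names(assignments)))
    rlang::abort("`assignments` must have columns read_id and species.")
  n_total <- nrow(assignments)
  if (n_total == 0L) rlang::abort("No reads in `assignments`.")
  assigned <- !is.na(assignments$species) & assignments$species != ""
  n_assigned <- sum(assigned)
  if (n_assigned == 0L)
    rlang::abort("No read is assigned; precision is undefined.")
  tp <- sum(assignments$species[assigned] %in% truth_species)
  tibble(precision = tp / n_assigned, recall = tp / n_total,
         tp = tp, n_assigned = n_assigned, n_reads = n_total)
}

#' Species assignment from alignments
#'
#' Each read is assigned the species label of its primary alignment target
#' (ties between multiple primary records are broken by first occurrence);
#' unmapped reads are unassigned.
#'
#' @param alignments Alignment-summary tibble.
#' @param species_map Optional tibble (`target_id`, `species`) translating
#'   alignment targets to species labels; by default the target id is the
#'   species.
#' @return Tibble with `read_id` and `species` (`NA` if unassigned).
#' @export
assign_species <- function(alignments, species_map = NULL) {
  first <- alignments[!duplicated(alignments$read_id), ]
  species <- ifelse(first$mapped, first$target_id, NA_character_)
  if (!is.null(species_map))
    species <- species_map$species[match(species, species_map$target_id)]
  tibble(read_id = first$read_id, species = species)
}

#' Read-length mean and SD
#'
#' @param reads Read tibble (`sequence` column) or a numeric vector of
#'   lengths.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return One-row tibble with `length_mean` and `length_sd`.
#' @export
length_summary <- function(reads, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  lengths <- if (is.numeric(reads)) reads else {
    assert_reads_tbl(reads, need = "sequence")
    nchar(reads$sequence)
  }
  if (length(lengths) < 2L)
    rlang::abort("At least 2 reads are needed for a length summary.")
  tibble(length_mean = mean(lengths),
         length_sd = pop_or_sample_sd(lengths, sd_type))
}

#' Full fidelity report for a simulated (or real) dataset
#'
#' Combines the alignment-derived metrics (error rate, percent unmapped,
#' identity mean/SD) with species-level precision/recall against a truth
#' table and, when reads are given, the length summary — one row in the
#' layout used for mock-community validation tables.
#'
#' @param alignments Alignment-summary tibble.
#' @param truth Optional truth tibble (`read_id`, `taxon`); its distinct
#'   taxa define the community species set.
#' @param reads Optional read tibble for the length summary.
#' @param species_map Optional target-to-species map for [assign_species()].
#' @param sd_type Passed to the SD computations.
#' @return A one-row tibble of metrics.
#' @export
evaluate_run <- function(alignments, truth = NULL, reads = NULL,
                         species_map = NULL,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  out <- tibble(error_rate = error_rate(alignments),
                pct_unmapped = pct_unmapped(alignments))
  out <- dplyr::bind_cols(out, identity_summary(alignments, sd_type))
  if (!is.null(truth)) {
    pr <- precision_recall(assign_species(alignments, species_map),
                           unique(truth$taxon))
    out$precision <- pr$precision
    out$recall <- pr$recall
  }
  if (!is.null(reads))
    out <- dplyr::bind_cols(out, length_summary(reads, sd_type))
  out
}
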