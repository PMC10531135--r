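# End-to-end read simulation pipeline.

#' Default per-read error-rate distribution
#'
#' Exponentiated Weibull parameters giving a mean per-read error rate of
#' about 14.5% with most mass between 8% and 20%, typical of R9.4.1 nanopore
#' 16S metabarcoding runs. Used when no trained model or profile file is
#' supplied.
#'
#' @return An [exp_weibull_params()] object.
#' @export
default_error_model <- function() {
  exp_weibull_params(a = 1.3, c = 2.2, loc = 5, scale = 9.7)
}

#' Simulate nanopore metabarcoding reads
#'
#' The full simulation pipeline applied to error-free amplicon reads:
#' 1. a per-read error profile is drawn from the exponentiated Weibull
#'    error-rate law and the error-type split (unless a profile is given);
#' 2. insertions, deletions (homopolymer-biased) and substitutions are
#'    injected ([inject_errors()]);
#' 3. reads are reshaped into the six length categories ([apply_length()]);
#' 4. optionally, `ceiling(random_fraction/100 * n)` fully random reads are
#'    appended ([generate_random_reads()]).
#'
#' All stages draw from deterministic sub-streams of `seed`, so a fixed seed
#' reproduces the output exactly.
#'
#' @param reads Error-free read tibble (`id`, `sequence`, ...), e.g. from
#'   [generate_amplicons()] or [read_fastq()].
#' @param profile Optional profile tibble (one row per read); overrides `ew`
#'   and `split`.
#' @param ew [exp_weibull_params()] for the error-rate draw (default
#'   [default_error_model()]).
#' @param split [error_type_split()] (default 0.28/0.42/0.30).
#' @param lengths [length_params()] mixture (default (67, 21, 1, 9, 2, 0)),
#'   or the bracketed string form `"[67,21,1,9,2,0]"`.
#' @param random_fraction Percentage of random reads to append (default 0).
#' @param seed Integer seed (NULL = current RNG stream).
#' @param run_weight_exponent Homopolymer bias exponent for the injector.
#' @param pad_strategy Read-lengthening strategy, see [apply_length()].
#' @param keep_log Attach the edit log (attribute `"edit_log"`).
#' @return A read tibble with `id`, `sequence`, `taxon`, realized `n_ins`,
#'   `n_del`, `n_sub`, `category`, and `template_length` (the error-free
#'   input length, 0 for random reads).
#' @examples
#' refs <- generate_references(2, length = 300, divergence = 0.1, seed = 1)
#' amp <- generate_amplicons(refs, tibble::tibble(taxon = refs$id,
#'                                                abundance = c(0.5, 0.5)),
#'                           n_reads = 5, seed = 2)
#' simulate_reads(amp, profile = constant_profile(5, 10), seed = 3)
#' @export
simulate_reads <- function(reads, profile = NULL, ew = default_error_model(),
                           split = error_type_split(),
                           lengths = length_params(), random_fraction = 0,
                           seed = NULL, run_weight_exponent = 1,
                           pad_strategy = "pad-random", keep_log = FALSE) {
  assert_reads_tbl(reads)
  if (!is.numeric(random_fraction) || random_fraction < 0 || random_fraction > 100)
    rlang::abort("`random_fraction` must be a percentage in [0, 100].")
  lengths <- if (inherits(lengths, "length_params")) lengths else
    parse_length_params(lengths)
  n <- nrow(reads)
  if (n == 0L) rlang::abort("`reads` is empty.")

  if (is.null(profile))
    profile <- make_profile(n, ew, split, seed = sub_seed(seed, 1L))
  validate_profile(profile)
  if (nrow(profile) != n)
    rlang::abort("`profile` must have one row per read.")

  reads$template_length <- nchar(reads$sequence)
  out <- inject_errors(reads, profile, seed = sub_seed(seed, 2L),
                       run_weight_exponent = run_weight_exponent,
                       keep_log = keep_log)
  log <- attr(out, "edit_log")
  cats <- sample_categories(n, lengths, seed = sub_seed(seed, 3L))
  out <- apply_length(out, categories = cats, seed = sub_seed(seed, 4L),
                      pad_strategy = pad_strategy)

  if (random_fraction > 0) {
    k <- as.integer(ceiling(random_fraction / 100 * n))
    rnd <- generate_random_reads(k, lengths, seed = sub_seed(seed, 5L))
    rnd$template_length <- 0L
    if (!"taxon" %in% names(out)) out$taxon <- NA_character_
    out <- bind_rows(out, rnd)
  }
  if (keep_log) attr(out, "edit_log") <- log
  out
}

#' Write a plain-text parameter log
#'
#' Flattens a named list of effective parameters into `key: value` lines for
#' run auditing.
#'
#' @param params Named list (nested lists are flattened with `.`-joined keys).
#' @param path Output path.
#' @export
write_param_log <- function(params, path) {
  flatten <- function(x, prefix = "") {
    out <- character()
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      v <- x[[nm]]
      if (is.list(v) && !is.null(names(v))) {
        out <- c(out, flatten(v, key))
      } else {
        out <- c(out, paste0(key, ": ", paste(format(unclass(v)), collapse = ", ")))
      }
    }
    out
  }
  writeLines(flatten(params), path)
  invisible(path)
}
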