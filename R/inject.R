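# Error injector: homopolymer-biased indels, then uniform substitutions.

#' Find maximal homopolymer runs
#'
#' Decomposes a sequence into its maximal runs of identical bases, left to
#' right. Runs tile the sequence: starts are 1-based and consecutive run
#' lengths sum to the sequence length.
#'
#' @param sequence A non-empty ACGT string.
#' @return A tibble with columns `start` (1-based), `length`, `base`.
#' @examples
#' find_homopolymers("AAACCG")
#' @export
find_homopolymers <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    rlang::abort("`sequence` must be a single non-empty string.")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_BASES))
    rlang::abort("`sequence` contains non-ACGT characters.")
  r <- rle(chars)
  len <- r$lengths
  tibble(start = c(1L, head(cumsum(len), -1L) + 1L),
         length = as.integer(len),
         base = r$values)
}

#' Introduce sequencing errors into error-free reads
#'
#' For each read, target edit counts are realized from its profile entry as
#' `k = round(L * pct / 100)` per error type, where `L` is the input read
#' length. Insertions and deletions are placed first by an iterative
#' algorithm: each indel event selects a homopolymer run with probability
#' proportional to `length^run_weight_exponent` (weights recomputed as runs
#' change), a deletion removing one base of the chosen run and an insertion
#' duplicating the run's base inside the run — the classic nanopore
#' homopolymer miscount. Substitutions are then drawn uniformly at distinct
#' positions of the post-indel sequence, each base replaced by one of the
#' other three (the substitution count is capped at the current read length).
#'
#' @param reads Read tibble (`id`, `sequence`, ...), e.g. from
#'   [generate_amplicons()].
#' @param profile Profile tibble (`ins_pct`, `del_pct`, `sub_pct`) with one
#'   row per read, e.g. from [make_profile()].
#' @param seed Integer seed (NULL = use current RNG stream).
#' @param run_weight_exponent Exponent on run length in the indel placement
#'   weight (default 1 = linear bias towards longer homopolymers).
#' @param keep_log If `TRUE`, attach the per-read edit log (see
#'   [replay_edits()]) as attribute `"edit_log"` of the result.
#' @return The read tibble with mutated `sequence` and realized counts in
#'   `n_ins`, `n_del`, `n_sub`. Output length = input length + n_ins - n_del.
#' @export
inject_errors <- function(reads, profile, seed = NULL,
                          run_weight_exponent = 1, keep_log = FALSE) {
  assert_reads_tbl(reads)
  validate_profile(profile)
  if (nrow(profile) != nrow(reads))
    rlang::abort("`profile` must have exactly one row per read.")
  if (!is.numeric(run_weight_exponent) || run_weight_exponent < 0)
    rlang::abort("`run_weight_exponent` must be >= 0.")

  L <- nchar(reads$sequence)
  k_ins <- as.integer(round(L * profile$ins_pct / 100))
  k_del <- as.integer(round(L * profile$del_pct / 100))
  k_sub <- as.integer(round(L * profile$sub_pct / 100))
  bad <- which(k_del >= L)
  if (length(bad))
    rlang::abort(sprintf(
      "Read '%s': %d deletions requested for a %d-base read (read would vanish).",
      reads$id[bad[1L]], k_del[bad[1L]], L[bad[1L]]))

  res <- with_seed(seed,
    cpp_inject(reads$sequence, k_ins, k_del, k_sub,
               as.double(run_weight_exponent), isTRUE(keep_log)))

  out <- reads
  out$sequence <- res$sequence
  out$n_ins <- k_ins
  out$n_del <- k_del
  out$n_sub <- pmin(k_sub, L + k_ins - k_del)
  if (isTRUE(keep_log)) {
    log <- tibble(
      read = res$log_read,
      read_id = reads$id[res$log_read],
      kind = c("ins", "del", "sub")[res$log_kind + 1L],
      pos = res$log_pos,
      base = DNA_BASES[res$log_base + 1L])
    attr(out, "edit_log") <- log
  }
  out
}

#' Replay an edit log
#'
#' Applies the ordered edit operations of one read's log to its source
#' sequence. Positions are 1-based and refer to the sequence as it stands
#' when each operation is applied, so sequential replay reproduces the
#' injector's output exactly.
#'
#' @param sequence Source sequence (string).
#' @param log Edit-log tibble for one read, with columns `kind`
#'   (`ins`/`del`/`sub`), `pos` and `base`, in application order.
#' @return The edited sequence (string).
#' @export
replay_edits <- function(sequence, log) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(log))) {
    kind <- log$kind[i]; pos <- log$pos[i]
    if (kind == "ins") {
      s <- append(s, log$base[i], after = pos - 1L)
    } else if (kind == "del") {
      s <- s[-pos]
    } else if (kind == "sub") {
      s[pos] <- log$base[i]
    } else {
      rlang::abort(paste0("Unknown edit kind: ", kind))
    }
  }
  paste(s, collapse = "")
}

#' Verify an injected read against its edit log
#'
#' Returns `TRUE` iff replaying `log` on `source` yields `output` and, when
#' expected counts are supplied, the per-kind tallies of the log equal them.
#'
#' @param source,output Source and edited sequences (strings).
#' @param log Edit-log tibble as produced by [inject_errors()].
#' @param n_ins,n_del,n_sub Optional expected counts (e.g. the title-line
#'   annotation values).
#' @return Logical scalar; `FALSE` on any mismatch (never throws).
#' @export
verify_edit_counts <- function(source, output, log,
                               n_ins = NULL, n_del = NULL, n_sub = NULL) {
  replayed <- tryCatch(replay_edits(source, log), error = function(e) NULL)
  if (is.null(replayed) || !identical(replayed, output)) return(FALSE)
  tally <- table(factor(log$kind, levels = c("ins", "del", "sub")))
  if (!is.null(n_ins) && tally[["ins"]] != n_ins) return(FALSE)
  if (!is.null(n_del) && tally[["del"]] != n_del) return(FALSE)
  if (!is.null(n_sub) && tally[["sub"]] != n_sub) return(FALSE)
  TRUE
}
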