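#' Read or write a per-read error profile file
#'
#' A profile file has one line per simulated read, holding the percentages of
#' insertions, deletions and substitutions (of read length) to introduce into
#' that read, as three comma-separated decimals written with 4 decimal places.
#' Line order equals the read order of the input FASTQ.
#'
#' @param path Profile file path.
#' @return `read_profile()` returns a tibble with columns `ins_pct`,
#'   `del_pct`, `sub_pct`.
#' @examples
#' tf <- tempfile()
#' write_profile(tibble::tibble(ins_pct = 4.06, del_pct = 6.09, sub_pct = 4.35), tf)
#' readLines(tf)
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("Profile file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(tibble(ins_pct = double(), del_pct = double(), sub_pct = double()))
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    rlang::abort(sprintf("Profile line %d does not have 3 comma-separated fields.",
                         bad[1L]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    rlang::abort(sprintf("Profile line %d contains a non-numeric field.", bad))
  }
  out <- tibble(ins_pct = m[, 1L], del_pct = m[, 2L], sub_pct = m[, 3L])
  validate_profile(out)
  out
}

#' @rdname read_profile
#' @param entries Tibble with columns `ins_pct`, `del_pct`, `sub_pct`.
#' @export
write_profile <- function(entries, path) {
  validate_profile(entries)
  lines <- sprintf("%.4f,%.4f,%.4f", entries$ins_pct, entries$del_pct,
                   entries$sub_pct)
  writeLines(lines, path)
  invisible(path)
}

validate_profile <- function(entries) {
  if (!is.data.frame(entries) ||
      !all(c("ins_pct", "del_pct", "sub_pct") %in% names(entries)))
    rlang::abort("Profile must have columns ins_pct, del_pct, sub_pct.")
  with(entries, {
    if (any(ins_pct < 0 | del_pct < 0 | sub_pct < 0))
      rlang::abort("Profile percentages must be non-negative.")
    if (any(ins_pct + del_pct + sub_pct > 100 + 1e-9))
      rlang::abort("Profile percentages must sum to at most 100 per read.")
  })
  invisible(entries)
}
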