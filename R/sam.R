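#' Summarise a SAM/BAM alignment file per primary record
#'
#' Consumes the subset of SAM needed for error-model training and evaluation:
#' one row per primary record (secondary 0x100 and supplementary 0x800 records
#' are skipped), with per-read match / mismatch / insertion / deletion base
#' counts derived from the CIGAR string and the `NM` tag. Hard- and
#' soft-clipped bases are not aligned columns and are excluded from the error
#' accounting. When an `MD` tag is present the mismatch count is cross-checked
#' against it and, on conflict, the MD-derived count is used (a single warning
#' reports how many records disagreed).
#'
#' @param path A SAM (text) or BAM file. SAM input is converted on the fly
#'   with [Rsamtools::asBam()].
#' @return A tibble with columns `read_id`, `mapped`, `target_id` (empty
#'   string if unmapped), `read_length`, `n_match`, `n_mismatch`, `n_ins`,
#'   `n_del`. Counts are all zero for unmapped reads. `n_mismatch` is
#'   `NM - n_ins - n_del`; `n_match` is the M/=/X column count minus
#'   `n_mismatch`.
#' @export
parse_sam <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("Alignment file not found: ", path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "cigar", "qwidth"),
    tag = c("NM", "MD"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]

  n <- length(res$qname)
  mapped <- !bitwAnd(res$flag, 4L)
  read_length <- ifelse(is.na(res$qwidth), 0L, res$qwidth)
  n_ins <- integer(n); n_del <- integer(n)
  n_mm <- integer(n); n_match <- integer(n)

  if (any(mapped)) {
    cig <- res$cigar[mapped]
    if (anyNA(cig))
      rlang::abort("Mapped record without a CIGAR string.")
    ops <- GenomicAlignments::cigarOpTable(cig)
    ins <- ops[, "I"]
    del <- ops[, "D"]
    mcols <- ops[, "M"] + ops[, "="] + ops[, "X"]
    nm <- if (is.null(res$tag$NM)) rep(NA_integer_, sum(mapped)) else
      res$tag$NM[mapped]
    if (anyNA(nm)) {
      bad <- res$qname[mapped][which(is.na(nm))[1L]]
      rlang::abort(paste0("Mapped record missing NM tag: ", bad))
    }
    mm <- nm - ins - del
    md <- res$tag$MD[mapped]
    if (!is.null(md) && any(!is.na(md))) {
      md_mm <- md_mismatch_count(md)
      conflict <- !is.na(md_mm) & md_mm != mm
      if (any(conflict)) {
        rlang::warn(sprintf(
          "NM/MD mismatch-count conflict in %d record(s); trusting MD.",
          sum(conflict)))
        mm[conflict] <- md_mm[conflict]
      }
    }
    if (any(mm < 0)) {
      bad <- res$qname[mapped][which(mm < 0)[1L]]
      rlang::abort(paste0("Inconsistent NM/CIGAR (negative mismatch count) for read: ", bad))
    }
    if (any(mm > mcols)) {
      bad <- res$qname[mapped][which(mm > mcols)[1L]]
      rlang::abort(paste0("Mismatch count exceeds aligned columns for read: ", bad))
    }
    n_ins[mapped] <- ins
    n_del[mapped] <- del
    n_mm[mapped] <- mm
    n_match[mapped] <- mcols - mm
  }

  tibble(
    read_id = res$qname,
    mapped = mapped,
    target_id = ifelse(mapped, as.character(res$rname), ""),
    read_length = as.integer(read_length),
    n_match = n_match,
    n_mismatch = n_mm,
    n_ins = n_ins,
    n_del = n_del)
}

# Mismatches encoded in an MD tag: single reference letters outside ^-prefixed
# deletion groups.
md_mismatch_count <- function(md) {
  vapply(md, function(x) {
    if (is.na(x)) return(NA_integer_)
    x <- gsub("\\^[A-Za-z]+", "", x)
    sum(stringr::str_count(x, "[A-Za-z]"))
  }, integer(1L), USE.NAMES = FALSE)
}
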