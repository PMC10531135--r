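#' Read a FASTQ file into a tibble
#'
#' Reads 4-line FASTQ records (phred+33 qualities). The simulator's title-line
#' annotation convention (`nbIns=<i> nbDel=<d> nbSub=<s> cat=<category>`,
#' optionally preceded by `taxon=<t>`) is parsed into columns when present.
#'
#' @param path Path to a FASTQ file.
#' @param parse_annotations If `TRUE` (default), extract `n_ins`, `n_del`,
#'   `n_sub`, `category` and `taxon` columns from the title lines where the
#'   annotation tokens are present (`NA` otherwise).
#' @return A tibble with one row per read: `id` (first whitespace-delimited
#'   token of the title line), `sequence`, `quality` (the phred+33 string),
#'   `description` (title-line remainder) and, if requested, the annotation
#'   columns.
#' @examples
#' tf <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1 nbIns=1 nbDel=0 nbSub=2 cat=gauss", "ACGT", "+", "))))"), tf)
#' read_fastq(tf)
#' @export
read_fastq <- function(path, parse_annotations = TRUE) {
  if (!file.exists(path)) rlang::abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    out <- tibble(id = character(), sequence = character(),
                  quality = character(), description = character())
    if (parse_annotations) out <- parse_read_annotations(out)
    return(out)
  }
  if (length(lines) %% 4L != 0L)
    rlang::abort("Malformed FASTQ: number of lines is not a multiple of 4.")
  title <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]

  bad <- which(!startsWith(title, "@"))
  if (length(bad))
    rlang::abort(sprintf("Malformed FASTQ record %d: title line does not start with '@'.",
                         bad[1L]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    rlang::abort(sprintf("Malformed FASTQ record %d: separator line does not start with '+'.",
                         bad[1L]))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    id_bad <- sub("\\s.*$", "", sub("^@", "", title[bad[1L]]))
    rlang::abort(sprintf(
      "Malformed FASTQ record '%s': sequence and quality lengths differ (%d vs %d).",
      id_bad, nchar(seqs[bad[1L]]), nchar(qual[bad[1L]])))
  }
  header <- sub("^@", "", title)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  if (anyDuplicated(id))
    rlang::warn("Duplicate read ids in FASTQ file.")
  out <- tibble(id = id, sequence = seqs, quality = qual, description = desc)
  if (parse_annotations) out <- parse_read_annotations(out)
  out
}

# Pull nbIns/nbDel/nbSub/cat/taxon tokens out of the description column.
parse_read_annotations <- function(reads) {
  grab <- function(key, desc) {
    m <- stringr::str_match(desc, paste0("(?:^|\\s)", key, "=(\\S+)"))[, 2L]
    m
  }
  desc <- if (nrow(reads)) reads$description else character()
  reads$n_ins <- as.integer(grab("nbIns", desc))
  reads$n_del <- as.integer(grab("nbDel", desc))
  reads$n_sub <- as.integer(grab("nbSub", desc))
  reads$category <- grab("cat", desc)
  reads$taxon <- grab("taxon", desc)
  reads
}

# Compose the canonical title-line suffix for one read row.
format_read_annotation <- function(n_ins, n_del, n_sub, category, taxon = NA) {
  ann <- sprintf("nbIns=%d nbDel=%d nbSub=%d cat=%s", n_ins, n_del, n_sub, category)
  ifelse(is.na(taxon) | taxon == "", ann, paste0("taxon=", taxon, " ", ann))
}

#' Write reads to FASTQ with a fixed quality value
#'
#' Every base receives the same phred quality (default 8, the usual quality
#' threshold in nanopore metabarcoding analyses), encoded as `chr(quality+33)`.
#' When the annotation columns `n_ins`, `n_del`, `n_sub` and `category` are
#' present, the canonical annotation `nbIns=<i> nbDel=<d> nbSub=<s>
#' cat=<category>` is appended to each title line (preceded by `taxon=<t>`
#' when a `taxon` column is present).
#'
#' @param reads Tibble with columns `id`, `sequence` and optionally the
#'   annotation columns.
#' @param path Output file path.
#' @param quality Single phred score in `[0, 93]` applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = 8L) {
  assert_reads_tbl(reads)
  if (!is.numeric(quality) || length(quality) != 1L || quality < 0 || quality > 93)
    rlang::abort("`quality` must be a single phred score in [0, 93].")
  qchar <- rawToChar(as.raw(as.integer(quality) + 33L))
  n <- nrow(reads)
  header <- paste0("@", reads$id)
  has_ann <- all(c("n_ins", "n_del", "n_sub", "category") %in% names(reads)) &&
    n > 0 && !anyNA(reads$category)
  if (has_ann) {
    taxon <- if ("taxon" %in% names(reads)) reads$taxon else rep(NA_character_, n)
    header <- paste(header, format_read_annotation(reads$n_ins, reads$n_del,
                                                   reads$n_sub, reads$category,
                                                   taxon))
  }
  qual <- strrep(qchar, nchar(reads$sequence))
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, 4L * n, by = 4L)] <- header
    lines[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- qual
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write FASTA via Biostrings
#'
#' Thin tibble-facing wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()].
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}

#' @rdname read_fasta
#' @param seqs Tibble with columns `id` and `sequence`.
#' @export
write_fasta <- function(seqs, path) {
  assert_reads_tbl(seqs)
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
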