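# Shared fixture builders; everything is generated in code at test time.

# Small mock community: references + error-free amplicons.
make_community <- function(n_reads = 500L, n_taxa = 8L, len = 1500L,
                           seed = 101L) {
  ab <- mock_community_profile("v2")[seq_len(n_taxa), ]
  ab$abundance <- ab$abundance / sum(ab$abundance)
  refs <- generate_references(n_taxa, length = len, divergence = 0.05,
                              seed = seed, taxa = ab$taxon)
  amp <- generate_amplicons(refs, ab, n_reads, seed = seed + 1L)
  list(refs = refs, abundances = ab, reads = amp)
}

# Write a SAM file from a tibble of record fields (header included).
write_sam_file <- function(records, path, refs = c(refA = 2000L, refB = 2000L)) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    qlen <- nchar(r$seq)
    fields <- c(r$qname, r$flag, r$rname, r$pos, "60", r$cigar, "*", "0", "0",
                r$seq, strrep("I", qlen))
    if (!is.na(r$nm)) fields <- c(fields, sprintf("NM:i:%d", r$nm))
    if ("md" %in% names(records) && !is.na(r$md))
      fields <- c(fields, sprintf("MD:Z:%s", r$md))
    paste(fields, collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  path
}

# Synthesize a SAM of n mapped reads with per-read error counts drawn around
# ONT-like rates; returns the path and the per-read truth counts.
synth_training_sam <- function(n = 200L, path = tempfile(fileext = ".sam"),
                               seed = 7L, rate_mean = 14) {
  withr::with_seed(seed, {
    L <- 1400L + sample.int(200L, n, replace = TRUE)
    rate <- pmax(rnorm(n, rate_mean, 2), 2) / 100
    k <- round(L * rate)
    k_ins <- round(0.28 * k); k_del <- round(0.42 * k)
    k_mm <- k - k_ins - k_del
    m <- L - k_del - k_mm  # matches
    recs <- tibble::tibble(
      qname = sprintf("real_%04d", seq_len(n)),
      flag = "0",
      rname = sample(c("refA", "refB"), n, replace = TRUE),
      pos = "1",
      cigar = sprintf("%dM%dI%dM%dD%dM", 10L, k_ins, m + k_mm - 20L, k_del, 10L),
      seq = vapply(10L + k_ins + (m + k_mm - 20L) + 10L,
                   function(l) paste(sample(c("A", "C", "G", "T"), l,
                                            replace = TRUE), collapse = ""),
                   character(1L)),
      nm = k_ins + k_del + k_mm,
      md = NA_character_)
    list(path = write_sam_file(recs, path,
                               refs = c(refA = 5000L, refB = 5000L)),
         n = n, k_ins = k_ins, k_del = k_del, k_mm = k_mm, match = m,
         read_length = 10L + k_ins + (m + k_mm - 20L) + 10L)
  })
}

# Two-sided Kolmogorov-Smirnov distance between two exponentiated Weibull
# parameter sets over a fine grid.
ew_ks_distance <- function(p1, p2, upper = 80, step = 0.01) {
  grid <- seq(0, upper, by = step)
  max(abs(pexpweibull(grid, p1) - pexpweibull(grid, p2)))
}
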