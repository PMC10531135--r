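# Read-length model: six empirical length categories plus random reads.

GAUSS_MEAN <- 1500
GAUSS_SD <- 30
SECOND_GAUSS_MEAN <- 1100
VERY_SHORT_MIN <- 20L    # avoids zero/near-zero reads that break SAM tooling
VERY_SHORT_MAX <- 199L
SHORT_MIN <- 200L
SHORT_MAX <- 999L
LONG_READ_MIN <- 1601L
LONG_READ_SCALE <- 200
LONG_DEL_OFFSET <- 50
LONG_DEL_SCALE <- 150
LONG_DEL_FINAL_MIN <- 1001L  # final length strictly between 1000 and 1450
LONG_DEL_FINAL_MAX <- 1449L

#' Length-category mixture parameters
#'
#' Six integer percentages, in the order (gauss, longDel, longRead, short,
#' veryShort, secondGauss), summing to 100. The defaults (67, 21, 1, 9, 2, 0)
#' describe a typical R9.4.1 nanopore 16S run: 67% of reads in the main
#' Gaussian peak, 21% carrying a long internal deletion, 1% long reads,
#' 9% short, 2% very short, and no second Gaussian peak.
#'
#' @param gauss,longDel,longRead,short,veryShort,secondGauss Integer
#'   percentages in `[0, 100]`.
#' @return An object of class `length_params` (named integer vector).
#' @export
length_params <- function(gauss = 67, longDel = 21, longRead = 1,
                          short = 9, veryShort = 2, secondGauss = 0) {
  p <- c(gauss = gauss, longDel = longDel, longRead = longRead,
         short = short, veryShort = veryShort, secondGauss = secondGauss)
  if (any(!is.numeric(p)) || any(p != floor(p)) || any(p < 0 | p > 100))
    rlang::abort("Length percentages must be integers in [0, 100].")
  if (sum(p) != 100)
    rlang::abort("Length percentages must sum to 100.")
  structure(as.integer(p), names = names(p), class = "length_params")
}

#' Parse a bracketed length-parameter list
#'
#' Accepts the command-line syntax `"[70,10,1,15,0,4]"` (order: gauss,
#' longDel, longRead, short, veryShort, secondGauss).
#'
#' @param text The bracketed list as a string (brackets optional).
#' @return A [length_params()] object.
#' @export
parse_length_params <- function(text) {
  if (inherits(text, "length_params")) return(text)
  body <- gsub("\\[|\\]|\\s", "", text)
  vals <- suppressWarnings(as.integer(strsplit(body, ",")[[1L]]))
  if (length(vals) != 6L || anyNA(vals))
    rlang::abort("Length parameter must be six comma-separated integers, e.g. \"[67,21,1,9,2,0]\".")
  length_params(vals[1L], vals[2L], vals[3L], vals[4L], vals[5L], vals[6L])
}

#' Draw length categories for a set of reads
#'
#' @param n Number of reads.
#' @param params A [length_params()] mixture.
#' @param seed Integer seed (NULL = current RNG stream).
#' @return Character vector of `n` category names.
#' @export
sample_categories <- function(n, params = length_params(), seed = NULL) {
  assert_count(n, "n")
  if (!inherits(params, "length_params"))
    params <- parse_length_params(params)
  with_seed(seed,
    sample(LENGTH_CATEGORIES, n, replace = TRUE, prob = params / 100))
}

# Draw target lengths for categories with a direct length law (everything
# except longDel, which operates on the input read).
draw_target_lengths <- function(category, m) {
  switch(category,
    gauss = , secondGauss = {
      mu <- if (category == "gauss") GAUSS_MEAN else SECOND_GAUSS_MEAN
      t <- round(rnorm(m, mu, GAUSS_SD))
      while (any(t < 1)) t[t < 1] <- round(rnorm(sum(t < 1), mu, GAUSS_SD))
      as.integer(t)
    },
    veryShort = VERY_SHORT_MIN +
      sample.int(VERY_SHORT_MAX - VERY_SHORT_MIN + 1L, m, replace = TRUE) - 1L,
    short = SHORT_MIN +
      sample.int(SHORT_MAX - SHORT_MIN + 1L, m, replace = TRUE) - 1L,
    longRead = LONG_READ_MIN + as.integer(round(rexp(m, 1 / LONG_READ_SCALE))),
    rlang::abort(paste0("No direct length law for category: ", category)))
}

# Resize sequences to target lengths: truncate the 3' end, or pad.
resize_to <- function(seqs, target, pad_strategy) {
  len <- nchar(seqs)
  shorter <- target < len
  seqs[shorter] <- substr(seqs[shorter], 1L, target[shorter])
  longer <- which(target > len)
  if (length(longer)) {
    padlen <- target[longer] - len[longer]
    if (pad_strategy == "pad-random") {
      pads <- random_dna(padlen)
    } else {  # duplicate-tail: recycle the read's own tail
      pads <- vapply(seq_along(longer), function(i) {
        s <- seqs[longer[i]]
        tailseq <- substr(s, max(1L, nchar(s) - padlen[i] + 1L), nchar(s))
        substr(strrep(tailseq, ceiling(padlen[i] / nchar(tailseq))), 1L, padlen[i])
      }, character(1L))
    }
    seqs[longer] <- paste0(seqs[longer], pads)
  }
  seqs
}

#' Reshape reads into their length categories
#'
#' Applies the per-category length law to each read and records the category
#' in the annotation:
#' * `gauss` / `secondGauss`: target length `T ~ Normal(1500, 30)` /
#'   `Normal(1100, 30)` (rounded; resampled only if `T < 1`, never truncated
#'   to the nominal 1450-1600 / second-peak ranges, which describe where such
#'   reads fall rather than the sampling law);
#' * `veryShort`: `T ~ Uniform{20..199}`; `short`: `T ~ Uniform{200..999}`;
#' * `longRead`: `T ~ 1601 + Exponential(scale 200)`, rounded;
#' * `longDel`: a contiguous internal block of size
#'   `D ~ 50 + Exponential(scale 150)` (rounded) is deleted at a uniform
#'   start, `D` resampled (up to 100 tries) until the final length falls in
#'   (1000, 1450). Inputs of 1001 bases or fewer cannot host such a deletion
#'   and are relabelled `veryShort`/`short` by their current length, with a
#'   warning.
#'
#' When `T` is below the current read length the 3' end is truncated
#' (sequencing-order interpretation of early pore exit); when above, the read
#' is extended according to `pad_strategy`.
#'
#' @param reads Read tibble (`id`, `sequence`, ...).
#' @param categories Character vector of categories, one per read (e.g. from
#'   [sample_categories()]); `NULL` draws them from `params`.
#' @param params [length_params()] used when `categories` is `NULL`.
#' @param seed Integer seed.
#' @param pad_strategy `"pad-random"` (default: uniform random bases) or
#'   `"duplicate-tail"`.
#' @return The read tibble with reshaped `sequence` and filled `category`.
#' @export
apply_length <- function(reads, categories = NULL, params = length_params(),
                         seed = NULL, pad_strategy = c("pad-random", "duplicate-tail")) {
  assert_reads_tbl(reads)
  pad_strategy <- match.arg(pad_strategy)
  n <- nrow(reads)
  with_seed(seed, {
    if (is.null(categories))
      categories <- sample_categories(n, params)
    if (length(categories) != n)
      rlang::abort("`categories` must have one entry per read.")
    if (!all(categories %in% LENGTH_CATEGORIES))
      rlang::abort("Unknown length category.")
    seqs <- reads$sequence

    # longDel feasibility: reads too short to host the deletion are
    # relabelled by their current length and left unchanged
    locked <- integer(0)
    idx_ld <- which(categories == "longDel")
    if (length(idx_ld)) {
      len <- nchar(seqs[idx_ld])
      infeasible <- len <= LONG_DEL_FINAL_MIN
      if (any(infeasible)) {
        relabel <- ifelse(len[infeasible] >= SHORT_MIN, "short", "veryShort")
        categories[idx_ld[infeasible]] <- relabel
        locked <- idx_ld[infeasible]
        rlang::warn(sprintf(
          "%d read(s) too short for the longDel category; relabelled by current length.",
          sum(infeasible)))
      }
    }

    for (cat in c("gauss", "secondGauss", "veryShort", "short", "longRead")) {
      idx <- setdiff(which(categories == cat), locked)
      if (!length(idx)) next
      target <- draw_target_lengths(cat, length(idx))
      seqs[idx] <- resize_to(seqs[idx], target, pad_strategy)
    }

    idx <- which(categories == "longDel")
    if (length(idx)) {
      len <- nchar(seqs[idx])
      D <- LONG_DEL_OFFSET + round(rexp(length(idx), 1 / LONG_DEL_SCALE))
      final <- len - D
      tries <- 0L
      repeat {
        bad <- final < LONG_DEL_FINAL_MIN | final > LONG_DEL_FINAL_MAX
        if (!any(bad) || tries >= 100L) break
        D[bad] <- LONG_DEL_OFFSET + round(rexp(sum(bad), 1 / LONG_DEL_SCALE))
        final[bad] <- len[bad] - D[bad]
        tries <- tries + 1L
      }
      bad <- final < LONG_DEL_FINAL_MIN | final > LONG_DEL_FINAL_MAX
      if (any(bad)) {  # force a valid final length (vanishingly rare)
        hi <- pmin(LONG_DEL_FINAL_MAX, len[bad] - 1L)
        final[bad] <- LONG_DEL_FINAL_MIN +
          floor(runif(sum(bad)) * (hi - LONG_DEL_FINAL_MIN + 1L))
        D[bad] <- len[bad] - final[bad]
      }
      s <- 1L + floor(runif(length(idx)) * (len - D + 1L))
      seqs[idx] <- paste0(substr(seqs[idx], 1L, s - 1L),
                          substr(seqs[idx], s + D, len))
    }

    out <- reads
    out$sequence <- seqs
    out$category <- categories
    out
  })
}

#' Generate fully random reads
#'
#' Reads of i.i.d. uniform ACGT bases, with lengths drawn through the same
#' category mixture as simulated reads (the longDel law acts on a nominal
#' 1500-base template). The annotation category is `random` and all error
#' counts are zero.
#'
#' @param k Number of random reads (>= 0).
#' @param params [length_params()] mixture for the length draw.
#' @param seed Integer seed.
#' @return A read tibble of `k` rows.
#' @export
generate_random_reads <- function(k, params = length_params(), seed = NULL) {
  assert_count(k, "k", min = 0L)
  if (k == 0L)
    return(tibble(id = character(), sequence = character(),
                  taxon = character(), n_ins = integer(), n_del = integer(),
                  n_sub = integer(), category = character()))
  with_seed(seed, {
    categories <- sample_categories(k, params)
    lens <- integer(k)
    for (cat in c("gauss", "secondGauss", "veryShort", "short", "longRead")) {
      idx <- which(categories == cat)
      if (length(idx)) lens[idx] <- draw_target_lengths(cat, length(idx))
    }
    idx <- which(categories == "longDel")
    if (length(idx)) {
      final <- GAUSS_MEAN - (LONG_DEL_OFFSET + round(rexp(length(idx), 1 / LONG_DEL_SCALE)))
      repeat {
        bad <- final < LONG_DEL_FINAL_MIN | final > LONG_DEL_FINAL_MAX
        if (!any(bad)) break
        final[bad] <- GAUSS_MEAN -
          (LONG_DEL_OFFSET + round(rexp(sum(bad), 1 / LONG_DEL_SCALE)))
      }
      lens[idx] <- as.integer(final)
    }
    tibble(
      id = sprintf("random_%05d", seq_len(k)),
      sequence = random_dna(lens),
      taxon = NA_character_,
      n_ins = 0L, n_del = 0L, n_sub = 0L,
      category = "random")
  })
}
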