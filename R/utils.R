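# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# seed = NULL consumes the current stream instead.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    rlang::abort("`seed` must be a single integer or NULL.")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a deterministic sub-seed for a pipeline stage, kept within 32-bit
# integer range; NULL propagates (stage consumes the ambient stream).
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k * 1117) %% 2147483587) + 1L
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    rlang::abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  invisible(as.integer(x))
}

assert_reads_tbl <- function(reads, need = c("id", "sequence")) {
  if (!is.data.frame(reads))
    rlang::abort("`reads` must be a data frame with at least columns id and sequence.")
  missing <- setdiff(need, names(reads))
  if (length(missing))
    rlang::abort(paste0("`reads` is missing column(s): ",
                        paste(missing, collapse = ", "), "."))
  invisible(reads)
}

# Random DNA of given total length, returned as a single string split into
# `lengths` pieces.
random_dna <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  big <- paste(bases, collapse = "")
  substring(big, starts, ends)
}
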