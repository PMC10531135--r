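# Trainer: estimate the error model and length mixture from real aligned data.

#' Error-type split from alignment summaries
#'
#' Pools insertion, deletion and mismatch base counts over all mapped
#' alignments and normalizes: `p_ins = sum(ins) / sum(ins + del + mismatch)`,
#' and analogously for deletions and substitutions.
#'
#' @param alignments Alignment-summary tibble from [parse_sam()] or
#'   [alignments_from_annotations()].
#' @return An [error_type_split()] object.
#' @export
error_type_split_from_alignments <- function(alignments) {
  m <- dplyr::filter(alignments, .data$mapped)
  if (nrow(m) == 0L) rlang::abort("No mapped alignments.")
  tot <- sum(m$n_ins) + sum(m$n_del) + sum(m$n_mismatch)
  if (tot == 0)
    rlang::abort("All alignments are error-free; cannot normalize the error-type split.")
  error_type_split(sum(m$n_ins) / tot, sum(m$n_del) / tot,
                   sum(m$n_mismatch) / tot)
}

#' Per-read identity histogram
#'
#' Per-read identity is `100 * match / (match + mismatch + ins + del)`
#' percent; mapped reads are binned over `[0, 100]` with the last bin
#' right-closed.
#'
#' @param alignments Alignment-summary tibble.
#' @param n_bins Number of bins (default 1000, i.e. 0.1% resolution).
#' @return A tibble with columns `lower`, `upper`, `mid`, `count`; the sum
#'   of `count` equals the number of mapped reads. An unmapped-only input
#'   yields an all-zero histogram with a warning.
#' @export
identity_histogram <- function(alignments, n_bins = 1000L) {
  assert_count(n_bins, "n_bins", min = 2L)
  width <- 100 / n_bins
  edges <- seq(0, 100, length.out = n_bins + 1L)
  m <- dplyr::filter(alignments, .data$mapped)
  if (nrow(m) == 0L) {
    rlang::warn("No mapped alignments; identity histogram is empty.")
    counts <- integer(n_bins)
  } else {
    cols <- m$n_match + m$n_mismatch + m$n_ins + m$n_del
    identity <- 100 * m$n_match / cols
    if (any(identity < 0 | identity > 100))
      rlang::abort("Identity outside [0, 100]; inconsistent alignment counts.")
    bin <- pmin(floor(identity / width) + 1L, n_bins)  # right-closed last bin
    counts <- tabulate(bin, nbins = n_bins)
  }
  tibble(lower = edges[-(n_bins + 1L)], upper = edges[-1L],
         mid = (edges[-(n_bins + 1L)] + edges[-1L]) / 2, count = counts)
}

#' Fit the exponentiated Weibull error-rate distribution
#'
#' The per-read error-rate sample is reconstructed from an identity
#' histogram as `100 - bin centre`, each value weighted by its bin count
#' (bias at most half a bin width, 0.05 points at 1000 bins), and the four
#' parameters are estimated by maximum likelihood with the location
#' constrained to `[0, min(sample)]`.
#'
#' When `ins_fraction > 0`, identity-derived error rates (whose denominator,
#' the alignment columns, is inflated by insertions) are first converted to
#' percent-of-read-length rates — the scale on which the injector consumes
#' them — via `r = e / (1 - ins_fraction * e / 100)`.
#'
#' @param hist An [identity_histogram()] tibble, or directly a numeric
#'   vector of per-read error-rate percentages.
#' @param ins_fraction Insertion fraction of the error-type split used for
#'   the denominator correction (default 0 = fit the rates as given).
#' @return An object of class `exp_weibull_fit` with elements `params`
#'   ([exp_weibull_params()]), `logLik`, `n`, `sample_mean`, `fitted_mean`
#'   and `ins_fraction`. Errors if the optimizer fails to converge or the
#'   fitted mean deviates from the sample mean by more than 5%.
#' @export
fit_exp_weibull <- function(hist, ins_fraction = 0) {
  if (is.numeric(hist)) {
    x <- as.double(hist)
    w <- rep(1, length(x))
    if (length(x) > 5000L) {
      # aggregate large samples at 0.1-point resolution (the same bias bound
      # as the histogram route) to keep the weighted likelihood cheap
      bin <- round(x, 1L)
      tab <- table(bin)
      x <- as.double(names(tab))
      w <- as.double(tab)
    }
  } else {
    if (!is.data.frame(hist) || !all(c("mid", "count") %in% names(hist)))
      rlang::abort("`hist` must be an identity_histogram tibble or a numeric vector.")
    keep <- hist$count > 0
    x <- 100 - hist$mid[keep]
    w <- as.double(hist$count[keep])
  }
  n <- sum(w)
  if (n < 100)
    rlang::abort("At least 100 observations are needed to fit the error-rate distribution.")
  if (ins_fraction < 0 || ins_fraction >= 1)
    rlang::abort("`ins_fraction` must be in [0, 1).")
  if (ins_fraction > 0)
    x <- x / (1 - ins_fraction * x / 100)
  x <- pmax(x, 1e-8)

  min_x <- min(x)
  mean_x <- sum(w * x) / n
  sd_x <- sqrt(max(sum(w * (x - mean_x)^2) / n, 1e-8))

  nll <- function(par) {
    p <- exp_weibull_params(exp(par[1L]), exp(par[2L]), par[3L], exp(par[4L]))
    v <- -sum(w * dexpweibull(x, p, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }

  loc_hi <- max(min_x - 1e-6, 0)
  starts <- list()
  for (a0 in c(0.5, 1, 2, 4)) for (loc0 in unique(c(0, 0.8 * loc_hi))) {
    c0 <- 1.5
    scale0 <- max((mean_x - loc0) / gamma(1 + 1 / c0), sd_x / 2, 1e-3)
    starts[[length(starts) + 1L]] <- c(log(a0), log(c0), loc0, log(scale0))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = c(-8, -8, 0, -8), upper = c(8, 8, loc_hi, 8),
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    rlang::abort("Exponentiated Weibull fit failed: optimizer did not converge from any start.")

  params <- exp_weibull_params(exp(best$par[1L]), exp(best$par[2L]),
                               best$par[3L], exp(best$par[4L]))
  fitted_mean <- exp_weibull_mean(params)
  if (abs(fitted_mean - mean_x) > 0.05 * max(mean_x, 1e-8))
    rlang::abort(sprintf(
      "Exponentiated Weibull fit rejected: fitted mean %.3f deviates from sample mean %.3f by more than 5%%.",
      fitted_mean, mean_x))

  structure(list(params = params, logLik = -best$value, n = n,
                 sample_mean = mean_x, fitted_mean = fitted_mean,
                 ins_fraction = ins_fraction),
            class = "exp_weibull_fit")
}

#' @export
print.exp_weibull_fit <- function(x, ...) {
  cat(sprintf("Exponentiated Weibull fit (n = %g reads)\n", x$n))
  print(x$params)
  cat(sprintf("  sample mean %.3f%%, fitted mean %.3f%%, logLik %.1f\n",
              x$sample_mean, x$fitted_mean, x$logLik))
  invisible(x)
}

#' Tidy methods for fitted error-rate distributions
#'
#' @param x An `exp_weibull_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per parameter (`term`, `estimate`);
#'   `glance()` a one-row model summary.
#' @export
tidy.exp_weibull_fit <- function(x, ...) {
  tibble(term = c("a", "c", "loc", "scale"),
         estimate = c(x$params$a, x$params$c, x$params$loc, x$params$scale))
}

#' @rdname tidy.exp_weibull_fit
#' @export
glance.exp_weibull_fit <- function(x, ...) {
  tibble(logLik = x$logLik, nobs = x$n, sample_mean = x$sample_mean,
         fitted_mean = x$fitted_mean, ins_fraction = x$ins_fraction)
}

#' Length-category percentages from read lengths
#'
#' Classifies read lengths into the five measurable categories
#' (`< 200` veryShort, `[200, 1000)` short, `[1000, 1450)` longDel,
#' `[1450, 1600]` gauss, `> 1600` longRead) and converts counts to integer
#' percentages summing to exactly 100 by largest-remainder rounding. The
#' second Gaussian peak is not separable from the longDel range by length
#' alone, so `second_gauss_pct`, when supplied by the user, is subtracted
#' from the longDel percentage.
#'
#' With `deconvolve_gauss = TRUE`, the raw class percentages are corrected
#' for the known spill-over of the Gaussian length law: `Normal(1500, 30)` is
#' not truncated to the 1450-1600 range, so a fixed fraction of Gauss-category
#' reads (about 4.6% below 1450, 0.04% above 1600) is classified into the
#' neighbouring ranges by length alone. The correction inverts that mixing so
#' that simulating with the trained percentages reproduces the observed
#' length-class composition (a fixed point of the train-simulate loop).
#'
#' @param lengths Integer vector of read lengths (>= 1 value).
#' @param second_gauss_pct Optional integer percentage for the secondGauss
#'   category; must not exceed the computed longDel percentage.
#' @param deconvolve_gauss Correct for the Gaussian boundary spill-over
#'   (default `FALSE`: report the raw classification).
#' @return A [length_params()] object.
#' @export
length_params_from_lengths <- function(lengths, second_gauss_pct = NULL,
                                       deconvolve_gauss = FALSE) {
  if (!is.numeric(lengths) || length(lengths) < 1L)
    rlang::abort("`lengths` must contain at least one read length.")
  cls <- cut(lengths, breaks = c(-Inf, 199.5, 999.5, 1449.5, 1600.5, Inf),
             labels = c("veryShort", "short", "longDel", "gauss", "longRead"))
  counts <- table(factor(cls, levels = c("gauss", "longDel", "longRead",
                                         "short", "veryShort")))
  pct <- 100 * as.numeric(counts) / length(lengths)
  if (isTRUE(deconvolve_gauss)) {
    q_lo <- stats::pnorm(1449.5, GAUSS_MEAN, GAUSS_SD)
    q_hi <- stats::pnorm(1600.5, GAUSS_MEAN, GAUSS_SD, lower.tail = FALSE)
    g <- pct[1L] / (1 - q_lo - q_hi)
    d <- max(pct[2L] - q_lo * g, 0)
    r <- max(pct[3L] - q_hi * g, 0)
    pct <- c(g, d, r, pct[4L], pct[5L])
    pct <- 100 * pct / sum(pct)
  }
  base <- floor(pct)
  need <- 100L - sum(base)
  if (need > 0) {
    give <- order(pct - base, decreasing = TRUE)[seq_len(need)]
    base[give] <- base[give] + 1L
  }
  sg <- 0L
  if (!is.null(second_gauss_pct)) {
    sg <- assert_count(second_gauss_pct, "second_gauss_pct", min = 0L)
    if (sg > base[2L])
      rlang::abort(sprintf(
        "second_gauss_pct (%d) exceeds the computed longDel percentage (%d).",
        sg, base[2L]))
    base[2L] <- base[2L] - sg
  }
  length_params(gauss = base[1L], longDel = base[2L], longRead = base[3L],
                short = base[4L], veryShort = base[5L], secondGauss = sg)
}

#' Alignment summaries from simulation annotations
#'
#' Converts a simulated read tibble into the same alignment-summary shape as
#' [parse_sam()], using the edit counts the simulator recorded: insertions
#' and deletions as annotated, mismatches equal to the substitution count,
#' and matches equal to the error-free template length minus deletions and
#' substitutions. Random reads are reported unmapped. This allows the
#' trainer to run without an external aligner.
#'
#' @param sim_reads Output of [simulate_reads()] (needs the
#'   `template_length` column).
#' @return An alignment-summary tibble.
#' @export
alignments_from_annotations <- function(sim_reads) {
  assert_reads_tbl(sim_reads,
                   need = c("id", "sequence", "n_ins", "n_del", "n_sub",
                            "template_length"))
  mapped <- if ("category" %in% names(sim_reads))
    sim_reads$category != "random" else rep(TRUE, nrow(sim_reads))
  taxon <- if ("taxon" %in% names(sim_reads))
    sim_reads$taxon else rep("", nrow(sim_reads))
  tibble(
    read_id = sim_reads$id,
    mapped = mapped,
    target_id = ifelse(mapped & !is.na(taxon), taxon, ""),
    read_length = nchar(sim_reads$sequence),
    n_match = ifelse(mapped,
                     sim_reads$template_length - sim_reads$n_del - sim_reads$n_sub,
                     0L),
    n_mismatch = ifelse(mapped, sim_reads$n_sub, 0L),
    n_ins = ifelse(mapped, sim_reads$n_ins, 0L),
    n_del = ifelse(mapped, sim_reads$n_del, 0L))
}

#' Train a full error model from alignments
#'
#' Runs the three estimators — error-type split, exponentiated Weibull fit
#' of the per-read error rates (via the 1000-bin identity histogram), and
#' length-category percentages — on a set of alignment summaries.
#'
#' @param alignments Alignment-summary tibble ([parse_sam()] or
#'   [alignments_from_annotations()]).
#' @param lengths Read lengths of the real dataset; defaults to the
#'   `read_length` column of `alignments` (positive entries).
#' @param n_bins Identity-histogram bins (default 1000).
#' @param second_gauss_pct Optional user-supplied secondGauss percentage.
#' @param correct_ins_inflation Convert identity-derived error rates to
#'   percent-of-read-length before fitting (default `TRUE`; see
#'   [fit_exp_weibull()]).
#' @param deconvolve_gauss Correct length percentages for the Gaussian
#'   boundary spill-over (default `TRUE`; see
#'   [length_params_from_lengths()]).
#' @return An object of class `trained_model`: list with `split`, `ew`
#'   (an `exp_weibull_fit`), `lengths` (a [length_params()]), `n_reads`.
#' @export
train_model <- function(alignments, lengths = NULL, n_bins = 1000L,
                        second_gauss_pct = NULL, correct_ins_inflation = TRUE,
                        deconvolve_gauss = TRUE) {
  split <- error_type_split_from_alignments(alignments)
  hist <- identity_histogram(alignments, n_bins = n_bins)
  ew <- fit_exp_weibull(hist, ins_fraction =
                          if (correct_ins_inflation) split$p_ins else 0)
  if (is.null(lengths)) {
    lengths <- alignments$read_length[alignments$read_length > 0]
  }
  lp <- length_params_from_lengths(lengths, second_gauss_pct = second_gauss_pct,
                                   deconvolve_gauss = deconvolve_gauss)
  structure(list(split = split, ew = ew, lengths = lp,
                 n_reads = nrow(alignments)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("Trained error model (%d reads)\n", x$n_reads))
  cat(sprintf("  split: ins %.3f / del %.3f / sub %.3f\n",
              x$split$p_ins, x$split$p_del, x$split$p_sub))
  print(x$ew$params)
  cat("  length mixture: [", paste(unclass(x$lengths), collapse = ","), "]\n")
  invisible(x)
}

#' Train on real alignments and simulate in one call
#'
#' The complete train-then-simulate pipeline: parse the SAM alignment of
#' real reads, estimate all model parameters, generate the per-read profile
#' file (one line per error-free input read), apply any user overrides, run
#' the injector and the length model, and write the simulated FASTQ plus a
#' parameter log. Mapping the real reads against the references is the
#' user's (external) step; this function consumes its SAM output.
#'
#' @param real_sam SAM/BAM alignment of real reads against the references.
#' @param error_free_fastq FASTQ of error-free community reads (the
#'   simulation templates); its read count sets the profile length.
#' @param out_dir Output directory (created if needed); receives
#'   `profile.csv`, `simulated.fastq` and `train_log.txt`.
#' @param overrides Named list of manual overrides: `lengths` (bracket
#'   string or [length_params()]), `random_fraction` (percent), `quality`
#'   (phred), `second_gauss_pct`.
#' @param seed Integer seed.
#' @return Invisibly, a list with the `trained_model`, the simulated read
#'   tibble and the output paths.
#' @export
train_and_simulate <- function(real_sam, error_free_fastq, out_dir,
                               overrides = list(), seed = NULL) {
  alignments <- parse_sam(real_sam)
  reads <- read_fastq(error_free_fastq)
  n <- nrow(reads)
  if (n == 0L) rlang::abort("No reads in the error-free FASTQ.")
  model <- train_model(alignments,
                       second_gauss_pct = overrides$second_gauss_pct)
  lengths <- if (!is.null(overrides$lengths))
    parse_length_params(overrides$lengths) else model$lengths
  random_fraction <- if (!is.null(overrides$random_fraction))
    overrides$random_fraction else 0
  quality <- if (!is.null(overrides$quality)) overrides$quality else 8L

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- make_profile(n, model$ew$params, model$split,
                          seed = sub_seed(seed, 11L))
  profile_path <- file.path(out_dir, "profile.csv")
  write_profile(profile, profile_path)

  sim <- simulate_reads(reads, profile = profile, lengths = lengths,
                        random_fraction = random_fraction,
                        seed = sub_seed(seed, 12L))
  fastq_path <- file.path(out_dir, "simulated.fastq")
  write_fastq(sim, fastq_path, quality = quality)

  log_path <- file.path(out_dir, "train_log.txt")
  write_param_log(list(
    n_reads = n,
    split = unclass(model$split),
    exp_weibull = unclass(model$ew$params),
    error_rate_sample_mean = model$ew$sample_mean,
    error_rate_fitted_mean = model$ew$fitted_mean,
    length_params = paste0("[", paste(unclass(lengths), collapse = ","), "]"),
    random_fraction = random_fraction,
    quality = quality,
    seed = if (is.null(seed)) NA else seed), log_path)

  invisible(list(model = model, reads = sim,
                 paths = list(profile = profile_path, fastq = fastq_path,
                              log = log_path)))
}
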