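make_aln <- function(ins, del, mm, match = 100L, mapped = TRUE) {
  tibble::tibble(read_id = sprintf("r%04d", seq_along(ins)),
                 mapped = mapped,
                 target_id = ifelse(mapped, "refA", ""),
                 read_length = match + mm + ins,
                 n_match = ifelse(mapped, match, 0L),
                 n_mismatch = ifelse(mapped, mm, 0L),
                 n_ins = ifelse(mapped, ins, 0L),
                 n_del = ifelse(mapped, del, 0L))
}

test_that("error-type split pools counts over mapped alignments", {
  one <- make_aln(28L, 42L, 30L)
  s <- error_type_split_from_alignments(one)
  expect_equal(c(s$p_ins, s$p_del, s$p_sub), c(0.28, 0.42, 0.30))

  two <- make_aln(c(1L, 0L), c(0L, 1L), c(0L, 0L))
  s2 <- error_type_split_from_alignments(two)
  expect_equal(c(s2$p_ins, s2$p_del, s2$p_sub), c(0.5, 0.5, 0))

  expect_error(error_type_split_from_alignments(make_aln(0L, 0L, 0L)),
               "error-free")
})

test_that("identity histograms bin per-read identity over [0, 100]", {
  perfect <- make_aln(0L, 0L, 0L)
  h <- identity_histogram(perfect)
  expect_equal(h$count[1000], 1L)          # identity 100 in the last bin
  expect_equal(sum(h$count), 1L)

  r <- make_aln(3L, 3L, 4L, match = 90L)   # identity 90.0
  h2 <- identity_histogram(r)
  expect_equal(h2$count[h2$lower <= 90 & h2$upper > 90], 1L)

  many <- make_aln(sample(0:5, 200, TRUE), sample(0:5, 200, TRUE),
                   sample(0:5, 200, TRUE))
  expect_equal(sum(identity_histogram(many)$count), 200L)

  expect_warning(h0 <- identity_histogram(make_aln(1L, 1L, 1L, mapped = FALSE)),
                 "No mapped")
  expect_equal(sum(h0$count), 0L)
})

test_that("the exponentiated Weibull fit recovers known parameters", {
  truth <- exp_weibull_params(a = 2, c = 1.5, loc = 5, scale = 8)
  x <- sample_error_rates(2e4, truth, seed = 91L)
  f <- fit_exp_weibull(x)
  expect_s3_class(f, "exp_weibull_fit")
  expect_lt(ew_ks_distance(f$params, truth), 0.02)
  expect_lt(abs(f$fitted_mean - f$sample_mean), 0.05 * f$sample_mean)

  # refitting a resample of the fit is stable
  x2 <- sample_error_rates(2e4, f$params, seed = 92L)
  f2 <- fit_exp_weibull(x2)
  expect_lt(ew_ks_distance(f2$params, f$params), 0.02)
  expect_lt(abs(f2$fitted_mean - f$fitted_mean), 0.5)

  # degenerate histogram: all mass in one bin, mean preserved
  mids <- seq(0.05, 99.95, by = 0.1)
  hd <- tibble::tibble(lower = mids - 0.05, upper = mids + 0.05, mid = mids,
                       count = ifelse(abs(mids - 90.05) < 1e-9, 500L, 0L))
  fd <- fit_exp_weibull(hd)
  expect_lt(abs(fd$fitted_mean - 9.95), 0.05 * 9.95)

  expect_error(fit_exp_weibull(x[1:50]), "100")
})

test_that("tidy and glance summarise the fit", {
  x <- sample_error_rates(5000, exp_weibull_params(1.5, 2, 4, 9), seed = 93L)
  f <- fit_exp_weibull(x)
  td <- tidy(f)
  expect_equal(td$term, c("a", "c", "loc", "scale"))
  expect_true(all(td$estimate > 0 | td$term == "loc"))
  gl <- glance(f)
  expect_equal(gl$nobs, 5000)
  expect_equal(gl$sample_mean, mean(x), tolerance = 1e-6)
})

test_that("length-category percentages use largest-remainder rounding", {
  expect_equal(unclass(length_params_from_lengths(rep(1500, 10))),
               unclass(length_params(100, 0, 0, 0, 0, 0)))
  expect_equal(unclass(length_params_from_lengths(c(100, 500, 1200, 1500, 1700))),
               unclass(length_params(gauss = 20, longDel = 20, longRead = 20,
                                     short = 20, veryShort = 20, secondGauss = 0)))
  # percentages always sum to 100 even with awkward fractions
  set.seed(94)
  for (i in 1:10) {
    lens <- sample(c(100, 500, 1200, 1500, 1700), sample(3:97, 1), TRUE)
    expect_equal(sum(unclass(length_params_from_lengths(lens))), 100L)
  }
  # user-provided secondGauss is carved out of longDel
  lens <- c(rep(1500, 70), rep(1200, 14), rep(1700, 1), rep(500, 15))
  lp <- length_params_from_lengths(lens, second_gauss_pct = 4L)
  expect_equal(unclass(lp),
               unclass(length_params(70, 10, 1, 15, 0, 4)))
  expect_error(length_params_from_lengths(lens, second_gauss_pct = 50L),
               "longDel")
})

test_that("training recovers the generating model from simulator truth", {
  comm <- make_community(n_reads = 8000L, seed = 95L)
  truth_ew <- exp_weibull_params(a = 2, c = 1.5, loc = 5, scale = 8)
  lp <- length_params(70, 20, 1, 7, 2, 0)
  sim <- simulate_reads(comm$reads, ew = truth_ew, lengths = lp, seed = 96L)
  aln <- alignments_from_annotations(sim)
  model <- train_model(aln, lengths = nchar(sim$sequence))

  expect_lt(abs(model$split$p_ins - 0.28), 0.03)
  expect_lt(abs(model$split$p_del - 0.42), 0.03)
  expect_lt(abs(model$split$p_sub - 0.30), 0.03)
  expect_true(all(abs(unclass(model$lengths) - unclass(lp)) <= 2L))
  expect_lt(abs(model$ew$fitted_mean - nanoampsim:::exp_weibull_mean(truth_ew)),
            0.5)
})

test_that("train_and_simulate writes profile, FASTQ and log with overrides", {
  synth <- synth_training_sam(n = 250L)
  comm <- make_community(n_reads = 300L, seed = 97L)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(comm$reads, fq)
  out_dir <- withr::local_tempdir()

  res <- train_and_simulate(synth$path, fq, out_dir,
                            overrides = list(lengths = "[95,5,0,0,0,0]"),
                            seed = 98L)
  prof <- read_profile(res$paths$profile)
  expect_equal(nrow(prof), 300L)            # n profile lines = n input reads
  sim <- read_fastq(res$paths$fastq)
  expect_equal(nrow(sim), 300L)
  expect_setequal(unique(sim$category), c("gauss", "longDel"))
  expect_true(all(strsplit(sim$quality[1], "")[[1]] == ")"))
  log_lines <- readLines(res$paths$log)
  expect_true(any(grepl("length_params: \\[95,5,0,0,0,0\\]", log_lines)))
  expect_true(any(grepl("split\\.p_ins", log_lines)))
})
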