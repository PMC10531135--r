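test_that("homopolymer runs are maximal and tile the sequence", {
  runs <- find_homopolymers("AAACCG")
  expect_equal(runs$start, c(1L, 4L, 6L))
  expect_equal(runs$length, c(3L, 2L, 1L))
  expect_equal(runs$base, c("A", "C", "G"))

  runs4 <- find_homopolymers("ACGT")
  expect_equal(runs4$length, rep(1L, 4))

  set.seed(21)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:80, 1), replace = TRUE),
               collapse = "")
    r <- find_homopolymers(s)
    expect_equal(sum(r$length), nchar(s))
    expect_equal(r$start, c(1L, head(cumsum(r$length), -1) + 1L))
  }
  expect_error(find_homopolymers("ACGN"), "ACGT")
})

test_that("edit counts are realized by rounding the profile percentages", {
  reads <- tibble::tibble(id = "r", sequence = strrep("ACGT", 250))  # L = 1000
  out <- inject_errors(reads, tibble::tibble(ins_pct = 2.8, del_pct = 4.2,
                                             sub_pct = 3.0), seed = 1L)
  expect_equal(c(out$n_ins, out$n_del, out$n_sub), c(28L, 42L, 30L))
  expect_equal(nchar(out$sequence), 1000L + 28L - 42L)

  zero <- inject_errors(reads, constant_profile(1, 0), seed = 1L)
  expect_identical(zero$sequence, reads$sequence)
  expect_equal(c(zero$n_ins, zero$n_del, zero$n_sub), c(0L, 0L, 0L))

  # whole read is one run: a single deletion has a forced outcome
  hp <- tibble::tibble(id = "h", sequence = "AAAAAA")
  one_del <- tibble::tibble(ins_pct = 0, del_pct = 100 / 6, sub_pct = 0)
  expect_equal(inject_errors(hp, one_del, seed = 2L)$sequence, "AAAAA")

  # a read may not vanish
  expect_error(
    inject_errors(tibble::tibble(id = "x", sequence = "ACGT"),
                  tibble::tibble(ins_pct = 0, del_pct = 100, sub_pct = 0)),
    "vanish")
})

test_that("edit logs replay exactly and tallies match annotations", {
  set.seed(33)
  n <- 100L
  reads <- tibble::tibble(
    id = sprintf("r%03d", 1:n),
    sequence = vapply(sample(40:200, n, replace = TRUE), function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1)))
  prof <- tibble::tibble(ins_pct = runif(n, 0, 8), del_pct = runif(n, 0, 8),
                         sub_pct = runif(n, 0, 8))
  out <- inject_errors(reads, prof, seed = 34L, keep_log = TRUE)
  log <- attr(out, "edit_log")
  expect_equal(nchar(out$sequence),
               nchar(reads$sequence) + out$n_ins - out$n_del)
  for (i in seq_len(n)) {
    expect_true(verify_edit_counts(reads$sequence[i], out$sequence[i],
                                   log[log$read == i, ],
                                   out$n_ins[i], out$n_del[i], out$n_sub[i]))
  }
  # tampering is detected
  expect_false(verify_edit_counts(reads$sequence[1],
                                  paste0(out$sequence[1], "A"),
                                  log[log$read == 1, ]))
  # empty log, unchanged read
  expect_true(verify_edit_counts("ACGT", "ACGT", log[0, ]))
})

test_that("edit distance never exceeds the number of introduced edits", {
  set.seed(44)
  n <- 100L
  reads <- tibble::tibble(
    id = sprintf("r%03d", 1:n),
    sequence = vapply(sample(50:200, n, replace = TRUE), function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1)))
  prof <- tibble::tibble(ins_pct = runif(n, 0, 6), del_pct = runif(n, 0, 6),
                         sub_pct = runif(n, 0, 6))
  out <- inject_errors(reads, prof, seed = 45L)
  lev <- diag(utils::adist(reads$sequence, out$sequence))
  expect_true(all(lev <= out$n_ins + out$n_del + out$n_sub))
})

test_that("indels favour long homopolymer runs in proportion to length", {
  # runs of length 5,1,1,1: the A-run should receive ~5/8 of single deletions
  n <- 10000L
  reads <- tibble::tibble(id = sprintf("r%05d", 1:n),
                          sequence = rep("AAAAACGT", n))
  one_del <- tibble::tibble(ins_pct = rep(0, n), del_pct = rep(100 / 8, n),
                            sub_pct = rep(0, n))
  out <- inject_errors(reads, one_del, seed = 55L, keep_log = TRUE)
  log <- attr(out, "edit_log")
  expect_equal(nrow(log), n)
  p_hat <- mean(log$pos == 1L)       # deletion taken from the A-run
  expect_lt(abs(p_hat - 5 / 8), 3 * sqrt(5 / 8 * 3 / 8 / n))

  # incidence is monotone in run length on a graded template
  template <- paste0("A", "CC", "GGG", "TTTT", "AAAAA", "CCCCCC")  # L = 21
  reads2 <- tibble::tibble(id = sprintf("q%05d", 1:n),
                           sequence = rep(template, n))
  one_del2 <- tibble::tibble(ins_pct = rep(0, n), del_pct = rep(100 / 21, n),
                             sub_pct = rep(0, n))
  out2 <- inject_errors(reads2, one_del2, seed = 56L, keep_log = TRUE)
  starts <- c(1L, 2L, 4L, 7L, 11L, 16L)
  counts <- table(factor(attr(out2, "edit_log")$pos, levels = starts))
  expect_true(all(diff(as.numeric(counts)) > 0))
})

test_that("a weight exponent of zero removes the homopolymer bias", {
  n <- 5000L
  reads <- tibble::tibble(id = sprintf("r%05d", 1:n),
                          sequence = rep("AAAAACGT", n))
  one_del <- tibble::tibble(ins_pct = rep(0, n), del_pct = rep(100 / 8, n),
                            sub_pct = rep(0, n))
  out <- inject_errors(reads, one_del, seed = 57L, keep_log = TRUE,
                       run_weight_exponent = 0)
  p_hat <- mean(attr(out, "edit_log")$pos == 1L)  # now 1 of 4 runs
  expect_lt(abs(p_hat - 1 / 4), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("substitutions are positionally uniform and never keep the base", {
  n <- 10000L
  template <- strrep("ACGT", 50)  # homopolymer-free, L = 200
  reads <- tibble::tibble(id = sprintf("r%05d", 1:n),
                          sequence = rep(template, n))
  one_sub <- tibble::tibble(ins_pct = rep(0, n), del_pct = rep(0, n),
                            sub_pct = rep(0.5, n))
  out <- inject_errors(reads, one_sub, seed = 66L, keep_log = TRUE)
  log <- attr(out, "edit_log")
  expect_equal(nrow(log), n)
  chi <- suppressWarnings(chisq.test(table(factor(log$pos, levels = 1:200))))
  expect_gt(chi$p.value, 0.001)
  # the replacement base differs from the original
  orig <- strsplit(template, "")[[1]][log$pos]
  expect_true(all(orig != log$base))
})
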