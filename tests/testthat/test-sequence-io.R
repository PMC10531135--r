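test_that("FASTQ reading handles minimal, empty and malformed input", {
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "9999"), tf)
  reads <- read_fastq(tf)
  expect_equal(reads$id, "r1")
  expect_equal(reads$sequence, "ACGT")
  expect_equal(reads$quality, "9999")

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(nrow(read_fastq(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "99"), bad)
  expect_error(read_fastq(bad), "r1")
})

test_that("FASTQ writing applies the fixed quality and annotation convention", {
  reads <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "GGA"),
                          n_ins = c(2L, 0L), n_del = c(3L, 0L),
                          n_sub = c(1L, 0L), category = c("gauss", "short"),
                          taxon = c("Ecoli", NA))
  tf <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, tf, quality = 8L)
  lines <- readLines(tf)
  expect_match(lines[1], "nbIns=2 nbDel=3 nbSub=1 cat=gauss", fixed = TRUE)
  expect_match(lines[1], "taxon=Ecoli", fixed = TRUE)
  expect_equal(lines[4], "))))")  # phred 8 -> ')'

  write_fastq(reads, tf, quality = 0L)
  expect_equal(readLines(tf)[4], "!!!!")  # phred 0 -> '!'
})

test_that("FASTQ round-trip preserves ids, sequences and annotations", {
  comm <- make_community(n_reads = 40L)
  sim <- simulate_reads(comm$reads, profile = constant_profile(40L, 10),
                        seed = 5L)
  tf <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim, tf)
  back <- read_fastq(tf)
  expect_equal(back$id, sim$id)
  expect_equal(back$sequence, sim$sequence)
  expect_equal(back$n_ins, sim$n_ins)
  expect_equal(back$n_del, sim$n_del)
  expect_equal(back$n_sub, sim$n_sub)
  expect_equal(back$category, sim$category)
  expect_equal(back$taxon, sim$taxon)
})

test_that("SAM parsing derives per-read counts from CIGAR and NM", {
  tf <- withr::local_tempfile(fileext = ".sam")
  recs <- tibble::tibble(
    qname = c("r1", "r2", "r3", "r4"),
    flag = c("0", "0", "4", "256"),
    rname = c("refA", "refA", "*", "refB"),
    pos = c("1", "1", "0", "1"),
    cigar = c("10M", "5M2I3M1D2M", "*", "10M"),
    seq = c("ACGTACGTAC", "ACGTACGTACGT", "ACGT", "ACGTACGTAC"),
    nm = c(0L, 4L, NA, 1L))
  write_sam_file(recs, tf)
  a <- parse_sam(tf)

  # one summary per primary record; the secondary (flag 256) is skipped
  expect_equal(nrow(a), 3L)
  expect_equal(a$read_id, c("r1", "r2", "r3"))

  r1 <- a[a$read_id == "r1", ]
  expect_equal(c(r1$n_match, r1$n_mismatch, r1$n_ins, r1$n_del), c(10, 0, 0, 0))

  # hand-expanded CIGAR arithmetic: I=2, D=1, mismatch = NM-I-D = 1, match = 10-1
  r2 <- a[a$read_id == "r2", ]
  expect_equal(c(r2$n_match, r2$n_mismatch, r2$n_ins, r2$n_del), c(9, 1, 2, 1))

  r3 <- a[a$read_id == "r3", ]
  expect_false(r3$mapped)
  expect_equal(r3$target_id, "")
  expect_equal(r3$n_match + r3$n_mismatch + r3$n_ins + r3$n_del, 0)
})

test_that("SAM parsing enforces NM presence and trusts MD on conflict", {
  tf <- withr::local_tempfile(fileext = ".sam")
  recs <- tibble::tibble(qname = "r1", flag = "0", rname = "refA", pos = "1",
                         cigar = "10M", seq = "ACGTACGTAC", nm = NA_integer_)
  write_sam_file(recs, tf)
  expect_error(parse_sam(tf), "NM")

  # NM says 2 mismatches, MD says 1: MD wins, with a warning
  recs <- tibble::tibble(qname = "r1", flag = "0", rname = "refA", pos = "1",
                         cigar = "10M", seq = "ACGTACGTAC", nm = 2L,
                         md = "4A5")
  write_sam_file(recs, tf)
  expect_warning(a <- parse_sam(tf), "MD")
  expect_equal(a$n_mismatch, 1L)
  expect_equal(a$n_match, 9L)
})

test_that("parse_sam conservation: match+mismatch columns equal CIGAR M ops", {
  synth <- synth_training_sam(n = 120L)
  a <- parse_sam(synth$path)
  expect_equal(nrow(a), synth$n)
  expect_equal(a$n_ins, synth$k_ins)
  expect_equal(a$n_del, synth$k_del)
  expect_equal(a$n_match + a$n_mismatch, synth$match + synth$k_mm)
})

test_that("profile files round-trip at 4-decimal precision", {
  entries <- tibble::tibble(ins_pct = c(4.06, 0), del_pct = c(6.09, 0),
                            sub_pct = c(4.35, 0))
  tf <- withr::local_tempfile()
  write_profile(entries, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "4.0600,6.0900,4.3500")
  expect_equal(lines[2], "0.0000,0.0000,0.0000")

  set.seed(11)
  rnd <- tibble::tibble(ins_pct = runif(50, 0, 10), del_pct = runif(50, 0, 10),
                        sub_pct = runif(50, 0, 10))
  write_profile(rnd, tf)
  back <- read_profile(tf)
  expect_equal(nrow(back), 50L)
  expect_equal(back$ins_pct, round(rnd$ins_pct, 4))
  expect_equal(back$del_pct, round(rnd$del_pct, 4))
  expect_equal(back$sub_pct, round(rnd$sub_pct, 4))

  writeLines(c("1.0,2.0", "1,2,3"), tf)
  expect_error(read_profile(tf), "line 1")
})
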