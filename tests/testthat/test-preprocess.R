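spec <- adapter_spec(bait_primer = strrep("AC", 10))

test_that("adapter and quality trimming behave and are idempotent", {
  q40 <- function(n) strrep("I", n)
  # nothing to trim
  r <- trim_read("ACGTACGT", q40(8), spec)
  expect_equal(r$seq, "ACGTACGT")
  # exact adapter suffix removed
  r <- trim_read(paste0("ACGT", spec$sequencing_adapter),
                 q40(4 + nchar(spec$sequencing_adapter)), spec)
  expect_equal(r$seq, "ACGT")
  # trailing sub-30 bases removed (Phred 20 = "5", Phred 40 = "I")
  r <- trim_read("ACGTACGT", paste0(strrep("I", 5), strrep("5", 3)), spec)
  expect_equal(r$seq, "ACGTA")
  expect_equal(r$quals, strrep("I", 5))
  # idempotence on random reads with random qualities
  set.seed(1)
  seqs <- random_barcodes(50, 80)
  quals <- vapply(1:50, function(i)
    rawToChar(as.raw(sample(33:73, 80, TRUE))), character(1))
  t1 <- trim_read(seqs, quals, spec)
  t2 <- trim_read(t1$seq, t1$quals, spec)
  expect_identical(t1, t2)
  # output is always a prefix
  expect_true(all(substr(seqs, 1, nchar(t1$seq)) == t1$seq))
  # mismatched lengths error
  expect_error(trim_read("ACGT", "III", spec), "lengths differ")
})

test_that("short-mate filtering keeps only pairs with both mates >= 25", {
  mk <- function(l1, l2) data.table::data.table(
    id = "r", seq1 = strrep("A", l1), qual1 = strrep("I", l1),
    seq2 = strrep("C", l2), qual2 = strrep("I", l2))
  expect_equal(nrow(filter_short(mk(150, 150))), 1)
  expect_equal(nrow(filter_short(mk(24, 150))), 0)
  expect_equal(nrow(filter_short(mk(150, 24))), 0)
  expect_equal(nrow(filter_short(mk(25, 25))), 1)
  expect_equal(nrow(filter_short(mk(150, 150)[0, ])), 0)
})

test_that("demultiplexing assigns unique indices and partitions input", {
  tab <- c(s1 = "ACGTAC", s2 = "TGCAGG")
  expect_equal(as.character(demultiplex("ACGTAC", tab)), "s1")
  # one mismatch tolerated by default
  expect_equal(as.character(demultiplex("ACGTAA", tab)), "s1")
  # distance max_mismatch + 1 from everything -> undetermined
  expect_equal(as.character(demultiplex("ACCAAC", tab)), "undetermined")
  # two samples, 10 reads each: compare against brute-force assignment
  set.seed(4)
  reads <- c(rep("ACGTAC", 10), rep("TGCAGG", 10))[sample(20)]
  got <- demultiplex(reads, tab)
  brute <- vapply(reads, function(r) {
    d <- vapply(tab, function(x)
      sum(strsplit(r, "")[[1]] != strsplit(x, "")[[1]]), integer(1))
    if (min(d) <= 1 && sum(d == min(d)) == 1) names(tab)[which.min(d)]
    else "undetermined"
  }, character(1), USE.NAMES = FALSE)
  expect_equal(as.character(got), brute)
  expect_equal(sum(table(got)), length(reads))  # partition
  # ambiguous index table rejected
  expect_error(demultiplex("ACGTAC", c(a = "ACGTAC", b = "ACGTAA")),
               "ambiguous")
})

test_that("RMB extraction reads the N-window and returns the prey tail", {
  f5 <- spec$bridge_flank5; f3 <- spec$bridge_flank3
  rmb <- strrep("GATC", 3)
  rmb <- paste0(rmb, "AT")  # 14 nt
  read2 <- paste0(f5, rmb, f3, "TTTTGGGGCCCCAAAA")
  r <- extract_rmb(read2, spec)
  expect_true(r$ok)
  expect_equal(r$rmb, rmb)
  expect_equal(r$prey_seq, "TTTTGGGGCCCCAAAA")
  # one mismatch per flank still accepted
  f5x <- paste0("T", substr(f5, 2, nchar(f5)))
  r <- extract_rmb(paste0(f5x, rmb, f3, "AAAA"), spec)
  expect_true(r$ok)
  # a read lacking the template fails as a signal, not an error
  r <- extract_rmb(strrep("ACGT", 20), spec)
  expect_false(r$ok)
  expect_true(is.na(r$rmb))
})

test_that("error-free simulated molecules give 100% RMB recovery", {
  sp <- sim_spec(n_molecules = 1000L, seed = 5L, duplication = 0,
                 error_rate = 0)
  lib <- simulate_library(sp)
  pre <- preprocess_reads(lib$reads, lib$adapters)
  expect_equal(nrow(pre$molecules), 1000L)
  mol_id <- sub("[.].*", "", pre$molecules$id)
  got <- pre$molecules$rmb[match(lib$truth$id, mol_id)]
  expect_identical(got, lib$truth$rmb)
})

test_that("bait primer verification tolerates one mismatch", {
  p <- spec$bait_primer
  expect_true(verify_bait_primer(paste0(p, "GGGG"), spec))
  expect_false(verify_bait_primer(strrep("G", 40), spec))
  p1 <- paste0("T", substr(p, 2, nchar(p)))
  expect_true(verify_bait_primer(paste0(p1, "GGGG"), spec))
  p2 <- paste0("TT", substr(p, 3, nchar(p)))
  expect_false(verify_bait_primer(paste0(p2, "GGGG"), spec))
})

test_that("preprocess_reads accounts for every pair in one disposition", {
  sp <- sim_spec(n_molecules = 300L, seed = 9L)
  lib <- simulate_library(sp)
  pre <- preprocess_reads(lib$reads, lib$adapters)
  cn <- setNames(pre$counts$n, pre$counts$stage)
  expect_equal(cn[["input"]], nrow(lib$reads))
  expect_equal(cn[["input"]],
               cn[["short_after_trim"]] + cn[["primer_fail"]] +
                 cn[["rmb_fail"]] + cn[["clean"]])
  expect_equal(cn[["clean"]], nrow(pre$molecules))
})

test_that("FASTQ round trip preserves reads (plain and gzip)", {
  sp <- sim_spec(n_molecules = 40L, seed = 2L)
  lib <- simulate_library(sp)
  for (ext in c(".fastq", ".fastq.gz")) {
    f1 <- tempfile(fileext = ext); f2 <- tempfile(fileext = ext)
    write_fastq_pairs(lib$reads, f1, f2)
    back <- read_fastq_pairs(f1, f2)
    expect_equal(back, lib$reads, ignore_attr = TRUE)
    unlink(c(f1, f2))
  }
})
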