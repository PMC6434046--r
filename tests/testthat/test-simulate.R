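# The synthetic library generator.

test_that("the generator is fully deterministic under a fixed seed", {
  sp <- sim_spec(n_molecules = 80L, seed = 71L)
  a <- simulate_library(sp)
  b <- simulate_library(sp)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  # byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_fastq_pairs(a$reads, f1, f2)
  write_fastq_pairs(b$reads, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))
  unlink(c(f1, f2, f3, f4))
})

test_that("implanted sites carry the requested mismatches and PAM state", {
  ot <- data.table::data.table(mismatches = c(0L, 3L, 5L),
                               pam = c("NGG", "NAG", "none"))
  sp <- sim_spec(seed = 72L, offtargets = ot)
  gen <- make_genome(sp)
  s <- gen$offtargets
  expect_equal(nrow(s), 3)
  for (k in 1:3) {
    written <- substr(gen$genome[[s$chrom[k]]], s$start[k], s$start[k] + 22L)
    site <- if (s$strand[k] == "+") written else
      paste(rev(strsplit(chartr("ACGT", "TGCA", written), "")[[1]]),
            collapse = "")
    proto <- substr(site, 1, 20)
    expect_equal(sum(strsplit(proto, "")[[1]] !=
                       strsplit(sp$guide, "")[[1]]),
                 ot$mismatches[k])
    pam23 <- substr(site, 22, 23)
    expect_equal(pam23, c("GG", "AG", "TT")[k])
  }
  # a 0-mismatch implant reproduces the guide exactly
  expect_equal(substr(s$seq[1], 1, 20), sp$guide)
  # the on-target cut convention matches the cryptic-site scanner
  m <- find_cryptic_site(gen$genome, gen$bait$chrom,
                         gen$bait$cut_pos - 5L, gen$bait$cut_pos + 5L,
                         sp$guide)
  expect_equal(m$presumed_cut, gen$bait$cut_pos)
})

test_that("degenerate mixtures produce only the requested category", {
  sp <- sim_spec(n_molecules = 50L, seed = 73L, mixture = c(germline = 1),
                 resection_mass = 0)
  gen <- make_genome(sp)
  mol <- simulate_molecules(sp, gen)
  expect_true(all(mol$truth$category == "germline"))
  # germline molecules are contiguous reference across the cut
  b <- gen$bait
  ref <- substr(gen$genome[[b$chrom]], b$primer_start,
                b$primer_start + mol$truth$frag_len[1] - 1L)
  expect_equal(mol$seqs[1], ref)
})

test_that("category frequencies converge to the stated mixture", {
  sp <- sim_spec(n_molecules = 10000L, seed = 74L)
  gen <- make_genome(sp)
  mol <- simulate_molecules(sp, gen)
  obs <- table(mol$truth$category)
  mix <- sp$mixture
  for (cat in names(mix)) {
    p <- mix[[cat]]
    ci <- qbinom(c(0.0005, 0.9995), 10000, p)
    expect_gte(obs[[cat]], ci[1])
    expect_lte(obs[[cat]], ci[2])
  }
})

test_that("large deletions and translocations have the stated geometry", {
  sp <- sim_spec(n_molecules = 3000L, seed = 75L,
                 mixture = c(large_deletion = 0.5,
                             background_translocation = 0.5))
  gen <- make_genome(sp)
  mol <- simulate_molecules(sp, gen)
  tr <- mol$truth
  ld <- tr[tr$category == "large_deletion", ]
  expect_true(all(ld$prey_chrom == gen$bait$chrom))
  expect_true(all(ld$prey_strand == "+"))
  expect_true(all(ld$prey_pos > gen$bait$cut_pos))
  tx <- tr[tr$category == "background_translocation", ]
  expect_true(all(tx$prey_chrom != gen$bait$chrom |
                    abs(tx$prey_pos - gen$bait$cut_pos) > 250000))
})

test_that("amplification copy counts follow 1 + Poisson(duplication)", {
  sp0 <- sim_spec(n_molecules = 200L, seed = 76L, duplication = 0,
                  error_rate = 0)
  lib0 <- simulate_library(sp0)
  expect_equal(nrow(lib0$reads), 200L)
  expect_true(all(lib0$truth$copies == 1L))
  sp3 <- sim_spec(n_molecules = 1000L, seed = 77L, duplication = 3)
  lib3 <- simulate_library(sp3)
  # mean 4 copies, sd = sqrt(1000 * 3)
  expect_lt(abs(nrow(lib3$reads) - 4000), 3 * sqrt(3000))
  # error-free copies of one molecule are identical
  sp <- sim_spec(n_molecules = 50L, seed = 78L, duplication = 5,
                 error_rate = 0)
  lib <- simulate_library(sp)
  first <- lib$reads[!duplicated(sub("[.].*", "", lib$reads$id)), ]
  key <- sub("[.].*", "", lib$reads$id)
  for (i in seq_len(nrow(first))) {
    sel <- key == sub("[.].*", "", first$id[i])
    expect_equal(unique(lib$reads$seq1[sel]), first$seq1[i])
    expect_equal(unique(lib$reads$seq2[sel]), first$seq2[i])
  }
})

test_that("the resection tail lands deletions 5-50 kb downstream", {
  sp <- sim_spec(n_molecules = 4000L, seed = 79L, resection_mass = 0.05)
  gen <- make_genome(sp)
  tr <- simulate_molecules(sp, gen)$truth
  dist <- tr$prey_pos - gen$bait$cut_pos
  res <- tr$category == "large_deletion" & !is.na(dist) &
    dist >= 5000 & dist <= 50000
  n_edit <- sum(tr$category != "germline")
  # implanted mass 5% of editing events, allow binomial slack
  expect_gt(sum(res) / n_edit, 0.03)
  expect_lt(sum(res) / n_edit, 0.07)
})

test_that("genome FASTA round trip preserves sequences", {
  sp <- sim_spec(genome_sizes = c(chr1 = 5000L, chr2 = 3000L), seed = 80L)
  gen <- make_genome(sp)
  f <- tempfile(fileext = ".fa")
  write_genome_fasta(gen$genome, f)
  back <- read_genome_fasta(f)
  expect_identical(back, gen$genome)
  unlink(f)
})
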