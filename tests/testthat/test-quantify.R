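# Library statistics, editing efficiency, profiles and resection.

test_that("tabulate counts categories and subcategories", {
  bait <- tiny_bait()
  calls <- rbind(
    do.call(rbind, lapply(1:6, function(i) mk_call(paste0("g", i), bait))),
    do.call(rbind, lapply(1:3, function(i)
      mk_call(paste0("i", i), bait, "chrT", bait$cut_pos + 1000L, "+"))),
    mk_call("t1", bait, "chr9", 5000L, "+"))
  cls <- classify_junctions(calls, mk_edit("none", "del", 1L)[0, ], bait)
  st <- tabulate_junctions(cls)
  expect_equal(c(st$G, st$I, st$T), c(6L, 3L, 1L))
  expect_equal(st$total, 10L)
  expect_equal(unname(st$subcounts[["large_deletion"]]), 3L)
  st0 <- tabulate_junctions(cls[0, ])
  expect_equal(c(st0$G, st0$I, st0$T), c(0L, 0L, 0L))
})

test_that("editing efficiency follows the control-corrected formula", {
  # identical sample and control cancel
  s <- library_stats(600, 350, 50)
  expect_equal(editing_efficiency(s, s, te = 0.7)$efficiency, 0)
  # (G,I,T) = (6,3,1) against an all-germline control at TE = 1
  e <- editing_efficiency(library_stats(6, 3, 1), library_stats(10, 0, 0))
  expect_equal(e$efficiency, 0.4)
  # editing fractions 35.7% indels + 2.7% translocations = 38.4%
  e <- editing_efficiency(library_stats(616, 357, 27),
                          library_stats(1000, 0, 0))
  expect_equal(e$raw_sample_fraction, 0.384)
  expect_equal(e$efficiency, 0.384)
  # TE rescales
  e2 <- editing_efficiency(library_stats(616, 357, 27),
                           library_stats(1000, 0, 0), te = 0.8)
  expect_equal(e2$efficiency, 0.384 / 0.8)
  # domain errors
  expect_error(editing_efficiency(s, s, te = 0), "TE")
  expect_error(editing_efficiency(s, s, te = 1.2), "TE")
  expect_error(editing_efficiency(library_stats(0, 0, 0), s), "molecules")
  # control above sample clamps to zero with a warning
  expect_warning(
    z <- editing_efficiency(library_stats(100, 1, 0),
                            library_stats(100, 5, 0)),
    "clamp")
  expect_equal(z$efficiency, 0)
})

test_that("efficiency is invariant under uniform count scaling", {
  s <- library_stats(600, 350, 50)
  c0 <- library_stats(980, 15, 5)
  e1 <- editing_efficiency(s, c0, te = 0.9)
  s7 <- library_stats(4200, 2450, 350)
  c7 <- library_stats(6860, 105, 35)
  e2 <- editing_efficiency(s7, c7, te = 0.9)
  expect_equal(e1$efficiency, e2$efficiency)
})

test_that("junction profiles bin counts and conserve totals", {
  bait <- tiny_bait()
  cut <- bait$cut_pos
  # all junctions at the center fall into the single central bin
  calls <- do.call(rbind, lapply(1:20, function(i)
    mk_call(paste0("c", i), bait, "chrT", cut, "+")))
  pr <- junction_profile(calls, "chrT", cut, window = 5000L, binsize = 50L)
  expect_equal(sum(pr$count), 20L)
  expect_equal(pr$count[pr$bin_start == 0 & pr$strand == "+"], 20L)
  # empty input gives a zero vector over the full grid
  pr0 <- junction_profile(calls[0, ], "chrT", cut)
  expect_true(all(pr0$count == 0L))
  expect_equal(nrow(pr0), 2 * (2 * 5000 / 50))
  # random junctions: bins sum to the number inside the window
  set.seed(3)
  pos <- cut + sample(-8000:8000, 300, TRUE)
  calls2 <- data.table::data.table(
    id = sprintf("r%d", 1:300), rmb = strrep("A", 14), bait_end = cut,
    prey_chrom = "chrT", prey_pos = pos, prey_strand = "+",
    junction_chrom = "chrT", junction_pos = pos,
    junction_strand = sample(c("+", "-"), 300, TRUE))
  pr2 <- junction_profile(calls2, "chrT", cut)
  expect_equal(sum(pr2$count), sum(abs(pos - cut) <= 5000))
  # orientation split agrees with totals
  pr3 <- junction_profile(calls2, "chrT", cut, split_by_orientation = FALSE)
  expect_equal(sum(pr3$count), sum(pr2$count))
})

test_that("resection fraction counts deletion-consistent distal junctions", {
  bait <- tiny_bait()
  cut <- bait$cut_pos
  stats <- library_stats(90000, 9000, 1000)
  calls <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mk_call(paste0("r", i), bait, "chrT", cut + 5000L + i * 1000L, "+"))),
    mk_call("wrongstrand", bait, "chrT", cut + 20000L, "-"),
    mk_call("upstream", bait, "chrT", cut - 20000L, "+"),
    mk_call("toofar", bait, "chrT", cut + 50001L, "+"),
    mk_call("toonear", bait, "chrT", cut + 4999L, "+"))
  calls <- classify_junctions(calls, mk_edit("x", "del", 1L)[0, ], bait)
  expect_equal(resection_fraction(stats, calls, bait), 5 / 10000)
  expect_equal(resection_fraction(stats, calls[0, ], bait), 0)
})

test_that("indel fraction is stable under read titration", {
  sp <- sim_spec(n_molecules = 1200L, seed = 61L)
  lib <- simulate_library(sp)
  frac <- function(reads) {
    pre <- preprocess_reads(reads, lib$adapters)
    st <- analyze_molecules(pre$molecules, lib$genome, lib$bait)$stats
    st$I / st$total
  }
  f_all <- frac(lib$reads)
  set.seed(1)
  f_half <- frac(lib$reads[sample(nrow(lib$reads), nrow(lib$reads) %/% 2), ])
  # binomial sampling error at n ~ 600 is about 0.02; allow 3 sd
  expect_lt(abs(f_all - f_half), 3 * sqrt(0.37 * 0.63 / 600))
})
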