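# Enrichment peak calling, cryptic-site matching, replicate merging,
# intensity and directional balance.

toy_sizes <- c(chrA = 10000000L)
toy_bait <- function() bait_config("chrB", "+", 901L, 920L, 1000L,
                                   strrep("AC", 10))

test_that("a tight junction cluster on a sparse background is the only
           candidate and matches the Poisson-tail oracle", {
  set.seed(15)
  cl <- data.table::data.table(
    chrom = "chrA", pos = 5000000L + sample(-40:40, 30, TRUE),
    strand = sample(c("+", "-"), 30, TRUE))
  bg <- data.table::data.table(
    chrom = "chrA", pos = sort(sample(10000000L, 30)),
    strand = sample(c("+", "-"), 30, TRUE))
  jx <- rbind(cl, bg)
  p <- peak_params()
  got <- call_enriched_regions(jx, toy_sizes, toy_bait(), p)
  expect_equal(nrow(got), 1)
  expect_gte(sum(cl$pos >= got$start & cl$pos <= got$end), 28)
  # q-values agree with the independent oracle on every candidate
  all_cand <- attr(got, "all_candidates")
  ora <- oracle_peaks(jx, toy_sizes, toy_bait(), p)
  expect_equal(nrow(all_cand), nrow(ora))
  expect_lt(max(abs(all_cand$qvalue - ora$qvalue)), 1e-9)
  expect_lt(max(abs(all_cand$pvalue - ora$pvalue)), 1e-9)
})

test_that("junction clusters inside the bait exclusion zone are ignored", {
  bait <- bait_config("chrA", "+", 4999901L, 4999920L, 5000000L,
                      strrep("AC", 10))
  cl <- data.table::data.table(chrom = "chrA",
                               pos = 5100000L + (1:30), strand = "+")
  got <- call_enriched_regions(cl, toy_sizes, bait)
  expect_equal(nrow(got), 0)
  # the same cluster outside the zone is called
  cl2 <- data.table::data.table(chrom = "chrA",
                                pos = 5300000L + (1:30), strand = "+")
  got2 <- call_enriched_regions(rbind(cl, cl2), toy_sizes, bait)
  expect_equal(nrow(got2), 1)
  expect_true(got2$start > 5250000)
  expect_equal(nrow(call_enriched_regions(cl[0, ], toy_sizes, bait)), 0)
})

test_that("lowering the q threshold never increases candidates", {
  set.seed(16)
  jx <- data.table::data.table(
    chrom = "chrA",
    pos = c(5e6 + sample(-30:30, 8, TRUE), sort(sample(1e7, 100))),
    strand = "+")
  n <- vapply(c(0.2, 0.05, 0.01, 0.001), function(q)
    nrow(call_enriched_regions(jx, toy_sizes, toy_bait(),
                               peak_params(q_threshold = q))),
    integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("uniform background alone yields no candidates in >= 95% of runs", {
  spec <- sim_spec(genome_sizes = setNames(rep(10000000L, 5),
                                           paste0("chr", 1:5)),
                   seed = 11L)
  gen <- make_genome(spec)
  sizes <- vapply(gen$genome, nchar, integer(1))
  nc <- vapply(1:20, function(s) {
    bg <- simulate_junction_set(gen, matrix(0L, 0, 1),
                                n_background = 167L, n_replicates = 1L,
                                seed = s)
    nrow(call_enriched_regions(bg[[1]], sizes, gen$bait))
  }, integer(1))
  expect_gte(mean(nc == 0), 0.95)
})

test_that("cryptic-site search finds implanted sites and agrees with the
           exhaustive oracle", {
  spec <- sim_spec(seed = 17L,
                   offtargets = data.table::data.table(
                     mismatches = 3L, pam = "NGG"))
  gen <- make_genome(spec)
  site <- gen$offtargets[1]
  m <- find_cryptic_site(gen$genome, site$chrom, site$cut - 10L,
                         site$cut + 10L, spec$guide)
  expect_equal(m$mismatches, 3L)
  expect_true(m$pam_ok)
  expect_equal(m$presumed_cut, site$cut)
  expect_equal(m$strand, site$strand)
  # perfect on-target site
  b <- gen$bait
  m0 <- find_cryptic_site(gen$genome, b$chrom, b$cut_pos - 10L,
                          b$cut_pos + 10L, spec$guide)
  expect_equal(m0$mismatches, 0L)
  expect_equal(m0$presumed_cut, b$cut_pos)
  # random stretch: none, confirmed by the exhaustive oracle
  lo <- 200000L; hi <- 202000L
  m1 <- find_cryptic_site(gen$genome, "chr2", lo, hi, spec$guide,
                          slop = 0L)
  ora <- oracle_best_site(substr(gen$genome[["chr2"]], lo, hi),
                          spec$guide, c("NGG", "NAG"), 6L)
  expect_identical(is.null(m1), is.null(ora))
  if (!is.null(m1)) expect_equal(m1$mismatches, ora$mm)
  expect_error(find_cryptic_site(gen$genome, "chr1", -5L, 100L,
                                 spec$guide), "outside")
})

test_that("replicate merging applies the junction and recurrence filters", {
  spec <- sim_spec(seed = 18L,
                   offtargets = data.table::data.table(
                     mismatches = c(2L, 2L, 2L),
                     pam = c("NGG", "NGG", "NGG")))
  gen <- make_genome(spec)
  sites <- gen$offtargets
  p <- peak_params()
  mkj <- function(site, n) data.table::data.table(
    chrom = site$chrom, pos = site$cut + seq_len(n) %% 7L - 3L,
    strand = rep(c("+", "-"), length.out = n))
  cand <- function(site) data.table::data.table(
    chrom = site$chrom, start = site$cut - 25L, end = site$cut + 25L,
    count = 5L, lambda = 1e-3, pvalue = 1e-9, qvalue = 1e-8)
  # site 1 in 3/3 replicates with 10, 5, 4 junctions -> kept, count 19
  # site 2 in 1/3 replicates -> removed
  # site 3 recurrent but only 2 pooled junctions -> removed
  cands <- list(rbind(cand(sites[1]), cand(sites[2]), cand(sites[3])),
                rbind(cand(sites[1]), cand(sites[3])),
                cand(sites[1]))
  jxs <- list(rbind(mkj(sites[1], 10L), mkj(sites[2], 10L),
                    mkj(sites[3], 1L)),
              rbind(mkj(sites[1], 5L), mkj(sites[3], 1L)),
              mkj(sites[1], 4L))
  hs <- filter_and_merge_hotspots(cands, jxs, gen$genome, gen$bait, p)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$presumed_cut, sites$cut[1])
  expect_equal(hs$junction_count, 19L)
  expect_equal(hs$replicate_support, 3L)
  # fewer replicates than min_replicates is a configuration error
  expect_error(filter_and_merge_hotspots(cands[1], jxs[1], gen$genome,
                                         gen$bait, p), "replicate")
})

test_that("hotspot intensity is junctions per 1e5 corrected editing events", {
  s <- library_stats(0, 30000, 10200)
  ctl <- library_stats(0, 100, 100)
  expect_equal(hotspot_intensity(20, s, ctl), 50)
  expect_equal(hotspot_intensity(0, s, ctl), 0)
  expect_error(hotspot_intensity(20, s, s), "denominator")
  # missing control defaults to zero correction
  expect_equal(hotspot_intensity(20, library_stats(0, 30000, 10000)), 50)
})

test_that("directional balance is an exact two-sided binomial test", {
  expect_equal(directional_balance(10, 10), 1)
  expect_equal(directional_balance(20, 0), 2 * 0.5^20)
  expect_equal(directional_balance(1, 0), 1)
  expect_error(directional_balance(0, 0), "junction")
})

test_that("implanted off-targets are recovered with no false hotspots", {
  ot <- data.table::data.table(mismatches = c(2L, 4L, 6L),
                               pam = c("NGG", "NAG", "NGG"))
  spec <- sim_spec(genome_sizes = setNames(rep(5000000L, 2),
                                           c("chr1", "chr2")),
                   seed = 19L, offtargets = ot)
  gen <- make_genome(spec)
  jx <- simulate_junction_set(gen, c(12L, 20L, 30L), n_background = 30L,
                              n_replicates = 2L, seed = 20L)
  hs <- call_hotspots(jx, gen$genome, gen$bait)
  expect_equal(sort(hs$presumed_cut), sort(gen$offtargets$cut))
  expect_equal(nrow(hs), 3)
  expect_true(all(hs$replicate_support == 2L))
})
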