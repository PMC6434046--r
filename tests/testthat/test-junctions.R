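# Junction calling, the classification rule table, and translocation
# splitting.

test_that("classification rule table reproduces all fixtures", {
  fx <- classification_fixtures()
  expect_gte(nrow(fx$expected), 20)
  got <- classify_junctions(fx$calls, fx$edits, fx$bait)
  m <- merge(got, fx$expected, by = "id")
  expect_equal(nrow(m), nrow(fx$expected))
  expect_equal(m$category, m$exp_cat)
  expect_equal(m$subcategory, m$exp_sub)
  # every subcategory except the hotspot-dependent one is covered
  expect_setequal(
    setdiff(unique(m$exp_sub), "offtarget_translocation"),
    c("perfect", "small_insertion", "small_deletion",
      "insertion_plus_deletion", "large_deletion", "inversion",
      "background_translocation"))
})

test_that("classification is invariant under strand mirroring", {
  fx <- classification_fixtures()
  got <- classify_junctions(fx$calls, fx$edits, fx$bait)
  # mirror the whole configuration around L
  L <- 2000000L
  bait_m <- tiny_bait(cut = L - fx$bait$cut_pos, strand = "-")
  calls_m <- data.table::copy(fx$calls)
  flip <- c("+" = "-", "-" = "+")
  calls_m[, bait_end := L - bait_end]
  calls_m[, prey_pos := ifelse(is.na(prey_pos), NA_integer_, L - prey_pos)]
  calls_m[, prey_strand := ifelse(is.na(prey_strand), NA_character_,
                                  flip[prey_strand])]
  calls_m[, junction_pos := L - junction_pos]
  calls_m[, junction_strand := flip[junction_strand]]
  edits_m <- data.table::copy(fx$edits)
  # a deletion interval [p, p+len-1] mirrors to [L-p-len+1, L-p]
  edits_m[, ref_pos := ifelse(type == "del", L - ref_pos - len + 1L,
                              L - ref_pos)]
  got_m <- classify_junctions(calls_m, edits_m, bait_m)
  expect_equal(got_m$category[match(got$id, got_m$id)], got$category)
  expect_equal(got_m$subcategory[match(got$id, got_m$id)],
               got$subcategory)
})

test_that("call_junctions derives bait_end, prey and junction position", {
  bait <- tiny_bait()
  seg <- data.table::data.table(
    id = c("g", "t", "t", "x"),
    rmb = strrep("A", 14),
    role = c("bait", "bait", "prey", "prey"),
    chrom = c("chrT", "chrT", "chrX", "chrX"),
    start = c(bait$primer_start, bait$primer_start, 7000L, 7000L),
    end = c(bait$primer_start + 149L, bait$cut_pos, 7069L, 7069L),
    strand = c("+", "+", "-", "-"),
    qstart = c(1L, 1L, 81L, 1L), qend = c(150L, 80L, 150L, 70L),
    mapq = 60L)
  jn <- call_junctions(seg, bait)
  g <- jn$calls[jn$calls$id == "g", ]
  expect_true(is.na(g$prey_chrom))
  expect_equal(g$junction_pos, g$bait_end)
  t <- jn$calls[jn$calls$id == "t", ]
  expect_equal(t$bait_end, bait$cut_pos)
  # minus-strand prey: proximal end is the segment end
  expect_equal(t$prey_pos, 7069L)
  expect_equal(t$junction_pos, 7069L)
  expect_equal(t$junction_strand, "-")
  # molecule with no bait-overlapping first segment is dropped
  expect_equal(jn$dropped$id, "x")
  expect_equal(jn$dropped$reason, "baitless")
})

test_that("split_translocations honours the counting window", {
  bait <- tiny_bait()
  calls <- rbind(
    mk_call("near", bait, "chr9", 50300L, "+"),
    mk_call("far", bait, "chr9", 60000L, "+"),
    mk_call("other", bait, "chr8", 50300L, "+"))
  calls <- classify_junctions(calls,
                              data.table::data.table(id = character(0),
                                                     type = character(0),
                                                     ref_pos = integer(0),
                                                     len = integer(0)),
                              bait)
  hs <- data.table::data.table(chrom = "chr9", presumed_cut = 50000L)
  out <- split_translocations(calls, hs, count_window = 500L)
  expect_equal(out$subcategory[out$id == "near"], "offtarget_translocation")
  expect_equal(out$subcategory[out$id == "far"], "background_translocation")
  expect_equal(out$subcategory[out$id == "other"],
               "background_translocation")
  # empty hotspot set: everything background
  out0 <- split_translocations(calls, NULL)
  expect_true(all(out0$subcategory[out0$category == "translocation"] ==
                    "background_translocation"))
  # tallies sum to total translocations
  expect_equal(sum(out$subcategory %in% c("offtarget_translocation",
                                          "background_translocation")),
               sum(out$category == "translocation"))
})

test_that("category counts conserve molecules through the pipeline", {
  sp <- sim_spec(n_molecules = 400L, seed = 44L)
  lib <- simulate_library(sp)
  pre <- preprocess_reads(lib$reads, lib$adapters)
  aln <- toy_align(pre$molecules, lib$genome, lib$bait)
  grp <- group_alignments(aln$segments)
  jn <- call_junctions(grp$segments, lib$bait)
  n_called <- nrow(jn$calls)
  n_dropped <- nrow(aln$dropped) + nrow(grp$dropped) + nrow(jn$dropped)
  expect_equal(n_called + n_dropped, nrow(pre$molecules))
  cls <- classify_junctions(jn$calls, aln$edits, lib$bait)
  expect_equal(sum(table(cls$category)), n_called)
})
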