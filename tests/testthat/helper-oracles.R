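# Independent oracles and fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check: brute-force
# pairwise distances via utils::adist, Poisson tails via dpois sums,
# Benjamini-Hochberg via an explicit sorted cummin.

# Brute-force barcode clustering: all-pairs distance matrix + union-find.
# N must match nothing, including another N: map N to different sentinel
# characters on the two sides so adist never matches them.
oracle_cluster <- function(barcodes, max_edit = 2L,
                           metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  n <- length(barcodes)
  if (n == 0L) return(integer(0))
  a <- chartr("N", "!", barcodes)
  b <- chartr("N", "?", barcodes)
  d <- if (metric == "levenshtein") {
    utils::adist(a, b)
  } else {
    m <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      x <- strsplit(a[i], "")[[1]]; y <- strsplit(b[j], "")[[1]]
      m[i, j] <- if (length(x) != length(y)) .Machine$integer.max
                 else sum(x != y)
    }
    m
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] <= max_edit) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Direct Poisson-tail + BH recomputation of enrichment candidates,
# mirroring the documented definition with independent arithmetic.
oracle_peaks <- function(junctions, genome_sizes, bait, params) {
  jx <- as.data.frame(junctions)
  jx <- jx[!(jx$chrom == bait$chrom &
               abs(jx$pos - bait$cut_pos) <= params$exclusion_span), ]
  eff <- sum(as.numeric(genome_sizes))
  if (bait$chrom %in% names(genome_sizes))
    eff <- eff - min(2 * params$exclusion_span + 1,
                     genome_sizes[[bait$chrom]])
  rate_bg <- nrow(jx) / eff
  half <- params$extsize %/% 2L
  rows <- list()
  for (ch in unique(jx$chrom)) {
    pos <- sort(jx$pos[jx$chrom == ch])
    lo <- pos - half
    hi <- pos + (params$extsize - half) - 1L
    # merge overlapping extensions by scan
    s <- lo[1]; e <- hi[1]
    flush <- function(s, e) {
      cnt <- sum(pos >= s & pos <= e)
      mid <- (s + e) / 2
      wlo <- max(1, mid - params$llocal / 2)
      whi <- min(genome_sizes[[ch]], mid + params$llocal / 2)
      rloc <- sum(pos >= wlo & pos <= whi) / (whi - wlo + 1)
      lam <- max(rate_bg, rloc) * (e - s + 1 + params$extsize)
      # Poisson upper tail P(X >= cnt) via 1 - sum of dpois
      p <- 1 - sum(stats::dpois(0:(cnt - 1), lam))
      data.frame(chrom = ch, start = s, end = e, count = cnt,
                 lambda = lam, pvalue = p)
    }
    if (length(pos) > 1) for (k in 2:length(pos)) {
      if (lo[k] <= e + 1L) { e <- max(e, hi[k]) }
      else { rows[[length(rows) + 1L]] <- flush(s, e); s <- lo[k]; e <- hi[k] }
    }
    rows[[length(rows) + 1L]] <- flush(s, e)
  }
  out <- do.call(rbind, rows)
  # manual BH: sorted p * m / rank, cumulative minimum from the largest
  m <- nrow(out)
  o <- order(out$pvalue)
  q <- out$pvalue[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out$qvalue <- NA_real_
  out$qvalue[o] <- q
  out[order(out$chrom, out$start), ]
}

# Exhaustive cryptic-site scan oracle (plain double loop, both strands).
oracle_best_site <- function(seqstr, guide, pam_patterns, max_mm) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqstr else rc1(seqstr)
    for (p in seq_len(nchar(s) - 22L)) {
      proto <- substr(s, p, p + 19L)
      pam <- substr(s, p + 20L, p + 22L)
      mm <- sum(strsplit(proto, "")[[1]] != strsplit(guide, "")[[1]])
      pam_ok <- any(vapply(pam_patterns, function(pp) {
        pc <- strsplit(pp, "")[[1]]; xc <- strsplit(pam, "")[[1]]
        all(pc == "N" | pc == xc)
      }, logical(1)))
      if (mm <= max_mm && (pam_ok || mm <= max_mm - 2L)) {
        if (is.null(best) || mm < best$mm)
          best <- list(mm = mm, strand = strand, pam_ok = pam_ok)
      }
    }
  }
  best
}

# A minimal bait configuration for constructed junction-call fixtures.
tiny_bait <- function(cut = 10000L, strand = "+") {
  if (strand == "+")
    bait_config("chrT", "+", cut - 79L, cut - 60L, cut,
                strrep("AC", 10))
  else
    bait_config("chrT", "-", cut + 60L, cut + 79L, cut,
                strrep("AC", 10))
}

# One constructed junction call plus optional edits.
mk_call <- function(id, bait, prey_chrom = NA_character_,
                    prey_pos = NA_integer_, prey_strand = NA_character_,
                    bait_end = bait$cut_pos, rmb = strrep("A", 14)) {
  data.table::data.table(
    id = id, rmb = rmb, bait_end = bait_end,
    prey_chrom = prey_chrom, prey_pos = as.integer(prey_pos),
    prey_strand = prey_strand,
    junction_chrom = ifelse(is.na(prey_chrom), bait$chrom, prey_chrom),
    junction_pos = as.integer(ifelse(is.na(prey_pos), bait_end, prey_pos)),
    junction_strand = ifelse(is.na(prey_strand), bait$strand, prey_strand))
}

mk_edit <- function(id, type, ref_pos, len = 1L) {
  data.table::data.table(id = id, type = type,
                         ref_pos = as.integer(ref_pos),
                         len = as.integer(len))
}

# The classification rule table used by both the unit tests and the
# acceptance suite: >= 20 fixtures covering every subcategory and the
# window boundaries (exactly 5 bp, exactly 250,000 bp).
classification_fixtures <- function() {
  bait <- tiny_bait()
  cut <- bait$cut_pos
  fx <- list(
    list("germline_plain",  NULL, NULL, "germline", "perfect"),
    list("del_at_cut",      list("del", cut, 2L), NULL,
         "indel", "small_deletion"),
    list("ins_at_cut",      list("ins", cut, 3L), NULL,
         "indel", "small_insertion"),
    list("ins_plus_del",    list("del", cut + 1L, 1L),
         list("ins", cut - 1L, 2L), "indel", "insertion_plus_deletion"),
    list("del_at_plus5",    list("del", cut + 5L, 4L), NULL,
         "indel", "small_deletion"),
    list("del_at_minus5",   list("del", cut - 5L, 1L), NULL,
         "indel", "small_deletion"),
    list("del_at_plus6",    list("del", cut + 6L, 2L), NULL,
         "germline", "perfect"),
    list("del_end_minus5",  list("del", cut - 9L, 5L), NULL,
         "indel", "small_deletion"),
    list("del_end_minus6",  list("del", cut - 9L, 4L), NULL,
         "germline", "perfect"),
    list("ins_at_plus5",    list("ins", cut + 5L, 1L), NULL,
         "indel", "small_insertion"),
    list("ins_at_plus6",    list("ins", cut + 6L, 1L), NULL,
         "germline", "perfect"))
  calls <- list(); edits <- list(); expect <- list()
  for (f in fx) {
    calls[[length(calls) + 1L]] <- mk_call(f[[1]], bait)
    for (e in f[2:3])
      if (!is.null(e))
        edits[[length(edits) + 1L]] <- mk_edit(f[[1]], e[[1]], e[[2]], e[[3]])
    expect[[length(expect) + 1L]] <-
      data.table::data.table(id = f[[1]], exp_cat = f[[4]],
                             exp_sub = f[[5]])
  }
  prey_fx <- list(
    list("ld_40kb",      "chrT", cut + 40000L, "+", "indel", "large_deletion"),
    list("ld_upstream",  "chrT", cut - 40000L, "+", "indel", "large_deletion"),
    list("inv_down",     "chrT", cut + 3000L, "-", "indel", "inversion"),
    list("inv_up",       "chrT", cut - 3000L, "-", "indel", "inversion"),
    list("ld_at_250k",   "chrT", cut + 250000L, "+", "indel", "large_deletion"),
    list("ld_at_m250k",  "chrT", cut - 250000L, "+", "indel", "large_deletion"),
    list("tx_250001",    "chrT", cut + 250001L, "+",
         "translocation", "background_translocation"),
    list("tx_m250001",   "chrT", cut - 250001L, "-",
         "translocation", "background_translocation"),
    list("tx_otherchr",  "chrX", 5000L, "+",
         "translocation", "background_translocation"),
    list("tx_otherchr2", "chrX", 5000L, "-",
         "translocation", "background_translocation"),
    list("inv_at_250k",  "chrT", cut + 250000L, "-", "indel", "inversion"))
  for (f in prey_fx) {
    calls[[length(calls) + 1L]] <-
      mk_call(f[[1]], bait, prey_chrom = f[[2]], prey_pos = f[[3]],
              prey_strand = f[[4]])
    expect[[length(expect) + 1L]] <-
      data.table::data.table(id = f[[1]], exp_cat = f[[5]],
                             exp_sub = f[[6]])
  }
  list(bait = bait,
       calls = data.table::rbindlist(calls),
       edits = if (length(edits)) data.table::rbindlist(edits) else
         data.table::data.table(id = character(0), type = character(0),
                                ref_pos = integer(0), len = integer(0)),
       expected = data.table::rbindlist(expect))
}

# Distinct random barcodes of length 14 (plain ACGT).
random_barcodes <- function(n, len = 14L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}
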