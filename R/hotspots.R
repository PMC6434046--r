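# Off-target hotspot identification from genome-wide translocation
# junctions: a from-scratch local-Poisson enrichment scan over
# extension-merged junction clusters, cryptic target-site matching with
# PAM rules, replicate recurrence, and intensity scoring per 100,000
# editing events.

#' Call translocation-enriched candidate regions
#'
#' Junctions proximal to the bait (within `exclusion_span` of the cut)
#' are removed; each remaining junction is extended to `extsize` bp and
#' overlapping extensions are merged into candidate regions. Each
#' candidate's junction count is tested against a Poisson background
#' `lambda = max(genome-wide rate, local rate) * (width + extsize)`,
#' where the local rate is measured in an `llocal`-bp window centred on
#' the candidate (clipped at chromosome ends; candidate junctions
#' included, which is conservative). P-values are Benjamini-Hochberg
#' corrected across all candidates, and candidates pass with
#' `q <= q_threshold` and at least `min_count` junctions (a single
#' extended fragment never constitutes a pile-up).
#'
#' @param junctions data.table with `chrom`, `pos`, `strand` of
#'   deduplicated translocation junctions.
#' @param genome_sizes named vector of chromosome lengths.
#' @param bait a [bait_config()] (for the exclusion zone).
#' @param params a [peak_params()].
#' @return A data.table of candidates: `chrom`, `start`, `end`, `count`,
#'   `lambda`, `pvalue`, `qvalue`, filtered to significant ones.
#'   All candidates (with their q-values) are attached as attribute
#'   `"all_candidates"` for diagnostics.
#' @export
call_enriched_regions <- function(junctions, genome_sizes, bait,
                                  params = peak_params()) {
  junctions <- as.data.table(junctions)
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), count = integer(0),
                      lambda = numeric(0), pvalue = numeric(0),
                      qvalue = numeric(0))
  if (nrow(junctions) == 0L) return(empty)
  keep <- !(junctions$chrom == bait$chrom &
              abs(junctions$pos - bait$cut_pos) <= params$exclusion_span)
  junctions <- junctions[keep, ]
  if (nrow(junctions) == 0L) return(empty)

  eff_genome <- sum(as.numeric(genome_sizes))
  if (bait$chrom %in% names(genome_sizes))
    eff_genome <- eff_genome - min(2 * params$exclusion_span + 1,
                                   genome_sizes[[bait$chrom]])
  rate_bg <- nrow(junctions) / eff_genome

  half <- params$extsize %/% 2L
  cands <- list()
  for (ch in unique(junctions$chrom)) {
    pos <- sort(junctions$pos[junctions$chrom == ch])
    ir <- IRanges::reduce(IRanges::IRanges(pos - half,
                                           pos + (params$extsize - half) - 1L))
    hits <- IRanges::countOverlaps(ir, IRanges::IRanges(pos, pos))
    mid <- (IRanges::start(ir) + IRanges::end(ir)) / 2
    wlo <- pmax(1, mid - params$llocal / 2)
    whi <- pmin(genome_sizes[[ch]], mid + params$llocal / 2)
    inwin <- IRanges::countOverlaps(IRanges::IRanges(as.integer(wlo),
                                                     as.integer(whi)),
                                    IRanges::IRanges(pos, pos))
    rate_loc <- inwin / (whi - wlo + 1)
    cands[[ch]] <- data.table(chrom = ch, start = IRanges::start(ir),
                              end = IRanges::end(ir),
                              count = as.integer(hits),
                              rate_local = rate_loc)
  }
  cand <- rbindlist(cands)
  cand[, lambda := pmax(rate_bg, cand$rate_local) *
         (end - start + 1L + params$extsize)]
  cand[, pvalue := ppois(count - 1L, lambda, lower.tail = FALSE)]
  cand[, qvalue := p.adjust(pvalue, method = "BH")]
  cand[, rate_local := NULL]
  setorder(cand, chrom, start)
  out <- cand[cand$qvalue <= params$q_threshold &
                cand$count >= params$min_count, ]
  data.table::setattr(out, "all_candidates", cand)
  out[]
}

#' Find the best cryptic target site near a candidate region
#'
#' Scans both strands of `candidate interval +/- slop` for the 20-mer
#' most similar to the guide followed by a 3-nt PAM. A site is acceptable
#' when its protospacer mismatch count is at most `max_mm` and either its
#' PAM matches one of the accepted patterns or the match is very close
#' (`mismatches <= max_mm - 2`); the best acceptable site (fewest
#' mismatches; intact PAM, forward strand and leftmost position as
#' tie-breaks) is returned, or `NULL` when none qualifies. The presumed
#' cut sits 3 bp 5' of the PAM, between protospacer positions 17 and 18.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom,start,end candidate interval (1-based inclusive).
#' @param guide 20-nt protospacer.
#' @param pam_patterns accepted PAM patterns (`N` matches any base).
#' @param max_mm maximum protospacer mismatches.
#' @param slop bp added on each side of the interval before scanning.
#' @return A one-row data.table (`chrom`, `site_start`, `strand`,
#'   `matched_seq`, `mismatches`, `pam_ok`, `presumed_cut`) or `NULL`.
#' @export
find_cryptic_site <- function(genome, chrom, start, end, guide,
                              pam_patterns = c("NGG", "NAG"),
                              max_mm = 6L, slop = 500L) {
  if (!chrom %in% names(genome)) stopf("unknown chromosome %s", chrom)
  glen <- nchar(genome[[chrom]])
  if (start < 1L || end > glen || start > end)
    stopf("interval outside the genome")
  lo <- max(1L, start - slop)
  hi <- min(glen, end + slop)
  win <- substr(genome[[chrom]], lo, hi)
  W <- nchar(win)
  site_w <- 23L
  if (W < site_w) return(NULL)

  scan_one <- function(seqstr) {
    chars <- strsplit(seqstr, "")[[1]]
    npos <- length(chars) - site_w + 1L
    gc <- strsplit(guide, "")[[1]]
    mm <- integer(npos)
    for (i in 1:20) mm <- mm + (chars[seq_len(npos) + i - 1L] != gc[i])
    pam3 <- substring(seqstr, seq_len(npos) + 20L, seq_len(npos) + 22L)
    pam_ok <- rep(FALSE, npos)
    for (p in pam_patterns) pam_ok <- pam_ok | motif_mismatch(pam3, p) == 0L
    data.table(p = seq_len(npos), mismatches = mm, pam_ok = pam_ok)
  }

  fwd <- scan_one(win)
  fwd[, strand := "+"]
  fwd[, site_start := lo + p - 1L]
  rev <- scan_one(revcomp(win))
  rev[, strand := "-"]
  rev[, site_start := hi - (p + site_w - 1L) + 1L]
  all <- rbind(fwd, rev)
  ok <- all[all$mismatches <= max_mm &
              (all$pam_ok | all$mismatches <= max_mm - 2L), ]
  if (nrow(ok) == 0L) return(NULL)
  setorder(ok, mismatches, -pam_ok, strand, site_start)
  best <- ok[1, ]
  site_seq <- substr(genome[[chrom]], best$site_start,
                     best$site_start + site_w - 1L)
  if (best$strand == "-") site_seq <- revcomp(site_seq)
  data.table(chrom = chrom, site_start = best$site_start,
             strand = best$strand, matched_seq = site_seq,
             mismatches = best$mismatches, pam_ok = best$pam_ok,
             presumed_cut = cut_from_site(best$site_start, best$strand))
}

#' Two-sided directional-balance test of junction orientations
#'
#' Genuine off-target cuts accumulate junctions in both orientations
#' centred on the cut; biased orientation suggests an
#' off-target-independent junction pile. Reported as an annotation, not
#' a hard filter.
#'
#' @param n_plus,n_minus junction counts by orientation.
#' @return Two-sided exact binomial p-value (1 for a single junction).
#' @export
directional_balance <- function(n_plus, n_minus) {
  n <- n_plus + n_minus
  if (n < 1L) stopf("at least one junction required")
  binom.test(n_plus, n, 0.5)$p.value
}

#' Filter candidates and merge them across replicate libraries
#'
#' For every candidate region a cryptic target site is sought; candidates
#' without one are removed. Surviving candidates are represented by their
#' presumed cut extended by `count_window` bp on each side and merged
#' across replicates by interval overlap. A merged site is kept iff it is
#' supported by at least `min_replicates` replicates and the pooled
#' junction count within `count_window` of the presumed cut is at least
#' `min_junctions`.
#'
#' @param candidates_by_rep list (one per replicate) of candidate tables
#'   from [call_enriched_regions()].
#' @param junctions_by_rep list of the corresponding junction tables.
#' @param genome named character vector of chromosome sequences.
#' @param bait a [bait_config()] (supplies the guide).
#' @param params a [peak_params()].
#' @return A hotspot table: `chrom`, `start`, `end`, `presumed_cut`,
#'   `strand`, `matched_seq`, `mismatches`, `pam_ok`, `junction_count`,
#'   `replicate_support`, `balance_p`.
#' @export
filter_and_merge_hotspots <- function(candidates_by_rep, junctions_by_rep,
                                      genome, bait,
                                      params = peak_params()) {
  n_rep <- length(candidates_by_rep)
  if (n_rep < params$min_replicates)
    stopf(paste0("need at least %d replicate libraries ",
                 "(or lower min_replicates explicitly)"),
          params$min_replicates)
  matched <- list()
  for (r in seq_len(n_rep)) {
    cd <- as.data.table(candidates_by_rep[[r]])
    if (nrow(cd) == 0L) next
    for (i in seq_len(nrow(cd))) {
      m <- find_cryptic_site(genome, cd$chrom[i], cd$start[i], cd$end[i],
                             bait$guide, params$pam_patterns,
                             params$max_mm, params$slop)
      if (is.null(m)) next
      matched[[length(matched) + 1L]] <-
        data.table(rep_id = r, chrom = m$chrom,
                   presumed_cut = m$presumed_cut)
    }
  }
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), presumed_cut = integer(0),
                      strand = character(0), matched_seq = character(0),
                      mismatches = integer(0), pam_ok = logical(0),
                      junction_count = integer(0),
                      replicate_support = integer(0),
                      balance_p = numeric(0))
  if (!length(matched)) return(empty)
  md <- rbindlist(matched)
  pooled <- rbindlist(lapply(junctions_by_rep, as.data.table))

  out <- list()
  for (ch in unique(md$chrom)) {
    sub <- md[md$chrom == ch, ]
    ir <- IRanges::IRanges(sub$presumed_cut - params$count_window,
                           sub$presumed_cut + params$count_window)
    merged <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)
    for (g in unique(grp)) {
      rows <- sub[grp == g, ]
      support <- length(unique(rows$rep_id))
      # canonical site: rescan the merged interval once
      m <- find_cryptic_site(genome, ch,
                             min(rows$presumed_cut),
                             max(rows$presumed_cut),
                             bait$guide, params$pam_patterns,
                             params$max_mm, params$slop)
      if (is.null(m)) next
      jp <- pooled[pooled$chrom == ch &
                     abs(pooled$pos - m$presumed_cut) <=
                       params$count_window, ]
      jc <- nrow(jp)
      if (support < params$min_replicates || jc < params$min_junctions)
        next
      bal <- if (jc >= 1L)
        directional_balance(sum(jp$strand == "+"), sum(jp$strand == "-"))
      else NA_real_
      out[[length(out) + 1L]] <- data.table(
        chrom = ch,
        start = m$presumed_cut - params$count_window,
        end = m$presumed_cut + params$count_window,
        presumed_cut = m$presumed_cut, strand = m$strand,
        matched_seq = m$matched_seq, mismatches = m$mismatches,
        pam_ok = m$pam_ok, junction_count = jc,
        replicate_support = support, balance_p = bal)
    }
  }
  if (!length(out)) return(empty)
  res <- rbindlist(out)
  setorder(res, chrom, presumed_cut)
  res[]
}

#' End-to-end hotspot calling across replicates
#'
#' Convenience wrapper: per-replicate enrichment calling followed by
#' cryptic-site filtering and replicate merging.
#'
#' @param junctions_by_rep list of junction tables (`chrom`, `pos`,
#'   `strand`), one per replicate.
#' @param genome named character vector of chromosome sequences.
#' @param bait a [bait_config()].
#' @param params a [peak_params()].
#' @return A hotspot table (see [filter_and_merge_hotspots()]).
#' @export
call_hotspots <- function(junctions_by_rep, genome, bait,
                          params = peak_params()) {
  sizes <- vapply(genome, nchar, integer(1))
  cands <- lapply(junctions_by_rep, call_enriched_regions,
                  genome_sizes = sizes, bait = bait, params = params)
  filter_and_merge_hotspots(cands, junctions_by_rep, genome, bait, params)
}

#' Hotspot intensity per 100,000 editing events
#'
#' `intensity = junctions / ((I_S - I_C) + (T_S - T_C)) * 100000`, the
#' hotspot junction count normalised to the control-corrected number of
#' editing events (indels plus translocations) in the treated library.
#'
#' @param junction_count hotspot junction count(s) within the counting
#'   window.
#' @param sample,control `library_stats` objects; when no control is
#'   available use `library_stats(0, 0, 0)` semantics via `control =
#'   NULL` (counts default to 0).
#' @return Intensity value(s) per 100,000 editing events.
#' @export
hotspot_intensity <- function(junction_count, sample, control = NULL) {
  ic <- if (is.null(control)) 0L else control$I
  tc <- if (is.null(control)) 0L else control$T
  denom <- (sample$I - ic) + (sample$T - tc)
  if (denom <= 0) stopf("non-positive editing-event denominator")
  junction_count / denom * 1e5
}
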