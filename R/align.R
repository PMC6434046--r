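# Primer-anchored split alignment of cleaned molecules against a toy
# genome. Not a general-purpose mapper: read 1 is anchored at the known
# bait primer, extended along the bait reference until it diverges, small
# indels are resolved by frame-shift resynchronisation, and any remaining
# tail is seed-mapped genome-wide to locate the prey segment. Adequate
# for error-free or low-error simulated reads; real libraries should be
# mapped with an external aligner and imported via [segments_from_bam()].

#' Toy aligner settings
#' @param min_prey_len minimum unaligned tail length (nt) to attempt a
#'   prey mapping; shorter tails drop the molecule.
#' @param max_del,max_ins largest deletion/insertion resolved in-read;
#'   larger events surface as split (prey-bearing) alignments.
#' @param seed_len,seed_offsets exact-match seed length and query offsets
#'   used for genome-wide tail mapping.
#' @param max_edit_frac maximum mismatch fraction tolerated across an
#'   aligned segment (chimera guard).
#' @return A list of aligner parameters.
#' @export
align_params <- function(min_prey_len = 20L, max_del = 18L, max_ins = 12L,
                         seed_len = 20L, seed_offsets = c(0L, 20L, 40L),
                         max_edit_frac = 0.10) {
  list(min_prey_len = as.integer(min_prey_len),
       max_del = as.integer(max_del), max_ins = as.integer(max_ins),
       seed_len = as.integer(seed_len),
       seed_offsets = as.integer(seed_offsets),
       max_edit_frac = max_edit_frac)
}

# bait-window position (1-based along the read direction) -> genome coord
b2g <- function(b, bait) {
  if (bait$strand == "+") bait$primer_start + b - 1L
  else bait$primer_end - b + 1L
}

#' Align cleaned molecules with the bundled primer-anchored aligner
#'
#' @param molecules data.table with columns `id`, `rmb`, `insert_seq`
#'   (trimmed read 1, primer first).
#' @param genome named character vector of chromosome sequences.
#' @param bait a [bait_config()].
#' @param params an [align_params()] list.
#' @return A list with `segments` (data.table `id`, `rmb`, `role`,
#'   `chrom`, `start`, `end`, `strand`, `qstart`, `qend`, `mapq`),
#'   `edits` (data.table `id`, `type` in ins/del, `ref_pos`, `len`), and
#'   `dropped` (data.table `id`, `reason`).
#' @export
toy_align <- function(molecules, genome, bait, params = align_params()) {
  molecules <- as.data.table(molecules)
  n <- nrow(molecules)
  empty <- list(
    segments = data.table(id = character(0), rmb = character(0),
                          role = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), qstart = integer(0),
                          qend = integer(0), mapq = integer(0)),
    edits = data.table(id = character(0), type = character(0),
                       ref_pos = integer(0), len = integer(0)),
    dropped = data.table(id = character(0), reason = character(0)))
  if (n == 0L) return(empty)

  seqs <- toupper(molecules$insert_seq)
  ids <- molecules$id
  rmbs <- molecules$rmb
  lens <- nchar(seqs)
  L <- max(lens)
  glens <- vapply(genome, nchar, integer(1))
  chromseq <- genome[[bait$chrom]]
  maxref <- L + params$max_del + 10L
  if (bait$strand == "+") {
    window <- substr(chromseq, bait$primer_start,
                     min(bait$primer_start + maxref - 1L, nchar(chromseq)))
  } else {
    lo <- max(1L, bait$primer_end - maxref + 1L)
    window <- revcomp(substr(chromseq, lo, bait$primer_end))
  }
  wc <- strsplit(window, "")[[1]]
  Lw <- length(wc)

  # column-wise mismatch matrix read vs bait window (FALSE beyond read end)
  M <- matrix(FALSE, n, L)
  for (j in seq_len(min(L, Lw))) {
    cj <- substring(seqs, j, j)
    M[, j] <- cj != wc[j] & cj != ""
  }
  C <- M * 1L
  if (L >= 2L) for (j in 2:L) C[, j] <- C[, j - 1L] + C[, j]

  # first query position of a >=5-mismatches-in-10 divergence window
  # (a junction or indel produces ~7.5/10; sequencing errors at realistic
  # rates essentially never cluster that densely, and spurious triggers
  # are caught by the in-frame recheck below)
  div <- rep(NA_integer_, n)
  if (L >= 10L) {
    for (j in seq_len(L - 9L)) {
      w10 <- C[, j + 9L] - (if (j > 1L) C[, j - 1L] else 0L)
      hit <- is.na(div) & w10 >= 5L & (j + 9L) <= lens
      div[hit] <- j
    }
  }

  # preallocated accumulators (built into data.tables only at the end)
  drop_id <- character(n); drop_reason <- character(n); n_drop <- 0L
  note_drop <- function(i, why) {
    n_drop <<- n_drop + 1L
    drop_id[n_drop] <<- ids[i]
    drop_reason[n_drop] <<- why
  }

  seg_full_flag <- logical(n)        # fully bait-aligned, no edits
  indel_idx <- integer(n)            # resynced in-read indel
  indel_type <- character(n); indel_size <- integer(n)
  indel_qend <- integer(n); n_indel <- 0L
  tail_idx <- integer(n); tail_qend <- integer(n); n_tail <- 0L

  full <- which(is.na(div))
  if (length(full)) {
    mm_total <- C[cbind(full, lens[full])]
    bad <- mm_total > params$max_edit_frac * lens[full]
    for (i in full[bad]) note_drop(i, "bait_mismatch")
    seg_full_flag[full[!bad]] <- TRUE
  }

  # constant resync candidate list, smallest shift first (del before ins)
  cand_type <- c(rbind(rep("del", max(params$max_del, params$max_ins)),
                       rep("ins", max(params$max_del, params$max_ins))))
  cand_size <- c(rbind(seq_len(max(params$max_del, params$max_ins)),
                       seq_len(max(params$max_del, params$max_ins))))
  keep_cand <- (cand_type == "del" & cand_size <= params$max_del) |
    (cand_type == "ins" & cand_size <= params$max_ins)
  cand_type <- cand_type[keep_cand]; cand_size <- cand_size[keep_cand]

  dvg <- which(!is.na(div))
  rcs <- strsplit(seqs[dvg], "")
  for (k in seq_along(dvg)) {
    i <- dvg[k]
    rc <- rcs[[k]]
    len <- lens[i]
    j0 <- div[i]
    fm <- j0
    while (fm <= len && !M[i, fm]) fm <- fm + 1L
    q_end <- fm - 1L

    # in-frame recheck: a divergence window tripped by chance alignment
    # noise, with the read actually continuing in frame
    qa <- q_end + 1L
    pl <- min(20L, len - qa + 1L, Lw - qa + 1L)
    if (pl >= 12L &&
        sum(rc[qa:(qa + pl - 1L)] != wc[qa:(qa + pl - 1L)]) <= 2L) {
      qspan <- qa:len
      if (qa + length(qspan) - 1L <= Lw &&
          sum(rc[qspan] != wc[qspan]) <=
            params$max_edit_frac * length(qspan)) {
        seg_full_flag[i] <- TRUE
        next
      }
    }

    resolved <- FALSE
    for (ci in seq_along(cand_size)) {
      d <- cand_size[ci]
      if (cand_type[ci] == "del") {
        qa <- q_end + 1L; ra <- q_end + 1L + d
      } else {
        qa <- q_end + d + 1L; ra <- q_end + 1L
      }
      pl <- min(20L, len - qa + 1L, Lw - ra + 1L)
      if (pl < 12L) next
      if (sum(rc[qa:(qa + pl - 1L)] != wc[ra:(ra + pl - 1L)]) > 2L) next
      qspan <- qa:len
      rspan <- ra:(ra + length(qspan) - 1L)
      if (max(rspan) > Lw) next
      if (sum(rc[qspan] != wc[rspan]) >
            params$max_edit_frac * length(qspan)) next
      n_indel <- n_indel + 1L
      indel_idx[n_indel] <- i
      indel_type[n_indel] <- cand_type[ci]
      indel_size[n_indel] <- d
      indel_qend[n_indel] <- q_end
      resolved <- TRUE
      break
    }
    if (resolved) next

    if (len - q_end < params$min_prey_len) {
      note_drop(i, "short_tail")
      next
    }
    n_tail <- n_tail + 1L
    tail_idx[n_tail] <- i
    tail_qend[n_tail] <- q_end
  }
  indel_idx <- indel_idx[seq_len(n_indel)]
  indel_type <- indel_type[seq_len(n_indel)]
  indel_size <- indel_size[seq_len(n_indel)]
  indel_qend <- indel_qend[seq_len(n_indel)]
  tail_idx <- tail_idx[seq_len(n_tail)]
  tail_qend <- tail_qend[seq_len(n_tail)]
  seg_full_idx <- which(seg_full_flag)

  seg_parts <- list()

  if (length(seg_full_idx)) {
    e <- b2g(lens[seg_full_idx], bait)
    s <- b2g(rep(1L, length(seg_full_idx)), bait)
    seg_parts$full <- data.table(
      id = ids[seg_full_idx], rmb = rmbs[seg_full_idx], role = "bait",
      chrom = bait$chrom, start = pmin(s, e), end = pmax(s, e),
      strand = bait$strand, qstart = 1L, qend = lens[seg_full_idx],
      mapq = 60L)
  }

  edits <- empty$edits
  if (length(indel_idx)) {
    shift <- ifelse(indel_type == "del", indel_size, -indel_size)
    s <- b2g(rep(1L, length(indel_idx)), bait)
    e <- b2g(lens[indel_idx] + shift, bait)
    seg_parts$indel <- data.table(
      id = ids[indel_idx], rmb = rmbs[indel_idx], role = "bait",
      chrom = bait$chrom, start = pmin(s, e), end = pmax(s, e),
      strand = bait$strand, qstart = 1L, qend = lens[indel_idx],
      mapq = 60L)
    g1 <- b2g(indel_qend + 1L, bait)
    g2 <- b2g(indel_qend + indel_size, bait)
    gi <- b2g(indel_qend, bait)
    edits <- data.table(
      id = ids[indel_idx], type = indel_type,
      ref_pos = ifelse(indel_type == "del", pmin(g1, g2), gi),
      len = indel_size)
  }

  # genome-wide seed mapping for unresolved tails
  if (length(tail_idx)) {
    sl <- params$seed_len
    tails <- substr(seqs[tail_idx], tail_qend + 1L, lens[tail_idx])
    tl <- nchar(tails)
    offs_all <- params$seed_offsets
    seed_tbl <- rbindlist(lapply(offs_all, function(o) {
      sel <- which(o + sl <= tl)
      data.table(t = sel, off = o,
                 seed = substr(tails[sel], o + 1L, o + sl))
    }))
    seed_tbl <- seed_tbl[!grepl("[^ACGT]", seed_tbl$seed), ]
    useeds <- unique(seed_tbl$seed)
    hits <- seed_hits(useeds, genome, sl)   # data.table seed_k/chrom/start/strand
    seed_tbl[, sig := match(seed, useeds)]
    hj <- merge(seed_tbl, hits, by.x = "sig", by.y = "seed_k",
                allow.cartesian = TRUE)
    if (nrow(hj)) {
      hj[, pos := ifelse(strand == "+", start - off,
                         start + sl - 1L + off)]
      setorder(hj, t, chrom, strand, pos)
    }
    hj_split <- if (nrow(hj)) split(hj, by = "t", keep.by = TRUE)
                else list()

    status <- rep("unmapped_tail", length(tail_idx))
    pr_t <- integer(0); pr_chrom <- character(0); pr_strand <- character(0)
    pr_start <- integer(0); pr_end <- integer(0)
    for (key in names(hj_split)) {
      h <- hj_split[[key]]
      ti <- h$t[1]
      uniq <- !duplicated(paste(h$chrom, h$strand, h$pos))
      ch <- h$chrom[uniq]; st <- h$strand[uniq]; px <- h$pos[uniq]
      grp_break <- c(FALSE, ch[-1] != ch[-length(ch)] |
                       st[-1] != st[-length(st)] |
                       diff(px) > 3L)
      if (any(grp_break)) {
        status[ti] <- "ambiguous_tail"
        next
      }
      prox <- px[1]
      tlen <- tl[ti]
      if (st[1] == "+") {
        pstart <- prox; pend <- prox + tlen - 1L
      } else {
        pstart <- prox - tlen + 1L; pend <- prox
      }
      if (pstart < 1L || pend > glens[[ch[1]]]) {
        status[ti] <- "tail_out_of_range"
        next
      }
      gseq <- substr(genome[[ch[1]]], pstart, pend)
      if (st[1] == "-") gseq <- revcomp(gseq)
      mm <- sum(strsplit(tails[ti], "")[[1]] != strsplit(gseq, "")[[1]])
      if (mm > params$max_edit_frac * tlen) {
        status[ti] <- "tail_mismatch"
        next
      }
      status[ti] <- "ok"
      pr_t <- c(pr_t, ti); pr_chrom <- c(pr_chrom, ch[1])
      pr_strand <- c(pr_strand, st[1])
      pr_start <- c(pr_start, pstart); pr_end <- c(pr_end, pend)
    }
    for (ti in which(status != "ok")) note_drop(tail_idx[ti], status[ti])

    if (length(pr_t)) {
      i <- tail_idx[pr_t]
      qe <- tail_qend[pr_t]
      s <- b2g(rep(1L, length(i)), bait)
      e <- b2g(qe, bait)
      seg_parts$split_bait <- data.table(
        id = ids[i], rmb = rmbs[i], role = "bait", chrom = bait$chrom,
        start = pmin(s, e), end = pmax(s, e), strand = bait$strand,
        qstart = 1L, qend = qe, mapq = 60L)
      seg_parts$split_prey <- data.table(
        id = ids[i], rmb = rmbs[i], role = "prey", chrom = pr_chrom,
        start = pr_start, end = pr_end, strand = pr_strand,
        qstart = qe + 1L, qend = lens[i], mapq = 60L)
    }
  }

  segments <- rbindlist(c(list(empty$segments), seg_parts))
  dropped <- data.table(id = drop_id[seq_len(n_drop)],
                        reason = drop_reason[seq_len(n_drop)])
  setorder(segments, id, qstart)
  list(segments = segments, edits = edits, dropped = dropped)
}

# Exact-match positions of constant-width seeds on both genome strands.
# Returns a data.table (seed_k = index into `useeds`, chrom, start,
# strand); `start` is the forward-strand start of the matched window.
seed_hits <- function(useeds, genome, sl) {
  out <- data.table(seed_k = integer(0), chrom = character(0),
                    start = integer(0), strand = character(0))
  if (!length(useeds)) return(out)
  fwd <- Biostrings::DNAStringSet(useeds)
  pd_f <- Biostrings::PDict(fwd)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
  parts <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_f else pd_r
      st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
      lens <- lengths(st)
      if (!sum(lens)) next
      parts[[length(parts) + 1L]] <- data.table(
        seed_k = rep(seq_along(useeds), lens),
        chrom = ch, start = unlist(st), strand = strand)
    }
  }
  rbindlist(c(list(out), parts))
}

#' Group alignment records per molecule and apply the uniqueness rule
#'
#' Molecules whose bait-anchored segment is missing or not uniquely
#' mapped (`mapq < min_mapq`) are dropped and counted; remaining segments
#' are returned keyed by molecule in query order.
#'
#' @param segments a segment table as produced by [toy_align()] or
#'   [segments_from_bam()]; must carry `rmb`.
#' @param min_mapq minimum mapping quality for the bait segment
#'   (default 1, i.e. any non-multimapping alignment).
#' @return A list with `segments` (filtered, ordered) and `dropped`
#'   (data.table `id`, `reason`).
#' @export
group_alignments <- function(segments, min_mapq = 1L) {
  segments <- as.data.table(segments)
  if (nrow(segments) && any(is.na(segments$rmb)))
    stopf("alignment records missing the RMB tag")
  setorder(segments, id, qstart)
  first <- segments[, .(bait_ok = .SD$role[1] == "bait" &
                          .SD$mapq[1] >= min_mapq), by = id]
  bad <- first$id[!first$bait_ok]
  dropped <- data.table(id = bad,
                        reason = rep("bait_not_unique", length(bad)))
  list(segments = segments[!segments$id %in% bad, ], dropped = dropped)
}

#' Import alignment segments from a BAM/SAM file
#'
#' Reads primary and supplementary alignments, takes the molecule barcode
#' from the `RM` tag (falling back to an `RMB:Z:` token in the read
#' name), and converts CIGAR strings into reference intervals and query
#' intervals. Requires the Rsamtools package.
#'
#' @param path BAM file path (SAM input is converted via
#'   `Rsamtools::asBam`).
#' @param bait a [bait_config()] used to label bait-overlapping segments.
#' @return A segment table compatible with [group_alignments()].
#' @export
segments_from_bam <- function(path, bait) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("segments_from_bam requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand"),
    tag = "RM")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  qname <- as.character(b$qname)[keep]
  cig <- as.character(b$cigar)[keep]
  ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))
  ref_len <- vapply(ops, function(o) {
    n <- as.integer(sub("[MIDNSHP=X]", "", o))
    sum(n[grepl("[MDN=X]", o)])
  }, integer(1))
  q_lead <- vapply(ops, function(o) {
    if (length(o) && grepl("[SH]", o[1]))
      as.integer(sub("[MIDNSHP=X]", "", o[1])) else 0L
  }, integer(1))
  q_len <- vapply(ops, function(o) {
    n <- as.integer(sub("[MIDNSHP=X]", "", o))
    sum(n[grepl("[MI=X]", o)])
  }, integer(1))
  rmb <- b$tag$RM
  if (is.null(rmb)) {
    rmb <- ifelse(grepl("RMB:Z:", qname),
                  sub(".*RMB:Z:([ACGTN]+).*", "\\1", qname), NA_character_)
  } else rmb <- as.character(rmb)[keep]
  id <- sub("[ _]RMB:Z:.*", "", qname)
  st <- as.integer(b$pos)[keep]
  seg <- data.table(id = id, rmb = rmb,
                    role = NA_character_,
                    chrom = as.character(b$rname)[keep],
                    start = st, end = st + ref_len - 1L,
                    strand = as.character(b$strand)[keep],
                    qstart = q_lead + 1L, qend = q_lead + q_len,
                    mapq = as.integer(b$mapq)[keep])
  on_bait <- seg$chrom == bait$chrom &
    seg$start <= bait$primer_end & seg$end >= bait$primer_start
  seg$role <- ifelse(on_bait, "bait", "prey")
  setorder(seg, id, qstart)
  seg
}
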