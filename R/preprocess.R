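# Read preprocessing: adapter/quality trimming, length filtering,
# demultiplexing, bridge-adapter RMB extraction and bait-primer check.
#
# A read pair table is a data.table with columns id, seq1, qual1, seq2,
# qual2 (Phred+33 quality strings, equal length to their mate sequence).

#' Trim sequencing adapter and low-quality 3' ends
#'
#' Removes everything from the leftmost occurrence of the sequencing
#' adapter onward, then strips bases from the 3' end while their Phred
#' quality is below `spec$quality_floor`. The result is always a prefix of
#' the input, so trimming is idempotent.
#'
#' @param seq,quals character vectors of sequences and Phred+33 quality
#'   strings (equal lengths element-wise).
#' @param spec an [adapter_spec()].
#' @return A list with trimmed `seq` and `quals` character vectors.
#' @export
trim_read <- function(seq, quals, spec) {
  if (any(nchar(seq) != nchar(quals)))
    stopf("sequence and quality lengths differ")
  hit <- regexpr(spec$sequencing_adapter, seq, fixed = TRUE)
  cutat <- ifelse(hit > 0L, hit - 1L, nchar(seq))
  seq <- substr(seq, 1L, cutat)
  quals <- substr(quals, 1L, cutat)
  f <- spec$quality_floor
  if (f > 0L) {
    # Phred+33: scores 0..(f-1) occupy ASCII 33..(32+f)
    cls <- sprintf("[\\x21-\\x%02x]+$", 32L + f)
    keep <- nchar(sub(cls, "", quals, perl = TRUE))
    seq <- substr(seq, 1L, keep)
    quals <- substr(quals, 1L, keep)
  }
  list(seq = seq, quals = quals)
}

#' Discard read pairs with a short mate
#'
#' A pair survives only if both mates are at least `min_len` bases after
#' trimming; input order is preserved.
#'
#' @param pairs a read pair table.
#' @param min_len minimum mate length (default 25).
#' @return The surviving rows of `pairs`.
#' @export
filter_short <- function(pairs, min_len = 25L) {
  pairs[nchar(pairs$seq1) >= min_len & nchar(pairs$seq2) >= min_len, ]
}

#' Assign reads to samples by index sequence
#'
#' Each index read is assigned to the unique sample whose index lies
#' within `max_mismatch` Hamming distance; reads matching no index go to
#' `"undetermined"`. The index table must be unambiguous: equal-length
#' indices with pairwise distance greater than `2 * max_mismatch`.
#'
#' @param index_seqs character vector of observed index reads.
#' @param index_table named character vector: `names` are sample ids,
#'   values are index sequences.
#' @param max_mismatch mismatch tolerance (default 1, the common
#'   demultiplexer default).
#' @return A factor of sample assignments with levels
#'   `c(names(index_table), "undetermined")`.
#' @export
demultiplex <- function(index_seqs, index_table, max_mismatch = 1L) {
  idx <- toupper(index_table)
  w <- nchar(idx)
  if (length(unique(w)) != 1L)
    stopf("index sequences must have equal length")
  if (length(idx) > 1L) {
    for (i in seq_along(idx)[-1]) {
      d <- hamming_mm(idx[seq_len(i - 1L)], idx[i])
      if (any(d <= 2L * max_mismatch))
        stopf("ambiguous index table: pairwise distance must exceed %d",
              2L * max_mismatch)
    }
  }
  obs <- substr(toupper(index_seqs), 1L, w[1])
  mm <- vapply(idx, function(p) hamming_mm(obs, p), integer(length(obs)))
  mm <- matrix(mm, nrow = length(obs))
  best <- max.col(-mm, ties.method = "first")
  ok <- mm[cbind(seq_along(obs), best)] <= max_mismatch
  lab <- ifelse(ok, names(idx)[best], "undetermined")
  factor(lab, levels = c(names(idx), "undetermined"))
}

#' Extract the random molecular barcode from the bridge adapter
#'
#' Locates the bridge-adapter template in the prey-side mate (each flank
#' matched with at most one mismatch, no indels, so the 14-nt barcode
#' stays frame-aligned), reads the 14 bases in the N-window as the RMB and
#' returns the sequence beyond the adapter. Failure to find the template
#' is a per-read signal (`ok = FALSE`), not an error.
#'
#' @param mate_seq character vector of trimmed prey-side mates.
#' @param spec an [adapter_spec()].
#' @return A data.table with columns `rmb`, `prey_seq`, `ok`.
#' @export
extract_rmb <- function(mate_seq, spec) {
  n <- length(mate_seq)
  f5 <- spec$bridge_flank5
  f3 <- spec$bridge_flank3
  n5 <- nchar(f5); n3 <- nchar(f3)
  out <- data.table(rmb = NA_character_, prey_seq = NA_character_,
                    ok = logical(n))
  if (n == 0L) return(out)
  subj <- Biostrings::DNAStringSet(chartr(" ", "N", mate_seq))
  hits <- Biostrings::vmatchPattern(f5, subj, max.mismatch = 1L,
                                    fixed = TRUE)
  first5 <- vapply(Biostrings::startIndex(hits), function(s)
    if (length(s)) min(s) else NA_integer_, integer(1))
  p_rmb <- first5 + n5
  p_f3 <- p_rmb + 14L
  need <- p_f3 + n3 - 1L
  cand <- !is.na(first5) & nchar(mate_seq) >= need
  if (any(cand)) {
    obs3 <- substr(mate_seq[cand], p_f3[cand], p_f3[cand] + n3 - 1L)
    good3 <- hamming_mm(obs3, f3) <= 1L
    okidx <- which(cand)[good3]
    out$ok[okidx] <- TRUE
    out$rmb[okidx] <- substr(mate_seq[okidx], p_rmb[okidx],
                             p_rmb[okidx] + 13L)
    out$prey_seq[okidx] <- substr(mate_seq[okidx],
                                  p_f3[okidx] + n3, nchar(mate_seq[okidx]))
  }
  out
}

#' Check that read 1 starts with the bait primer
#'
#' @param read1_seq character vector of trimmed read-1 sequences.
#' @param spec an [adapter_spec()].
#' @param max_mismatch mismatch tolerance (default 1).
#' @return Logical vector: `TRUE` where the read begins with the bait
#'   primer within the mismatch tolerance.
#' @export
verify_bait_primer <- function(read1_seq, spec, max_mismatch = 1L) {
  p <- spec$bait_primer
  w <- nchar(p)
  long_enough <- nchar(read1_seq) >= w
  mm <- hamming_mm(substr(read1_seq, 1L, w), p)
  long_enough & mm <= max_mismatch
}

#' Clean a raw read-pair table into molecules
#'
#' Runs the full preprocessing chain: adapter/quality trimming of both
#' mates, discarding pairs with a mate shorter than `spec$min_len`,
#' bait-primer verification on read 1 and RMB extraction from read 2.
#' Every input pair lands in exactly one disposition counter.
#'
#' @param reads a read pair table (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param spec an [adapter_spec()].
#' @return A list with `molecules` (data.table `id`, `rmb`, `insert_seq`,
#'   `insert_qual`, `mate_seq`) and `counts` (data.table `stage`, `n`;
#'   stages `input`, `short_after_trim`, `primer_fail`, `rmb_fail`,
#'   `clean`).
#' @export
preprocess_reads <- function(reads, spec) {
  reads <- as.data.table(reads)
  n_in <- nrow(reads)
  t1 <- trim_read(reads$seq1, reads$qual1, spec)
  t2 <- trim_read(reads$seq2, reads$qual2, spec)
  dt <- data.table(id = reads$id, seq1 = t1$seq, qual1 = t1$quals,
                   seq2 = t2$seq, qual2 = t2$quals)
  kept <- filter_short(dt, spec$min_len)
  n_short <- n_in - nrow(kept)
  primer_ok <- verify_bait_primer(kept$seq1, spec)
  n_primer <- sum(!primer_ok)
  kept <- kept[primer_ok, ]
  rmbx <- extract_rmb(kept$seq2, spec)
  n_rmb <- sum(!rmbx$ok)
  mol <- data.table(id = kept$id[rmbx$ok],
                    rmb = rmbx$rmb[rmbx$ok],
                    insert_seq = kept$seq1[rmbx$ok],
                    insert_qual = kept$qual1[rmbx$ok],
                    mate_seq = rmbx$prey_seq[rmbx$ok])
  counts <- data.table(stage = c("input", "short_after_trim", "primer_fail",
                                 "rmb_fail", "clean"),
                       n = c(n_in, n_short, n_primer, n_rmb, nrow(mol)))
  list(molecules = mol, counts = counts)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param fq1,fq2 paths to the two mate FASTQ files (gzip allowed).
#' @return A read pair table (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) stopf("mate files differ in read count")
  ids <- sub(" .*", "", names(r1))
  data.table(id = ids,
             seq1 = as.character(r1),
             qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             seq2 = as.character(r2),
             qual2 = as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write a read-pair table as paired FASTQ
#'
#' @param reads a read pair table.
#' @param fq1,fq2 output paths; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq_pairs <- function(reads, fq1, fq2) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", path))
  }
  write_one(reads$seq1, reads$qual1, reads$id, fq1)
  write_one(reads$seq2, reads$qual2, reads$id, fq2)
  invisible(NULL)
}

#' Write cleaned molecules as interleaved FASTQ with the RMB in the name
#'
#' Read names carry the barcode as an `RMB:Z:` suffix so downstream tools
#' keep the molecule label.
#'
#' @param molecules the `molecules` table from [preprocess_reads()].
#' @param path output FASTQ path (`.gz` for compression).
#' @export
write_clean_fastq <- function(molecules, path) {
  x <- Biostrings::DNAStringSet(molecules$insert_seq)
  names(x) <- sprintf("%s RMB:Z:%s", molecules$id, molecules$rmb)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                molecules$insert_qual),
                              compress = grepl("\\.gz$", path))
  invisible(NULL)
}
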