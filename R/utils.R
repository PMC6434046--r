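# Shared small helpers. Coordinates are 1-based inclusive internally (the
# R/Bioconductor convention); BED/BEDPE exports convert to 0-based
# half-open.

DNA_ALPHABET <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x),
         function(s) rawToChar(rev(charToRaw(s))),
         character(1), USE.NAMES = FALSE)
}

# Random DNA string(s) of length n, memory-frugal for large n.
random_dna <- function(n) {
  idx <- sample.int(4L, n, replace = TRUE)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])
}

random_dna_set <- function(count, len) {
  if (count == 0L) return(character(0))
  idx <- sample.int(4L, count * len, replace = TRUE)
  m <- matrix(c("A", "C", "G", "T")[idx], nrow = count)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Vectorised Hamming mismatch count between equal-length strings and a
# single pattern (or between two equally long vectors).
hamming_mm <- function(x, pattern) {
  w <- nchar(pattern[1])
  mm <- integer(length(x))
  for (i in seq_len(w)) {
    pi <- substring(pattern, i, i)
    mm <- mm + (substring(x, i, i) != pi)
  }
  mm
}

# IUPAC-aware match of a fixed-position motif such as "NGG"/"NAG": N
# matches any base; other letters must match exactly.
motif_mismatch <- function(x, motif) {
  w <- nchar(motif)
  cs <- strsplit(motif, "")[[1]]
  mm <- integer(length(x))
  for (i in seq_len(w)) {
    if (cs[i] == "N") next
    mm <- mm + (substring(x, i, i) != cs[i])
  }
  mm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0

# Presumed cleavage coordinate for a protospacer+PAM site. `site_start` is
# the genomic start (1-based) of the 23-mer as written on the forward
# strand. The blunt cut falls between protospacer positions 17 and 18
# (3 bp 5' of the PAM); we report the last base of the lower-coordinate
# flank.
cut_from_site <- function(site_start, strand) {
  ifelse(strand == "+", site_start + 16L, site_start + 5L)
}
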