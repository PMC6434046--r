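#' On-target locus description
#'
#' Describes the bait side of a PEM-seq experiment: the chromosome and
#' strand carrying the biotinylated primer, the primer interval, the
#' presumed Cas9 cleavage coordinate, and the guide sequence with its PAM
#' pattern. The primer must sit within 200 bp of the cleavage site so that
#' the junction falls inside read 1.
#'
#' @param chrom reference sequence name.
#' @param strand `"+"` or `"-"`; the strand the bait primer anneals to, i.e.
#'   the direction in which read 1 extends toward the cut.
#' @param primer_start,primer_end 1-based inclusive interval of the bait
#'   primer on `chrom`.
#' @param cut_pos 1-based coordinate of the presumed cleavage site (the
#'   last base of the lower-coordinate fragment of a blunt cut).
#' @param guide 20-nt protospacer sequence (5' to 3').
#' @param pam PAM pattern, e.g. `"NGG"` (`N` matches any base).
#' @return An object of class `bait_config`.
#' @examples
#' bait_config("chr1", "+", 901, 920, 1000, strrep("AC", 10))
#' @export
bait_config <- function(chrom, strand, primer_start, primer_end, cut_pos,
                        guide, pam = "NGG") {
  stopifnot(strand %in% c("+", "-"), primer_start <= primer_end)
  guide <- toupper(guide)
  if (nchar(guide) != 20L) stopf("guide sequence must be 20 nt, got %d",
                                 nchar(guide))
  dist <- max(abs(cut_pos - primer_start), abs(cut_pos - primer_end))
  if (dist > 200L)
    stopf("bait primer must lie within 200 bp of the cleavage site (%d bp)",
          dist)
  structure(list(chrom = chrom, strand = strand,
                 primer_start = as.integer(primer_start),
                 primer_end = as.integer(primer_end),
                 cut_pos = as.integer(cut_pos),
                 guide = guide, pam = toupper(pam)),
            class = "bait_config")
}

#' @export
print.bait_config <- function(x, ...) {
  cat(sprintf("bait_config: %s:%d-%d(%s), cut at %d, guide %s + %s\n",
              x$chrom, x$primer_start, x$primer_end, x$strand, x$cut_pos,
              x$guide, x$pam))
  invisible(x)
}

#' Adapter and trimming settings
#'
#' Sequences and thresholds used during read preprocessing. The bridge
#' adapter template must contain exactly one contiguous run of 14 `N`s
#' marking the random molecular barcode (RMB); the flanks on either side
#' are matched with at most one mismatch each so the barcode stays
#' frame-aligned. By convention read 2 starts with the bridge adapter:
#' `flank5 + RMB(14) + flank3 + genomic sequence`.
#'
#' @param sequencing_adapter 3' sequencing adapter removed from both mates.
#' @param bridge_template bridge adapter template containing one 14-`N`
#'   window, e.g. `"ACCGTAGT" + strrep("N",14) + "TGCAGGTA"`.
#' @param bait_primer bait primer sequence expected at the start of read 1.
#' @param quality_floor Phred score below which trailing bases are trimmed
#'   (default 30).
#' @param min_len minimum mate length after trimming (default 25).
#' @return An object of class `adapter_spec`.
#' @export
adapter_spec <- function(sequencing_adapter = "AGATCGGAAGAGC",
                         bridge_template = paste0("ACCGTAGT",
                                                  strrep("N", 14),
                                                  "TGCAGGTA"),
                         bait_primer,
                         quality_floor = 30L,
                         min_len = 25L) {
  bridge_template <- toupper(bridge_template)
  nrun <- gregexpr("N+", bridge_template)[[1]]
  if (length(nrun) != 1L || attr(nrun, "match.length") != 14L)
    stopf("bridge template must contain exactly one run of 14 N's")
  flank5 <- substr(bridge_template, 1L, nrun - 1L)
  flank3 <- substr(bridge_template, nrun + 14L, nchar(bridge_template))
  if (nchar(flank5) < 4L || nchar(flank3) < 4L)
    stopf("bridge adapter flanks must be at least 4 nt to anchor the RMB")
  structure(list(sequencing_adapter = toupper(sequencing_adapter),
                 bridge_template = bridge_template,
                 bridge_flank5 = flank5, bridge_flank3 = flank3,
                 bait_primer = toupper(bait_primer),
                 quality_floor = as.integer(quality_floor),
                 min_len = as.integer(min_len)),
            class = "adapter_spec")
}

#' Hotspot peak-calling parameters
#'
#' Tuning parameters for off-target hotspot identification. Defaults
#' correspond to junction extension 50 bp, FDR 0.05, a 10-Mb local
#' background window, exclusion of the bait +/- 250 kb, a minimum of 3
#' pooled junctions within +/- 500 bp of the presumed cut, and recurrence
#' in at least 2 replicate libraries.
#'
#' @param extsize bp each junction is extended to when building candidate
#'   regions.
#' @param q_threshold Benjamini-Hochberg FDR level.
#' @param llocal span (bp) of the local Poisson background window.
#' @param exclusion_span bp around the bait cut excluded from calling.
#' @param min_junctions minimum pooled junctions within `count_window` of
#'   the presumed cut.
#' @param count_window bp on each side of the presumed cut used to count
#'   hotspot junctions.
#' @param min_replicates minimum replicate libraries a site must recur in.
#' @param min_count minimum junctions a candidate region must contain
#'   before it is tested (a single extended fragment never constitutes a
#'   pile-up).
#' @param max_mm maximum protospacer mismatches for a cryptic target match.
#' @param pam_patterns PAM patterns accepted as "definite PAM".
#' @param slop bp added on each side of a candidate when scanning for a
#'   cryptic target site.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(extsize = 50L, q_threshold = 0.05, llocal = 1e7,
                        exclusion_span = 250000L, min_junctions = 3L,
                        count_window = 500L, min_replicates = 2L,
                        min_count = 2L, max_mm = 6L,
                        pam_patterns = c("NGG", "NAG"), slop = 500L) {
  vals <- c(extsize, q_threshold, llocal, exclusion_span, min_junctions,
            count_window, min_replicates, min_count, max_mm, slop)
  if (any(vals <= 0)) stopf("all peak parameters must be positive")
  structure(list(extsize = as.integer(extsize), q_threshold = q_threshold,
                 llocal = as.numeric(llocal),
                 exclusion_span = as.integer(exclusion_span),
                 min_junctions = as.integer(min_junctions),
                 count_window = as.integer(count_window),
                 min_replicates = as.integer(min_replicates),
                 min_count = as.integer(min_count),
                 max_mm = as.integer(max_mm),
                 pam_patterns = toupper(pam_patterns),
                 slop = as.integer(slop)),
            class = "peak_params")
}
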