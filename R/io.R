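# Flat-file interfaces. Internal coordinates are 1-based inclusive;
# BED/BEDPE exports use the 0-based half-open convention of those
# formats.

CATEGORY_CODE <- c(germline = 0L, indel = 1L, translocation = 2L)

#' Write junction calls as BEDPE
#'
#' One record per molecule: the bait side is the 1-bp interval ending at
#' `bait_end`, the second side is the junction position (prey proximal
#' coordinate, or `bait_end` again for preyless molecules). `name` is the
#' molecule id; extra columns carry category, subcategory and RMB.
#'
#' @param calls classified junction calls.
#' @param bait a [bait_config()].
#' @param path output path.
#' @export
write_junctions_bedpe <- function(calls, bait, path) {
  calls <- as.data.table(calls)
  out <- data.table(
    chrom1 = rep(bait$chrom, nrow(calls)),
    start1 = calls$bait_end - 1L, end1 = calls$bait_end,
    chrom2 = calls$junction_chrom,
    start2 = calls$junction_pos - 1L, end2 = calls$junction_pos,
    name = calls$id,
    score = CATEGORY_CODE[calls$category],
    strand1 = rep(bait$strand, nrow(calls)),
    strand2 = calls$junction_strand,
    category = calls$category, subcategory = calls$subcategory,
    rmb = calls$rmb)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a junction BEDPE written by [write_junctions_bedpe()]
#' @param path BEDPE path.
#' @return A junction-call table (1-based coordinates restored).
#' @export
read_junctions_bedpe <- function(path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "category",
            "subcategory", "rmb")
  dt <- fread(path, sep = "\t", header = FALSE, col.names = cols)
  data.table(id = dt$name, rmb = dt$rmb, bait_end = dt$end1,
             junction_chrom = dt$chrom2, junction_pos = dt$end2,
             junction_strand = dt$strand2,
             category = dt$category, subcategory = dt$subcategory)
}

#' Extract the translocation junction table for hotspot calling
#' @param calls classified (deduplicated) calls.
#' @return data.table with `chrom`, `pos`, `strand`.
#' @export
junctions_from_calls <- function(calls) {
  calls <- as.data.table(calls)
  tx <- calls[calls$category == "translocation", ]
  data.table(chrom = tx$junction_chrom, pos = tx$junction_pos,
             strand = tx$junction_strand)
}

#' Write hotspots as BED (plus a full TSV)
#'
#' The BED interval is the counting window around the presumed cut,
#' `name` is the matched cryptic site sequence, `score` the intensity.
#'
#' @param hotspots a hotspot table (with `intensity` column if scored).
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @export
write_hotspots <- function(hotspots, bed_path = NULL, tsv_path = NULL) {
  hotspots <- as.data.table(hotspots)
  if (!is.null(tsv_path)) fwrite(hotspots, tsv_path, sep = "\t")
  if (!is.null(bed_path)) {
    sc <- if ("intensity" %in% names(hotspots)) hotspots$intensity
          else hotspots$junction_count
    bed <- data.table(chrom = hotspots$chrom,
                      start = hotspots$start - 1L, end = hotspots$end,
                      name = hotspots$matched_seq, score = sc,
                      strand = hotspots$strand)
    fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  invisible(hotspots)
}

#' Write per-library statistics as a one-row TSV
#' @param stats_list list of `library_stats`.
#' @param path output path.
#' @export
write_stats_tsv <- function(stats_list, path) {
  rows <- lapply(stats_list, function(s) {
    base <- data.table(label = s$label, G = s$G, I = s$I, T = s$T,
                       total = s$total)
    if (!is.null(s$subcounts))
      for (nm in names(s$subcounts)) base[[nm]] <- s$subcounts[[nm]]
    base
  })
  fwrite(rbindlist(rows, fill = TRUE), path, sep = "\t")
  invisible(path)
}
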