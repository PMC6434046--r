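# Junction detection and molecule classification.
#
# One junction call per molecule: the coordinate where the bait-anchored
# alignment stops, an optional prey segment (the partner locus joined to
# the bait), and a category among germline / indel / translocation with a
# finer subcategory.

JUNCTION_CATEGORIES <- c("germline", "indel", "translocation")
JUNCTION_SUBCATEGORIES <- c("perfect", "small_insertion", "small_deletion",
                            "insertion_plus_deletion", "large_deletion",
                            "inversion", "offtarget_translocation",
                            "background_translocation")

#' Call the bait-to-prey junction of every molecule
#'
#' For each molecule the bait-anchored segment must overlap the primer on
#' the bait strand; its junction-facing reference end becomes `bait_end`.
#' If a second (prey) segment exists, the prey coordinate is its proximal
#' end -- the reference coordinate facing the junction in query order --
#' and the junction position used for deduplication and hotspot counting
#' is that prey coordinate; otherwise it is `bait_end`.
#'
#' @param segments a segment table (from [toy_align()] or
#'   [segments_from_bam()]) already filtered by [group_alignments()].
#' @param bait a [bait_config()].
#' @return A list with `calls` (data.table `id`, `rmb`, `bait_end`,
#'   `prey_chrom`, `prey_pos`, `prey_strand`, `junction_chrom`,
#'   `junction_pos`, `junction_strand`) and `dropped` (`id`, `reason` for
#'   bait-less molecules).
#' @export
call_junctions <- function(segments, bait) {
  segments <- as.data.table(segments)
  setorder(segments, id, qstart)
  firsts <- segments[, .SD[1], by = id]
  on_bait <- firsts$role == "bait" & firsts$chrom == bait$chrom &
    firsts$strand == bait$strand &
    firsts$start <= bait$primer_end & firsts$end >= bait$primer_start
  dropped <- data.table(id = firsts$id[!on_bait],
                        reason = rep("baitless", sum(!on_bait)))
  firsts <- firsts[on_bait, ]
  bait_end <- if (bait$strand == "+") firsts$end else firsts$start

  prey <- segments[segments$role == "prey" & segments$id %in% firsts$id, ]
  prey <- prey[, .SD[1], by = id]
  prox <- ifelse(prey$strand == "+", prey$start, prey$end)
  pmap <- setNames(seq_len(nrow(prey)), prey$id)
  k <- pmap[firsts$id]
  calls <- data.table(
    id = firsts$id, rmb = firsts$rmb, bait_end = bait_end,
    prey_chrom = ifelse(is.na(k), NA_character_, prey$chrom[k]),
    prey_pos = ifelse(is.na(k), NA_integer_, prox[k]),
    prey_strand = ifelse(is.na(k), NA_character_, prey$strand[k]))
  calls[, junction_chrom := ifelse(is.na(prey_chrom), bait$chrom,
                                   prey_chrom)]
  calls[, junction_pos := ifelse(is.na(prey_pos), bait_end, prey_pos)]
  calls[, junction_strand := ifelse(is.na(prey_strand), bait$strand,
                                    prey_strand)]
  list(calls = calls, dropped = dropped)
}

#' Classify junction calls as germline, indel or translocation
#'
#' Applies the category rules: a molecule is germline iff it has no prey
#' segment and no insertion/deletion within `cut +/- indel_window`; it is
#' an indel if it has such an edit (subcategory `small_insertion`,
#' `small_deletion` or `insertion_plus_deletion`) or if its prey lies on
#' the bait chromosome within `+/- proximal_span` of the cut (subcategory
#' `large_deletion` when the orientation is deletion-consistent --
#' strand-matched and downstream of the cut in the bait direction --
#' `inversion` when strand-flipped); any other prey is a genome-wide
#' translocation. Both windows are inclusive at their boundaries.
#' Substitution-only differences never leave germline (they are
#' indistinguishable from sequencing error).
#'
#' @param calls the `calls` table from [call_junctions()].
#' @param edits the edit-operation table from the aligner (`id`, `type`,
#'   `ref_pos`, `len`).
#' @param bait a [bait_config()].
#' @param indel_window bp on each side of the cut inspected for indels
#'   (default 5).
#' @param proximal_span bp on each side of the cut within which a
#'   same-chromosome prey still counts as an indel (default 250000).
#' @return `calls` with added `category` and `subcategory` columns.
#' @export
classify_junctions <- function(calls, edits, bait, indel_window = 5L,
                               proximal_span = 250000L) {
  calls <- as.data.table(calls)
  edits <- as.data.table(edits)
  cutp <- bait$cut_pos
  win_lo <- cutp - indel_window
  win_hi <- cutp + indel_window

  if (nrow(edits)) {
    eend <- edits$ref_pos + ifelse(edits$type == "del", edits$len - 1L, 0L)
    ew <- edits[eend >= win_lo & edits$ref_pos <= win_hi, ]
    has_ins <- unique(ew$id[ew$type == "ins"])
    has_del <- unique(ew$id[ew$type == "del"])
  } else {
    has_ins <- has_del <- character(0)
  }

  dir <- if (bait$strand == "+") 1L else -1L
  has_prey <- !is.na(calls$prey_chrom)
  same_chrom <- has_prey & calls$prey_chrom == bait$chrom
  offset <- (calls$prey_pos - cutp) * dir
  proximal <- same_chrom & abs(calls$prey_pos - cutp) <= proximal_span
  flipped <- has_prey & calls$prey_strand != bait$strand

  category <- rep("germline", nrow(calls))
  subcategory <- rep("perfect", nrow(calls))

  ins <- calls$id %in% has_ins
  del <- calls$id %in% has_del
  category[!has_prey & (ins | del)] <- "indel"
  subcategory[!has_prey & ins & !del] <- "small_insertion"
  subcategory[!has_prey & del & !ins] <- "small_deletion"
  subcategory[!has_prey & del & ins] <- "insertion_plus_deletion"

  category[has_prey & proximal] <- "indel"
  subcategory[has_prey & proximal & !flipped] <- "large_deletion"
  subcategory[has_prey & proximal & flipped] <- "inversion"

  tx <- has_prey & !proximal
  category[tx] <- "translocation"
  subcategory[tx] <- "background_translocation"

  calls[, category := category]
  calls[, subcategory := subcategory]
  calls[]
}

#' Split translocations into off-target and background joins
#'
#' A translocation joins an off-target DSB iff its junction lies within
#' `count_window` of a hotspot's presumed cut; all others are genome-wide
#' low-level (background) joins. With an empty hotspot set everything is
#' background.
#'
#' @param calls classified calls (see [classify_junctions()]).
#' @param hotspots a hotspot table with `chrom` and `presumed_cut`
#'   columns, or `NULL`/empty.
#' @param count_window bp on each side of a presumed cut (default 500).
#' @return `calls` with translocation subcategories reassigned.
#' @export
split_translocations <- function(calls, hotspots, count_window = 500L) {
  calls <- as.data.table(calls)
  tx <- which(calls$category == "translocation")
  calls$subcategory[tx] <- "background_translocation"
  if (!is.null(hotspots) && nrow(as.data.table(hotspots)) > 0L) {
    hs <- as.data.table(hotspots)
    for (i in tx) {
      near <- hs$chrom == calls$junction_chrom[i] &
        abs(hs$presumed_cut - calls$junction_pos[i]) <= count_window
      if (any(near)) calls$subcategory[i] <- "offtarget_translocation"
    }
  }
  calls[]
}
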