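# Library-level quantities: G/I/T composition, editing efficiency with
# uncut-control and transfection-efficiency correction, junction
# profiles, and the resection fraction.

#' Tabulate deduplicated calls into library statistics
#'
#' @param calls classified, deduplicated junction calls.
#' @param label a sample label.
#' @return An object of class `library_stats`: counts `G` (germline), `I`
#'   (indels, including large deletions and inversions rejoined within
#'   the proximal span), `T` (genome-wide translocations), `total`, and a
#'   named `subcounts` vector.
#' @export
tabulate_junctions <- function(calls, label = "sample") {
  calls <- as.data.table(calls)
  cat_tab <- table(factor(calls$category, levels = JUNCTION_CATEGORIES))
  sub_tab <- table(factor(calls$subcategory,
                          levels = JUNCTION_SUBCATEGORIES))
  structure(list(G = as.integer(cat_tab[["germline"]]),
                 I = as.integer(cat_tab[["indel"]]),
                 T = as.integer(cat_tab[["translocation"]]),
                 total = nrow(calls),
                 subcounts = setNames(as.integer(sub_tab),
                                      names(sub_tab)),
                 label = label),
            class = "library_stats")
}

#' Construct library statistics from raw counts
#'
#' Mainly for control libraries quantified elsewhere and for the
#' closed-form examples.
#'
#' @param G,I,T germline, indel and translocation molecule counts.
#' @param subcounts optional named subcategory counts; must sum to the
#'   matching category totals when given.
#' @param label sample label.
#' @return A `library_stats` object.
#' @export
library_stats <- function(G, I, T, subcounts = NULL, label = "sample") {
  if (any(c(G, I, T) < 0)) stopf("counts must be non-negative")
  if (!is.null(subcounts)) {
    isub <- sum(subcounts[intersect(names(subcounts),
                                    c("small_insertion", "small_deletion",
                                      "insertion_plus_deletion",
                                      "large_deletion", "inversion"))])
    tsub <- sum(subcounts[intersect(names(subcounts),
                                    c("offtarget_translocation",
                                      "background_translocation"))])
    if (isub != I || tsub != T)
      stopf("subcategory counts do not add up to I and T")
  }
  structure(list(G = as.integer(G), I = as.integer(I), T = as.integer(T),
                 total = as.integer(G + I + T), subcounts = subcounts,
                 label = label),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("library_stats [%s]: G=%d I=%d T=%d (total %d)\n",
              x$label, x$G, x$I, x$T, x$total))
  invisible(x)
}

#' Editing efficiency with control and transfection-efficiency correction
#'
#' Computes
#' \deqn{\mathrm{eff} = \frac{(I_S+T_S)/(G_S+I_S+T_S) -
#'   (I_C+T_C)/(G_C+I_C+T_C)}{\mathrm{TE}}}
#' where S is the nuclease-treated library, C the uncut control and TE
#' the transfection efficiency. A negative numerator (sampling noise near
#' zero) is clamped to 0 with a warning; the result is clamped to 1.
#'
#' @param sample,control `library_stats` objects.
#' @param te transfection efficiency, a fraction in (0, 1].
#' @return An object of class `efficiency_result` with fields
#'   `efficiency`, `raw_sample_fraction`, `raw_control_fraction`, `te`.
#' @export
editing_efficiency <- function(sample, control, te = 1) {
  if (te <= 0 || te > 1) stopf("TE must be in (0, 1]")
  if (sample$total <= 0 || control$total <= 0)
    stopf("both libraries must contain molecules")
  fs <- (sample$I + sample$T) / sample$total
  fc <- (control$I + control$T) / control$total
  eff <- (fs - fc) / te
  if (eff < 0) {
    warning("control editing fraction exceeds sample; clamping to 0")
    eff <- 0
  }
  if (eff > 1) eff <- 1
  structure(list(efficiency = eff, raw_sample_fraction = fs,
                 raw_control_fraction = fc, te = te),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf(paste0("editing efficiency: %.4f (sample %.4f, control ",
                     "%.4f, TE %.2f)\n"),
              x$efficiency, x$raw_sample_fraction,
              x$raw_control_fraction, x$te))
  invisible(x)
}

#' Binned junction frequency profile around a position
#'
#' Counts junctions in fixed-size bins across `center +/- window`,
#' optionally split by junction orientation, mirroring the +/- 5 kb /
#' 50 bp junction profiles and wider binned genome views. Bins start at
#' `center - window`; a final partial bin is truncated at the window end.
#'
#' @param calls a junction table with `junction_chrom`, `junction_pos`,
#'   `junction_strand`.
#' @param chrom,center profile chromosome and center coordinate.
#' @param window half-width of the profiled region (bp).
#' @param binsize bin width (bp).
#' @param split_by_orientation if `TRUE` (default), counts are reported
#'   per junction strand.
#' @return A data.table with `bin_start` (offset of the bin's first base
#'   from `center`), `strand`, `count`; the counts sum to the number of
#'   junctions inside the window.
#' @export
junction_profile <- function(calls, chrom, center, window = 5000L,
                             binsize = 50L, split_by_orientation = TRUE) {
  calls <- as.data.table(calls)
  lo <- center - window
  hi <- center + window
  sel <- calls$junction_chrom == chrom & calls$junction_pos >= lo &
    calls$junction_pos <= hi
  offs <- calls$junction_pos[sel] - lo
  bin <- pmin(offs %/% binsize, ceiling(2 * window / binsize) - 1L)
  starts <- seq(0L, 2L * window - 1L, by = binsize) - window
  strands <- if (split_by_orientation) c("+", "-") else "*"
  grid <- data.table(bin_start = rep(starts, each = length(strands)),
                     strand = rep(strands, length(starts)))
  if (!any(sel)) {
    grid[, count := 0L]
    return(grid[])
  }
  st <- if (split_by_orientation) calls$junction_strand[sel]
        else rep("*", sum(sel))
  obs <- data.table(bin_start = starts[bin + 1L], strand = st)
  cnt <- obs[, .(count = .N), by = .(bin_start, strand)]
  out <- merge(grid, cnt, by = c("bin_start", "strand"), all.x = TRUE)
  out[is.na(count), count := 0L]
  setorder(out, bin_start, strand)
  out[]
}

#' Fraction of editing events with resection-scale deletions
#'
#' Fraction of total editing events (indels plus translocations) whose
#' junction is deletion-consistent -- on the bait chromosome, matching
#' the bait strand -- and lies in a downstream distance window of the
#' cut, by default 5-50 kb.
#'
#' @param stats `library_stats` of the (deduplicated) library.
#' @param calls the deduplicated, classified calls the stats came from.
#' @param bait a [bait_config()].
#' @param region two-element downstream distance window in bp (default
#'   `c(5000, 50000)`), inclusive.
#' @return A single fraction: region junctions / (I + T).
#' @export
resection_fraction <- function(stats, calls, bait,
                               region = c(5000L, 50000L)) {
  calls <- as.data.table(calls)
  denom <- stats$I + stats$T
  if (denom <= 0) return(0)
  dir <- if (bait$strand == "+") 1L else -1L
  off <- (calls$junction_pos - bait$cut_pos) * dir
  hit <- calls$junction_chrom == bait$chrom &
    calls$junction_strand == bait$strand &
    !is.na(off) & off >= region[1] & off <= region[2] &
    calls$category != "germline"
  sum(hit) / denom
}
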