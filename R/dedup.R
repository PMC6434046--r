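# PCR-duplicate removal by random molecular barcode clustering.
#
# Molecules sharing a junction signature (same chromosome and strand,
# coordinates within a small positional tolerance) are candidates for
# being PCR copies of one original template; within such a group,
# barcodes within edit distance 2 of each other are linked and connected
# components collapse to one molecule.

#' Cluster barcodes by edit distance
#'
#' Two barcodes are linked iff their edit distance (Levenshtein by
#' default; Hamming as a configuration switch) is at most `max_edit`;
#' clusters are the connected components of the link graph. `N` matches
#' nothing, including another `N`.
#'
#' @param barcodes character vector of barcodes.
#' @param max_edit maximum linking distance (default 2).
#' @param metric `"levenshtein"` (default) or `"hamming"`.
#' @return Integer vector of 1-based cluster ids, numbered by first
#'   appearance.
#' @export
cluster_barcodes <- function(barcodes, max_edit = 2L,
                             metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  .umi_components_cpp(toupper(barcodes), as.integer(max_edit),
                      metric == "hamming")
}

#' Collapse PCR duplicates of junction calls
#'
#' Two calls are linked iff they share chromosome and strand, their
#' junction coordinates differ by at most `pos_tol` bp, and their
#' barcodes are within `max_edit`; connected components collapse to one
#' representative call: the one carrying the cluster's most frequent
#' barcode (ties broken by lexicographically smallest barcode, then
#' smallest id). The positional condition is pairwise, so two molecules
#' at clearly different coordinates are never merged merely because a
#' chain of intermediate positions exists.
#'
#' @param calls a junction-call table carrying `rmb`, `junction_chrom`,
#'   `junction_pos`, `junction_strand`.
#' @param max_edit barcode linking distance (default 2).
#' @param pos_tol positional tolerance (bp) when forming junction groups
#'   (default 2; absorbs alignment jitter of the junction coordinate).
#' @param metric edit-distance metric, see [cluster_barcodes()].
#' @return A list with `unique` (one call per original molecule),
#'   `report` (data.table `cluster_size`, `n_clusters`) and
#'   `n_duplicates` (reads removed).
#' @export
dedup_junctions <- function(calls, max_edit = 2L, pos_tol = 2L,
                            metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L)
    return(list(unique = calls,
                report = data.table(cluster_size = integer(0),
                                    n_clusters = integer(0)),
                n_duplicates = 0L))
  setorder(calls, junction_chrom, junction_strand, junction_pos, rmb, id)
  # single-linkage positional grouping within (chrom, strand)
  newgrp <- c(TRUE,
              calls$junction_chrom[-1] != calls$junction_chrom[-nrow(calls)] |
              calls$junction_strand[-1] != calls$junction_strand[-nrow(calls)] |
              diff(calls$junction_pos) > pos_tol)
  calls[, pos_group := cumsum(newgrp)]
  # within each chained block, link pairwise on (position, barcode);
  # cluster over distinct (barcode, position) pairs, then map back
  calls[, cluster := {
    key <- paste(rmb, junction_pos)
    u <- !duplicated(key)
    comp <- .umi_components_pos_cpp(rmb[u], junction_pos[u],
                                    as.integer(max_edit),
                                    as.integer(pos_tol),
                                    metric == "hamming")
    comp[match(key, key[u])]
  }, by = pos_group]

  pick <- calls[, {
    tab <- sort(table(rmb), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    rep_rmb <- sort(best)[1]
    idx <- which(rmb == rep_rmb)[1]
    c(.SD[idx], list(cluster_size = .N))
  }, by = .(pos_group, cluster)]

  sizes <- pick[, .(n_clusters = .N), by = .(cluster_size)]
  setorder(sizes, cluster_size)
  unique_calls <- pick[, !c("pos_group", "cluster", "cluster_size"),
                       with = FALSE]
  setorder(unique_calls, junction_chrom, junction_pos, rmb, id)
  list(unique = unique_calls,
       report = sizes,
       n_duplicates = nrow(calls) - nrow(unique_calls))
}
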