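# Closed-form gel-based indel estimators. All three are pure functions
# of band intensities or clone counts and are scale-invariant in their
# inputs.

#' RFLP indel estimate
#'
#' After amplifying the target locus and digesting with a restriction
#' enzyme whose site spans the cut, edited alleles resist digestion:
#' `indels = I_C / (I_C + I_U)` where `I_C` is the summed intensity of
#' the cleaved bands and `I_U` the uncleaved band intensity.
#'
#' @param cleaved,uncleaved non-negative band intensities; their sum must
#'   be positive.
#' @return Indel fraction in `[0, 1]`.
#' @examples
#' rflp_indels(1, 1)  # 0.5
#' @export
rflp_indels <- function(cleaved, uncleaved) {
  if (any(cleaved < 0) || any(uncleaved < 0))
    stopf("band intensities must be non-negative")
  if (any(cleaved + uncleaved <= 0))
    stopf("total band intensity must be positive")
  cleaved / (cleaved + uncleaved)
}

#' T7EI indel estimate
#'
#' The T7 endonuclease cleaves heteroduplexes formed by re-annealing a
#' mixed pool of edited and unedited amplicons. Under completely random
#' annealing the heteroduplex probability is `FC = 1 - (1 - p)^2` for
#' indel fraction `p`, giving the closed form
#' `indels = 1 - sqrt(1 - FC)`.
#'
#' @param fc fraction cleaved, in `[0, 1]`.
#' @return Indel fraction in `[0, 1]`, monotone in `fc`.
#' @examples
#' t7ei_indels(0.75)  # 0.5
#' @export
t7ei_indels <- function(fc) {
  if (any(fc < 0 | fc > 1)) stopf("fraction cleaved must be in [0, 1]")
  1 - sqrt(1 - fc)
}

#' Single-cell (clonal) RFLP indel estimate
#'
#' Single clones are scored by their digestion pattern: fully digested
#' clones have all alleles edited (score = ploidy), non-digested clones
#' none (score 0), and partially digested clones are scored `ploidy / 2`
#' since one or more alleles may be edited with equal chance. With counts
#' `I_I` (fully), `I_H` (partially) and `I_G` (non-digested):
#' `indels = (ploidy * I_I + ploidy/2 * I_H) / (ploidy * (I_I+I_H+I_G))`.
#' The default ploidy of 3 reflects the triploid HEK293T line; note the
#' ploidy cancels algebraically under the equal-chance scoring, so the
#' parameter only matters if a different partial-clone score is supplied.
#'
#' @param fully,partial,none clone counts (fully / partially /
#'   non-digested); total must be positive.
#' @param ploidy allele copies per cell (default 3).
#' @param partial_score score assigned to a partially digested clone
#'   (default `ploidy / 2`).
#' @return Indel fraction in `[0, 1]`.
#' @examples
#' sc_rflp_indels(0, 2, 0)  # 0.5
#' @export
sc_rflp_indels <- function(fully, partial, none, ploidy = 3,
                           partial_score = ploidy / 2) {
  if (any(c(fully, partial, none) < 0)) stopf("counts must be non-negative")
  total <- fully + partial + none
  if (any(total <= 0)) stopf("total clone count must be positive")
  (ploidy * fully + partial_score * partial) / (ploidy * total)
}

#' Bootstrap confidence interval for the clonal RFLP estimate
#'
#' Resamples clones with replacement; off by default in the estimator
#' itself since the original formulation reports a point estimate.
#'
#' @param fully,partial,none clone counts.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param ploidy,partial_score see [sc_rflp_indels()].
#' @return Named numeric vector `c(lower, estimate, upper)`.
#' @export
sc_rflp_ci <- function(fully, partial, none, n_boot = 2000L, conf = 0.95,
                       ploidy = 3, partial_score = ploidy / 2) {
  total <- fully + partial + none
  probs <- c(fully, partial, none) / total
  draws <- stats::rmultinom(n_boot, total, probs)
  est <- (ploidy * draws[1, ] + partial_score * draws[2, ]) /
    (ploidy * total)
  alpha <- (1 - conf) / 2
  c(lower = unname(stats::quantile(est, alpha)),
    estimate = sc_rflp_indels(fully, partial, none, ploidy, partial_score),
    upper = unname(stats::quantile(est, 1 - alpha)))
}
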