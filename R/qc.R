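#' Mean SNP-calling accuracy under the heterozygosity mixture model
#'
#' Genotype calls split into a heterozygous fraction `rho` validated at
#' `acc_het` percent and a homozygous remainder validated at `acc_hom`
#' percent; the cohort mean accuracy is the affine mixture
#' `rho * acc_het + (1 - rho) * acc_hom`.
#'
#' @param rho heterozygous-call fraction in `[0, 1]`.
#' @param acc_het,acc_hom validated accuracies (percent, `[0, 100]`).
#' @return mean accuracy in percent.
#' @examples
#' mean_accuracy(0.01552)  # ~98.84
#' @export
mean_accuracy <- function(rho, acc_het = 63.6, acc_hom = 99.4) {
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  if (any(c(acc_het, acc_hom) < 0 | c(acc_het, acc_hom) > 100)) {
    stop("accuracies are percents in [0, 100]")
  }
  rho * acc_het + (1 - rho) * acc_hom
}

#' Pooled variant-calling sensitivity
#'
#' Sum of called variants over sum of independently validated true
#' variants, pooled across validation regions.
#'
#' @param truth_counts,called_counts integer vectors of equal length;
#'   `called_counts <= truth_counts` elementwise.
#' @return pooled fraction, or `NA` when no true variants exist.
#' @examples
#' variant_sensitivity(c(32, 17), c(24, 11))  # 35/49 = 0.714
#' @export
variant_sensitivity <- function(truth_counts, called_counts) {
  if (length(truth_counts) != length(called_counts)) {
    stop("count vectors must have equal length")
  }
  if (any(called_counts > truth_counts)) {
    stop("called counts cannot exceed truth counts")
  }
  if (any(truth_counts < 0) || any(called_counts < 0)) {
    stop("counts must be non-negative")
  }
  tot <- sum(truth_counts)
  if (tot == 0) return(NA_real_)
  sum(called_counts) / tot
}

#' Group SNP shares of a cohort total
#'
#' `100 * count / total` per group, rounded to `digits` decimals.
#' Groups overlap (shared SNPs count in several groups), so shares need
#' not sum to 100.
#'
#' @param group_counts named numeric vector of per-group SNP counts.
#' @param total cohort SNP total (> 0).
#' @param digits decimals to round to (default 2).
#' @return named numeric vector of percents.
#' @examples
#' group_shares(c(wild = 3381514), total = 4567069)  # 74.04
#' @export
group_shares <- function(group_counts, total, digits = 2) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0) {
    stop("`total` must be a single positive count")
  }
  round(100 * group_counts / total, digits)
}
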