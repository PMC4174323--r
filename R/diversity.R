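#' Tajima's D normalizing constants
#'
#' Computes the full constant set of the D statistic for a sample of
#' `n_seq` sequences (haplotypes): `a1`, `a2`, `b1`, `b2`, `c1`, `c2`,
#' `e1`, `e2`.  These standardize the difference between mean pairwise
#' diversity and the segregating-sites estimator.
#'
#' @param n_seq number of sequences (haplotypes), >= 2.
#' @return a list with components `n_seq`, `a1`, `a2`, `b1`, `b2`,
#'   `c1`, `c2`, `e1`, `e2`.
#' @examples
#' tajima_constants(10)$a1  # harmonic number H_9
#' @export
tajima_constants <- function(n_seq) {
  if (!is.numeric(n_seq) || length(n_seq) != 1L || n_seq < 2 ||
      n_seq != round(n_seq)) {
    stop("`n_seq` must be a single integer >= 2")
  }
  n <- as.numeric(n_seq)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n_seq = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Per-site dosage summaries for a codes slice (samples x sites, values
# 0/1/2/NA).  Returns called sample count, derived-allele count and the
# number of called haplotypes per site.
site_allele_counts <- function(codes) {
  codes <- as.matrix(codes)
  called <- colSums(!is.na(codes))
  ac <- colSums(codes, na.rm = TRUE)
  list(n_called = called, alt_count = ac, n_hap = 2 * called)
}

#' Count segregating sites in a genotype slice
#'
#' A site segregates when the called genotypes of the slice carry both
#' alleles (derived-allele count strictly between 0 and the number of
#' called haplotypes).  Sites with fewer than two called samples are
#' ignored.
#'
#' @param codes matrix of diploid dosage codes (samples x sites; 0 hom-ref,
#'   1 het, 2 hom-alt, NA missing).
#' @return integer count S.
#' @export
segregating_sites <- function(codes) {
  if (length(codes) == 0L) return(0L)
  sc <- site_allele_counts(codes)
  usable <- sc$n_called >= 2
  sum(usable & sc$alt_count > 0 & sc$alt_count < sc$n_hap)
}

# Unbiased per-site pairwise diversity from dosages: 2*p*(1-p)*n/(n-1)
# over n called haplotypes.  Equals the mean difference over all
# haplotype pairs (derived count a among n haplotypes: a*(n-a)/C(n,2)).
per_site_pi <- function(codes) {
  sc <- site_allele_counts(codes)
  ok <- sc$n_called >= 2
  a <- sc$alt_count[ok]
  n <- sc$n_hap[ok]
  pi <- a * (n - a) / (n * (n - 1) / 2)
  list(pi = pi, n_skipped = sum(!ok))
}

#' Nucleotide diversity (pi) per site over a window
#'
#' Sums the unbiased per-site pairwise diversity `2*p*(1-p)*n/(n-1)`
#' (n = called haplotypes at the site) over the polymorphic sites of a
#' window and divides by the effective window length.  Sites with fewer
#' than two called samples are skipped and the effective length reduced
#' accordingly; invariant positions not present in the matrix count as
#' monomorphic coverage.
#'
#' @inheritParams segregating_sites
#' @param L window length in bp (before reduction for skipped sites).
#' @return pi per site, or `NA` if the effective length is zero.
#' @examples
#' # one site, two diploids 0 and 2: p = 0.5 over 4 haplotypes
#' nucleotide_diversity(matrix(c(0, 2), ncol = 1), L = 1)  # 2*.25*4/3
#' @export
nucleotide_diversity <- function(codes, L) {
  stopifnot(is.numeric(L), length(L) == 1L, L >= 0)
  if (length(codes) == 0L) {
    return(if (L > 0) 0 else NA_real_)
  }
  ps <- per_site_pi(codes)
  L_eff <- L - ps$n_skipped
  if (L_eff <= 0) return(NA_real_)
  sum(ps$pi) / L_eff
}

#' Watterson's theta per site
#'
#' `S / (a1 * L)` with `a1` the harmonic number of `n_hap - 1`.
#'
#' @param S number of segregating sites.
#' @param n_hap number of haplotypes sampled (2x diploid accessions).
#' @param L effective sequence length in bp (> 0).
#' @return theta_w per site.
#' @examples
#' watterson_theta(5, n_hap = 4, L = 1e4)
#' @export
watterson_theta <- function(S, n_hap, L) {
  stopifnot(is.numeric(S), S >= 0)
  if (!is.numeric(L) || length(L) != 1L || L <= 0) {
    stop("`L` must be a single positive length")
  }
  k <- tajima_constants(n_hap)
  S / (k$a1 * L)
}

#' Tajima's D for a genotype slice
#'
#' Standardized difference between the window's total pairwise diversity
#' and `S/a1`, using the full constant set at `n_hap = 2 *` (samples in
#' the slice).  Windows with fewer than `s_min` segregating sites return
#' `NA` (the variance estimate is degenerate for tiny S).
#'
#' @inheritParams segregating_sites
#' @param s_min minimum number of segregating sites for D to be defined
#'   (default 3).
#' @return D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(codes, s_min = 3L) {
  codes <- as.matrix(codes)
  n_hap <- 2L * nrow(codes)
  if (n_hap < 4L) return(NA_real_)
  S <- segregating_sites(codes)
  if (S < s_min || S < 1L) return(NA_real_)
  k <- tajima_constants(n_hap)
  pi_total <- sum(per_site_pi(codes)$pi)
  vd <- k$e1 * S + k$e2 * S * (S - 1)
  if (vd <= 0) return(NA_real_)
  (pi_total - S / k$a1) / sqrt(vd)
}

#' Per-accession heterozygous-call ratio
#'
#' The fraction rho of an accession's called genotypes that are
#' heterozygous; strongly depressed by selfing and clonal propagation.
#'
#' @param gm a [genotype_matrix].
#' @param sample sample identifier present in `gm`.
#' @return rho in `[0, 1]`, or `NA` if no sites are called.
#' @export
het_ratio <- function(gm, sample) {
  codes <- genotype_codes(gm)
  if (!sample %in% rownames(codes)) {
    stop("sample '", sample, "' not present in the genotype matrix")
  }
  x <- codes[sample, ]
  called <- sum(!is.na(x))
  if (called == 0L) return(NA_real_)
  sum(x == 1L, na.rm = TRUE) / called
}

#' Heterozygosity profile of a cohort
#'
#' Per-accession called-site and heterozygous-call counts with the ratio
#' `rho`, plus per-role means.
#'
#' @param gm a [genotype_matrix].
#' @param groups a [sample_groups] table.
#' @return a list with `samples` (data.frame: sample_id, subgroup, role,
#'   called, het, rho) and `roles` (data.frame: role, mean_rho).
#' @export
het_profile <- function(gm, groups) {
  codes <- genotype_codes(gm)
  groups <- as_sample_groups(groups)
  idx <- match(rownames(codes), groups$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from groups table: ",
         paste(rownames(codes)[is.na(idx)], collapse = ", "))
  }
  called <- rowSums(!is.na(codes))
  het <- rowSums(codes == 1L, na.rm = TRUE)
  samples <- data.frame(
    sample_id = rownames(codes),
    subgroup = groups$subgroup[idx],
    role = groups$role[idx],
    called = as.integer(called),
    het = as.integer(het),
    rho = ifelse(called > 0, het / called, NA_real_),
    stringsAsFactors = FALSE
  )
  mean_rho <- tapply(samples$rho, samples$role, mean, na.rm = TRUE)
  roles <- data.frame(role = names(mean_rho),
                      mean_rho = as.numeric(mean_rho),
                      stringsAsFactors = FALSE)
  rownames(roles) <- NULL
  list(samples = samples, roles = roles)
}
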