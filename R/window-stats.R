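#' Windowed diversity statistics per subgroup
#'
#' For every (window, subgroup) pair computes the number of segregating
#' sites S, nucleotide diversity pi per site, Watterson's theta per site
#' and Tajima's D.  Constants for theta and D use `n_hap = 2 *`
#' (subgroup accessions); per-site statistics use pairwise-complete
#' data, and the effective window length excludes variant sites with
#' fewer than two called subgroup samples.
#'
#' @param gm a [genotype_matrix].
#' @param groups a [sample_groups] table.
#' @param windows window table from [iter_windows()].
#' @param subgroups subgroup labels to scan (default: all in `groups`).
#' @param s_min minimum S for D to be defined (default 3).
#' @return a `window_stats` data.frame: `contig`, `start`, `end`,
#'   `length`, `subgroup`, `n` (accessions), `S`, `pi`, `theta_w`, `D`.
#' @export
window_stats <- function(gm, groups, windows,
                         subgroups = NULL, s_min = 3L) {
  groups <- as_sample_groups(groups)
  if (is.null(subgroups)) subgroups <- unique(groups$subgroup)
  codes <- genotype_codes(gm)
  sites <- variant_sites(gm)
  out <- vector("list", length(subgroups) * nrow(windows))
  k <- 0L
  for (sg in subgroups) {
    members <- group_members(groups, sg)
    sub <- codes[members, , drop = FALSE]
    n_acc <- length(members)
    a1 <- tajima_constants(2L * n_acc)$a1
    for (w in seq_len(nrow(windows))) {
      in_w <- sites$contig == windows$contig[w] &
        (sites$pos - 1L) >= windows$start[w] &
        (sites$pos - 1L) < windows$end[w]
      slice <- sub[, in_w, drop = FALSE]
      S <- segregating_sites(slice)
      ps <- if (ncol(slice)) per_site_pi(slice) else list(pi = numeric(), n_skipped = 0L)
      L_eff <- windows$length[w] - ps$n_skipped
      pi <- if (L_eff > 0) sum(ps$pi) / L_eff else NA_real_
      tw <- if (L_eff > 0) S / (a1 * L_eff) else NA_real_
      D <- tajimas_d(slice, s_min = s_min)
      k <- k + 1L
      out[[k]] <- data.frame(
        contig = windows$contig[w], start = windows$start[w],
        end = windows$end[w], length = windows$length[w],
        subgroup = sg, n = n_acc, S = S, pi = pi, theta_w = tw, D = D,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_stats", "data.frame")
  res
}

#' Reduction of diversity (ROD)
#'
#' `ROD = 1 - pi_cul / pi_wild`; near 1 where domestication erased
#' variation, 0 where cultivated and wild diversity match.
#'
#' @param pi_cul,pi_wild nucleotide diversity of the cultivated and wild
#'   groups (vectors recycled).
#' @return ROD values in `(-Inf, 1]`; `NA` where `pi_wild` is zero or
#'   missing.
#' @export
rod <- function(pi_cul, pi_wild) {
  ifelse(!is.na(pi_wild) & pi_wild > 0 & !is.na(pi_cul),
         1 - pi_cul / pi_wild, NA_real_)
}

#' Hudson-type Fst between two groups over a window
#'
#' `Fst = (pi_Between - pi_Within) / pi_Between`, where pi_Between is
#' the mean pairwise difference between haplotypes sampled from
#' different groups and pi_Within the average of the two within-group
#' diversities.  Computed from dosage-derived allele frequencies,
#' summed over the window's sites.
#'
#' @param gm a [genotype_matrix] (or plain codes matrix).
#' @param samples1,samples2 sample ids of the two groups.
#' @param contig,start,end optional 0-based half-open window restriction.
#' @return Fst, or `NA` when a group has fewer than two called samples
#'   throughout or pi_Between is zero.
#' @export
fst_hudson <- function(gm, samples1, samples2,
                       contig = NULL, start = NULL, end = NULL) {
  g1 <- subset_matrix(gm, samples1, contig, start, end)
  g2 <- subset_matrix(gm, samples2, contig, start, end)
  if (nrow(g1) < 2L || nrow(g2) < 2L) return(NA_real_)
  c1 <- site_allele_counts(g1)
  c2 <- site_allele_counts(g2)
  ok <- c1$n_called >= 1 & c2$n_called >= 1
  if (!any(ok)) return(NA_real_)
  p1 <- (c1$alt_count / c1$n_hap)[ok]
  p2 <- (c2$alt_count / c2$n_hap)[ok]
  n1 <- c1$n_hap[ok]
  n2 <- c2$n_hap[ok]
  pi_between <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  within1 <- 2 * p1 * (1 - p1) * n1 / (n1 - 1)
  within2 <- 2 * p2 * (1 - p2) * n2 / (n2 - 1)
  pi_within <- sum((within1 + within2) / 2)
  if (pi_between <= 0) return(NA_real_)
  (pi_between - pi_within) / pi_between
}

#' Windowed cultivated-vs-wild divergence (ROD and Fst)
#'
#' @param gm a [genotype_matrix].
#' @param groups a [sample_groups] table.
#' @param windows window table from [iter_windows()].
#' @param cultivated,wild group labels resolved by [group_members()]
#'   (defaults: the `"cultivated"` view and the `"wild"` role).
#' @return data.frame per window: `contig`, `start`, `end`, `pi_cul`,
#'   `pi_wild`, `rod`, `fst`.
#' @export
divergence_stats <- function(gm, groups, windows,
                             cultivated = "cultivated", wild = "wild") {
  groups <- as_sample_groups(groups)
  cul <- group_members(groups, cultivated)
  wld <- group_members(groups, wild)
  rows <- lapply(seq_len(nrow(windows)), function(w) {
    ctg <- windows$contig[w]; s <- windows$start[w]; e <- windows$end[w]
    pc <- nucleotide_diversity(subset_matrix(gm, cul, ctg, s, e),
                               L = windows$length[w])
    pw <- nucleotide_diversity(subset_matrix(gm, wld, ctg, s, e),
                               L = windows$length[w])
    data.frame(contig = ctg, start = s, end = e,
               pi_cul = pc, pi_wild = pw,
               rod = rod(pc, pw),
               fst = fst_hudson(gm, cul, wld, ctg, s, e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
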