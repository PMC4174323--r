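#' Read a VCF cohort and its sample-group table
#'
#' Loads diploid genotypes from a VCF (v4.2) and the sample-to-subgroup
#' assignment from a TSV with columns `sample_id`, `subgroup`, `role`.
#' Non-SNP and multi-allelic records are dropped (their count is
#' reported via `message()`); GT fields are recoded `0/0 -> 0`,
#' `0/1`/`1/0 -> 1`, `1/1 -> 2`, `./. -> NA`.
#'
#' @param vcf_path path to a VCF file.
#' @param groups_path path to the groups TSV.
#' @return list with elements `matrix` (a [genotype_matrix]) and
#'   `groups` (a [sample_groups]).
#' @export
read_cohort <- function(vcf_path, groups_path) {
  for (p in c(vcf_path, groups_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  is_snp <- fix$REF %in% nt & fix$ALT %in% nt
  n_dropped <- sum(!is_snp)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " non-SNP or multi-allelic record(s)")
  }
  if (!any(is_snp)) stop("no usable biallelic SNP records in ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  groups <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  groups <- sample_groups(groups)
  missing <- setdiff(colnames(gt), groups$sample_id)
  if (length(missing)) {
    stop("VCF sample(s) absent from groups table: ",
         paste(missing, collapse = ", "))
  }

  codes <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), NULL))
  g <- t(gt)
  g <- gsub("|", "/", g, fixed = TRUE)
  codes[g %in% c("0/0")] <- 0L
  codes[g %in% c("0/1", "1/0")] <- 1L
  codes[g %in% c("1/1")] <- 2L

  sites <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  o <- order(sites$contig, sites$pos)
  sites <- sites[o, , drop = FALSE]
  codes <- codes[, o, drop = FALSE]
  list(matrix = genotype_matrix(codes, sites), groups = groups)
}

#' Filter population SNPs by call rate and minor-allele frequency
#'
#' Call-rate and MAF thresholds stand as genotype-level proxies for the
#' original raw-read depth and mapping-rate filters: a site is retained
#' when the fraction of called genotypes reaches `min_called_fraction`
#' and the minor-allele frequency among called genotypes reaches
#' `maf_min`.  Site order is preserved.
#'
#' @param gm a [genotype_matrix].
#' @param min_called_fraction minimum fraction of samples with a called
#'   genotype, in `[0, 1]`.
#' @param maf_min minimum minor-allele frequency, in `[0, 0.5)`.
#' @return a filtered [genotype_matrix] (possibly with zero sites).
#' @export
filter_population_snps <- function(gm, min_called_fraction = 0.5,
                                   maf_min = 0) {
  stopifnot(min_called_fraction >= 0, min_called_fraction <= 1,
            maf_min >= 0, maf_min < 0.5)
  codes <- genotype_codes(gm)
  sites <- variant_sites(gm)
  if (ncol(codes) == 0L) return(gm)
  n <- nrow(codes)
  called <- colSums(!is.na(codes))
  ac <- colSums(codes, na.rm = TRUE)
  af <- ifelse(called > 0, ac / (2 * called), NA_real_)
  maf <- pmin(af, 1 - af)
  maf_ok <- if (maf_min > 0) !is.na(maf) & maf >= maf_min else TRUE
  keep <- called / n >= min_called_fraction & maf_ok
  genotype_matrix(codes[, keep, drop = FALSE],
                  sites[keep, , drop = FALSE])
}

#' Tile contigs into (sliding) windows
#'
#' Windows are 0-based half-open.  The last window of a contig may be
#' partial; it is kept and its true length recorded.
#'
#' @param contig_lengths named integer vector of contig lengths in bp.
#' @param window_size window width in bp (> 0).
#' @param step distance between window starts; `0 < step <= window_size`
#'   (default: `window_size`, disjoint tiling).
#' @return data.frame with columns `contig`, `start`, `end`, `length`.
#' @examples
#' iter_windows(c(chr1 = 25000), 10000, 5000)
#' @export
iter_windows <- function(contig_lengths, window_size, step = window_size) {
  stopifnot(window_size > 0, step > 0, step <= window_size)
  if (length(contig_lengths) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), length = integer()))
  }
  if (is.null(names(contig_lengths))) stop("contig lengths must be named")
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_size, len)
    data.frame(contig = ctg, start = as.integer(starts),
               end = as.integer(ends),
               length = as.integer(ends - starts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
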