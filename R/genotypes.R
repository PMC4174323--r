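#' Genotype matrix of a biallelic SNP cohort
#'
#' Container pairing a samples-by-sites matrix of diploid dosage codes
#' (0 hom-ref, 1 het, 2 hom-alt, `NA` missing) with a parallel variant
#' table.  Sites must be biallelic single-nucleotide variants strictly
#' ordered by (contig, position).
#'
#' @param codes integer matrix, samples in rows (rownames = sample ids),
#'   sites in columns.
#' @param sites data.frame with columns `contig`, `pos` (1-based, VCF
#'   convention), `ref`, `alt`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, sites) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes))) {
    stop("`codes` must carry sample ids as rownames")
  }
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  if (nrow(sites) != ncol(codes)) {
    stop("`sites` rows (", nrow(sites), ") must match `codes` columns (",
         ncol(codes), ")")
  }
  bad <- codes[!is.na(codes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  nt <- c("A", "C", "G", "T")
  if (nrow(sites)) {
    if (!all(sites$ref %in% nt) || !all(sites$alt %in% nt)) {
      stop("ref/alt must be single nucleotides (A/C/G/T)")
    }
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    o <- order(sites$contig, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      stop("sites must be ordered by (contig, position)")
    }
    key <- paste(sites$contig, sites$pos)
    if (anyDuplicated(key)) stop("duplicate site positions")
  }
  rownames(sites) <- NULL
  structure(list(codes = codes, sites = sites), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "samples x", ncol(x$codes),
      "biallelic SNPs on", length(unique(x$sites$contig)), "contig(s)\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
genotype_codes <- function(gm) {
  if (is.matrix(gm)) return(gm)
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$codes
}

#' @rdname genotype_matrix
#' @export
variant_sites <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$sites
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

# Subset a genotype matrix by sample ids and/or a window
# (0-based half-open genomic interval).
subset_matrix <- function(gm, samples = NULL, contig = NULL,
                          start = NULL, end = NULL) {
  codes <- genotype_codes(gm)
  sites <- variant_sites(gm)
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(contig)) keep <- keep & sites$contig == contig
  if (!is.null(start)) keep <- keep & (sites$pos - 1L) >= start
  if (!is.null(end)) keep <- keep & (sites$pos - 1L) < end
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(codes))
    if (length(miss)) {
      stop("samples not in matrix: ", paste(miss, collapse = ", "))
    }
    codes <- codes[samples, , drop = FALSE]
  }
  codes[, keep, drop = FALSE]
}

#' Sample-to-subgroup assignment table
#'
#' @param df data.frame with columns `sample_id`, `subgroup`, `role`
#'   (role one of `"wild"`, `"ornamental"`, `"edible"`).
#' @return a `sample_groups` data.frame.
#' @export
sample_groups <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("sample_id", "subgroup", "role") %in% names(df)))
  if (anyDuplicated(df$sample_id)) {
    stop("each sample must be assigned to exactly one subgroup")
  }
  if (!all(df$role %in% c("wild", "ornamental", "edible"))) {
    stop("role must be one of wild/ornamental/edible")
  }
  df <- df[, c("sample_id", "subgroup", "role")]
  rownames(df) <- NULL
  class(df) <- c("sample_groups", "data.frame")
  df
}

as_sample_groups <- function(x) {
  if (inherits(x, "sample_groups")) x else sample_groups(x)
}

#' Samples belonging to a subgroup or derived group view
#'
#' `group` may be a subgroup label, a role (`"wild"`, `"ornamental"`,
#' `"edible"`), or the derived view `"cultivated"` (ornamental plus
#' edible) or `"all"`.
#'
#' @param groups a [sample_groups] table.
#' @param group label to resolve.
#' @return character vector of sample ids.
#' @export
group_members <- function(groups, group) {
  groups <- as_sample_groups(groups)
  if (group == "all") return(groups$sample_id)
  if (group == "cultivated") {
    return(groups$sample_id[groups$role %in% c("ornamental", "edible")])
  }
  if (group %in% groups$role) {
    return(groups$sample_id[groups$role == group])
  }
  if (group %in% groups$subgroup) {
    return(groups$sample_id[groups$subgroup == group])
  }
  stop("unknown group '", group, "'")
}
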