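#' Composite LD between two sites
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors over samples
#' called at both sites (composite LD; no phasing required).  Both sites
#' must pass the minor-allele-frequency threshold among those samples.
#'
#' @param gm a [genotype_matrix] or codes matrix.
#' @param site_i,site_j column indices of the two sites.
#' @param maf_min minimum minor-allele frequency (default 0.1).
#' @return r-squared in `[0, 1]`, or `NA` when either site is
#'   monomorphic among shared called samples or fails the MAF filter.
#' @export
ld_r2 <- function(gm, site_i, site_j, maf_min = 0.1) {
  codes <- genotype_codes(gm)
  x <- codes[, site_i]
  y <- codes[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  maf <- function(v) {
    p <- mean(v) / 2
    min(p, 1 - p)
  }
  if (maf(x) < maf_min || maf(y) < maf_min) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay curve and half-decay distance
#'
#' Mean r-squared per distance bin over all intra-contig site pairs
#' within `max_dist`, for the samples of one group.  The half-decay
#' distance is where the binned curve first falls below half of its
#' maximum, linearly interpolated between bin midpoints.
#'
#' @param gm a [genotype_matrix].
#' @param samples sample ids of the group.
#' @param max_dist maximum pair distance in bp (default 1e6).
#' @param bin_width distance bin width in bp (default 1000).
#' @param maf_min minimum minor-allele frequency (default 0.1).
#' @param max_sites_per_contig cap on sites per contig entering the
#'   pairwise computation; when exceeded an evenly spaced deterministic
#'   subsample is used.
#' @return an `ld_decay_curve`: list with `bins` (data.frame
#'   `dist_lo`, `dist_hi`, `dist_mid`, `mean_r2`, `n_pairs`), `max_r2`
#'   and `half_decay_distance` (`NA` when the curve never falls below
#'   half its maximum).
#' @export
ld_decay <- function(gm, samples, max_dist = 1e6, bin_width = 1000,
                     maf_min = 0.1, max_sites_per_contig = 2000L) {
  codes <- genotype_codes(gm)[samples, , drop = FALSE]
  sites <- variant_sites(gm)
  if (length(samples) == 0L) stop("`samples` must be non-empty")

  all_d <- numeric(0)
  all_r2 <- numeric(0)
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    sub <- codes[, idx, drop = FALSE]
    called <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * pmax(called, 1L))
    maf <- pmin(p, 1 - p)
    keep <- called >= 2 & maf >= maf_min
    idx <- idx[keep]
    if (length(idx) < 2L) next
    if (length(idx) > max_sites_per_contig) {
      pick <- round(seq(1L, length(idx), length.out = max_sites_per_contig))
      idx <- idx[unique(pick)]
    }
    X <- codes[, idx, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))^2
    pos <- sites$pos[idx]
    dmat <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dmat)
    sel <- ut & dmat <= max_dist & dmat > 0 & !is.na(r2)
    all_d <- c(all_d, dmat[sel])
    all_r2 <- c(all_r2, r2[sel])
  }
  if (!length(all_d)) {
    return(structure(list(bins = data.frame(dist_lo = numeric(),
                                            dist_hi = numeric(),
                                            dist_mid = numeric(),
                                            mean_r2 = numeric(),
                                            n_pairs = integer()),
                          max_r2 = NA_real_,
                          half_decay_distance = NA_real_),
                     class = "ld_decay_curve"))
  }
  bin <- pmax(1L, ceiling(all_d / bin_width))
  mean_r2 <- tapply(all_r2, bin, mean)
  n_pairs <- tapply(all_r2, bin, length)
  b <- as.integer(names(mean_r2))
  bins <- data.frame(dist_lo = (b - 1) * bin_width,
                     dist_hi = b * bin_width,
                     dist_mid = (b - 0.5) * bin_width,
                     mean_r2 = as.numeric(mean_r2),
                     n_pairs = as.integer(n_pairs))
  bins <- bins[order(bins$dist_mid), ]
  rownames(bins) <- NULL
  max_r2 <- max(bins$mean_r2)
  half <- max_r2 / 2
  hd <- NA_real_
  below <- which(bins$mean_r2 < half)
  if (length(below)) {
    j <- below[1]
    if (j == 1L) {
      hd <- bins$dist_mid[1]
    } else {
      x0 <- bins$dist_mid[j - 1]; y0 <- bins$mean_r2[j - 1]
      x1 <- bins$dist_mid[j]; y1 <- bins$mean_r2[j]
      hd <- x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
    }
  }
  structure(list(bins = bins, max_r2 = max_r2, half_decay_distance = hd),
            class = "ld_decay_curve")
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  cat("ld_decay_curve:", nrow(x$bins), "bins, max r2 =",
      signif(x$max_r2, 3), ", half-decay =",
      if (is.na(x$half_decay_distance)) "undefined"
      else paste0(round(x$half_decay_distance), " bp"), "\n")
  invisible(x)
}

#' Principal component analysis of 0/1/2 genotypes
#'
#' Missing codes are imputed to the per-site mean dosage, sites are
#' centered (no variance standardization), and the sample-by-sample
#' covariance matrix is eigendecomposed.  Sample coordinates are the
#' eigenvectors; each eigenvector's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param gm a [genotype_matrix] or codes matrix.
#' @param k number of components to return (default: all).
#' @return list with `scores` (samples x k), `eigenvalues`
#'   (non-increasing), `proportion` (variance shares) and `covariance`
#'   (the decomposed matrix).
#' @export
pca_genotypes <- function(gm, k = NULL) {
  X <- genotype_codes(gm)
  if (nrow(X) < 2L) stop("PCA needs at least two samples")
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  poly <- apply(X, 2, function(v) stats::var(v) > 0)
  if (!any(poly)) stop("all sites monomorphic; PCA undefined")
  Xc <- scale(X[, poly, drop = FALSE], center = TRUE, scale = FALSE)
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(X)
  if (is.null(k)) k <- ncol(V)
  k <- min(k, ncol(V))
  lam <- pmax(e$values, 0)
  list(scores = V[, seq_len(k), drop = FALSE],
       eigenvalues = e$values,
       proportion = lam / sum(lam),
       covariance = C)
}
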