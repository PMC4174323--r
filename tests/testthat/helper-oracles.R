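# Independent oracle implementations used to cross-check the package's
# statistics.  Everything here is written as a second route: explicit
# haplotype-pair enumeration and whole-protein translation, never calls
# into the implementation under test.

# Expand diploid dosage codes (samples x sites) into a haplotype allele
# matrix (2*samples x sites); het = one 0 and one 1.  NA genotypes give
# two NA haplotypes.
expand_haplotypes <- function(codes) {
  n <- nrow(codes)
  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = ncol(codes))
  for (j in seq_len(ncol(codes))) {
    for (i in seq_len(n)) {
      g <- codes[i, j]
      if (is.na(g)) next
      hap[2L * i - 1L, j] <- if (g >= 1L) 1L else 0L
      hap[2L * i, j] <- if (g == 2L) 1L else 0L
    }
  }
  hap
}

# Tajima constants via literal harmonic loops (independent arithmetic).
oracle_constants <- function(n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i / i
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1 * a1 + a2))
}

# Mean pairwise difference summed over sites, by explicit enumeration of
# all called haplotype pairs at each site.
oracle_pi_total <- function(codes) {
  hap <- expand_haplotypes(codes)
  total <- 0
  for (j in seq_len(ncol(hap))) {
    h <- hap[!is.na(hap[, j]), j]
    if (length(h) < 2L) next
    diff <- 0; pairs <- 0
    for (a in seq_len(length(h) - 1)) {
      for (b in (a + 1):length(h)) {
        diff <- diff + as.integer(h[a] != h[b])
        pairs <- pairs + 1
      }
    }
    total <- total + diff / pairs
  }
  total
}

oracle_segregating_sites <- function(codes) {
  hap <- expand_haplotypes(codes)
  S <- 0L
  for (j in seq_len(ncol(hap))) {
    h <- hap[!is.na(hap[, j]), j]
    if (length(h) >= 2L && length(unique(h)) > 1L) S <- S + 1L
  }
  S
}

oracle_tajima_d <- function(codes, s_min = 3L) {
  n_hap <- 2L * nrow(codes)
  S <- oracle_segregating_sites(codes)
  if (S < s_min) return(NA_real_)
  k <- oracle_constants(n_hap)
  num <- oracle_pi_total(codes) - S / k$a1
  den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  num / den
}

# Hudson Fst by explicit enumeration of between- and within-group
# haplotype pairs (within-group pairs include within-individual pairs,
# matching the dosage-frequency estimator).
oracle_fst <- function(codes1, codes2) {
  h1 <- expand_haplotypes(codes1)
  h2 <- expand_haplotypes(codes2)
  btw <- 0; wth <- 0
  for (j in seq_len(ncol(h1))) {
    a <- h1[!is.na(h1[, j]), j]
    b <- h2[!is.na(h2[, j]), j]
    if (!length(a) || !length(b)) next
    d <- 0
    for (x in a) for (y in b) d <- d + as.integer(x != y)
    btw <- btw + d / (length(a) * length(b))
    wsite <- 0
    for (h in list(a, b)) {
      d <- 0; p <- 0
      for (x in seq_len(length(h) - 1)) {
        for (y in (x + 1):length(h)) {
          d <- d + as.integer(h[x] != h[y]); p <- p + 1
        }
      }
      wsite <- wsite + d / p
    }
    wth <- wth + wsite / 2
  }
  if (btw <= 0) return(NA_real_)
  (btw - wth) / btw
}

# Whole-protein translation oracle for coding effects: mutate the
# genome, re-splice the transcript's CDS, translate both proteins with
# Biostrings and compare.
oracle_cds_effect <- function(fasta_path, gff_path, tx_id,
                              contig, pos, alt) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path)
  cds <- gff[gff$type == "CDS" &
               vapply(gff$Parent, function(p) length(p) && p[[1]] == tx_id,
                      logical(1))]
  cds <- cds[order(GenomicRanges::start(cds))]
  strand <- as.character(GenomicRanges::strand(cds))[1]
  splice <- function(genome) {
    parts <- lapply(seq_along(cds), function(i) {
      Biostrings::subseq(genome[[contig]],
                         GenomicRanges::start(cds)[i],
                         GenomicRanges::end(cds)[i])
    })
    s <- do.call(Biostrings::xscat, parts)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    s
  }
  mutant <- seqs
  mseq <- as.character(mutant[[contig]])
  substr(mseq, pos, pos) <- alt
  mutant[[contig]] <- Biostrings::DNAString(mseq)
  p_ref <- as.character(Biostrings::translate(splice(seqs),
                                              no.init.codon = TRUE,
                                              if.fuzzy.codon = "solve"))
  p_alt <- as.character(Biostrings::translate(splice(mutant),
                                              no.init.codon = TRUE,
                                              if.fuzzy.codon = "solve"))
  if (identical(p_ref, p_alt)) "synonymous" else "nonsynonymous"
}

# Deterministic random dosage matrix with sample ids.
rand_codes <- function(n_samples, n_sites, seed, na_rate = 0) {
  set.seed(seed)
  m <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE,
                     prob = c(0.6, 0.25, 0.15)),
              nrow = n_samples)
  if (na_rate > 0) m[runif(length(m)) < na_rate] <- NA_integer_
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}
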