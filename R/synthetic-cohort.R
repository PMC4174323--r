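#' Default subgroup design of the synthetic cohort
#'
#' One wild subgroup of 10 accessions plus six cultivated subgroups
#' (one ornamental, five edible) whose sizes mirror the scan's printed
#' sample sizes (6 to 9 accessions).
#'
#' @return data.frame with `name`, `role`, `n_accessions`.
#' @export
default_subgroups <- function() {
  data.frame(
    name = c("W", "A", "B", "C", "D", "E", "F"),
    role = c("wild", "ornamental", rep("edible", 5)),
    n_accessions = c(10L, 8L, 6L, 8L, 7L, 9L, 9L),
    stringsAsFactors = FALSE)
}

#' Default sweep plan
#'
#' One sweep confined to the four edible rule subgroups and one confined
#' to the ornamental subgroup, both of the low-frequency-excess kind
#' with the surviving diversity reduced to 30% of neutral.
#'
#' @return data.frame with `contig`, `window`, `subgroups`, `mode`,
#'   `reduction`.
#' @export
default_sweep_plan <- function() {
  data.frame(
    contig = c("chr1", "chr2"),
    window = c(5L, 8L),
    subgroups = c("C,D,E,F", "A"),
    mode = "low_freq_excess",
    reduction = 0.3,
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' Collects everything the generator needs: contigs, subgroup design,
#' per-subgroup scaled mutation rate and inbreeding coefficient, window
#' size, sweep plan and seed.  Defaults encode the emulated study
#' design: wild diversity at the genome-wide scale 2.6e-3 with
#' cultivated subgroups below it, and selfing-strength inbreeding
#' (F = 0.75 cultivated, 0.45 wild) so per-accession heterozygous-call
#' ratios land in the observed few-percent regime (roughly 1-2%
#' cultivated, 3-4% wild).
#'
#' @param contigs named integer vector of contig lengths (bp).
#' @param subgroups data.frame as [default_subgroups()].
#' @param window_size scan window in bp (default 10000).
#' @param theta_per_site named per-subgroup expected pairwise diversity
#'   per site; unnamed scalar recycled to all subgroups.
#' @param inbreeding_f named per-subgroup inbreeding coefficient in
#'   `[0, 1]`; unnamed scalar recycled.
#' @param sweep_plan data.frame as [default_sweep_plan()]; `NULL` or
#'   zero rows for a fully neutral cohort.
#' @param missing_rate per-call missing probability (default 0).
#' @param ld_block_bp optional haplotype-block length in bp: sites in
#'   the same block share one haplotype ordering, creating non-trivial
#'   r-squared for LD-decay tests; `NULL` (default) simulates sites
#'   independently.
#' @param genes_per_10kb expected gene density of the toy genome.
#' @param seed integer RNG seed; the whole artifact is a deterministic
#'   function of the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(contigs = c(chr1 = 200000L, chr2 = 200000L),
                        subgroups = default_subgroups(),
                        window_size = 10000L,
                        theta_per_site = c(W = 2.6e-3, A = 1.3e-3,
                                           B = 1.8e-3, C = 1.8e-3,
                                           D = 1.8e-3, E = 1.8e-3,
                                           F = 1.8e-3),
                        inbreeding_f = c(W = 0.45, A = 0.75, B = 0.75,
                                         C = 0.75, D = 0.75, E = 0.75,
                                         F = 0.75),
                        sweep_plan = default_sweep_plan(),
                        missing_rate = 0,
                        ld_block_bp = NULL,
                        genes_per_10kb = 1,
                        seed = 1L) {
  stopifnot(is.numeric(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)))
  stopifnot(is.data.frame(subgroups),
            all(c("name", "role", "n_accessions") %in% names(subgroups)))
  if (anyDuplicated(subgroups$name)) stop("subgroup names must be unique")
  if (any(subgroups$n_accessions < 2L)) {
    stop("every subgroup needs n_accessions >= 2")
  }
  if (!all(subgroups$role %in% c("wild", "ornamental", "edible"))) {
    stop("subgroup role must be wild/ornamental/edible")
  }
  expand <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) != 1L) stop(what, " must be named or scalar")
      x <- stats::setNames(rep(x, nrow(subgroups)), subgroups$name)
    }
    miss <- setdiff(subgroups$name, names(x))
    if (length(miss)) stop(what, " missing for subgroup(s): ",
                           paste(miss, collapse = ", "))
    x[subgroups$name]
  }
  theta_per_site <- expand(theta_per_site, "theta_per_site")
  inbreeding_f <- expand(inbreeding_f, "inbreeding_f")
  if (any(theta_per_site < 0)) stop("theta_per_site must be >= 0")
  if (any(inbreeding_f < 0 | inbreeding_f > 1)) {
    stop("inbreeding_f must lie in [0, 1]")
  }
  if (any(contigs < window_size)) {
    stop("contig(s) shorter than one window: ",
         paste(names(contigs)[contigs < window_size], collapse = ", "))
  }
  if (is.null(sweep_plan)) {
    sweep_plan <- default_sweep_plan()[0, ]
  }
  if (nrow(sweep_plan)) {
    stopifnot(all(c("contig", "window", "subgroups", "mode",
                    "reduction") %in% names(sweep_plan)))
    if (!all(sweep_plan$contig %in% names(contigs))) {
      stop("sweep plan names unknown contig(s)")
    }
    n_win <- ceiling(contigs[sweep_plan$contig] / window_size)
    if (any(sweep_plan$window < 1L | sweep_plan$window > n_win)) {
      stop("sweep window index outside its contig")
    }
    if (anyDuplicated(sweep_plan[, c("contig", "window")])) {
      stop("overlapping sweep windows on one contig are not allowed")
    }
    if (!all(sweep_plan$mode %in% c("low_freq_excess",
                                    "intermediate_excess"))) {
      stop("sweep mode must be low_freq_excess or intermediate_excess")
    }
    if (any(sweep_plan$reduction <= 0 | sweep_plan$reduction > 1)) {
      stop("diversity_reduction must lie in (0, 1]")
    }
    affected <- unlist(strsplit(sweep_plan$subgroups, ","))
    if (!all(trimws(affected) %in% subgroups$name)) {
      stop("sweep plan names unknown subgroup(s)")
    }
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(contigs = contigs, subgroups = subgroups,
                 window_size = as.integer(window_size),
                 theta_per_site = theta_per_site,
                 inbreeding_f = inbreeding_f,
                 sweep_plan = sweep_plan,
                 missing_rate = missing_rate,
                 ld_block_bp = ld_block_bp,
                 genes_per_10kb = genes_per_10kb,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a derived-allele count from a site-frequency spectrum
#'
#' `neutral` draws from the standard neutral spectrum `P(i) ~ 1/i`
#' (simulated D then centers near 0); `low_freq_excess` draws from
#' `P(i) ~ 1/i^4`, the near-complete singleton excess left by a hard
#' sweep; `intermediate_excess` concentrates mass near `n_hap/2`
#' (Gaussian weights, sd `n_hap/8`), the balancing-selection regime.
#'
#' @param n_hap number of haplotypes (>= 2).
#' @param mode one of `"neutral"`, `"low_freq_excess"`,
#'   `"intermediate_excess"`.
#' @param size number of draws.
#' @return integer derived counts in `[1, n_hap - 1]`.
#' @export
site_frequency_sample <- function(n_hap, mode = "neutral", size = 1L) {
  if (!is.numeric(n_hap) || n_hap < 2) stop("`n_hap` must be >= 2")
  mode <- match.arg(mode, c("neutral", "low_freq_excess",
                            "intermediate_excess"))
  i <- seq_len(n_hap - 1)
  w <- switch(mode,
              neutral = 1 / i,
              low_freq_excess = 1 / i^4,
              intermediate_excess = exp(-(i - n_hap / 2)^2 /
                                          (2 * (n_hap / 8)^2)))
  if (length(i) == 1L) return(rep(1L, size))
  sample(i, size, replace = TRUE, prob = w / sum(w))
}

# Simulate the diploid dosage matrix of one subgroup over one window.
# Returns n_acc x S integer matrix (S ~ Poisson(reduction * theta * a1 * L)).
#
# Inbreeding is modeled at the lineage level (the standard selfing
# mixture): with probability F an accession carries one
# identical-by-descent lineage (both haplotypes are copies), otherwise
# two independent lineages.  The derived-allele count is drawn from the
# mode's site-frequency spectrum over the site's lineages, so
# low-frequency excess survives any F and heterozygous calls scale with
# (1 - F).
#
# `block` optionally gives a per-site block id; sites sharing a block id
# share one IBD pattern and lineage ordering (nested derived-allele
# carriers), which creates strong within-block LD for decay tests.
simulate_window_genotypes <- function(n_acc, theta, L,
                                      mode = "neutral",
                                      inbreeding_f = 0,
                                      reduction = 1,
                                      S = NULL, block = NULL) {
  n_hap <- 2L * n_acc
  if (is.null(S)) {
    a1 <- tajima_constants(n_hap)$a1
    S <- stats::rpois(1L, reduction * theta * a1 * L)
  }
  out <- matrix(0L, nrow = n_acc, ncol = S)
  if (S == 0L) return(out)
  block_state <- list()
  for (s in seq_len(S)) {
    b <- if (!is.null(block)) as.character(block[s]) else NA_character_
    if (!is.na(b) && !is.null(block_state[[b]])) {
      st <- block_state[[b]]
    } else {
      ibd <- stats::runif(n_acc) < inbreeding_f
      # lineage layout: IBD accession -> 1 lineage, outbred -> 2
      n_lin <- n_acc + sum(!ibd)
      st <- list(ibd = ibd, n_lin = n_lin, perm = sample.int(n_lin))
      if (!is.na(b)) block_state[[b]] <- st
    }
    i <- site_frequency_sample(st$n_lin, mode, size = 1L)
    carriers <- st$perm[seq_len(i)]
    lin <- integer(st$n_lin)
    lin[carriers] <- 1L
    # expand lineages back to diploid dosages
    dosage <- integer(n_acc)
    pos <- 1L
    for (a in seq_len(n_acc)) {
      if (st$ibd[a]) {
        dosage[a] <- 2L * lin[pos]
        pos <- pos + 1L
      } else {
        dosage[a] <- lin[pos] + lin[pos + 1L]
        pos <- pos + 2L
      }
    }
    out[, s] <- dosage
  }
  out
}

.codons <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                 paste0), c("T", "C", "A", "G"), paste0))
.stop_codons <- c("TAA", "TAG", "TGA")
.sense_codons <- setdiff(.codons, .stop_codons)

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Build one toy gene model inside [slot_start, slot_end] (1-based,
# inclusive).  Returns NULL when the slot is too small, else a list with
# the locus sequence (genome plus-strand), gene coordinates and feature
# rows (1-based inclusive, genomic).
simulate_gene <- function(gene_id, contig, slot_start, slot_end) {
  n_ex <- sample(2:4, 1)
  m <- sample(60:150, 1)                      # codons incl. start+stop
  cds_len <- 3L * m
  u5 <- sample(30:100, 1)
  u3 <- sample(30:150, 1)
  introns <- sample(50:300, n_ex - 1, replace = TRUE)
  locus_len <- u5 + cds_len + u3 + sum(introns)
  avail <- slot_end - slot_start + 1L
  if (locus_len + 10L > avail) return(NULL)
  gene_start <- slot_start + sample.int(avail - locus_len, 1) - 1L
  strand <- sample(c("+", "-"), 1)

  cds_seq <- paste0("ATG",
                    paste(sample(.sense_codons, m - 2, replace = TRUE),
                          collapse = ""),
                    sample(.stop_codons, 1))
  # split CDS into n_ex chunks, each >= 3 bp
  if (n_ex > 1) {
    cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), n_ex - 1))
    part_len <- diff(c(0L, cuts, cds_len))
  } else {
    part_len <- cds_len
  }
  # transcript-order segments: type, length, sequence chunk
  segs <- list(list(type = "five_prime_UTR", len = u5, seq = random_seq(u5)))
  off <- 0L
  for (j in seq_len(n_ex)) {
    chunk <- substr(cds_seq, off + 1L, off + part_len[j])
    segs[[length(segs) + 1L]] <- list(type = "CDS", len = part_len[j],
                                      seq = chunk,
                                      phase = (3L - off %% 3L) %% 3L)
    off <- off + part_len[j]
    if (j < n_ex) {
      segs[[length(segs) + 1L]] <- list(type = "intron", len = introns[j],
                                        seq = random_seq(introns[j]))
    }
  }
  segs[[length(segs) + 1L]] <- list(type = "three_prime_UTR", len = u3,
                                    seq = random_seq(u3))

  pre_mrna <- paste(vapply(segs, `[[`, character(1), "seq"), collapse = "")
  locus_seq <- if (strand == "+") pre_mrna else revcomp_chr(pre_mrna)
  gene_end <- gene_start + locus_len - 1L

  # genomic coordinates of each transcript-order segment
  feat <- list()
  cum <- 0L
  for (sg in segs) {
    if (strand == "+") {
      s <- gene_start + cum
      e <- s + sg$len - 1L
    } else {
      e <- gene_end - cum
      s <- e - sg$len + 1L
    }
    if (sg$type != "intron") {
      feat[[length(feat) + 1L]] <- data.frame(
        type = sg$type, start = s, end = e,
        phase = if (sg$type == "CDS") sg$phase else NA_integer_,
        stringsAsFactors = FALSE)
    }
    cum <- cum + sg$len
  }
  feat <- do.call(rbind, feat)
  # exon spans: union of non-intron genomic segments that touch
  fo <- feat[order(feat$start), ]
  run <- cumsum(c(TRUE, fo$start[-1] != fo$end[-nrow(fo)] + 1L))
  exons <- data.frame(start = tapply(fo$start, run, min),
                      end = tapply(fo$end, run, max))
  list(gene_id = gene_id, contig = contig, strand = strand,
       start = gene_start, end = gene_end, seq = locus_seq,
       features = feat, exons = exons)
}

# Assemble the toy genome: contig sequences plus GFF3 rows.
simulate_genome <- function(spec) {
  seqs <- list()
  gff <- list("##gff-version 3")
  gene_n <- 0L
  for (ctg in names(spec$contigs)) {
    len <- spec$contigs[[ctg]]
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    slot <- 10000L
    n_slot <- len %/% slot
    for (s in seq_len(n_slot)) {
      if (stats::runif(1) > spec$genes_per_10kb) next
      gene_n <- gene_n + 1L
      gid <- sprintf("gene%03d", gene_n)
      g <- simulate_gene(gid, ctg, (s - 1L) * slot + 1L, s * slot)
      if (is.null(g)) next
      chars[g$start:g$end] <- strsplit(g$seq, "")[[1]]
      tid <- paste0(gid, ".t1")
      row9 <- function(type, st, en, phase, attrs) {
        paste(ctg, "sweepscan", type, st, en, ".", g$strand,
              ifelse(is.na(phase), ".", phase), attrs, sep = "\t")
      }
      gff[[length(gff) + 1L]] <-
        row9("gene", g$start, g$end, NA, paste0("ID=", gid))
      gff[[length(gff) + 1L]] <-
        row9("mRNA", g$start, g$end, NA, paste0("ID=", tid, ";Parent=", gid))
      for (i in seq_len(nrow(g$exons))) {
        gff[[length(gff) + 1L]] <-
          row9("exon", g$exons$start[i], g$exons$end[i], NA,
               paste0("Parent=", tid))
      }
      for (i in seq_len(nrow(g$features))) {
        f <- g$features[i, ]
        gff[[length(gff) + 1L]] <-
          row9(f$type, f$start, f$end,
               if (f$type == "CDS") f$phase else NA,
               paste0("Parent=", tid))
      }
    }
    seqs[[ctg]] <- paste(chars, collapse = "")
  }
  list(seqs = seqs, gff = unlist(gff))
}

#' Generate a complete synthetic cohort on disk
#'
#' Deterministically (given the spec's seed) writes a toy reference
#' FASTA, GFF3 gene models, a sorted biallelic-SNP VCF with diploid GT
#' fields, the sample-group TSV and a truth BED of injected sweep
#' windows.  Neutral windows carry site counts and frequency spectra
#' matching each subgroup's `theta_per_site`; sweep windows in affected
#' subgroups have S reduced by the plan's `reduction` and frequencies
#' drawn from the sweep mode; inbreeding lowers heterozygous calls by
#' the factor `(1 - F)`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return named list of file paths: `fasta`, `gff`, `vcf`, `groups`,
#'   `truth`.
#' @export
simulate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  genome <- simulate_genome(spec)

  sg <- spec$subgroups
  sample_ids <- unlist(lapply(seq_len(nrow(sg)), function(i) {
    sprintf("%s%02d", sg$name[i], seq_len(sg$n_accessions[i]))
  }))
  sample_sg <- rep(sg$name, sg$n_accessions)
  n_total <- length(sample_ids)

  windows <- iter_windows(spec$contigs, spec$window_size)
  win_index <- stats::ave(seq_len(nrow(windows)), windows$contig,
                          FUN = seq_along)

  plan_key <- if (nrow(spec$sweep_plan)) {
    paste(spec$sweep_plan$contig, spec$sweep_plan$window)
  } else character()

  site_rows <- list()
  for (w in seq_len(nrow(windows))) {
    ctg <- windows$contig[w]
    Lw <- windows$length[w]
    pk <- match(paste(ctg, win_index[w]), plan_key)
    sweep <- if (!is.na(pk)) spec$sweep_plan[pk, ] else NULL
    affected <- if (!is.null(sweep)) {
      trimws(strsplit(sweep$subgroups, ",")[[1]])
    } else character()

    geno_by_sg <- list()
    for (i in seq_len(nrow(sg))) {
      name <- sg$name[i]
      is_aff <- name %in% affected
      block <- NULL
      n_hap <- 2L * sg$n_accessions[i]
      a1 <- tajima_constants(n_hap)$a1
      red <- if (is_aff) sweep$reduction else 1
      S <- stats::rpois(1L, red * spec$theta_per_site[[name]] * a1 * Lw)
      geno_by_sg[[name]] <- list(S = S,
                                 mode = if (is_aff) sweep$mode else "neutral")
    }
    S_tot <- sum(vapply(geno_by_sg, `[[`, integer(1), "S"))
    if (S_tot == 0L) next
    pos <- sort(sample.int(Lw, min(S_tot, Lw))) + windows$start[w]
    if (length(pos) < S_tot) {
      # more sites than bp (pathological theta); trim proportionally
      S_tot <- length(pos)
    }
    owner <- sample(rep(sg$name, vapply(geno_by_sg, `[[`, integer(1), "S"))[
      seq_len(S_tot)])
    for (name in sg$name) {
      mine <- which(owner == name)
      if (!length(mine)) next
      block <- if (!is.null(spec$ld_block_bp)) {
        (pos[mine] - windows$start[w] - 1L) %/% spec$ld_block_bp
      } else NULL
      G <- simulate_window_genotypes(
        n_acc = sg$n_accessions[sg$name == name],
        theta = spec$theta_per_site[[name]], L = Lw,
        mode = geno_by_sg[[name]]$mode,
        inbreeding_f = spec$inbreeding_f[[name]],
        S = length(mine), block = block)
      geno_by_sg[[name]]$G <- G
      geno_by_sg[[name]]$sites <- mine
    }
    # assemble cohort dosages for this window's sites
    dos <- matrix(0L, nrow = n_total, ncol = S_tot)
    for (name in sg$name) {
      if (is.null(geno_by_sg[[name]]$G)) next
      dos[sample_sg == name, geno_by_sg[[name]]$sites] <-
        geno_by_sg[[name]]$G
    }
    site_rows[[length(site_rows) + 1L]] <-
      list(contig = ctg, pos = pos, dos = dos)
  }

  # flatten, draw alleles from the reference, apply missingness
  contig_v <- unlist(lapply(site_rows, function(x) rep(x$contig, length(x$pos))))
  pos_v <- unlist(lapply(site_rows, function(x) x$pos))
  dos_m <- if (length(site_rows)) {
    do.call(cbind, lapply(site_rows, `[[`, "dos"))
  } else matrix(0L, nrow = n_total, ncol = 0L)
  if (spec$missing_rate > 0 && length(dos_m)) {
    drop <- matrix(stats::runif(length(dos_m)) < spec$missing_rate,
                   nrow = nrow(dos_m))
    dos_m[drop] <- NA_integer_
  }
  nt <- c("A", "C", "G", "T")
  ref_v <- character(length(pos_v))
  alt_v <- character(length(pos_v))
  for (ctg in unique(contig_v)) {
    sel <- contig_v == ctg
    chars <- strsplit(genome$seqs[[ctg]], "")[[1]]
    ref_v[sel] <- chars[pos_v[sel]]
  }
  for (i in seq_along(pos_v)) {
    alt_v[i] <- sample(setdiff(nt, ref_v[i]), 1)
  }

  paths <- list(fasta = file.path(out_dir, "reference.fa"),
                gff = file.path(out_dir, "annotation.gff3"),
                vcf = file.path(out_dir, "cohort.vcf"),
                groups = file.path(out_dir, "groups.tsv"),
                truth = file.path(out_dir, "truth.bed"))

  fa <- Biostrings::DNAStringSet(unlist(genome$seqs))
  Biostrings::writeXStringSet(fa, paths$fasta)
  writeLines(genome$gff, paths$gff)

  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan-simulate",
    sprintf("##contig=<ID=%s,length=%d>", names(spec$contigs),
            spec$contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- character(length(pos_v))
  if (length(pos_v)) {
    gt_chr <- matrix("./.", nrow = n_total, ncol = length(pos_v))
    ok <- !is.na(dos_m)
    gt_chr[ok] <- gt_code[dos_m[ok] + 1L]
    body <- vapply(seq_along(pos_v), function(i) {
      paste(c(contig_v[i], pos_v[i], ".", ref_v[i], alt_v[i], ".",
              "PASS", ".", "GT", gt_chr[, i]), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), paths$vcf)

  groups_df <- data.frame(sample_id = sample_ids, subgroup = sample_sg,
                          role = sg$role[match(sample_sg, sg$name)])
  utils::write.table(groups_df, paths$groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- character()
  if (nrow(spec$sweep_plan)) {
    for (i in seq_len(nrow(spec$sweep_plan))) {
      p <- spec$sweep_plan[i, ]
      start <- (p$window - 1L) * spec$window_size
      end <- min(p$window * spec$window_size, spec$contigs[[p$contig]])
      truth[i] <- paste(p$contig, start, end,
                        paste0(p$mode, ";subgroups=", p$subgroups),
                        sep = "\t")
    }
  }
  writeLines(truth, paths$truth)
  paths
}
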