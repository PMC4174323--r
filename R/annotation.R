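#' Load a reference genome and its gene models
#'
#' Reads contig sequences from FASTA and gene/mRNA/exon/CDS/UTR features
#' from GFF3 into the internal annotation model used for site
#' classification and coding-effect calls.  For every gene a
#' representative transcript is fixed up front: the one with the longest
#' exonic length, ties broken by the lexicographically smallest
#' transcript ID.
#'
#' @param fasta_path reference FASTA.
#' @param gff_path GFF3 gene models (types gene, mRNA, exon, CDS,
#'   five_prime_UTR, three_prime_UTR).
#' @return an object of class `genome_annotation`.
#' @export
read_annotation <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = as.character(gff$type),
    id = if (!is.null(gff$ID)) as.character(gff$ID) else NA_character_,
    parent = vapply(
      if (!is.null(gff$Parent)) gff$Parent else replicate(length(gff), character()),
      function(p) if (length(p)) p[[1]] else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  genes <- df[df$type == "gene", c("id", "contig", "start", "end", "strand")]
  names(genes)[1] <- "gene_id"
  tx <- df[df$type == "mRNA", c("id", "parent", "contig", "start", "end", "strand")]
  names(tx)[1:2] <- c("tx_id", "gene_id")
  feats <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"),
              c("parent", "type", "contig", "start", "end", "strand")]
  names(feats)[1] <- "tx_id"

  exlen <- tapply(
    ifelse(feats$type == "exon", feats$end - feats$start + 1L, 0L),
    feats$tx_id, sum)
  tx$exonic_length <- as.integer(exlen[tx$tx_id])
  # representative transcript per gene: longest exonic length, then ID
  tx_o <- tx[order(tx$gene_id, -tx$exonic_length, tx$tx_id), ]
  rep_tx <- tx_o[!duplicated(tx_o$gene_id), c("gene_id", "tx_id")]

  ann <- structure(list(
    seqs = seqs, genes = genes, transcripts = tx, features = feats,
    rep_tx = rep_tx, cache = new.env(parent = emptyenv())
  ), class = "genome_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  cds_len <- tapply(
    ifelse(ann$features$type == "CDS",
           ann$features$end - ann$features$start + 1L, 0L),
    ann$features$tx_id, sum)
  bad <- names(cds_len)[cds_len > 0 & cds_len %% 3 != 0]
  if (length(bad)) {
    stop("CDS length not a multiple of 3 for transcript(s): ",
         paste(bad, collapse = ", "))
  }
  ctg_len <- stats::setNames(Biostrings::width(ann$seqs), names(ann$seqs))
  miss <- setdiff(ann$genes$contig, names(ctg_len))
  if (length(miss)) stop("gene contig(s) absent from FASTA: ",
                         paste(miss, collapse = ", "))
  out <- ann$genes$end > ctg_len[ann$genes$contig]
  if (any(out)) stop("gene(s) extend beyond contig bounds: ",
                     paste(ann$genes$gene_id[out], collapse = ", "))
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$seqs), "contig(s),",
      nrow(x$genes), "gene(s),", nrow(x$transcripts), "transcript(s)\n")
  invisible(x)
}

# CDS segments of one transcript in translation order, plus the spliced
# coding sequence (cached).
cds_model <- function(ann, tx_id) {
  key <- paste0("cds_", tx_id)
  if (!is.null(ann$cache[[key]])) return(ann$cache[[key]])
  seg <- ann$features[ann$features$tx_id == tx_id &
                        ann$features$type == "CDS", , drop = FALSE]
  if (!nrow(seg)) stop("transcript '", tx_id, "' has no CDS")
  strand <- seg$strand[1]
  seg <- seg[order(seg$start, decreasing = (strand == "-")), , drop = FALSE]
  chunks <- lapply(seq_len(nrow(seg)), function(i) {
    s <- Biostrings::subseq(ann$seqs[[seg$contig[i]]], seg$start[i], seg$end[i])
    if (strand == "-") Biostrings::reverseComplement(s) else s
  })
  cds_seq <- do.call(Biostrings::xscat, chunks)
  model <- list(segments = seg, strand = strand,
                seq = as.character(cds_seq))
  ann$cache[[key]] <- model
  model
}

# 1-based coordinate of a genomic position within the spliced CDS of a
# transcript, or NA when the position is not coding in that transcript.
cds_coordinate <- function(model, pos) {
  seg <- model$segments
  off <- 0L
  for (i in seq_len(nrow(seg))) {
    w <- seg$end[i] - seg$start[i] + 1L
    if (pos >= seg$start[i] && pos <= seg$end[i]) {
      within <- if (model$strand == "-") seg$end[i] - pos else pos - seg$start[i]
      return(off + within + 1L)
    }
    off <- off + w
  }
  NA_integer_
}

# class priority used when several transcripts overlap a site
.class_priority <- c(CDS = 1, UTR5 = 2, UTR3 = 3, intronic = 4, intergenic = 5)

# Classify one position against one transcript.
classify_in_tx <- function(ann, tx_id, pos) {
  f <- ann$features[ann$features$tx_id == tx_id, , drop = FALSE]
  inside <- function(type) {
    g <- f[f$type == type, , drop = FALSE]
    any(pos >= g$start & pos <= g$end)
  }
  if (inside("CDS")) return("CDS")
  if (inside("five_prime_UTR")) return("UTR5")
  if (inside("three_prime_UTR")) return("UTR3")
  "intronic"
}

#' Classify a SNP position by genomic context
#'
#' Assigns exactly one of `intergenic`, `UTR5`, `UTR3`, `intronic`,
#' `CDS`.  Each overlapping gene contributes its representative (longest)
#' transcript; when several genes overlap, the highest-priority class
#' wins (`CDS > UTR5 > UTR3 > intronic`).  Positions outside every gene
#' span are intergenic.
#'
#' @param ann a [read_annotation()] result.
#' @param contig,pos position (1-based) to classify; vectors accepted.
#' @return character vector of classes.
#' @export
classify_site <- function(ann, contig, pos) {
  stopifnot(inherits(ann, "genome_annotation"))
  unknown <- setdiff(unique(contig), names(ann$seqs))
  if (length(unknown)) {
    stop("contig(s) absent from annotation: ", paste(unknown, collapse = ", "))
  }
  vapply(seq_along(pos), function(i) {
    g <- ann$genes[ann$genes$contig == contig[i] &
                     ann$genes$start <= pos[i] &
                     ann$genes$end >= pos[i], , drop = FALSE]
    if (!nrow(g)) return("intergenic")
    txs <- ann$rep_tx$tx_id[match(g$gene_id, ann$rep_tx$gene_id)]
    classes <- vapply(txs, classify_in_tx, character(1),
                      ann = ann, pos = pos[i])
    classes[which.min(.class_priority[classes])]
  }, character(1))
}

#' Coding effect of a SNP (synonymous vs nonsynonymous)
#'
#' Substitutes the alternate allele into the strand-corrected codon of
#' the representative transcript covering the position and translates
#' both codons with the standard genetic code.  For minus-strand CDS the
#' genome-forward alleles are complemented.
#'
#' @inheritParams classify_site
#' @param ref,alt genome-forward reference and alternate alleles (single
#'   nucleotides).
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_cds_effect <- function(ann, contig, pos, ref, alt) {
  stopifnot(inherits(ann, "genome_annotation"), length(pos) == 1L)
  genome_base <- as.character(Biostrings::subseq(ann$seqs[[contig]], pos, pos))
  if (genome_base != ref) {
    stop("reference allele mismatch at ", contig, ":", pos,
         " (FASTA has ", genome_base, ", variant says ", ref, ")")
  }
  g <- ann$genes[ann$genes$contig == contig & ann$genes$start <= pos &
                   ann$genes$end >= pos, , drop = FALSE]
  txs <- ann$rep_tx$tx_id[match(g$gene_id, ann$rep_tx$gene_id)]
  hit <- NULL
  for (tx in txs) {
    m <- cds_model(ann, tx)
    cpos <- cds_coordinate(m, pos)
    if (!is.na(cpos)) { hit <- list(model = m, cpos = cpos); break }
  }
  if (is.null(hit)) stop("position ", contig, ":", pos, " is not coding")
  m <- hit$model
  cpos <- hit$cpos
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  coding_ref <- if (m$strand == "-") comp[[ref]] else ref
  coding_alt <- if (m$strand == "-") comp[[alt]] else alt
  codon_i <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L
  codon <- substr(m$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (substr(codon, within + 1L, within + 1L) != coding_ref) {
    stop("internal codon/reference inconsistency at ", contig, ":", pos)
  }
  mutant <- codon
  substr(mutant, within + 1L, within + 1L) <- coding_alt
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[mutant]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Nonsynonymous/synonymous count ratio
#'
#' @param nonsyn,syn SNP counts.
#' @param digits decimals to round to (default 2, the reporting
#'   convention).
#' @return the rounded ratio, `NA` when `syn` is zero.
#' @export
nonsyn_syn_ratio <- function(nonsyn, syn, digits = 2) {
  ifelse(syn > 0, round(nonsyn / syn, digits), NA_real_)
}

#' Summarize SNPs by group and genomic class
#'
#' Builds the per-group accounting of total SNPs and their split into
#' intergenic, UTR, intronic and CDS classes, with the CDS SNPs further
#' divided into nonsynonymous and synonymous and their ratio.  A site
#' counts for a group when at least one member carries a called
#' non-reference allele.
#'
#' @param gm a [genotype_matrix].
#' @param groups a [sample_groups] table.
#' @param ann a [read_annotation()] result.
#' @param report_groups group labels to tabulate (resolved by
#'   [group_members()]); default the three roles plus `"all"`.
#' @return a `variant_summary` data.frame, one row per group, columns
#'   `group`, `n_samples`, `total`, `intergenic`, `utr3`, `utr5`,
#'   `intronic`, `cds`, `nonsyn`, `syn`, `ratio`.
#' @export
summarize_variants <- function(gm, groups, ann,
                               report_groups = c("wild", "ornamental",
                                                 "edible", "all")) {
  codes <- genotype_codes(gm)
  sites <- variant_sites(gm)
  groups <- as_sample_groups(groups)
  classes <- classify_site(ann, sites$contig, sites$pos)
  effect <- rep(NA_character_, nrow(sites))
  is_cds <- classes == "CDS"
  for (i in which(is_cds)) {
    effect[i] <- classify_cds_effect(ann, sites$contig[i], sites$pos[i],
                                     sites$ref[i], sites$alt[i])
  }
  rows <- lapply(report_groups, function(grp) {
    members <- group_members(groups, grp)
    sub <- codes[members, , drop = FALSE]
    present <- colSums(sub > 0, na.rm = TRUE) > 0
    cnt <- function(cl) sum(present & classes == cl)
    ns <- sum(present & !is.na(effect) & effect == "nonsynonymous")
    sy <- sum(present & !is.na(effect) & effect == "synonymous")
    data.frame(group = grp, n_samples = length(members),
               total = sum(present),
               intergenic = cnt("intergenic"), utr3 = cnt("UTR3"),
               utr5 = cnt("UTR5"), intronic = cnt("intronic"),
               cds = cnt("CDS"), nonsyn = ns, syn = sy,
               ratio = nonsyn_syn_ratio(ns, sy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_summary", "data.frame")
  out
}
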