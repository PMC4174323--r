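write_mini_vcf <- function(records, samples = c("s1", "s2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

write_mini_groups <- function(samples, subgroup = "A", role = "wild") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubgroup\trole",
               paste(samples, subgroup, role, sep = "\t")), path)
  path
}

test_that("read_cohort keeps only biallelic SNPs and recodes GT", {
  vcf <- write_mini_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/0\t0/0",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",   # deletion
    "chr1\t300\t.\tC\tG,T\t.\tPASS\t.\tGT\t1/2\t0/0",  # triallelic
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t1/1"))
  groups <- write_mini_groups(c("s1", "s2"))
  suppressMessages(cohort <- read_cohort(vcf, groups))
  codes <- genotype_codes(cohort$matrix)
  expect_equal(ncol(codes), 2)                      # SNPs at 100 and 400
  expect_equal(unname(codes["s1", 1]), 1L)          # unphased 1/0 -> 1
  expect_equal(unname(codes["s2", 1]), 0L)
  expect_true(is.na(codes["s1", 2]))
  expect_equal(unname(codes["s2", 2]), 2L)
})

test_that("read_cohort names a sample missing from the groups table", {
  vcf <- write_mini_vcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0")
  groups <- write_mini_groups("s1")
  expect_error(read_cohort(vcf, groups), "s2")
})

test_that("matrix dimensions match the emitted cohort", {
  sc <- shared_cohort()
  n_records <- sum(!startsWith(readLines(sc$paths$vcf), "#"))
  expect_equal(dim(genotype_codes(sc$matrix)),
               c(sum(default_subgroups()$n_accessions), n_records))
})

test_that("population filters act on call rate and MAF", {
  codes <- rbind(
    s01 = c(0L, NA, 0L),
    s02 = c(0L, NA, 0L),
    s03 = c(0L, NA, 0L),
    s04 = c(0L, NA, 0L),
    s05 = c(0L, NA, 0L),
    s06 = c(0L, NA, 1L),
    s07 = c(0L, NA, 0L),
    s08 = c(0L, NA, 0L),
    s09 = c(0L, NA, 0L),
    s10 = c(1L, NA, 0L))
  sites <- data.frame(contig = "c", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "G")
  gm <- genotype_matrix(codes, sites)
  # no thresholds: identity
  expect_equal(variant_sites(filter_population_snps(gm, 0, 0))$pos,
               sites$pos)
  # all-missing site dropped at call rate 0.5
  expect_equal(variant_sites(filter_population_snps(gm, 0.5, 0))$pos,
               c(10L, 30L))
  # MAF 1/20 = 0.05 < 0.1: both polymorphic sites dropped
  out <- filter_population_snps(gm, 0, maf_min = 0.1)
  expect_equal(ncol(genotype_codes(out)), 0)
})

test_that("window tiling keeps flagged partial windows", {
  w <- iter_windows(c(chrA = 30000L), 10000)
  expect_equal(nrow(w), 3)
  expect_equal(w$length, rep(10000L, 3))
  w2 <- iter_windows(c(chrA = 25000L), 10000, 5000)
  expect_equal(w2$start, c(0L, 5000L, 10000L, 15000L, 20000L))
  expect_equal(w2$end, c(10000L, 15000L, 20000L, 25000L, 25000L))
  expect_equal(w2$length[4:5], c(10000L, 5000L))
  expect_equal(nrow(iter_windows(integer(0), 1000)), 0)
})

test_that("site classes follow the CDS > UTR5 > UTR3 > intronic priority", {
  ann <- toy_annotation()
  expect_equal(classify_site(ann, "tig", 5), "intergenic")
  expect_equal(classify_site(ann, "tig", 15), "UTR5")
  expect_equal(classify_site(ann, "tig", 25), "CDS")
  expect_equal(classify_site(ann, "tig", 45), "intronic")
  expect_equal(classify_site(ann, "tig", 75), "UTR3")
  # minus-strand gene: transcript orientation is reversed in the genome
  expect_equal(classify_site(ann, "tig", 105), "UTR3")
  expect_equal(classify_site(ann, "tig", 150), "CDS")
  expect_equal(classify_site(ann, "tig", 130), "intronic")
  expect_equal(classify_site(ann, "tig", 170), "UTR5")
  expect_equal(classify_site(ann, "tig", 250), "intergenic")
  expect_error(classify_site(ann, "nope", 10), "absent")
})

test_that("codon substitution effects are strand-corrected", {
  ann <- toy_annotation()
  # plus strand, codon 2 is GCT (Ala) at genomic 24-26
  expect_equal(classify_cds_effect(ann, "tig", 26, "T", "C"), "synonymous")
  expect_equal(classify_cds_effect(ann, "tig", 25, "C", "A"),
               "nonsynonymous")
  # minus strand: coding GCT wobble T sits at genomic 155 as A;
  # genome-forward A->G is coding T->C (GCC, still Ala)
  expect_equal(classify_cds_effect(ann, "tig", 155, "A", "G"), "synonymous")
  # reference mismatch is a data inconsistency
  expect_error(classify_cds_effect(ann, "tig", 26, "G", "C"), "mismatch")
})

test_that("effects agree with the whole-protein translation oracle", {
  f <- toy_genome_files()
  ann <- toy_annotation()
  cases <- expand.grid(pos = c(21:40, 61:70, 111:120, 141:160),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  checked <- 0L
  for (i in seq_len(nrow(cases))) {
    pos <- cases$pos[i]
    alt <- cases$alt[i]
    ref <- as.character(Biostrings::subseq(ann$seqs[["tig"]], pos, pos))
    if (ref == alt) next
    tx <- if (pos <= 80) "gene_p.t1" else "gene_m.t1"
    expect_equal(classify_cds_effect(ann, "tig", pos, ref, alt),
                 oracle_cds_effect(f$fasta, f$gff, tx, "tig", pos, alt),
                 label = paste0("tig:", pos, ref, ">", alt))
    checked <- checked + 1L
  }
  expect_gte(checked, 150L)
})

test_that("variant summary satisfies the class partition identity", {
  sc <- shared_cohort()
  s <- summarize_variants(sc$matrix, sc$groups, sc$ann)
  expect_equal(s$intergenic + s$utr3 + s$utr5 + s$intronic + s$cds,
               s$total)
  expect_equal(s$nonsyn + s$syn, s$cds)
  all_row <- s[s$group == "all", ]
  for (g in c("wild", "ornamental", "edible")) {
    expect_lte(s$total[s$group == g], all_row$total)
  }
  # exclusive + shared partition of the cohort total
  codes <- genotype_codes(sc$matrix)
  present <- sapply(c("wild", "ornamental", "edible"), function(g) {
    sub <- codes[group_members(sc$groups, g), , drop = FALSE]
    colSums(sub > 0, na.rm = TRUE) > 0
  })
  n_groups <- rowSums(present)
  expect_equal(sum(n_groups >= 1), all_row$total)
  shares <- group_shares(c(exclusive = sum(n_groups == 1),
                           shared = sum(n_groups > 1)),
                         total = all_row$total)
  expect_equal(sum(shares), 100, tolerance = 0.02)
})

test_that("a group with no alternate alleles reports NA ratio", {
  codes <- rbind(w1 = c(1L, 2L), w2 = c(0L, 1L),
                 a1 = c(0L, 0L), a2 = c(0L, 0L))
  sites <- data.frame(contig = "tig", pos = c(25L, 26L),
                      ref = c("C", "T"), alt = c("A", "C"))
  gm <- genotype_matrix(codes, sites)
  groups <- sample_groups(data.frame(
    sample_id = c("w1", "w2", "a1", "a2"),
    subgroup = c("W", "W", "A", "A"),
    role = c("wild", "wild", "ornamental", "ornamental")))
  s <- summarize_variants(gm, groups, toy_annotation(),
                          report_groups = c("wild", "ornamental"))
  orn <- s[s$group == "ornamental", ]
  expect_equal(orn$total, 0)
  expect_true(is.na(orn$ratio))
})
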