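# A 300 bp toy contig with two genes of known structure, one per
# strand, sharing the coding sequence
#   ATG GCT GAT AAA CCC GGG TTT CAC GTC TAA
# gene_p (+): UTR5 11-20, CDS 21-40 + 61-70 (intron 41-60), UTR3 71-80
# gene_m (-): genomic ascending layout UTR3 101-110, CDS 111-120,
#             intron 121-140, CDS 141-160, UTR5 161-180
# Every coordinate is 1-based inclusive, as in GFF3.

toy_cds <- "ATGGCTGATAAACCCGGGTTTCACGTCTAA"

toy_genome_files <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    chars <- rep("A", 300)
    put <- function(chars, at, s) {
      chars[at] <- strsplit(s, "")[[1]]
      chars
    }
    chars <- put(chars, 21:40, substr(toy_cds, 1, 20))
    chars <- put(chars, 61:70, substr(toy_cds, 21, 30))
    chars <- put(chars, 141:160, rc(substr(toy_cds, 1, 20)))
    chars <- put(chars, 111:120, rc(substr(toy_cds, 21, 30)))

    dir <- tempfile("toygenome")
    dir.create(dir)
    fasta <- file.path(dir, "toy.fa")
    writeLines(c(">tig", paste(chars, collapse = "")), fasta)
    g <- function(type, s, e, strand, phase, attrs) {
      paste("tig", "test", type, s, e, ".", strand, phase, attrs,
            sep = "\t")
    }
    gff <- file.path(dir, "toy.gff3")
    writeLines(c(
      "##gff-version 3",
      g("gene", 11, 80, "+", ".", "ID=gene_p"),
      g("mRNA", 11, 80, "+", ".", "ID=gene_p.t1;Parent=gene_p"),
      g("exon", 11, 40, "+", ".", "Parent=gene_p.t1"),
      g("exon", 61, 80, "+", ".", "Parent=gene_p.t1"),
      g("five_prime_UTR", 11, 20, "+", ".", "Parent=gene_p.t1"),
      g("CDS", 21, 40, "+", "0", "Parent=gene_p.t1"),
      g("CDS", 61, 70, "+", "1", "Parent=gene_p.t1"),
      g("three_prime_UTR", 71, 80, "+", ".", "Parent=gene_p.t1"),
      g("gene", 101, 180, "-", ".", "ID=gene_m"),
      g("mRNA", 101, 180, "-", ".", "ID=gene_m.t1;Parent=gene_m"),
      g("exon", 101, 120, "-", ".", "Parent=gene_m.t1"),
      g("exon", 141, 180, "-", ".", "Parent=gene_m.t1"),
      g("three_prime_UTR", 101, 110, "-", ".", "Parent=gene_m.t1"),
      g("CDS", 111, 120, "-", "1", "Parent=gene_m.t1"),
      g("CDS", 141, 160, "-", "0", "Parent=gene_m.t1"),
      g("five_prime_UTR", 161, 180, "-", ".", "Parent=gene_m.t1")
    ), gff)
    cache <<- list(fasta = fasta, gff = gff)
    cache
  }
})

toy_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- toy_genome_files()
      cache <<- read_annotation(f$fasta, f$gff)
    }
    cache
  }
})

# A small simulated cohort shared across tests (files + loaded objects).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    plan <- data.frame(contig = c("chr1", "chr2"),
                       window = c(3L, 4L),
                       subgroups = c("C,D,E,F", "A"),
                       mode = "low_freq_excess",
                       reduction = 0.3,
                       stringsAsFactors = FALSE)
    spec <- cohort_spec(contigs = c(chr1 = 60000L, chr2 = 60000L),
                        sweep_plan = plan, seed = 20260901L)
    dir <- tempfile("cohort")
    paths <- simulate_cohort(spec, dir)
    cohort <- read_cohort(paths$vcf, paths$groups)
    ann <- read_annotation(paths$fasta, paths$gff)
    cache <<- list(spec = spec, paths = paths, matrix = cohort$matrix,
                   groups = cohort$groups, ann = ann)
    cache
  }
})
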