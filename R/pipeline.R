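#' Pipeline configuration
#'
#' Validates and normalizes the full set of analysis options.  Accepts a
#' YAML file path or a named list; flags given directly override file
#' values.
#'
#' @param config path to a YAML file, or a named list.
#' @param ... individual overrides (same names as the list fields).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    vcf = NULL, groups = NULL, fasta = NULL, gff = NULL, truth_bed = NULL,
    out_dir = NULL,
    window_size = 10000L, step = NULL,
    min_called_fraction = 0.5, maf_min = 0,
    level = 0.95, ci_sample_size = "accessions", s_min = 3L,
    edible_subgroups = c("C", "D", "E", "F"),
    ornamental_subgroups = "A",
    ignore_subgroups = "B",
    ld_max_dist = 1e6, ld_bin_width = 1000, ld_maf_min = 0.1,
    seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, list(...))
  for (field in c("vcf", "groups", "out_dir")) {
    if (is.null(cfg[[field]])) stop("config field '", field, "' is required")
  }
  for (field in c("vcf", "groups")) {
    if (!file.exists(cfg[[field]])) {
      stop("config: ", field, " path does not exist: ", cfg[[field]])
    }
  }
  if (is.null(cfg$step)) cfg$step <- cfg$window_size
  if (!cfg$ci_sample_size %in% c("accessions", "haplotypes")) {
    stop("ci_sample_size must be 'accessions' or 'haplotypes'")
  }
  stopifnot(cfg$window_size > 0, cfg$step > 0, cfg$step <= cfg$window_size,
            cfg$level > 0, cfg$level < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Interval-overlap recovery of injected sweeps: a truth interval is
# recalled when any labeled region overlaps it; a labeled region is a
# true positive when it overlaps any truth interval.
sweep_recovery <- function(regions, truth) {
  overlap <- function(a_s, a_e, b_s, b_e) a_s < b_e & b_s < a_e
  if (!nrow(truth)) {
    return(list(recall = NA_real_, precision = NA_real_))
  }
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    any(regions$contig == truth$contig[i] &
          overlap(regions$start, regions$end, truth$start[i], truth$end[i]))
  }, logical(1))
  tp <- vapply(seq_len(nrow(regions)), function(i) {
    any(truth$contig == regions$contig[i] &
          overlap(truth$start, truth$end, regions$start[i], regions$end[i]))
  }, logical(1))
  list(recall = mean(recalled),
       precision = if (nrow(regions)) mean(tp) else NA_real_)
}

read_truth_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character()))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("contig", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name" else bed$name <- "."
  bed
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on a cohort: load and filter genotypes,
#' Table-1-style variant summary, windowed diversity statistics,
#' neutral ranges per subgroup, per-subgroup candidate scan, subgroup
#' set-logic combination into labeled regions, windowed ROD/Fst
#' divergence, region annotation with genes, LD decay per role, and
#' per-accession heterozygosity.  All intermediate tables are written
#' as TSV (regions also as BED), a MANIFEST lists completed stages, and
#' a structured log records every filter count.  Identical inputs and
#' config give byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return invisibly, a list with every stage result and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  done <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))
  }
  on.exit({
    writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
  }, add = TRUE)

  cfg_out <- unclass(cfg)
  cfg_out <- cfg_out[!vapply(cfg_out, is.null, logical(1))]
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config.yaml"))
  set.seed(cfg$seed)

  stage <- "load"
  res <- withCallingHandlers(
    tryCatch({
      cohort <- read_cohort(cfg$vcf, cfg$groups)
      note("load: ", ncol(genotype_codes(cohort$matrix)), " SNPs, ",
           nrow(genotype_codes(cohort$matrix)), " samples")
      done("load")

      stage <- "filter"
      gm <- filter_population_snps(cohort$matrix,
                                   cfg$min_called_fraction, cfg$maf_min)
      note("filter: retained ", ncol(genotype_codes(gm)), " of ",
           ncol(genotype_codes(cohort$matrix)),
           " sites (call rate >= ", cfg$min_called_fraction,
           ", MAF >= ", cfg$maf_min, ")")
      done("filter")
      groups <- cohort$groups

      ann <- NULL
      summary_tab <- NULL
      if (!is.null(cfg$fasta) && !is.null(cfg$gff)) {
        stage <- "summarize"
        ann <- read_annotation(cfg$fasta, cfg$gff)
        summary_tab <- summarize_variants(gm, groups, ann)
        write_tsv(summary_tab, file.path(cfg$out_dir, "variant_summary.tsv"))
        note("summarize: ", nrow(summary_tab), " group rows")
        done("summarize")
        contig_lengths <- stats::setNames(Biostrings::width(ann$seqs),
                                          names(ann$seqs))
      } else {
        sites <- variant_sites(gm)
        contig_lengths <- tapply(sites$pos, sites$contig, max)
        contig_lengths <- stats::setNames(as.integer(contig_lengths),
                                          names(contig_lengths))
      }

      stage <- "stats"
      windows <- iter_windows(contig_lengths, cfg$window_size, cfg$step)
      stats_tab <- window_stats(gm, groups, windows, s_min = cfg$s_min)
      write_tsv(stats_tab, file.path(cfg$out_dir, "window_stats.tsv"))
      note("stats: ", nrow(windows), " windows x ",
           length(unique(stats_tab$subgroup)), " subgroups")
      done("stats")

      stage <- "neutral-range"
      sg_tab <- unique(data.frame(subgroup = groups$subgroup,
                                  stringsAsFactors = FALSE))
      sg_n <- vapply(sg_tab$subgroup, function(s)
        length(group_members(groups, s)), integer(1))
      ci_n <- if (cfg$ci_sample_size == "accessions") sg_n else 2L * sg_n
      ranges <- lapply(ci_n, d_confidence_limits, level = cfg$level)
      names(ranges) <- sg_tab$subgroup
      range_tab <- cbind(subgroup = sg_tab$subgroup,
                         neutral_range_table(ci_n, cfg$level))
      write_tsv(range_tab, file.path(cfg$out_dir, "neutral_ranges.tsv"))
      done("neutral-range")

      stage <- "scan"
      candidates <- list()
      for (s in sg_tab$subgroup) {
        cand <- scan_subgroup(stats_tab[stats_tab$subgroup == s, ],
                              ranges[[s]])
        candidates[[s]] <- cand
        note("scan: subgroup ", s, ": ", nrow(cand), " candidate windows")
      }
      cand_all <- do.call(rbind, candidates)
      write_tsv(cand_all, file.path(cfg$out_dir, "candidate_windows.tsv"))
      regions <- combine_subgroups(candidates, windows,
                                   cfg$edible_subgroups,
                                   cfg$ornamental_subgroups,
                                   cfg$ignore_subgroups)
      note("scan: ", sum(regions$label == "edible_selected"),
           " edible-selected and ",
           sum(regions$label == "ornamental_selected"),
           " ornamental-selected regions")
      done("scan")

      stage <- "divergence"
      divergence <- divergence_stats(gm, groups, windows)
      write_tsv(divergence, file.path(cfg$out_dir, "divergence.tsv"))
      regions <- annotate_regions(regions, divergence, ann)
      write_tsv(regions, file.path(cfg$out_dir, "selection_regions.tsv"))
      bed <- regions[, c("contig", "start", "end", "label")]
      utils::write.table(bed, file.path(cfg$out_dir, "selection_regions.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      done("divergence")

      stage <- "ld"
      ld <- list()
      for (role in unique(groups$role)) {
        members <- group_members(groups, role)
        curve <- ld_decay(gm, members, cfg$ld_max_dist, cfg$ld_bin_width,
                          cfg$ld_maf_min)
        ld[[role]] <- curve
        write_tsv(curve$bins,
                  file.path(cfg$out_dir, paste0("ld_decay_", role, ".tsv")))
        note("ld: ", role, " half-decay = ",
             if (is.na(curve$half_decay_distance)) "undefined"
             else round(curve$half_decay_distance))
      }
      done("ld")

      stage <- "het-profile"
      het <- het_profile(gm, groups)
      write_tsv(het$samples, file.path(cfg$out_dir, "het_profile.tsv"))
      write_tsv(het$roles, file.path(cfg$out_dir, "het_roles.tsv"))
      done("het-profile")

      recovery <- NULL
      if (!is.null(cfg$truth_bed)) {
        stage <- "truth-eval"
        truth <- read_truth_bed(cfg$truth_bed)
        recovery <- sweep_recovery(regions, truth)
        write_tsv(data.frame(metric = c("recall", "precision"),
                             value = c(recovery$recall,
                                       recovery$precision)),
                  file.path(cfg$out_dir, "sweep_recovery.tsv"))
        done("truth-eval")
      }

      done("report")
      list(config = cfg, matrix = gm, groups = groups,
           summary = summary_tab, windows = windows, stats = stats_tab,
           ranges = ranges, candidates = candidates, regions = regions,
           divergence = divergence, ld = ld, het = het,
           recovery = recovery,
           out_dir = cfg$out_dir)
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }),
    message = function(m) {
      note(sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  invisible(res)
}
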