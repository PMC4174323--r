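#' Selection intensity of a window's Tajima's D
#'
#' Percent distance of D from the midpoint of the neutral range,
#' normalized so that each confidence limit sits at exactly 100%.  The
#' normalization is asymmetric (different scale above and below the
#' midpoint), which is the only reading under which "intensity > 100%"
#' coincides with D falling outside the range.
#'
#' @param d Tajima's D value(s); `NA` propagates.
#' @param range a [d_confidence_limits()] result.
#' @return data.frame with columns `percent` and `direction`
#'   (`"high"`/`"low"`).
#' @examples
#' r <- d_confidence_limits(8)
#' intensity(r$upper, r)  # 100%
#' @export
intensity <- function(d, range) {
  stopifnot(inherits(range, "neutral_range"))
  m <- (range$lower + range$upper) / 2
  high <- !is.na(d) & d >= m
  pct <- rep(NA_real_, length(d))
  pct[high] <- 100 * (d[high] - m) / (range$upper - m)
  low <- !is.na(d) & d < m
  pct[low] <- 100 * (m - d[low]) / (m - range$lower)
  data.frame(percent = pct,
             direction = ifelse(is.na(d), NA_character_,
                                ifelse(high, "high", "low")),
             stringsAsFactors = FALSE)
}

#' Candidate selected windows of one subgroup
#'
#' Flags exactly the windows whose intensity strictly exceeds 100%, i.e.
#' whose D lies outside the subgroup's neutral mutation range.  Windows
#' with undefined D are never candidates.
#'
#' @param stats a [window_stats()] table restricted to one subgroup.
#' @param range the subgroup's [d_confidence_limits()].
#' @return the candidate rows of `stats` with `percent` and `direction`
#'   columns appended.
#' @export
scan_subgroup <- function(stats, range) {
  if (nrow(stats) == 0L) {
    out <- cbind(stats, percent = numeric(0), direction = character(0))
    return(out)
  }
  if (length(unique(stats$subgroup)) > 1L) {
    stop("`stats` must contain a single subgroup")
  }
  it <- intensity(stats$D, range)
  out <- cbind(stats, it)
  out <- out[!is.na(out$percent) & out$percent > 100, , drop = FALSE]
  rownames(out) <- NULL
  out
}

window_key <- function(df) paste0(df$contig, ":", df$start, "-", df$end)

# Merge window keys (shared grid) into maximal contiguous intervals.
merge_windows <- function(windows, keys) {
  sel <- windows[window_key(windows) %in% keys, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), n_windows = integer()))
  }
  sel <- sel[order(sel$contig, sel$start), , drop = FALSE]
  new_run <- c(TRUE, sel$contig[-1] != sel$contig[-nrow(sel)] |
                 sel$start[-1] != sel$end[-nrow(sel)])
  run <- cumsum(new_run)
  data.frame(
    contig = tapply(sel$contig, run, `[`, 1),
    start = as.integer(tapply(sel$start, run, min)),
    end = as.integer(tapply(sel$end, run, max)),
    n_windows = as.integer(tapply(sel$start, run, length)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine per-subgroup candidate windows into labeled selection regions
#'
#' Set logic separating the two selection regimes on a shared window
#' grid: a window is *edible-selected* when it is a candidate in every
#' edible rule subgroup but not in the ornamental subgroup(s), and
#' *ornamental-selected* when it is a candidate in the ornamental
#' subgroup(s) but in none of the edible rule subgroups.  Subgroups in
#' `ignore_subgroups` take no part.  Labeled windows are then merged
#' into maximal contiguous regions.
#'
#' @param candidates named list: subgroup label -> candidate window
#'   data.frame (as from [scan_subgroup()]).
#' @param windows the shared window grid ([iter_windows()]).
#' @param edible_subgroups,ornamental_subgroups subgroup labels entering
#'   each rule.
#' @param ignore_subgroups subgroups excluded from both rules.
#' @return a `selection_regions` data.frame: `label`, `contig`, `start`,
#'   `end`, `n_windows`.
#' @export
combine_subgroups <- function(candidates, windows,
                              edible_subgroups = c("C", "D", "E", "F"),
                              ornamental_subgroups = "A",
                              ignore_subgroups = "B") {
  required <- setdiff(c(edible_subgroups, ornamental_subgroups),
                      ignore_subgroups)
  miss <- setdiff(required, names(candidates))
  if (length(miss)) {
    stop("candidate sets missing for subgroup(s): ",
         paste(miss, collapse = ", "))
  }
  edible_subgroups <- setdiff(edible_subgroups, ignore_subgroups)
  ornamental_subgroups <- setdiff(ornamental_subgroups, ignore_subgroups)
  keys <- lapply(candidates, window_key)
  inter <- function(sgs) {
    if (!length(sgs)) return(character())
    Reduce(intersect, keys[sgs])
  }
  uni <- function(sgs) {
    if (!length(sgs)) return(character())
    Reduce(union, keys[sgs])
  }
  edible_keys <- setdiff(inter(edible_subgroups), uni(ornamental_subgroups))
  orn_keys <- setdiff(inter(ornamental_subgroups), uni(edible_subgroups))
  stopifnot(length(intersect(edible_keys, orn_keys)) == 0L)
  ed <- merge_windows(windows, edible_keys)
  orn <- merge_windows(windows, orn_keys)
  out <- rbind(
    if (nrow(ed)) cbind(label = "edible_selected", ed),
    if (nrow(orn)) cbind(label = "ornamental_selected", orn))
  if (is.null(out)) {
    out <- data.frame(label = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_windows = integer())
  }
  rownames(out) <- NULL
  class(out) <- c("selection_regions", "data.frame")
  out
}

#' Genes overlapping selection regions
#'
#' A gene is listed for a region when its genomic span overlaps the
#' region by at least one bp; lists are deduplicated and sorted.
#'
#' @param regions a data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param ann a [read_annotation()] result.
#' @return list (one character vector of gene ids per region row).
#' @export
map_genes <- function(regions, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  lapply(seq_len(nrow(regions)), function(i) {
    g <- ann$genes
    hit <- g$contig == regions$contig[i] &
      g$start <= regions$end[i] &        # 1-based gene vs half-open region
      g$end >= regions$start[i] + 1L
    sort(unique(g$gene_id[hit]))
  })
}

#' Attach divergence means and gene lists to selection regions
#'
#' @param regions a [combine_subgroups()] result.
#' @param divergence a [divergence_stats()] window table.
#' @param ann optional [read_annotation()] result for gene mapping.
#' @return `regions` with `mean_rod`, `mean_fst`, `n_genes` and a
#'   `genes` column (comma-separated ids) appended.
#' @export
annotate_regions <- function(regions, divergence, ann = NULL) {
  if (!nrow(regions)) {
    regions$mean_rod <- numeric(0)
    regions$mean_fst <- numeric(0)
    regions$n_genes <- integer(0)
    regions$genes <- character(0)
    return(regions)
  }
  mr <- mf <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    inside <- divergence$contig == regions$contig[i] &
      divergence$start >= regions$start[i] &
      divergence$end <= regions$end[i]
    if (any(inside)) {
      mr[i] <- mean(divergence$rod[inside], na.rm = TRUE)
      mf[i] <- mean(divergence$fst[inside], na.rm = TRUE)
    }
  }
  regions$mean_rod <- mr
  regions$mean_fst <- mf
  if (!is.null(ann)) {
    gl <- map_genes(regions, ann)
    regions$n_genes <- vapply(gl, length, integer(1))
    regions$genes <- vapply(gl, paste, character(1), collapse = ",")
  } else {
    regions$n_genes <- NA_integer_
    regions$genes <- NA_character_
  }
  regions
}
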