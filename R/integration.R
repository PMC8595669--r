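# H3K9me3 ChIP/Input marking of compartments and TADs, group intensity
# comparisons, and expression summaries over structure groups.

#' Bin a ChIP/Input signal track
#'
#' Length-weighted mean ratio per fixed-width bin. Intervals must be sorted
#' and non-overlapping (bedGraph convention); bins with no covered base are
#' `NA`.
#'
#' @param track data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `ratio` (>= 0).
#' @param resolution bin width in bp.
#' @param n_bins number of bins; inferred from the last interval end when
#'   omitted.
#' @return numeric vector of per-bin mean ratios.
#' @export
bin_signal <- function(track, resolution, n_bins = NULL) {
  if (nrow(track) == 0L) stop("empty track")
  if (is.unsorted(track$start))
    stop("unsorted signal track")
  if (any(utils::head(track$end, -1) > utils::tail(track$start, -1)))
    stop("overlapping signal intervals")
  if (any(track$ratio < 0)) stop("negative ratio")
  if (is.null(n_bins)) n_bins <- ceiling(max(track$end) / resolution)
  wsum <- cov <- numeric(n_bins)
  for (k in seq_len(nrow(track))) {
    s <- track$start[k]; e <- track$end[k]; v <- track$ratio[k]
    b0 <- floor(s / resolution); b1 <- ceiling(e / resolution) - 1L
    for (b in b0:min(b1, n_bins - 1L)) {
      lo <- max(s, b * resolution); hi <- min(e, (b + 1L) * resolution)
      if (hi > lo) {
        wsum[b + 1L] <- wsum[b + 1L] + v * (hi - lo)
        cov[b + 1L] <- cov[b + 1L] + (hi - lo)
      }
    }
  }
  ifelse(cov > 0, wsum / cov, NA_real_)
}

#' Mark regions by ChIP/Input enrichment
#'
#' A region is marked when at least `frac_min` of its defined bins have
#' ratio >= `ratio_min`. Regions with no defined bin are excluded with a
#' warning. Raising either threshold never enlarges the marked set.
#'
#' @param regions data.frame with `start`, `end` (bp, 0-based half-open) and
#'   optionally a `group` column.
#' @param binned per-bin ratio vector from [bin_signal()].
#' @param resolution bin width of `binned`.
#' @param ratio_min per-bin enrichment threshold.
#' @param frac_min minimum fraction of qualifying bins.
#' @return a `MarkedRegionReport`: the regions with `mean_ratio`, `marked`
#'   columns, plus attribute `group_fraction` (marked fraction per group)
#'   when groups are present.
#' @export
mark_regions <- function(regions, binned, resolution, ratio_min = 2,
                         frac_min = 0.5) {
  n <- nrow(regions)
  mean_ratio <- rep(NA_real_, n)
  marked <- rep(NA, n)
  for (k in seq_len(n)) {
    b0 <- floor(regions$start[k] / resolution) + 1L
    b1 <- ceiling(regions$end[k] / resolution)
    v <- binned[b0:min(b1, length(binned))]
    v <- v[!is.na(v)]
    if (!length(v)) next
    mean_ratio[k] <- mean(v)
    marked[k] <- mean(v >= ratio_min) >= frac_min
  }
  if (anyNA(marked))
    warning(sum(is.na(marked)), " region(s) with no defined bins excluded")
  out <- regions
  out$mean_ratio <- mean_ratio
  out$marked <- marked
  if ("group" %in% names(regions)) {
    gf <- tapply(marked, regions$group, function(x) mean(x, na.rm = TRUE))
    attr(out, "group_fraction") <- gf
  }
  class(out) <- c("MarkedRegionReport", "data.frame")
  out
}

#' Pairwise Wilcoxon rank-sum comparison across groups
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups, with
#' significance stars in the bands `***` (p <= 0.0005), `**`
#' (0.0005 < p <= 0.005), `*` (0.005 < p <= 0.05). Pairs with a group
#' smaller than `min_n` get `NA`.
#'
#' @param values_by_group named list of numeric vectors, or a data.frame
#'   with `group` and `value` columns.
#' @param min_n minimum group size per pair.
#' @return data.frame with `group1`, `group2`, `p`, `stars`.
#' @export
group_intensity_compare <- function(values_by_group, min_n = 3L) {
  if (is.data.frame(values_by_group))
    values_by_group <- split(values_by_group$value, values_by_group$group)
  gn <- names(values_by_group)
  if (length(gn) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(gn, 2L)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = NA_real_, stars = "", stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- values_by_group[[pairs[1, k]]]
    y <- values_by_group[[pairs[2, k]]]
    if (length(x) < min_n || length(y) < min_n) next
    out$p[k] <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
    out$stars[k] <- if (is.na(out$p[k])) "" else
      if (out$p[k] <= 0.0005) "***" else
        if (out$p[k] <= 0.005) "**" else
          if (out$p[k] <= 0.05) "*" else "ns"
  }
  out
}

#' Summarise gene expression over labelled structure groups
#'
#' Genes are assigned to regions by TSS position (half-open intervals:
#' a TSS equal to the region end is outside). Returns the per-gene mean
#' FPKM per condition together with its group label, in long format suited
#' for [group_intensity_compare()].
#'
#' @param expr data.frame with `gene`, `chrom`, `tss` (bp) and one FPKM
#'   column per condition (any further columns are treated as conditions).
#' @param regions data.frame with `chrom`, `start`, `end`, `group`.
#' @return data.frame `gene`, `group`, `condition`, `value`; genes outside
#'   all regions are omitted. Groups with no genes are reported in the
#'   `empty_groups` attribute.
#' @export
expression_by_structure <- function(expr, regions) {
  cond_cols <- setdiff(names(expr), c("gene", "chrom", "tss"))
  if (!length(cond_cols)) stop("no condition columns in expression table")
  g <- GenomicRanges::GRanges(expr$chrom,
                              IRanges::IRanges(expr$tss + 1L, expr$tss + 1L))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  hits <- GenomicRanges::findOverlaps(g, r, select = "first")
  keep <- which(!is.na(hits))
  rows <- lapply(keep, function(i) {
    data.frame(gene = expr$gene[i],
               group = regions$group[hits[i]],
               condition = cond_cols,
               value = as.numeric(expr[i, cond_cols]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), group = character(),
               condition = character(), value = numeric())
  empty <- setdiff(unique(regions$group), unique(out$group))
  attr(out, "empty_groups") <- empty
  rownames(out) <- NULL
  out
}

#' Intersect a DEG list with abnormal structures
#'
#' Differentially expressed genes are placed into abnormal regions
#' (labelled by structural layer, e.g. Compartment/TAD/Loop) by TSS.
#' Genes lacking a TSS are skipped with a warning.
#'
#' @param degs data.frame with `gene`, `chrom`, `tss`, and optionally
#'   `padj`, `direction`.
#' @param abnormal data.frame with `chrom`, `start`, `end`, `layer`.
#' @return list with `counts` (per-layer DEG counts) and `genes`
#'   (per-layer gene list as a data.frame).
#' @export
degs_in_abnormal <- function(degs, abnormal) {
  missing_tss <- is.na(degs$tss) | is.na(degs$chrom)
  if (any(missing_tss)) {
    warning(sum(missing_tss), " DEG(s) without TSS skipped")
    degs <- degs[!missing_tss, , drop = FALSE]
  }
  g <- GenomicRanges::GRanges(degs$chrom,
                              IRanges::IRanges(degs$tss + 1L, degs$tss + 1L))
  r <- GenomicRanges::GRanges(abnormal$chrom,
                              IRanges::IRanges(abnormal$start + 1L,
                                               abnormal$end))
  hits <- GenomicRanges::findOverlaps(g, r)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  assigned <- unique(data.frame(gene = degs$gene[qh],
                                layer = abnormal$layer[sh]))
  counts <- table(factor(assigned$layer, levels = unique(abnormal$layer)))
  list(counts = counts, genes = assigned)
}
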