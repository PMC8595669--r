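# ATAC peak-intensity matrix normalisation, K-means clustering into shared /
# donor-specific / ESC-specific classes, differential ESC-specific subsets,
# and genomic-context annotation.

#' Construct a PeakMatrix
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   optionally `summit` (absolute bp).
#' @param intensity numeric matrix, peaks x samples, non-negative.
#' @param samples sample names; default taken from `colnames(intensity)`.
#' @return an object of class `PeakMatrix`.
#' @export
peak_matrix <- function(peaks, intensity, samples = colnames(intensity)) {
  intensity <- as.matrix(intensity)
  if (nrow(peaks) != nrow(intensity)) stop("peak/intensity row mismatch")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.null(samples)) stop("sample names required")
  colnames(intensity) <- samples
  structure(list(peaks = peaks, samples = samples, intensity = intensity,
                 normalized = FALSE, logcpm = NULL, zscore = NULL,
                 size_factors = NULL, cluster = rep(NA_character_,
                                                    nrow(peaks))),
            class = "PeakMatrix")
}

#' @export
print.PeakMatrix <- function(x, ...) {
  cat(sprintf("PeakMatrix: %d peaks x %d samples (%s)%s\n",
              nrow(x$intensity), length(x$samples),
              paste(x$samples, collapse = ", "),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalise a peak-intensity matrix
#'
#' Columns are depth-scaled to counts-per-million within peaks, then
#' `log2(x + 1)` transformed; a per-peak z-score view is stored alongside
#' for clustering. Size factors are retained so the raw matrix can be
#' recovered.
#'
#' @param pm a `PeakMatrix` of raw counts/coverage.
#' @return the `PeakMatrix` with `logcpm`, `zscore` and `size_factors`
#'   filled in and `normalized = TRUE`.
#' @export
normalize_peak_matrix <- function(pm) {
  depth <- colSums(pm$intensity)
  if (any(depth == 0)) stop("all-zero sample column")
  sf <- depth / 1e6
  cpm <- sweep(pm$intensity, 2L, sf, "/")
  logcpm <- log2(cpm + 1)
  mu <- rowMeans(logcpm)
  sdv <- apply(logcpm, 1L, stats::sd)
  # moderated scaling: flooring the row sd at the median row sd stops flat
  # rows (uniformly open peaks) from being blown up into pure noise
  floor_sd <- stats::median(sdv[sdv > 0])
  if (!is.finite(floor_sd) || floor_sd <= 0) floor_sd <- 1
  z <- (logcpm - mu) / pmax(sdv, floor_sd)
  pm$logcpm <- logcpm
  pm$zscore <- z
  pm$size_factors <- sf
  pm$normalized <- TRUE
  pm
}

#' Partition peaks into shared / donor-specific / ESC-specific clusters
#'
#' K-means (k = 3, `n_init` restarts, fixed seed) on the per-peak z-score
#' view, followed by deterministic semantic relabelling from sample-group
#' means: `C1` is the cluster with the highest minimum per-sample mean
#' (open in all cell types), `C2` the one with the largest donor-vs-ESC mean
#' contrast (donor-specific), and `C3` the remainder (ESC-specific).
#'
#' @param pm a normalised `PeakMatrix`.
#' @param k number of clusters (the semantic relabelling assumes 3).
#' @param seed RNG seed for reproducibility.
#' @param n_init number of random restarts.
#' @param donor name of the donor sample (default `"CC"` or first sample).
#' @return the `PeakMatrix` with `cluster` set to C1/C2/C3.
#' @export
kmeans_clusters <- function(pm, k = 3L, seed = 1L, n_init = 10L,
                            donor = NULL) {
  if (!pm$normalized) pm <- normalize_peak_matrix(pm)
  if (k > nrow(pm$zscore)) stop("k exceeds number of peaks")
  if (is.null(donor))
    donor <- if ("CC" %in% pm$samples) "CC" else pm$samples[1]
  Z <- pm$zscore
  if (all(apply(Z, 2L, stats::sd) == 0))
    warning("degenerate intensity matrix: a single effective cluster")
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = n_init, iter.max = 100L)
  # semantic relabelling from group means of the z-scores
  centre_means <- km$centers                       # k x samples
  esc_cols <- setdiff(pm$samples, donor)
  lab <- rep(NA_character_, k)
  c1 <- which.max(apply(centre_means, 1L, min))
  lab[c1] <- "C1"
  rest <- setdiff(seq_len(k), c1)
  contrast <- centre_means[rest, donor] -
    rowMeans(centre_means[rest, esc_cols, drop = FALSE])
  c2 <- rest[which.max(contrast)]
  lab[c2] <- "C2"
  lab[setdiff(rest, c2)] <- "C3"
  pm$cluster <- lab[km$cluster]
  pm
}

#' Identify differential ESC-specific peak subsets
#'
#' Within the ESC-specific cluster (C3), peaks whose mean log2 intensity is
#' significantly higher in the fertilised-ESC samples than the
#' nuclear-transfer samples (Welch t-test on log2 normalised intensities,
#' fold >= `fc`, p < `alpha`) are relabelled `C4`; peaks with the reverse
#' trend become `C5`; the remainder stay `C3`.
#'
#' @param pm a clustered `PeakMatrix` (see [kmeans_clusters()]).
#' @param fc minimum fold change (linear scale).
#' @param alpha significance level.
#' @param nt_samples,f_samples column names of the two nuclear-transfer and
#'   two fertilised-ESC samples.
#' @return the `PeakMatrix` with C4/C5 assigned within the former C3 set.
#' @export
differential_esc_peaks <- function(pm, fc = 2, alpha = 0.05,
                                   nt_samples = c("NT5", "NT6"),
                                   f_samples = c("F35", "F40")) {
  if (!all(c(nt_samples, f_samples) %in% pm$samples))
    stop("sample columns not found")
  if (length(nt_samples) < 2L || length(f_samples) < 2L)
    stop("need at least 2 samples per group")
  if (all(is.na(pm$cluster))) stop("run kmeans_clusters() first")
  idx <- which(pm$cluster == "C3")
  lth <- log2(fc)
  for (i in idx) {
    xf <- pm$logcpm[i, f_samples]
    xn <- pm$logcpm[i, nt_samples]
    lfcv <- mean(xf) - mean(xn)
    pv <- if (stats::sd(xf) < 1e-12 && stats::sd(xn) < 1e-12)
      # degenerate noiseless groups: separated means are unambiguous
      as.numeric(abs(lfcv) < 1e-12)
    else tryCatch(stats::t.test(xf, xn)$p.value, error = function(e) 1)
    if (!is.na(pv) && pv < alpha) {
      if (lfcv >= lth) pm$cluster[i] <- "C4"
      else if (lfcv <= -lth) pm$cluster[i] <- "C5"
    }
  }
  pm
}

#' Annotate peaks by genomic context
#'
#' Classifies each peak by the position of its centre (or summit when
#' available) with precedence promoter > exon > intron > intergenic.
#' Promoters are TSS +/- 1 kb, i.e. the 0-based half-open window
#' `[TSS - 1000, TSS + 1000)`; for minus-strand genes the TSS is the gene
#' end. Introns are gene-body positions not in any exon.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, optional `summit`.
#' @param genes data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`).
#' @param exons data.frame with `chrom`, `start`, `end`.
#' @return factor of categories, one per peak
#'   (promoter/exon/intron/intergenic).
#' @export
annotate_peaks <- function(peaks, genes, exons) {
  need <- function(df, cols, what)
    if (!all(cols %in% names(df))) stop("malformed ", what, " annotation")
  need(genes, c("chrom", "start", "end", "strand"), "gene")
  need(exons, c("chrom", "start", "end"), "exon")
  if (any(genes$end <= genes$start) || any(exons$end <= exons$start))
    stop("malformed annotation: empty intervals")
  centre <- if ("summit" %in% names(peaks)) peaks$summit
  else floor((peaks$start + peaks$end) / 2)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(centre + 1L, centre + 1L))
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(0L, tss - 1000L) + 1L,
                                                  tss + 1000L))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  exon_gr <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start + 1L,
                                                     exons$end))
  in_prom <- IRanges::overlapsAny(pk, prom)
  in_exon <- IRanges::overlapsAny(pk, exon_gr)
  in_gene <- IRanges::overlapsAny(pk, gene_gr)
  cat_ <- rep("intergenic", length(pk))
  cat_[in_gene] <- "intron"
  cat_[in_exon] <- "exon"
  cat_[in_prom] <- "promoter"
  factor(cat_, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Cluster-by-context annotation summary
#'
#' Cross-tabulates peak clusters against genomic-context categories
#' (counts and within-cluster percentages).
#'
#' @param pm an annotated, clustered `PeakMatrix`.
#' @param annotation factor from [annotate_peaks()].
#' @return list with `counts` and `percent` tables.
#' @export
annotation_summary <- function(pm, annotation) {
  tab <- table(cluster = pm$cluster, category = annotation)
  list(counts = tab, percent = 100 * prop.table(tab, margin = 1L))
}
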