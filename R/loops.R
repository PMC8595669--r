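# Focal chromatin-loop calling with local-background Poisson tests,
# aggregate peak analysis (APA), and loop-dynamics classification.

# Neighborhood masks (offsets relative to the candidate pixel) in the style
# of donut-background loop callers: donut annulus, lower-left quadrant,
# horizontal and vertical stripes, each excluding the centre 3x3 block.
loop_neighborhoods <- function(outer_r = 7L, inner_r = 3L) {
  off <- expand.grid(da = -outer_r:outer_r, db = -outer_r:outer_r)
  cheb <- pmax(abs(off$da), abs(off$db))
  centre3 <- cheb <= 1L          # centre 3x3
  ring <- cheb <= outer_r & pmax(abs(off$da), abs(off$db)) > (inner_r - 1L)
  donut <- ring & !centre3
  ll <- off$da >= 1L & off$da <= outer_r & off$db <= -1L & off$db >= -outer_r &
    !(abs(off$da) <= 1L & abs(off$db) <= 1L)
  horiz <- abs(off$da) <= 1L & abs(off$db) >= 2L & abs(off$db) <= outer_r
  vert <- abs(off$db) <= 1L & abs(off$da) >= 2L & abs(off$da) <= outer_r
  lapply(list(donut = donut, lower_left = ll, horizontal = horiz,
              vertical = vert),
         function(sel) as.matrix(off[sel, , drop = FALSE]))
}

# Sum of M over shifted positions given an offset list; returns a matrix the
# same shape as M. Positions falling outside the matrix contribute 0.
shift_sum <- function(M, offsets) {
  n <- nrow(M); p <- ncol(M)
  acc <- matrix(0, n, p)
  for (k in seq_len(nrow(offsets))) {
    da <- offsets[k, 1]; db <- offsets[k, 2]
    r_dst <- max(1L, 1L - da):min(n, n - da)
    c_dst <- max(1L, 1L - db):min(p, p - db)
    acc[r_dst, c_dst] <- acc[r_dst, c_dst] + M[r_dst + da, c_dst + db]
  }
  acc
}

#' Call focal chromatin loops
#'
#' Scans the distance band for pixels enriched over four local-background
#' expectations (donut, lower-left, horizontal, vertical neighbourhoods,
#' each excluding the centre 3x3 block). For each neighbourhood, the
#' expected count is the distance-decay expectation at the pixel scaled by
#' the neighbourhood's observed/expected ratio; the pixel's Poisson
#' upper-tail p-value is taken against the most conservative (largest) of
#' the four. P-values are Benjamini-Hochberg adjusted across the band;
#' significant pixels are clustered with 8-connectivity and each cluster's
#' centroid reported as a loop.
#'
#' @param m a `ContactMatrix` of raw counts (Poisson model; typically 20 kb
#'   or 5 kb resolution).
#' @param min_dist,max_dist distance band in bp (default 100 kb - 2 Mb).
#' @param fdr Benjamini-Hochberg threshold.
#' @param outer_r,inner_r donut radii in bins.
#' @param min_count minimum observed count for a candidate pixel.
#' @return a `LoopSet` data.frame: `bin1`, `bin2` (1-based), `start1`,
#'   `end1`, `start2`, `end2` (bp), `obs`, `expected`, `enrichment`,
#'   `p`, `q`, `n_pixels` (cluster size).
#' @export
call_loops <- function(m, min_dist = 1e5, max_dist = 2e6, fdr = 0.1,
                       outer_r = 7L, inner_r = 3L, min_count = 3L) {
  res <- m$resolution
  n <- n_bins(m)
  dmin <- as.integer(ceiling(min_dist / res))
  dmax <- as.integer(floor(max_dist / res))
  if (dmin > dmax || dmin >= n) stop("empty distance band at this resolution")
  un <- rep(FALSE, n); un[unmasked_bins(m)] <- TRUE
  e <- expected_profile(m)
  dist <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(e$values[dist + 1L], n, n)
  E[is.na(E) | E <= 0] <- NA_real_
  V <- outer(un, un, "&") & !is.na(E)       # valid pixels
  Mo <- m$counts; Mo[!V] <- 0
  Me <- E; Me[!V] <- 0; Me[is.na(Me)] <- 0
  nb <- loop_neighborhoods(outer_r, inner_r)
  lambda <- matrix(-Inf, n, n)
  for (mask in nb) {
    so <- shift_sum(Mo, mask)
    se <- shift_sum(Me, mask)
    lam <- ifelse(se > 0, so / se, NA_real_) * E
    lambda <- pmax(lambda, lam, na.rm = TRUE)
  }
  band <- which(dist >= dmin & dist <= dmax & upper.tri(dist) & V &
                  is.finite(lambda), arr.ind = TRUE)
  if (nrow(band) == 0L) stop("empty distance band")
  obs <- m$counts[band]
  lam <- lambda[band]
  p <- stats::ppois(obs - 1, lam, lower.tail = FALSE)
  p[obs < min_count] <- 1
  # BH within lambda chunks (log2 width 1/3): the expected count spans more
  # than a decade across the distance band, and a single band-wide FDR pass
  # would let shallow far-distance chunks ride on the many discoveries of
  # the deep short-distance chunks
  chunk <- floor(3 * log2(pmax(lam, 1e-6)))
  q <- rep(NA_real_, length(p))
  for (ch in unique(chunk)) {
    ix <- which(chunk == ch)
    q[ix] <- stats::p.adjust(p[ix], method = "BH")
  }
  sig <- which(q <= fdr)
  loops <- cluster_pixels(band[sig, , drop = FALSE], obs[sig], lam[sig],
                          p[sig], q[sig])
  # singleton clusters are kept only under a stricter FDR (isolated pixels
  # are far more likely to be counting noise than bin-spanning focal peaks)
  loops <- loops[loops$n_pixels > 1L | loops$q <= fdr / 5, , drop = FALSE]
  if (nrow(loops)) {
    loops$start1 <- (loops$bin1 - 1L) * res; loops$end1 <- loops$bin1 * res
    loops$start2 <- (loops$bin2 - 1L) * res; loops$end2 <- loops$bin2 * res
    loops <- loops[, c("bin1", "bin2", "start1", "end1", "start2", "end2",
                       "obs", "expected", "enrichment", "p", "q", "n_pixels")]
  }
  class(loops) <- c("LoopSet", "data.frame")
  attr(loops, "resolution") <- res
  attr(loops, "chrom") <- m$chrom
  loops
}

# Cluster significant pixels with 8-connectivity; report the peak pixel
# (largest enrichment) of each cluster as its representative.
cluster_pixels <- function(px, obs, lam, p, q) {
  if (nrow(px) == 0L)
    return(data.frame(bin1 = integer(), bin2 = integer(), obs = numeric(),
                      expected = numeric(), enrichment = numeric(),
                      p = numeric(), q = numeric(), n_pixels = integer()))
  np <- nrow(px)
  cl <- seq_len(np)
  repeat {
    changed <- FALSE
    for (i in seq_len(np)) {
      nbr <- which(abs(px[, 1] - px[i, 1]) <= 1L &
                     abs(px[, 2] - px[i, 2]) <= 1L)
      newc <- min(cl[nbr])
      if (any(cl[nbr] != newc)) { cl[nbr] <- newc; changed <- TRUE }
    }
    if (!changed) break
  }
  enr <- obs / lam
  do.call(rbind, lapply(split(seq_len(np), cl), function(ix) {
    best <- ix[which.max(enr[ix])]
    data.frame(bin1 = px[best, 1], bin2 = px[best, 2], obs = obs[best],
               expected = lam[best], enrichment = enr[best],
               p = p[best], q = q[best], n_pixels = length(ix))
  }))
}

#' Focal enrichment of given loops in a matrix
#'
#' Pixel count over the maximum of the four local-background expectations —
#' the same statistic the caller thresholds — evaluated at fixed loop
#' positions, for cross-condition comparison over a union loop list.
#'
#' @param m a `ContactMatrix` of raw counts.
#' @param loops a `LoopSet` (or data.frame with `bin1`, `bin2`).
#' @param outer_r,inner_r donut radii in bins.
#' @return numeric enrichment per loop; `NA` where anchors are masked.
#' @export
loop_enrichment <- function(m, loops, outer_r = 7L, inner_r = 3L) {
  n <- n_bins(m)
  un <- rep(FALSE, n); un[unmasked_bins(m)] <- TRUE
  e <- expected_profile(m)
  dist <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(e$values[dist + 1L], n, n)
  E[is.na(E) | E <= 0] <- NA_real_
  V <- outer(un, un, "&") & !is.na(E)
  Mo <- m$counts; Mo[!V] <- 0
  Me <- E; Me[!V] <- 0; Me[is.na(Me)] <- 0
  nb <- loop_neighborhoods(outer_r, inner_r)
  lambda <- matrix(-Inf, n, n)
  for (mask in nb) {
    so <- shift_sum(Mo, mask)
    se <- shift_sum(Me, mask)
    lam <- ifelse(se > 0, so / se, NA_real_) * E
    lambda <- pmax(lambda, lam, na.rm = TRUE)
  }
  vapply(seq_len(nrow(loops)), function(k) {
    i <- loops$bin1[k]; j <- loops$bin2[k]
    if (i < 1L || j > n || !V[i, j] || !is.finite(lambda[i, j])) return(NA_real_)
    m$counts[i, j] / lambda[i, j]
  }, numeric(1))
}

#' Aggregate peak analysis (APA)
#'
#' Averages `(2k+1) x (2k+1)` O/E windows centred on each loop pixel. The
#' APA score is the centre value divided by the mean of the 3x3 lower-left
#' corner block (short-distance background). Loops too close to the diagonal
#' or the chromosome ends for a full window are skipped.
#'
#' @param oe O/E `ContactMatrix`.
#' @param loops a `LoopSet` (or data.frame with `bin1`, `bin2`).
#' @param k window half-width in bins.
#' @return an `ApaResult`: list with `window` (aggregate matrix),
#'   `apa_score`, `n_loops` (number aggregated).
#' @export
apa_score <- function(oe, loops, k = 5L) {
  if (is.null(loops) || nrow(loops) == 0L) stop("empty loop list")
  n <- n_bins(oe)
  w <- 2L * k + 1L
  acc <- matrix(0, w, w)
  used <- 0L
  for (idx in seq_len(nrow(loops))) {
    i <- loops$bin1[idx]; j <- loops$bin2[idx]
    if (i - k < 1L || j + k > n || i + k < 1L || j - k < 1L) next
    if ((j - i) <= 2L * k) next       # diagonal bleed
    acc <- acc + oe$counts[(i - k):(i + k), (j - k):(j + k)]
    used <- used + 1L
  }
  if (used == 0L) stop("no loops usable for APA at this window")
  Wm <- acc / used
  centre <- Wm[k + 1L, k + 1L]
  corner <- mean(Wm[(w - 2L):w, 1:3])
  structure(list(window = Wm, apa_score = centre / corner, n_loops = used),
            class = "ApaResult")
}

#' @export
print.ApaResult <- function(x, ...) {
  cat(sprintf("APA over %d loops: score %.3f\n", x$n_loops, x$apa_score))
  invisible(x)
}

#' Classify loop dynamics across conditions
#'
#' Applies the Static/Resis/Repro/Hyper rule of [classify_tad_dynamics()] to
#' per-loop focal enrichments over a union loop list, and additionally flags
#' `CC-specific disappeared` loops (called in the donor condition only) and
#' `ESC-like gained` loops (called in fESC and ntESC but not the donor) when
#' per-condition called flags are supplied.
#'
#' @param e_cc,e_nt,e_f per-loop focal enrichments (see [loop_enrichment()]).
#' @param called_cc,called_nt,called_f optional logical vectors: loop called
#'   in that condition.
#' @param fold,delta thresholds as in [classify_tad_dynamics()].
#' @return data.frame with `dynamics` and (when flags given) `category`
#'   in {CC-specific disappeared, ESC-like gained, other}; loops with
#'   undefined enrichment are `NA`.
#' @export
classify_loop_dynamics <- function(e_cc, e_nt, e_f,
                                   called_cc = NULL, called_nt = NULL,
                                   called_f = NULL,
                                   fold = 1.5, delta = 0.15) {
  dyn <- classify_tad_dynamics(e_cc, e_nt, e_f, fold = fold, delta = delta)
  out <- data.frame(dynamics = dyn)
  if (!is.null(called_cc) && !is.null(called_nt) && !is.null(called_f)) {
    cat_ <- rep("other", length(e_cc))
    cat_[called_cc & !called_nt & !called_f] <- "CC-specific disappeared"
    cat_[!called_cc & called_nt & called_f] <- "ESC-like gained"
    out$category <- factor(cat_, levels = c("CC-specific disappeared",
                                            "ESC-like gained", "other"))
  }
  out
}
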