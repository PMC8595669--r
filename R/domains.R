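# Insulation scores, TAD boundary calling, relative TAD intensity (RTI) and
# TAD-dynamics classification.

#' Insulation-score track
#'
#' For each bin `i`, the diamond mean is the mean contact between the `w`
#' bins upstream and the `w` bins downstream of `i` (`w = window /
#' resolution`), excluding masked pairs. The score is
#' `log2(diamond / mean of all defined diamonds)`, so it averages ~0 along
#' the chromosome and is invariant to global matrix scaling. Undefined within
#' `w` bins of the chromosome ends and at masked bins.
#'
#' @param m a balanced `ContactMatrix` (typically 40 kb).
#' @param window diamond half-width in bp; multiple of the resolution.
#' @return an `InsulationTrack`: list with `chrom`, `resolution`, `window`
#'   and `score` (length `n_bins`, `NA` where undefined).
#' @export
insulation_track <- function(m, window = 480e3) {
  w <- as.integer(round(window / m$resolution))
  if (w < 2L) stop("window must span at least 2 bins")
  n <- n_bins(m)
  un <- rep(FALSE, n); un[unmasked_bins(m)] <- TRUE
  diam <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1L || i + w > n || !un[i]) next
    rows <- (i - w):(i - 1L); cols <- (i + 1L):(i + w)
    ok <- outer(un[rows], un[cols], "&")
    if (!any(ok)) next
    diam[i] <- mean(m$counts[rows, cols][ok])
  }
  mu <- mean(diam, na.rm = TRUE)
  if (!is.finite(mu) || mu <= 0) stop("no defined diamonds")
  structure(list(chrom = m$chrom, resolution = m$resolution,
                 window = w * m$resolution, score = log2(diam / mu)),
            class = "InsulationTrack")
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score whose contrast — the
#' mean of the two nearest flanking local maxima minus the minimum — reaches
#' `min_delta` (log2 units). Minima within 2 bins of each other are merged,
#' keeping the deeper one.
#'
#' @param t an `InsulationTrack`.
#' @param min_delta minimum boundary contrast.
#' @return data.frame of class `BoundarySet`: `bin` (1-based), `start`,
#'   `end` (bp of the boundary bin), `insulation`, `strength`.
#' @export
call_boundaries <- function(t, min_delta = 0.1) {
  s <- t$score
  if (all(is.na(s))) stop("all-undefined insulation track")
  n <- length(s)
  is_min <- is_max <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    if (is.na(s[i - 1]) || is.na(s[i]) || is.na(s[i + 1])) next
    if (s[i] <= s[i - 1] && s[i] <= s[i + 1] &&
        (s[i] < s[i - 1] || s[i] < s[i + 1])) is_min[i] <- TRUE
    if (s[i] >= s[i - 1] && s[i] >= s[i + 1] &&
        (s[i] > s[i - 1] || s[i] > s[i + 1])) is_max[i] <- TRUE
  }
  mins <- which(is_min); maxs <- which(is_max)
  if (!length(mins))
    return(empty_boundaries(t))
  strength <- vapply(mins, function(i) {
    lmax <- maxs[maxs < i]; rmax <- maxs[maxs > i]
    lv <- if (length(lmax)) s[max(lmax)] else max(s[seq_len(i)], na.rm = TRUE)
    rv <- if (length(rmax)) s[min(rmax)] else max(s[i:n], na.rm = TRUE)
    mean(c(lv, rv)) - s[i]
  }, numeric(1))
  keep <- strength >= min_delta
  mins <- mins[keep]; strength <- strength[keep]
  if (!length(mins)) return(empty_boundaries(t))
  # merge minima closer than 2 bins, keeping the deeper
  ord <- order(mins)
  mins <- mins[ord]; strength <- strength[ord]
  out_bin <- integer(); out_str <- numeric()
  i <- 1L
  while (i <= length(mins)) {
    j <- i
    while (j < length(mins) && mins[j + 1L] - mins[j] <= 2L) j <- j + 1L
    grp <- i:j
    best <- grp[which.min(s[mins[grp]])]
    out_bin <- c(out_bin, mins[best]); out_str <- c(out_str, strength[best])
    i <- j + 1L
  }
  res <- t$resolution
  out <- data.frame(bin = out_bin, start = (out_bin - 1L) * res,
                    end = out_bin * res, insulation = s[out_bin],
                    strength = out_str)
  class(out) <- c("BoundarySet", "data.frame")
  out
}

empty_boundaries <- function(t) {
  out <- data.frame(bin = integer(), start = numeric(), end = numeric(),
                    insulation = numeric(), strength = numeric())
  class(out) <- c("BoundarySet", "data.frame")
  out
}

#' Assemble TADs from consecutive boundaries
#'
#' Consecutive boundary pairs delimit TADs; domains shorter than `min_bins`
#' bins are dropped.
#'
#' @param bounds a `BoundarySet` (>= 2 boundaries for any output).
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @param min_bins minimum TAD length in bins.
#' @return data.frame of class `TadSet`: `chrom`, `start`, `end` (bp,
#'   half-open), `start_bin`, `end_bin` (1-based, inclusive).
#' @export
boundaries_to_tads <- function(bounds, resolution, chrom = "chrS",
                               min_bins = 3L) {
  b <- sort(unique(bounds$bin))
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    start_bin = integer(), end_bin = integer())
  if (length(b) >= 2L) {
    s <- b[-length(b)]; e <- b[-1]
    keep <- (e - s) >= min_bins
    if (any(keep))
      out <- data.frame(chrom = chrom, start = (s[keep] - 1L) * resolution,
                        end = (e[keep] - 1L) * resolution,
                        start_bin = s[keep], end_bin = e[keep] - 1L)
  }
  class(out) <- c("TadSet", "data.frame")
  out
}

#' Aggregate contact profile around boundaries
#'
#' Mean of O/E submatrices centred on each boundary, over boundaries at
#' least `flank` from the chromosome ends.
#'
#' @param oe O/E `ContactMatrix`.
#' @param bounds a `BoundarySet`.
#' @param flank window half-width in bp (default 600 kb).
#' @return a `(2*flank/res + 1)` square matrix.
#' @export
aggregate_boundary_profile <- function(oe, bounds, flank = 600e3) {
  f <- as.integer(round(flank / oe$resolution))
  n <- n_bins(oe)
  ok <- bounds$bin[bounds$bin - f >= 1L & bounds$bin + f <= n]
  if (!length(ok)) stop("no boundaries eligible at this flank")
  acc <- matrix(0, 2L * f + 1L, 2L * f + 1L)
  for (b in ok)
    acc <- acc + oe$counts[(b - f):(b + f), (b - f):(b + f)]
  acc / length(ok)
}

#' Relative TAD intensity (RTI)
#'
#' Mean O/E within the TAD square divided by the mean O/E of the two
#' inter-domain rectangles between the TAD and its equal-length flanks
#' (truncated at chromosome ends). RTI is 1 on structureless O/E and grows
#' with domain strength.
#'
#' @param oe O/E `ContactMatrix`.
#' @param tads a `TadSet` (or data.frame with `start_bin`, `end_bin`).
#' @return numeric RTI per TAD; `NA` (with a flag attribute) when both
#'   flanks are fully masked.
#' @export
relative_tad_intensity <- function(oe, tads) {
  n <- n_bins(oe)
  un <- rep(FALSE, n); un[unmasked_bins(oe)] <- TRUE
  vapply(seq_len(nrow(tads)), function(k) {
    a <- tads$start_bin[k]; b <- tads$end_bin[k]
    L <- b - a + 1L
    sq <- oe$counts[a:b, a:b]
    okq <- outer(un[a:b], un[a:b], "&")
    intra <- if (any(okq)) mean(sq[okq]) else NA_real_
    inter_vals <- numeric(0)
    if (a > 1L) {
      lf <- max(1L, a - L):(a - 1L)
      okl <- outer(un[a:b], un[lf], "&")
      if (any(okl)) inter_vals <- c(inter_vals, oe$counts[a:b, lf, drop = FALSE][okl])
    }
    if (b < n) {
      rf <- (b + 1L):min(n, b + L)
      okr <- outer(un[a:b], un[rf], "&")
      if (any(okr)) inter_vals <- c(inter_vals, oe$counts[a:b, rf, drop = FALSE][okr])
    }
    if (!length(inter_vals) || is.na(intra)) return(NA_real_)
    intra / mean(inter_vals)
  }, numeric(1))
}

#' Classify TAD dynamics across conditions
#'
#' A TAD is `Static` when the donor/fESC intensity contrast is below the
#' fold threshold: `|log2(rti_cc / rti_f)| < log2(fold)`. Otherwise the
#' progress statistic `(rti_nt - rti_cc) / (rti_f - rti_cc)` assigns
#' `Resis` (r <= delta), `Repro` (`1 - delta < r <= 1 + delta`), `Hyper`
#' (r > 1 + delta); intermediate values (no separate Partial group for
#' TADs) go to `Repro` when r > 0.5, else `Resis`.
#'
#' @param rti_cc,rti_nt,rti_f per-TAD intensities in the donor,
#'   nuclear-transfer and fertilised conditions.
#' @param fold Static threshold on the CC/fESC intensity ratio.
#' @param delta class boundary half-width.
#' @return factor with levels Static/Repro/Resis/Hyper.
#' @export
classify_tad_dynamics <- function(rti_cc, rti_nt, rti_f, fold = 1.5,
                                  delta = 0.15) {
  stopifnot(length(rti_cc) == length(rti_nt),
            length(rti_cc) == length(rti_f))
  out <- rep(NA_character_, length(rti_cc))
  for (i in seq_along(rti_cc)) {
    cc <- rti_cc[i]; nt <- rti_nt[i]; f <- rti_f[i]
    if (anyNA(c(cc, nt, f))) next
    if (abs(log2(cc / f)) < log2(fold) || abs(f - cc) < 1e-12) {
      out[i] <- "Static"; next
    }
    r <- (nt - cc) / (f - cc)
    out[i] <- if (r <= delta) "Resis"
    else if (r > 1 + delta) "Hyper"
    else if (r > 1 - delta) "Repro"
    else if (r > 0.5) "Repro" else "Resis"
  }
  factor(out, levels = c("Static", "Repro", "Resis", "Hyper"))
}

#' Condition-specific TADs
#'
#' `CC-specific` when the donor intensity exceeds `fold` times the fESC
#' intensity; `ESC-specific` for the reverse; otherwise `unspecific`.
#'
#' @param rti_cc,rti_f per-TAD intensities.
#' @param fold specificity fold threshold.
#' @return factor with levels CC-specific/ESC-specific/unspecific.
#' @export
specific_tads <- function(rti_cc, rti_f, fold = 1.5) {
  lab <- ifelse(rti_cc >= fold * rti_f, "CC-specific",
                ifelse(rti_f >= fold * rti_cc, "ESC-specific", "unspecific"))
  factor(lab, levels = c("CC-specific", "ESC-specific", "unspecific"))
}

#' Consensus boundaries across conditions
#'
#' Union of boundary positions supported by at least `min_support`
#' conditions within +/- 1 bin; the reported position is the rounded mean of
#' the supporting positions. Lets cross-condition RTI triples be computed
#' over identical intervals.
#'
#' @param boundary_sets list of `BoundarySet`s, one per condition.
#' @param min_support minimum number of supporting conditions.
#' @param resolution bin width in bp.
#' @return a `BoundarySet` (strength/insulation are means over supporters).
#' @export
consensus_boundaries <- function(boundary_sets, min_support = 2L,
                                 resolution) {
  all_b <- do.call(rbind, lapply(seq_along(boundary_sets), function(i) {
    b <- boundary_sets[[i]]
    if (nrow(b) == 0L) return(NULL)
    data.frame(cond = i, bin = b$bin, insulation = b$insulation,
               strength = b$strength)
  }))
  if (is.null(all_b) || nrow(all_b) == 0L)
    stop("no boundaries in any condition")
  all_b <- all_b[order(all_b$bin), ]
  # cluster positions within +/-1 bin
  brk <- c(TRUE, diff(all_b$bin) > 1L)
  cid <- cumsum(brk)
  out <- do.call(rbind, lapply(split(all_b, cid), function(g) {
    if (length(unique(g$cond)) < min_support) return(NULL)
    data.frame(bin = as.integer(round(mean(g$bin))),
               insulation = mean(g$insulation), strength = mean(g$strength))
  }))
  if (is.null(out)) stop("no consensus boundaries at this support level")
  out$start <- (out$bin - 1L) * resolution
  out$end <- out$bin * resolution
  out <- out[, c("bin", "start", "end", "insulation", "strength")]
  rownames(out) <- NULL
  class(out) <- c("BoundarySet", "data.frame")
  out
}
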