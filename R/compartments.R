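# A/B compartment calling, switch detection, reprogramming-dynamics
# classification and NT-vs-iPSC process comparison.

#' Pearson correlation matrix of an O/E map
#'
#' Entry (i, j) is the Pearson correlation of O/E rows i and j computed over
#' unmasked columns. Rows for masked bins are `NA`.
#'
#' @param oe a `ContactMatrix` holding an observed/expected map (typically
#'   at 200 kb).
#' @return an `n x n` correlation matrix with `NA` rows/columns at masked
#'   bins and unit diagonal on unmasked bins.
#' @export
pearson_oe_matrix <- function(oe) {
  un <- unmasked_bins(oe)
  if (length(un) < 10L) stop("fewer than 10 unmasked bins")
  X <- oe$counts[un, un, drop = FALSE]
  C <- stats::cor(t(X))
  n <- n_bins(oe)
  out <- matrix(NA_real_, n, n)
  out[un, un] <- C
  out
}

#' Leading principal component of a correlation matrix
#'
#' Unit-norm first principal component of the column-centred correlation
#' matrix, restricted to bins with defined correlations; masked bins are
#' `NA` in the result. The global sign is arbitrary until oriented with
#' [orient_and_call()].
#'
#' @param corr correlation matrix as from [pearson_oe_matrix()].
#' @param which component to extract (1 for PC1, 2 for PC2).
#' @return numeric vector of length `nrow(corr)` with `NA` at masked bins.
#' @export
compute_pc1 <- function(corr, which = 1L) {
  un <- which(apply(corr, 1L, function(r) any(!is.na(r))))
  if (length(un) < 3L) stop("too few defined bins")
  X <- corr[un, un, drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (max(abs(Xc)) < 1e-12) stop("no principal axis: degenerate matrix")
  sv <- svd(Xc, nu = 0, nv = max(2L, which))
  if (sv$d[which] < 1e-12 * sv$d[1]) stop("no principal axis: rank too low")
  v <- (Xc %*% sv$v[, which])[, 1]
  v <- v / sqrt(sum(v^2))
  out <- rep(NA_real_, nrow(corr))
  out[un] <- v
  out
}

#' Orient PC1 by an activity reference and call A/B states
#'
#' Flips the global sign of the eigenvector when its Pearson correlation
#' with an activity track (gene density or ATAC coverage binned at the same
#' resolution) is negative, then assigns compartment A to positive and B to
#' negative values. Bins with `pc1 == 0` or `NA` get state `NA`.
#'
#' @param pc1 numeric vector from [compute_pc1()].
#' @param activity per-bin reference signal, same length.
#' @param chrom,resolution metadata recorded on the track.
#' @return a `CompartmentTrack`: data.frame with columns `bin` (0-based),
#'   `start`, `end`, `pc1`, `state` (factor A/B with `NA`).
#' @export
orient_and_call <- function(pc1, activity, chrom = "chrS", resolution = 2e5) {
  if (length(activity) != length(pc1)) stop("length mismatch")
  ok <- !is.na(pc1) & !is.na(activity)
  if (stats::sd(activity[ok]) == 0) stop("orientation undefined: zero-variance activity")
  r <- stats::cor(pc1[ok], activity[ok])
  if (!is.na(r) && r < 0) pc1 <- -pc1
  state <- ifelse(is.na(pc1) | pc1 == 0, NA_character_,
                  ifelse(pc1 > 0, "A", "B"))
  out <- data.frame(bin = seq_along(pc1) - 1L,
                    start = (seq_along(pc1) - 1L) * resolution,
                    end = seq_along(pc1) * resolution,
                    pc1 = pc1,
                    state = factor(state, levels = c("A", "B")))
  attr(out, "chrom") <- chrom
  attr(out, "resolution") <- resolution
  class(out) <- c("CompartmentTrack", "data.frame")
  out
}

#' Call compartments from an O/E matrix
#'
#' Convenience wrapper: correlation matrix, leading eigenvector, activity
#' orientation. If PC1 barely correlates with the activity reference
#' (|r| < 0.2) while PC2 correlates more strongly (the classic arm-tracking
#' failure of the leading component), PC2 is substituted and a message
#' emitted.
#'
#' @param oe O/E `ContactMatrix` at compartment resolution.
#' @param activity per-bin activity reference.
#' @return a `CompartmentTrack` (see [orient_and_call()]).
#' @export
call_compartments <- function(oe, activity) {
  corr <- pearson_oe_matrix(oe)
  p1 <- compute_pc1(corr, 1L)
  ok <- !is.na(p1) & !is.na(activity)
  r1 <- suppressWarnings(stats::cor(p1[ok], activity[ok]))
  use <- p1
  if (!is.na(r1) && abs(r1) < 0.2) {
    p2 <- tryCatch(compute_pc1(corr, 2L), error = function(e) NULL)
    if (!is.null(p2)) {
      r2 <- suppressWarnings(stats::cor(p2[ok], activity[ok]))
      if (!is.na(r2) && abs(r2) > abs(r1)) {
        message("PC1 tracks chromosome arms; substituting PC2")
        use <- p2
      }
    }
  }
  orient_and_call(use, activity, chrom = oe$chrom, resolution = oe$resolution)
}

#' Compartmentalisation strength (saddle ratio)
#'
#' Bins are ranked by PC1 and cut into `n_quantiles` groups; strength is the
#' mean O/E among (top x top) and (bottom x bottom) pairs divided by the mean
#' O/E among (top x bottom) pairs, self-pairs excluded. Structureless maps
#' give 1; stronger A/B segregation gives larger values.
#'
#' @param oe O/E `ContactMatrix`.
#' @param track `CompartmentTrack` on the same binning.
#' @param n_quantiles number of PC1 rank groups (>= 2).
#' @return scalar strength (> 0).
#' @export
compartment_strength <- function(oe, track, n_quantiles = 5L) {
  if (n_quantiles < 2L) stop("n_quantiles must be >= 2")
  if (nrow(track) != n_bins(oe)) stop("binning mismatch")
  un <- intersect(unmasked_bins(oe), which(!is.na(track$pc1)))
  rk <- rank(track$pc1[un], ties.method = "first")
  grp <- ceiling(rk / (length(un) / n_quantiles))
  top <- un[grp == n_quantiles]
  bot <- un[grp == 1L]
  offdiag <- function(i, j) {
    M <- oe$counts[i, j, drop = FALSE]
    if (identical(i, j)) M[upper.tri(M) | lower.tri(M)] else as.numeric(M)
  }
  within <- c(offdiag(top, top), offdiag(bot, bot))
  between <- offdiag(top, bot)
  mean(within) / mean(between)
}

#' Detect compartment switches between donor and ESC states
#'
#' Per bin, the donor state comes from the donor-cell (CC) track and the ESC
#' state from the two fertilised-ESC lines, used only where both lines agree
#' in PC1 sign; disagreeing bins are `NA` and excluded from totals. Adjacent
#' bins with the same transition are merged into regions. Condition PC1 for
#' nuclear-transfer and fertilised ESCs is the mean of the two lines.
#'
#' @param cc donor `CompartmentTrack`.
#' @param nt_lines list of two ntESC `CompartmentTrack`s.
#' @param f_lines list of two fESC `CompartmentTrack`s.
#' @return list with `bins` (per-bin data.frame: `cc_pc1`, `nt_pc1`,
#'   `f_pc1`, `donor_state`, `esc_state`, `transition`), `regions` (merged
#'   same-transition runs), and `percent` (percent of defined bins per
#'   transition type).
#' @export
call_switches <- function(cc, nt_lines, f_lines) {
  stopifnot(length(nt_lines) == 2L, length(f_lines) == 2L)
  n <- nrow(cc)
  for (t in c(nt_lines, f_lines))
    if (nrow(t) != n) stop("binning mismatch across tracks")
  res <- attr(cc, "resolution")
  nt_pc1 <- rowMeans(cbind(nt_lines[[1]]$pc1, nt_lines[[2]]$pc1))
  f1 <- f_lines[[1]]$pc1; f2 <- f_lines[[2]]$pc1
  f_agree <- !is.na(f1) & !is.na(f2) & sign(f1) == sign(f2) & f1 != 0
  f_pc1 <- ifelse(f_agree, (f1 + f2) / 2, NA_real_)
  donor <- as.character(cc$state)
  esc <- ifelse(f_agree, ifelse(f_pc1 > 0, "A", "B"), NA_character_)
  defined <- !is.na(donor) & !is.na(esc) & !is.na(nt_pc1)
  transition <- rep(NA_character_, n)
  transition[defined & donor == esc] <- "stable"
  transition[defined & donor == "A" & esc == "B"] <- "A-to-B"
  transition[defined & donor == "B" & esc == "A"] <- "B-to-A"
  bins <- data.frame(bin = cc$bin, start = cc$start, end = cc$end,
                     cc_pc1 = cc$pc1, nt_pc1 = nt_pc1, f_pc1 = f_pc1,
                     donor_state = donor, esc_state = esc,
                     transition = transition)
  # merge adjacent same-transition bins into regions
  def <- which(!is.na(transition))
  regions <- NULL
  if (length(def)) {
    brk <- c(TRUE, diff(def) != 1L |
               transition[def[-1]] != transition[def[-length(def)]])
    rid <- cumsum(brk)
    regions <- do.call(rbind, lapply(split(def, rid), function(ix) {
      data.frame(start = (ix[1] - 1L) * res, end = ix[length(ix)] * res,
                 n_bins = length(ix), transition = transition[ix[1]],
                 cc_pc1 = mean(cc$pc1[ix]), nt_pc1 = mean(nt_pc1[ix]),
                 f_pc1 = mean(f_pc1[ix]))
    }))
    rownames(regions) <- NULL
  }
  nd <- sum(!is.na(transition))
  pct <- c(`A-to-B` = 100 * sum(transition == "A-to-B", na.rm = TRUE) / nd,
           `B-to-A` = 100 * sum(transition == "B-to-A", na.rm = TRUE) / nd,
           stable = 100 * sum(transition == "stable", na.rm = TRUE) / nd)
  list(bins = bins, regions = regions, percent = pct)
}

#' Classify reprogramming dynamics of switched compartments
#'
#' For each switched record, the normalised progress of the ntESC PC1 along
#' the donor-to-fESC trajectory is r = `(nt - cc) / (f - cc)`. Classes:
#' `Resis` when r <= delta or the ntESC sign still matches the donor;
#' `Hyper` when r > 1 + delta; `Repro` when 1 - delta < r <= 1 + delta;
#' `Partial` otherwise (intermediate PC1 with the fESC sign). Records with
#' `f == cc` are skipped with a warning (undefined trajectory).
#'
#' @param records data.frame with columns `cc_pc1`, `nt_pc1`, `f_pc1`
#'   restricted to switched bins/regions (donor state differs from ESC
#'   state), e.g. from [call_switches()].
#' @param delta class boundary half-width in `r` units, in (0, 0.5).
#' @return the records with added columns `r` and `class`, plus a `counts`
#'   attribute (named table of class counts).
#' @export
classify_dynamics <- function(records, delta = 0.15) {
  if (delta <= 0 || delta >= 0.5) stop("delta must be in (0, 0.5)")
  cc <- records$cc_pc1; nt <- records$nt_pc1; f <- records$f_pc1
  skip <- f == cc
  if (any(skip)) warning(sum(skip), " record(s) skipped: f_pc1 == cc_pc1")
  r <- (nt - cc) / (f - cc)
  cls <- rep(NA_character_, nrow(records))
  idx <- which(!skip)
  for (i in idx) {
    cls[i] <- if (r[i] <= delta || (sign(nt[i]) == sign(cc[i]) && nt[i] != 0))
      "Resis"
    else if (r[i] > 1 + delta) "Hyper"
    else if (r[i] > 1 - delta) "Repro"
    else "Partial"
  }
  out <- records
  out$r <- r
  out$class <- factor(cls, levels = c("Repro", "Partial", "Hyper", "Resis"))
  attr(out, "counts") <- table(out$class)
  out
}

#' Consensus ESC compartment track
#'
#' Bins where two ESC tracks agree in PC1 sign keep the mean PC1; others are
#' set to `NA`. Used to define the reference ESC state shared by fESC and a
#' standard ESC line.
#'
#' @param a,b two `CompartmentTrack`s on the same binning.
#' @return a `CompartmentTrack`.
#' @export
consensus_track <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  agree <- !is.na(a$pc1) & !is.na(b$pc1) & sign(a$pc1) == sign(b$pc1) &
    a$pc1 != 0
  pc1 <- ifelse(agree, (a$pc1 + b$pc1) / 2, NA_real_)
  out <- a
  out$pc1 <- pc1
  out$state <- factor(ifelse(is.na(pc1), NA_character_,
                             ifelse(pc1 > 0, "A", "B")), levels = c("A", "B"))
  out
}

#' Compare compartment switching in NT and iPSC reprogramming
#'
#' Per bin where all five states are defined: the NT process switches when
#' the donor-cell (CC) state differs from the consensus ESC state and the
#' ntESC reaches the ESC state; the iPSC process likewise from MEF. Bins
#' switching in both processes are `common`; otherwise `NT-specific` or
#' `iPSC-specific`. Non-common switches are `donor-specific` when CC and MEF
#' states differ, and `method-specific` when CC and MEF agree but ntESC and
#' iPSC states differ.
#'
#' @param cc,mef,nt,ipsc,esc `CompartmentTrack`s on identical binning;
#'   `esc` is the consensus ESC reference (see [consensus_track()]).
#' @return list with `bins` (per-bin categories) and `percent` (percentage
#'   of switching bins per category).
#' @export
compare_processes <- function(cc, mef, nt, ipsc, esc) {
  tracks <- list(cc = cc, mef = mef, nt = nt, ipsc = ipsc, esc = esc)
  n <- nrow(cc)
  st <- lapply(tracks, function(t) {
    if (is.null(t) || nrow(t) != n) stop("missing or mismatched condition track")
    as.character(t$state)
  })
  defined <- Reduce(`&`, lapply(st, function(s) !is.na(s)))
  nt_switch <- defined & st$cc != st$esc & st$nt == st$esc
  ip_switch <- defined & st$mef != st$esc & st$ipsc == st$esc
  category <- rep(NA_character_, n)
  category[nt_switch & ip_switch] <- "common"
  category[nt_switch & !ip_switch] <- "NT-specific"
  category[!nt_switch & ip_switch] <- "iPSC-specific"
  specificity <- rep(NA_character_, n)
  noncommon <- !is.na(category) & category != "common"
  specificity[noncommon & st$cc != st$mef] <- "donor-specific"
  specificity[noncommon & st$cc == st$mef & st$nt != st$ipsc] <- "method-specific"
  bins <- data.frame(bin = cc$bin, start = cc$start, end = cc$end,
                     cc = st$cc, mef = st$mef, nt = st$nt, ipsc = st$ipsc,
                     esc = st$esc, category = category,
                     specificity = specificity)
  nsw <- sum(!is.na(category))
  pct <- 100 * table(factor(category,
                            levels = c("common", "NT-specific",
                                       "iPSC-specific"))) / max(nsw, 1L)
  list(bins = bins, percent = c(pct))
}
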