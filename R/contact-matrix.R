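# Binned per-chromosome Hi-C contact maps: construction, I/O, balancing,
# distance normalisation.

#' Construct a ContactMatrix
#'
#' A `ContactMatrix` is a symmetric, non-negative, binned contact map for a
#' single chromosome, together with its balancing state and a mask of
#' excluded bins. Bins are fixed-width (`resolution` bp), 0-based half-open
#' in genomic coordinates; internally bin `i` of the matrix is row/column `i`
#' (1-based, R convention).
#'
#' @param counts symmetric numeric matrix of contact counts (or balanced
#'   frequencies), all entries >= 0.
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param balanced logical; `TRUE` once iterative correction has been applied.
#' @param mask integer vector of 1-based bin indices excluded from analysis;
#'   masked rows/columns are set to zero.
#' @param bias numeric bias vector from balancing (multiplicative, one entry
#'   per bin), or `NULL` if unbalanced.
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(counts, chrom = "chrS", resolution = 2e5,
                           balanced = FALSE, mask = integer(), bias = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("'counts' must be square")
  if (any(counts < 0, na.rm = TRUE))
    stop("'counts' must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    stop("'counts' must be symmetric")
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1L || max(mask) > nrow(counts)))
    stop("mask indices out of range")
  counts[mask, ] <- 0
  counts[, mask] <- 0
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 counts = counts, balanced = isTRUE(balanced),
                 mask = mask, bias = bias),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s: %d bins @ %g bp, %s, %d masked\n",
              x$chrom, n_bins(x), x$resolution,
              if (x$balanced) "balanced" else "raw", length(x$mask)))
  invisible(x)
}

#' Number of bins of a ContactMatrix
#' @param m a `ContactMatrix`.
#' @return integer bin count.
#' @export
n_bins <- function(m) nrow(m$counts)

#' Indices of analysable (unmasked) bins
#' @param m a `ContactMatrix`.
#' @return integer vector of 1-based bin indices.
#' @export
unmasked_bins <- function(m) setdiff(seq_len(n_bins(m)), m$mask)

#' Load a contact matrix from text
#'
#' Reads either a 3-column triplet file (`bin_i bin_j count`, 0-based bin
#' indices, whitespace separated, upper or lower triangle; a header line is
#' tolerated) or a dense whitespace-separated matrix. Bins with zero marginal
#' count are flagged in the mask.
#'
#' @param path file path.
#' @param chrom chromosome name to record.
#' @param resolution bin width in bp.
#' @param n_bins number of bins; required for triplet input unless inferable
#'   from the largest index.
#' @param format one of `"auto"`, `"triplet"`, `"dense"`.
#' @return a `ContactMatrix`.
#' @export
load_matrix <- function(path, chrom = "chrS", resolution = 2e5,
                        n_bins = NULL, format = c("auto", "triplet", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(suppressWarnings(data.table::fread(path, header = "auto")),
                 error = function(e) stop("unreadable contact file: ",
                                          conditionMessage(e)))
  if (nrow(dt) == 0L) stop("no records in ", path)
  if (format == "auto")
    format <- if (ncol(dt) == 3L) "triplet" else "dense"
  if (format == "triplet") {
    if (ncol(dt) != 3L) stop("triplet input must have 3 columns")
    i <- as.integer(dt[[1]]); j <- as.integer(dt[[2]]); v <- as.numeric(dt[[3]])
    if (anyNA(i) || anyNA(j) || anyNA(v)) stop("malformed triplet records")
    if (any(v < 0)) stop("negative counts")
    nb <- if (is.null(n_bins)) max(i, j) + 1L else as.integer(n_bins)
    if (max(i, j) + 1L > nb) stop("bin index exceeds n_bins")
    m <- matrix(0, nb, nb)
    # detect inconsistent duplicates of (i,j) vs (j,i)
    key <- paste(pmin(i, j), pmax(i, j))
    agg <- tapply(v, key, function(x) length(unique(x)))
    dupkey <- names(agg)[agg > 1]
    if (length(dupkey))
      stop("asymmetric triplet records for pairs: ",
           paste(utils::head(dupkey, 3), collapse = "; "))
    m[cbind(i + 1L, j + 1L)] <- v
    m[cbind(j + 1L, i + 1L)] <- v
  } else {
    m <- as.matrix(dt)
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) stop("dense input must be square")
    storage.mode(m) <- "double"
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      stop("dense input is not symmetric")
  }
  marg <- rowSums(m)
  contact_matrix(m, chrom = chrom, resolution = resolution,
                 mask = which(marg == 0))
}

#' Write a contact matrix as triplet text
#'
#' Upper-triangle (including diagonal) nonzero entries, 0-based bin indices.
#'
#' @param m a `ContactMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  dt <- data.table::data.table(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                               count = m$counts[idx])
  data.table::setorder(dt, bin1, bin2)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Apply the default mask rule
#'
#' Masks bins whose marginal count is zero or below the `q`-th quantile of
#' the nonzero marginals (default: 1st percentile). Applied before balancing.
#'
#' @param m a `ContactMatrix`.
#' @param q quantile of nonzero marginals below which bins are masked.
#' @return a `ContactMatrix` with the mask applied.
#' @export
mask_low_coverage <- function(m, q = 0.01) {
  marg <- rowSums(m$counts)
  nz <- marg[marg > 0]
  thr <- if (length(nz)) stats::quantile(nz, q, names = FALSE) else 0
  bad <- which(marg == 0 | marg < thr)
  contact_matrix(m$counts, m$chrom, m$resolution, balanced = m$balanced,
                 mask = union(m$mask, bad), bias = m$bias)
}

#' Balance a contact matrix by iterative correction
#'
#' Sequential row/column scaling (ICE) on the unmasked submatrix until the
#' variance of the normalised row sums falls below `tol`. The multiplicative
#' bias vector is retained so the raw matrix can be recovered.
#'
#' @param m an unbalanced `ContactMatrix` (mask applied; see
#'   [mask_low_coverage()]).
#' @param max_iter maximum sweeps.
#' @param tol convergence tolerance on the variance of normalised row sums.
#' @return a balanced `ContactMatrix` with unit mean row sum on unmasked bins.
#' @export
balance_matrix <- function(m, max_iter = 200L, tol = 1e-5) {
  un <- unmasked_bins(m)
  if (length(un) < 2L) stop("fewer than 2 unmasked bins")
  W <- m$counts
  bias <- rep(1, n_bins(m))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)[un]
    sn <- s / mean(s)
    if (stats::var(sn) < tol) { converged <- TRUE; break }
    db <- rep(1, n_bins(m))
    db[un] <- sn
    W <- W / outer(db, db)
    bias <- bias * db
  }
  if (!converged && stats::var(rowSums(W)[un] / mean(rowSums(W)[un])) >= tol)
    warning("balancing did not converge in ", max_iter,
            " iterations; returning best effort")
  # normalise to unit mean row sum on unmasked bins
  sc <- mean(rowSums(W)[un])
  W <- W / sc
  bias <- bias * sqrt(sc)
  out <- contact_matrix(W, m$chrom, m$resolution, balanced = TRUE,
                        mask = m$mask, bias = bias)
  attr(out, "converged") <- converged
  out
}

#' Expected contact per genomic separation
#'
#' For each separation `d` (in bins), the mean contact over unmasked bin
#' pairs at that separation; pairs touching masked bins are excluded.
#'
#' @param m a balanced `ContactMatrix`.
#' @return an `ExpectedProfile`: list with `resolution` and `values`
#'   (length `n_bins`, entry `d+1` is the mean at separation `d`).
#' @export
expected_profile <- function(m) {
  n <- n_bins(m)
  un <- rep(FALSE, n); un[unmasked_bins(m)] <- TRUE
  if (!any(un)) stop("all bins masked")
  vals <- numeric(n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    ok <- un[i] & un[i + d]
    vals[d + 1L] <- if (any(ok)) mean(m$counts[cbind(i[ok], i[ok] + d)]) else NA_real_
  }
  structure(list(resolution = m$resolution, values = vals),
            class = "ExpectedProfile")
}

#' Observed/expected normalisation
#'
#' Divides each entry by the expected value at its separation; entries whose
#' expected value is zero or undefined become 0. Masked bins stay masked.
#'
#' @param m a `ContactMatrix`.
#' @param e an `ExpectedProfile` from [expected_profile()]; recomputed from
#'   `m` when omitted.
#' @return a `ContactMatrix` holding the O/E map (balanced flag inherited).
#' @export
observed_over_expected <- function(m, e = NULL) {
  if (is.null(e)) e <- expected_profile(m)
  if (!inherits(e, "ExpectedProfile")) stop("'e' must be an ExpectedProfile")
  if (e$resolution != m$resolution) stop("resolution mismatch")
  n <- n_bins(m)
  if (length(e$values) != n) stop("profile length mismatch")
  dist <- abs(outer(seq_len(n), seq_len(n), "-"))
  ev <- e$values[dist + 1L]
  ev[is.na(ev) | ev <= 0] <- Inf     # -> 0 after division
  oe <- m$counts / ev
  contact_matrix(oe, m$chrom, m$resolution, balanced = m$balanced,
                 mask = m$mask, bias = m$bias)
}

#' Contact-decay curve
#'
#' Mean contact probability as a function of genomic separation, aggregated
#' into log-spaced separation bins and normalised to sum to one, so curves
#' from different libraries are directly comparable at fixed separations.
#'
#' @param m a balanced `ContactMatrix`.
#' @param bins_per_decade number of log-spaced separation bins per decade.
#' @param min_sep smallest separation (bp); defaults to one bin.
#' @return a `DecayCurve`: data.frame with `separation` (bp, geometric mid)
#'   and `probability` columns.
#' @export
contact_decay_curve <- function(m, bins_per_decade = 10L, min_sep = NULL) {
  res <- m$resolution
  if (is.null(min_sep)) min_sep <- res
  if (min_sep < res) stop("resolution too coarse for requested minimum separation")
  n <- n_bins(m)
  e <- expected_profile(m)
  d_bp <- (seq_len(n - 1L)) * res              # separations >= 1 bin
  p <- e$values[-1L]
  keep <- !is.na(p) & d_bp >= min_sep
  d_bp <- d_bp[keep]; p <- p[keep]
  if (!length(p)) stop("no usable separations")
  edges <- 10^seq(floor(log10(min(d_bp))), ceiling(log10(max(d_bp))),
                  by = 1 / bins_per_decade)
  grp <- cut(d_bp, edges, include.lowest = TRUE, labels = FALSE)
  sep <- tapply(d_bp, grp, function(x) exp(mean(log(x))))
  pr <- tapply(p, grp, mean)
  out <- data.frame(separation = as.numeric(sep),
                    probability = as.numeric(pr / sum(pr)))
  out <- out[order(out$separation), ]
  rownames(out) <- NULL
  class(out) <- c("DecayCurve", "data.frame")
  out
}

#' Interpolate a decay curve at given separations
#'
#' @param curve a `DecayCurve`.
#' @param at separations in bp.
#' @return probabilities, linearly interpolated in log-log space.
#' @export
decay_at <- function(curve, at) {
  exp(stats::approx(log(curve$separation), log(curve$probability),
                    xout = log(at), rule = 2)$y)
}
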