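# Synthetic-data generator with planted ground truth. Truth is generated
# first; matrices, peak tables and tracks are derived from it, so every
# pipeline stage can be validated against known labels without downloads.

#' Simulation configuration
#'
#' Defaults describe a desk-scale synthetic chromosome: 600 bins at 200 kb
#' (120 Mb) for compartment-level maps and 1500 bins at 40 kb (60 Mb) for
#' TAD-level maps, power-law distance decay with exponent 1, plaid
#' compartment structure with 2x within-type enrichment, TADs with 3x
#' intra-domain enrichment, focal loops at 2.5x, Poisson counting noise with
#' sequencing depth set so the median pixel in the distance band is ~5
#' counts.
#'
#' @param seed RNG seed; a fixed seed makes every output reproducible.
#' @param n_bins bins per synthetic chromosome (compartment resolution).
#' @param resolution bin width in bp.
#' @param alpha distance-decay exponent.
#' @param depth scalar depth, or `"auto"` for median in-band count ~5.
#' @param block_len mean compartment block length in bins.
#' @param within_enrich plaid within-type enrichment (between = 1/within).
#' @param switch_frac fraction of compartment regions switching state
#'   between donor and ESC.
#' @param dynamics_props proportions of Repro/Partial/Hyper/Resis among
#'   switched regions.
#' @param hyper_scale overshoot factor for Hyper regions (multiple of the
#'   fESC value).
#' @param tad_n_bins,tad_resolution TAD-level map geometry.
#' @param n_tads,tad_size_range,tad_enrich planted domain structure.
#' @param n_loops,loop_band,loop_enrich planted focal loops (band in bp).
#' @param bin_bias_sd sd of optional log-normal per-bin bias (exercises
#'   balancing); 0 disables.
#' @param peak_sigma sd (log2 units) of peak-intensity noise.
#' @param chip_marked_mean,chip_unmarked_mean ChIP/Input ratio means.
#' @param chip_sigma lognormal sd of the ChIP/Input ratio.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_bins = 600L, resolution = 2e5, alpha = 1.0,
                       depth = "auto",
                       block_len = 10L, within_enrich = 2,
                       switch_frac = 0.2,
                       dynamics_props = c(Repro = 0.4, Partial = 0.2,
                                          Hyper = 0.2, Resis = 0.2),
                       hyper_scale = 1.4,
                       tad_n_bins = 1500L, tad_resolution = 4e4,
                       n_tads = 10L, tad_size_range = c(20L, 50L),
                       tad_enrich = 3,
                       n_loops = 20L, loop_band = c(1e5, 2e6),
                       loop_enrich = 2.5,
                       bin_bias_sd = 0,
                       peak_sigma = 0.1,
                       chip_marked_mean = 3, chip_unmarked_mean = 1,
                       chip_sigma = 0.2) {
  if (within_enrich <= 0 || tad_enrich <= 0 || loop_enrich <= 0)
    stop("enrichments must be > 0")
  if (sum(dynamics_props) > 1 + 1e-9)
    stop("class proportions must sum to <= 1")
  structure(as.list(environment()), class = "SimulationConfig")
}

# depth giving median expected count ~target over pixels in the given
# separation band (pixel-weighted median separation)
auto_depth <- function(n, alpha, target = 5, dmin = 1L, dmax = n - 1L) {
  d <- dmin:dmax
  w <- n - d                        # pairs per separation
  cw <- cumsum(w) / sum(w)
  dm <- d[which(cw >= 0.5)[1]]      # median separation over pixels
  target * dm^alpha
}

poisson_symmetric <- function(mu) {
  n <- nrow(mu)
  up <- which(upper.tri(mu, diag = TRUE))
  x <- stats::rpois(length(up), mu[up])
  M <- matrix(0, n, n)
  M[up] <- x
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

# compartment block partition with alternating signs
plant_blocks <- function(n_bins, block_len) {
  lens <- integer(0)
  tot <- 0L
  while (tot < n_bins) {
    l <- max(3L, stats::rpois(1L, block_len))
    lens <- c(lens, l); tot <- tot + l
  }
  lens[length(lens)] <- lens[length(lens)] - (tot - n_bins)
  start <- cumsum(c(1L, utils::head(lens, -1)))
  data.frame(region = seq_along(lens), start_bin = start,
             end_bin = start + lens - 1L,
             donor_sign = rep_len(c(1, -1), length(lens)))
}

#' Simulate a single contact matrix with planted structure
#'
#' Poisson-sampled counts around
#' `mu(i, j) = depth * d^(-alpha) * plaid(i, j) * tad(i, j) * loop(i, j)`,
#' where the plaid factor is `within_enrich^(v_i * v_j)` for per-bin
#' compartment values `v` (+1 = A, -1 = B at full strength), the TAD factor
#' is `tad_enrich` inside planted domains and the loop factor `loop_enrich`
#' on planted focal pixels.
#'
#' @param cfg a `SimulationConfig`.
#' @param v optional per-bin compartment values; planted afresh when `NULL`.
#' @param with_tads,with_loops include domain / focal structure.
#' @param noise `"poisson"` or `"none"` (returns the expected counts).
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return list with `matrix` (a `ContactMatrix`), `truth` (list with
#'   `v`, `blocks`, `tads`, `loops`, `mu`) and `activity` (a per-bin
#'   reference signal correlated with planted A bins).
#' @export
simulate_contact_matrix <- function(cfg = sim_config(), v = NULL,
                                    with_tads = FALSE, with_loops = FALSE,
                                    noise = c("poisson", "none"),
                                    seed = NULL) {
  noise <- match.arg(noise)
  set.seed(if (is.null(seed)) cfg$seed else seed)
  n <- cfg$n_bins
  blocks <- NULL
  if (is.null(v)) {
    blocks <- plant_blocks(n, cfg$block_len)
    v <- numeric(n)
    for (k in seq_len(nrow(blocks)))
      v[blocks$start_bin[k]:blocks$end_bin[k]] <- blocks$donor_sign[k]
  }
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  depth <- if (identical(cfg$depth, "auto")) {
    if (with_loops)
      auto_depth(n, cfg$alpha,
                 dmin = max(1L, ceiling(cfg$loop_band[1] / cfg$resolution)),
                 dmax = min(n - 1L, floor(cfg$loop_band[2] / cfg$resolution)))
    else auto_depth(n, cfg$alpha)
  } else cfg$depth
  mu <- depth * pmax(d, 1)^(-cfg$alpha) * cfg$within_enrich^outer(v, v)
  tads <- NULL
  if (with_tads) {
    tads <- plant_tads(n, cfg$n_tads, cfg$tad_size_range)
    for (k in seq_len(nrow(tads))) {
      ix <- tads$start_bin[k]:tads$end_bin[k]
      mu[ix, ix] <- mu[ix, ix] * cfg$tad_enrich
    }
  }
  loops <- NULL
  if (with_loops) {
    loops <- plant_loops(n, cfg$n_loops, cfg$loop_band, cfg$resolution)
    # punctate focal peaks bleed into adjacent pixels at bin-size anchors,
    # so the enrichment covers the 3x3 vicinity of the anchor pair
    for (k in seq_len(nrow(loops))) {
      i <- loops$bin1[k]; j <- loops$bin2[k]
      ri <- max(1L, i - 1L):min(n, i + 1L)
      rj <- max(1L, j - 1L):min(n, j + 1L)
      mu[ri, rj] <- mu[ri, rj] * cfg$loop_enrich
      mu[rj, ri] <- t(mu[ri, rj])
    }
  }
  if (cfg$bin_bias_sd > 0) {
    b <- exp(stats::rnorm(n, 0, cfg$bin_bias_sd))
    mu <- mu * outer(b, b)
  }
  counts <- if (noise == "poisson") poisson_symmetric(mu) else mu
  m <- contact_matrix(counts, chrom = "chrS", resolution = cfg$resolution,
                      mask = which(rowSums(counts) == 0))
  activity <- pmax(0, 1 + v) + abs(stats::rnorm(n, 0, 0.05))
  list(matrix = m,
       truth = list(v = v, blocks = blocks, tads = tads, loops = loops,
                    mu = mu, depth = depth),
       activity = activity)
}

plant_tads <- function(n_bins, n_tads, size_range) {
  sizes <- sample(size_range[1]:size_range[2], n_tads, replace = TRUE)
  gaps <- sample(5:12, n_tads + 1L, replace = TRUE)
  need <- sum(sizes) + sum(gaps)
  if (need > n_bins)
    stop("chromosome too short for requested TADs")
  start <- cumsum(gaps[seq_len(n_tads)]) +
    cumsum(c(0L, utils::head(sizes, -1)))
  data.frame(tad = seq_len(n_tads), start_bin = start,
             end_bin = start + sizes - 1L)
}

# Loop anchors separated by a log-normal distance (median ~300 kb, the
# scale of published loop-size distributions), truncated to the band.
plant_loops <- function(n_bins, n_loops, band_bp, resolution) {
  dmin <- ceiling(band_bp[1] / resolution)
  dmax <- min(floor(band_bp[2] / resolution), n_bins - 2L)
  out <- data.frame(bin1 = integer(), bin2 = integer())
  tries <- 0L
  while (nrow(out) < n_loops && tries < 200L * n_loops) {
    tries <- tries + 1L
    sep_bp <- stats::rlnorm(1L, meanlog = log(3e5), sdlog = 0.6)
    sep <- as.integer(round(sep_bp / resolution))
    if (sep < dmin || sep > dmax) next
    i <- sample(seq_len(n_bins - sep), 1L)
    j <- i + sep
    if (nrow(out) == 0L ||
        all(abs(out$bin1 - i) > 3L | abs(out$bin2 - j) > 3L))
      out <- rbind(out, data.frame(bin1 = i, bin2 = j))
  }
  out
}

#' Simulate a multi-condition compartment series with planted dynamics
#'
#' Plants donor-cell compartment blocks, flips a `switch_frac` fraction of
#' regions in the ESC state, assigns each switched region a dynamics class,
#' and derives per-condition per-bin compartment values: donor (CC) keeps
#' the donor sign; the two fESC lines carry the ESC state; the two ntESC
#' lines sit on the donor-to-ESC trajectory at the class position (Repro at
#' the fESC value, Partial at the midpoint, Hyper at `hyper_scale` times the
#' fESC value, Resis at the donor value). Each line is an independent
#' Poisson draw from its condition's expected map. Optionally adds MEF,
#' iPSC and E14 conditions for process comparison: MEF shares the CC state
#' on most regions (a planted subset differs), E14 equals the fESC state,
#' and iPSC reaches the ESC state except on iPSC-resistant regions.
#'
#' @param cfg a `SimulationConfig`.
#' @param conditions character vector of conditions to emit; line pairs
#'   NT5/NT6 and F35/F40 share a condition mean.
#' @param mef_diff_frac fraction of regions where the MEF state differs
#'   from CC (donor-specific material).
#' @param ipsc_resis_frac fraction of MEF-switched regions resistant in the
#'   iPSC process.
#' @return list with `matrices` (named list of `ContactMatrix`), `truth`
#'   (region table with per-condition signs and planted classes, per-bin
#'   values per condition) and `activity`.
#' @export
simulate_condition_series <- function(cfg = sim_config(),
                                      conditions = c("CC", "NT5", "NT6",
                                                     "F35", "F40"),
                                      mef_diff_frac = 0.3,
                                      ipsc_resis_frac = 0.1) {
  set.seed(cfg$seed)
  n <- cfg$n_bins
  blocks <- plant_blocks(n, cfg$block_len)
  nr <- nrow(blocks)
  n_switch <- round(cfg$switch_frac * nr)
  switched <- sort(sample(nr, n_switch))
  cls <- rep("stable", nr)
  if (n_switch > 0) {
    props <- cfg$dynamics_props / sum(cfg$dynamics_props)
    cls[switched] <- sample(names(props), n_switch, replace = TRUE,
                            prob = props)
  }
  blocks$class <- cls
  blocks$esc_sign <- ifelse(cls == "stable", blocks$donor_sign,
                            -blocks$donor_sign)
  # trajectory position of the ntESC value
  r_of <- c(stable = 1, Repro = 1, Partial = 0.5, Hyper = cfg$hyper_scale,
            Resis = 0)
  blocks$nt_value <- blocks$donor_sign +
    r_of[cls] * (blocks$esc_sign - blocks$donor_sign)
  # optional iPSC-process conditions
  extra <- intersect(conditions, c("MEF", "iPSC", "E14"))
  if (length(extra)) {
    mef_diff <- sort(sample(nr, round(mef_diff_frac * nr)))
    blocks$mef_sign <- blocks$donor_sign
    blocks$mef_sign[mef_diff] <- -blocks$donor_sign[mef_diff]
    # iPSC reaches the ESC state except on its own resistant regions
    mef_sw <- which(blocks$mef_sign != blocks$esc_sign)
    ip_res <- mef_sw[stats::runif(length(mef_sw)) < ipsc_resis_frac]
    blocks$ipsc_sign <- blocks$esc_sign
    blocks$ipsc_sign[ip_res] <- blocks$mef_sign[ip_res]
  }
  expand <- function(vals) {
    v <- numeric(n)
    for (k in seq_len(nr)) v[blocks$start_bin[k]:blocks$end_bin[k]] <- vals[k]
    v
  }
  vcond <- list(CC = expand(blocks$donor_sign),
                NT = expand(blocks$nt_value),
                F = expand(blocks$esc_sign))
  if ("MEF" %in% extra) vcond$MEF <- expand(blocks$mef_sign)
  if ("iPSC" %in% extra) vcond$iPSC <- expand(blocks$ipsc_sign)
  if ("E14" %in% extra) vcond$E14 <- expand(blocks$esc_sign)
  cond_of <- c(CC = "CC", NT5 = "NT", NT6 = "NT", F35 = "F", F40 = "F",
               MEF = "MEF", iPSC = "iPSC", E14 = "E14")
  if (!all(conditions %in% names(cond_of)))
    stop("conditions requested without trajectory entries: ",
         paste(setdiff(conditions, names(cond_of)), collapse = ", "))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  depth <- if (identical(cfg$depth, "auto")) auto_depth(n, cfg$alpha)
  else cfg$depth
  decay <- depth * pmax(d, 1)^(-cfg$alpha)
  matrices <- lapply(conditions, function(cd) {
    v <- vcond[[cond_of[cd]]]
    mu <- decay * cfg$within_enrich^outer(v, v)
    counts <- poisson_symmetric(mu)
    contact_matrix(counts, chrom = "chrS", resolution = cfg$resolution,
                   mask = which(rowSums(counts) == 0))
  })
  names(matrices) <- conditions
  activity <- pmax(0, 1 + vcond$F) + abs(stats::rnorm(n, 0, 0.05))
  list(matrices = matrices,
       truth = list(blocks = blocks, v = vcond),
       activity = activity)
}

#' Simulate switched-compartment PC1 records with planted classes
#'
#' Directly plants condition-mean PC1 triples for switched regions: the
#' donor and fESC values sit at opposite signs and the ntESC value at the
#' class's trajectory position `r` (Resis 0.05, Partial 0.5, Repro 1.0,
#' Hyper 1.4 by default), plus Gaussian noise on each PC1.
#'
#' The donor magnitude is set below the ESC magnitude so that the PC1 zero
#' crossing sits below the mid-trajectory position: a Partial compartment
#' is by definition intermediate *with the ESC sign*, so planted Partials
#' at r = 0.5 must land past zero to be realizable at all.
#'
#' @param n_regions number of switched regions.
#' @param r_means named trajectory positions per class.
#' @param sigma PC1 noise sd.
#' @param magnitude_cc,magnitude_f donor and fESC PC1 magnitudes.
#' @param seed RNG seed.
#' @return data.frame `cc_pc1`, `nt_pc1`, `f_pc1`, `class` (planted truth).
#' @export
simulate_dynamics_records <- function(n_regions = 200L,
                                      r_means = c(Resis = 0.05,
                                                  Partial = 0.5,
                                                  Repro = 1.0,
                                                  Hyper = 1.4),
                                      sigma = 0.05, magnitude_cc = 0.4,
                                      magnitude_f = 0.8,
                                      seed = 1L) {
  set.seed(seed)
  cls <- sample(names(r_means), n_regions, replace = TRUE)
  dir <- sample(c(-1, 1), n_regions, replace = TRUE)  # B-to-A or A-to-B
  cc <- -dir * magnitude_cc + stats::rnorm(n_regions, 0, sigma)
  f <- dir * magnitude_f + stats::rnorm(n_regions, 0, sigma)
  nt <- cc + r_means[cls] * (f - cc) + stats::rnorm(n_regions, 0, sigma)
  data.frame(cc_pc1 = cc, nt_pc1 = nt, f_pc1 = f,
             class = factor(cls, levels = names(r_means)))
}

#' Simulate a three-condition TAD series with planted RTI dynamics
#'
#' Plants domains on a TAD-resolution chromosome and assigns each a
#' dynamics class. Per condition, the intra-domain enrichment follows the
#' trajectory: donor TADs at `tad_enrich`, fESC TADs weakened to
#' `esc_enrich`, ntESC at the class position between them.
#'
#' @param cfg a `SimulationConfig`.
#' @param esc_enrich intra-domain enrichment in the ESC conditions
#'   (weaker than the donor's `tad_enrich`, mirroring boundary weakening
#'   during reprogramming).
#' @param classes optional vector of planted classes per TAD (recycled);
#'   default all `"Repro"`.
#' @param noise `"poisson"` or `"none"`.
#' @return list with `matrices` (CC/NT/F `ContactMatrix`), `truth` (TAD
#'   table with planted classes and per-condition enrichments).
#' @export
simulate_tad_series <- function(cfg = sim_config(), esc_enrich = 2,
                                classes = "Repro",
                                noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  set.seed(cfg$seed)
  n <- cfg$tad_n_bins
  tads <- plant_tads(n, cfg$n_tads, cfg$tad_size_range)
  tads$class <- rep_len(classes, nrow(tads))
  r_of <- c(Static = 1, Repro = 1, Resis = 0, Hyper = cfg$hyper_scale)
  e_cc <- rep(cfg$tad_enrich, nrow(tads))
  e_f <- ifelse(tads$class == "Static", e_cc, esc_enrich)
  e_nt <- e_cc + r_of[tads$class] * (e_f - e_cc)
  tads$e_cc <- e_cc; tads$e_nt <- e_nt; tads$e_f <- e_f
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  depth <- if (identical(cfg$depth, "auto")) auto_depth(n, cfg$alpha)
  else cfg$depth
  decay <- depth * pmax(d, 1)^(-cfg$alpha)
  build <- function(e_vec) {
    mu <- decay
    for (k in seq_len(nrow(tads))) {
      ix <- tads$start_bin[k]:tads$end_bin[k]
      mu[ix, ix] <- mu[ix, ix] * e_vec[k]
    }
    counts <- if (noise == "poisson") poisson_symmetric(mu) else mu
    contact_matrix(counts, chrom = "chrS", resolution = cfg$tad_resolution,
                   mask = which(rowSums(counts) == 0))
  }
  list(matrices = list(CC = build(e_cc), NT = build(e_nt), F = build(e_f)),
       truth = tads)
}

#' Simulate an ATAC peak-intensity matrix with five planted archetypes
#'
#' Archetype mean log2 intensities over samples (CC, NT5, NT6, F35, F40):
#' C1 open everywhere, C2 donor-specific, C3 ESC-shared, C4 ESC-specific
#' with fESC 2 log2 units above ntESC, C5 the reverse. Peaks get log-normal
#' noise (sd `peak_sigma` in log2 units) around their archetype and raw
#' intensities `2^x`; sample depths differ to exercise CPM normalisation.
#'
#' @param cfg a `SimulationConfig`.
#' @param n_per_class peaks per archetype (C1..C5).
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return list with `pm` (a raw `PeakMatrix`) and `truth` (planted labels).
#' @export
simulate_peak_matrix <- function(cfg = sim_config(),
                                 n_per_class = c(C1 = 400L, C2 = 300L,
                                                 C3 = 300L, C4 = 150L,
                                                 C5 = 150L),
                                 seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed else seed)
  samples <- c("CC", "NT5", "NT6", "F35", "F40")
  arch <- rbind(C1 = c(6, 6, 6, 6, 6),
                C2 = c(7, 1, 1, 1, 1),
                C3 = c(1, 6, 6, 6, 6),
                C4 = c(1, 3, 3, 5, 5),
                C5 = c(1, 5, 5, 3, 3))
  colnames(arch) <- samples
  labels <- rep(names(n_per_class), n_per_class)
  np <- length(labels)
  logi <- arch[labels, ] + matrix(stats::rnorm(np * 5, 0, cfg$peak_sigma),
                                  np, 5)
  raw <- 2^logi
  depth_factor <- c(1, 1.4, 0.8, 1.2, 0.9)
  raw <- sweep(raw, 2L, depth_factor, "*")
  peaks <- data.frame(chrom = "chrS",
                      start = seq_len(np) * 2000L,
                      end = seq_len(np) * 2000L + 500L)
  pm <- peak_matrix(peaks, raw, samples)
  list(pm = pm, truth = labels)
}

#' Simulate a ChIP/Input track and expression table from planted truth
#'
#' The ChIP/Input ratio is log-normal with mean `chip_marked_mean` inside
#' planted marked regions and `chip_unmarked_mean` elsewhere. Expression is
#' planted so that genes in resistant A-to-B regions are lower in the ESC
#' conditions than in the donor, while other groups have no systematic
#' condition effect.
#'
#' @param cfg a `SimulationConfig`.
#' @param regions data.frame with `start`, `end` (bp), `group` and logical
#'   `marked` (the planted truth).
#' @param genes_per_region genes planted per region.
#' @param resolution signal interval width in bp.
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return list with `track` (bedGraph-style data.frame), `expr`
#'   (gene/chrom/tss + FPKM per condition CC/NT/F).
#' @export
simulate_signal_and_expression <- function(cfg = sim_config(), regions,
                                           genes_per_region = 5L,
                                           resolution = 2e4,
                                           seed = NULL) {
  if (is.null(regions$marked)) stop("truth regions must carry 'marked'")
  set.seed(if (is.null(seed)) cfg$seed else seed)
  len <- max(regions$end)
  n_iv <- ceiling(len / resolution)
  start <- (seq_len(n_iv) - 1L) * resolution
  end <- pmin(start + resolution, len)
  mid <- (start + end) / 2
  in_marked <- vapply(mid, function(x)
    any(x >= regions$start & x < regions$end & regions$marked), logical(1))
  mu <- ifelse(in_marked, cfg$chip_marked_mean, cfg$chip_unmarked_mean)
  ratio <- exp(log(mu) + stats::rnorm(n_iv, 0, cfg$chip_sigma))
  track <- data.frame(chrom = "chrS", start = start, end = end,
                      ratio = ratio)
  rows <- lapply(seq_len(nrow(regions)), function(k) {
    tss <- round(seq(regions$start[k], regions$end[k] - 1,
                     length.out = genes_per_region))
    base <- exp(stats::rnorm(genes_per_region, log(10), 0.4))
    lowered <- regions$group[k] == "Resis_AtoB"
    data.frame(gene = sprintf("g%03d_%02d", k, seq_len(genes_per_region)),
               chrom = "chrS", tss = tss,
               CC = base * exp(stats::rnorm(genes_per_region, 0, 0.2)),
               NT = base * (if (lowered) 0.25 else 1) *
                 exp(stats::rnorm(genes_per_region, 0, 0.2)),
               F = base * (if (lowered) 0.25 else 1) *
                 exp(stats::rnorm(genes_per_region, 0, 0.2)))
  })
  list(track = track, expr = do.call(rbind, rows))
}
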