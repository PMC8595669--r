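# insulation scores, boundaries, TADs, RTI, TAD dynamics

test_that("insulation score has closed-form behaviour on toy matrices", {
  # uniform matrix -> score 0 wherever defined
  m <- contact_matrix(matrix(2, 30, 30), resolution = 4e4, balanced = TRUE)
  t1 <- insulation_track(m, window = 4 * 4e4)
  expect_equal(t1$score[!is.na(t1$score)],
               rep(0, sum(!is.na(t1$score))), tolerance = 1e-12)
  # edges undefined
  expect_true(all(is.na(t1$score[1:4])))

  # 12-bin two-block matrix: unique minimum at the junction
  W <- matrix(1, 12, 12)
  W[1:6, 1:6] <- 4; W[7:12, 7:12] <- 4
  mb <- contact_matrix(W, resolution = 4e4, balanced = TRUE)
  t2 <- insulation_track(mb, window = 3 * 4e4)
  # hand-computed diamonds (window 3): bins 4..9 defined;
  # diamond at bin i spans rows i-3..i-1, cols i+1..i+3
  hand <- sapply(4:9, function(i)
    mean(W[(i - 3):(i - 1), (i + 1):(i + 3)]))
  expect_equal(t2$score[4:9], log2(hand / mean(hand)), tolerance = 1e-12)
  expect_equal(which.min(t2$score), 6)

  # scale invariance
  t3 <- insulation_track(contact_matrix(2 * W, resolution = 4e4,
                                        balanced = TRUE), window = 3 * 4e4)
  expect_equal(t3$score, t2$score, tolerance = 1e-12)
  expect_error(insulation_track(mb, window = 4e4), "at least 2 bins")
})

test_that("boundary calling finds contrasted local minima and merges close ones", {
  mk <- function(score) structure(list(chrom = "chrS", resolution = 4e4,
                                       window = 12e4, score = score),
                                  class = "InsulationTrack")
  # monotone track -> no boundaries
  expect_equal(nrow(call_boundaries(mk(seq(-1, 1, length.out = 20)))), 0L)
  # two minima 1 bin apart -> keep the deeper
  s <- c(1, 1, 0.9, -0.5, -0.8, 0.9, 1, 1, 1, 1)
  b <- call_boundaries(mk(s), min_delta = 0.1)
  expect_equal(b$bin, 5L)
  expect_error(call_boundaries(mk(rep(NA_real_, 10))), "undefined")
})

test_that("planted TAD boundaries are recovered within one bin", {
  cfg <- sim_config(seed = 5, tad_n_bins = 600, n_tads = 10)
  ts <- simulate_tad_series(cfg, classes = "Static")
  m <- balance_matrix(mask_low_coverage(ts$matrices$CC))
  bounds <- call_boundaries(insulation_track(m, window = 480e3),
                            min_delta = 0.1)
  truth_b <- sort(c(ts$truth$start_bin, ts$truth$end_bin + 1L))
  hit <- vapply(truth_b, function(tb) any(abs(bounds$bin - tb) <= 1),
                logical(1))
  expect_gte(mean(hit), 0.9)
  false_b <- sum(vapply(bounds$bin, function(cb)
    all(abs(truth_b - cb) > 1), logical(1)))
  expect_lte(false_b, 1)
})

test_that("TAD assembly from boundaries applies the length rule", {
  b <- data.frame(bin = c(10L, 20L, 30L), insulation = 0, strength = 1)
  tads <- boundaries_to_tads(b, resolution = 4e4)
  expect_equal(tads$start_bin, c(10L, 20L))
  expect_equal(tads$end_bin, c(19L, 29L))
  expect_equal(tads$start, c(9, 19) * 4e4)
  b2 <- data.frame(bin = c(10L, 11L), insulation = 0, strength = 1)
  expect_equal(nrow(boundaries_to_tads(b2, resolution = 4e4)), 0L)
})

test_that("aggregate boundary profile shows quadrant depletion", {
  # uniform O/E -> constant aggregate
  oe <- contact_matrix(matrix(1, 100, 100), resolution = 4e4)
  b <- data.frame(bin = 50L)
  prof <- aggregate_boundary_profile(oe, b, flank = 5 * 4e4)
  expect_equal(prof, matrix(1, 11, 11), tolerance = 1e-12)
  expect_error(aggregate_boundary_profile(oe, data.frame(bin = 2L),
                                          flank = 5 * 4e4), "eligible")

  # planted 2x insulation: cross-boundary quadrants depleted
  W <- matrix(1, 100, 100)
  for (a in list(1:50, 51:100)) W[a, a] <- 2
  oeb <- contact_matrix(W, resolution = 4e4)
  p2 <- aggregate_boundary_profile(oeb, data.frame(bin = c(51L)),
                                   flank = 5 * 4e4)
  within_q <- mean(c(p2[1:5, 1:5], p2[7:11, 7:11]))
  across_q <- mean(p2[7:11, 1:5])
  expect_gte(within_q / across_q, 1.5)
})

test_that("RTI matches hand computation and is monotone in enrichment", {
  # all-ones O/E -> RTI 1
  oe1 <- contact_matrix(matrix(1, 30, 30), resolution = 4e4)
  tad <- data.frame(start_bin = 11L, end_bin = 20L)
  expect_equal(relative_tad_intensity(oe1, tad), 1, tolerance = 1e-12)

  # 9-bin toy: intra 3, inter 1 -> RTI 3
  W <- matrix(1, 9, 9)
  W[4:6, 4:6] <- 3
  oe3 <- contact_matrix(W, resolution = 4e4)
  expect_equal(relative_tad_intensity(
    oe3, data.frame(start_bin = 4L, end_bin = 6L)), 3, tolerance = 1e-12)

  # scaling intra by c > 1 strictly increases RTI
  W2 <- W; W2[4:6, 4:6] <- 4.5
  expect_gt(relative_tad_intensity(contact_matrix(W2, resolution = 4e4),
                                   data.frame(start_bin = 4L, end_bin = 6L)),
            3)
})

test_that("TAD dynamics rules and specificity labels are total and correct", {
  expect_equal(as.character(classify_tad_dynamics(2, 2, 2, fold = 1.5)),
               "Static")
  expect_equal(as.character(classify_tad_dynamics(3, 1.55, 1.5,
                                                  fold = 1.5, delta = 0.15)),
               "Repro")
  expect_equal(as.character(classify_tad_dynamics(3, 2.9, 1.5)), "Resis")
  expect_equal(as.character(classify_tad_dynamics(3, 0.8, 1.5)), "Hyper")

  # planted four-group triples with 5% multiplicative noise -> >= 90%
  set.seed(21)
  n <- 200
  cls <- sample(c("Static", "Repro", "Resis", "Hyper"), n, replace = TRUE)
  r_of <- c(Static = 1, Repro = 1, Resis = 0, Hyper = 1.4)
  cc <- rep(3, n)
  f <- ifelse(cls == "Static", 3, 1.5)
  nt <- cc + r_of[cls] * (f - cc)
  noise <- function(x) x * exp(stats::rnorm(n, 0, 0.05))
  lab <- classify_tad_dynamics(noise(cc), noise(nt), noise(f))
  expect_gt(mean(as.character(lab) == cls), 0.9)

  expect_equal(as.character(specific_tads(3, 1, fold = 1.5)), "CC-specific")
  expect_equal(as.character(specific_tads(1, 1)), "unspecific")
  expect_equal(as.character(specific_tads(1, 3)), "ESC-specific")
  # exact recovery at zero noise
  lab2 <- specific_tads(cc, f, fold = 1.5)
  expect_true(all(as.character(lab2)[cls != "Static"] == "CC-specific"))
  expect_true(all(as.character(lab2)[cls == "Static"] == "unspecific"))
})

test_that("donor boundaries are stronger than ESC boundaries in the weakened world", {
  cfg <- sim_config(seed = 15, tad_n_bins = 500, n_tads = 8)
  ts <- simulate_tad_series(cfg, esc_enrich = 1.8, classes = "Repro")
  strength <- function(m) {
    b <- call_boundaries(insulation_track(
      balance_matrix(mask_low_coverage(m)), window = 480e3), min_delta = 0.05)
    mean(b$strength)
  }
  expect_gt(strength(ts$matrices$CC), strength(ts$matrices$F))
})

test_that("consensus boundaries pool conditions within one bin", {
  b1 <- data.frame(bin = c(10L, 30L), insulation = -1, strength = 0.5)
  b2 <- data.frame(bin = c(11L, 50L), insulation = -1, strength = 0.5)
  b3 <- data.frame(bin = c(10L, 30L, 50L), insulation = -1, strength = 0.5)
  cons <- consensus_boundaries(list(b1, b2, b3), min_support = 2L,
                               resolution = 4e4)
  expect_equal(cons$bin, c(10L, 30L, 50L))
})
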