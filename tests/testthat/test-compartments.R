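# A/B compartment calling, switches, dynamics classes, process comparison

make_track <- function(pc1, resolution = 2e5) {
  state <- ifelse(is.na(pc1) | pc1 == 0, NA_character_,
                  ifelse(pc1 > 0, "A", "B"))
  out <- data.frame(bin = seq_along(pc1) - 1L,
                    start = (seq_along(pc1) - 1L) * resolution,
                    end = seq_along(pc1) * resolution,
                    pc1 = pc1, state = factor(state, levels = c("A", "B")))
  attr(out, "resolution") <- resolution
  attr(out, "chrom") <- "chrS"
  class(out) <- c("CompartmentTrack", "data.frame")
  out
}

test_that("O/E correlation matrix matches the direct Pearson formula", {
  raw <- random_symmetric(15, seed = 2)
  oe <- observed_over_expected(contact_matrix(raw, resolution = 2e5))
  C <- pearson_oe_matrix(oe)
  expect_equal(C, oracle_pearson(oe$counts), tolerance = 1e-9)
  expect_equal(diag(C), rep(1, 15), tolerance = 1e-12)
  small <- contact_matrix(random_symmetric(5, 1), resolution = 2e5)
  expect_error(pearson_oe_matrix(observed_over_expected(small)),
               "fewer than 10")
})

test_that("PC1 splits block structure and fails on degenerate input", {
  # 12-bin two-block checkerboard correlation
  v <- rep(c(1, -1), each = 6)
  C <- outer(v, v)
  p <- compute_pc1(C)
  expect_true(all(sign(p[1:6]) == sign(p[1])))
  expect_true(all(sign(p[7:12]) == -sign(p[1])))
  expect_equal(sum(p^2), 1, tolerance = 1e-12)

  # 6-bin alternating plaid: signs alternate, agreeing with a full
  # eigendecomposition of the centred matrix
  v2 <- rep(c(1, -1), 3)
  oe <- contact_matrix(2^outer(v2, v2) + 0, resolution = 2e5)
  Xc <- scale(oe$counts, center = TRUE, scale = FALSE)
  ev <- eigen(t(Xc) %*% Xc)$vectors[, 1]
  p2 <- compute_pc1(oe$counts)
  expect_equal(abs(stats::cor(p2, as.numeric(Xc %*% ev))), 1,
               tolerance = 1e-9)
  expect_true(all(p2[c(1, 3, 5)] * p2[c(2, 4, 6)] < 0))

  expect_error(compute_pc1(matrix(1, 12, 12)), "no principal axis")
})

test_that("orientation follows the activity reference and assigns states", {
  pc1 <- c(0.5, 0.5, -0.5, -0.5)
  act <- c(0, 0, 3, 3)                    # anti-correlated -> flip
  tr <- orient_and_call(pc1, act)
  expect_equal(tr$pc1, -pc1)
  expect_equal(as.character(tr$state), c("B", "B", "A", "A"))
  tr2 <- orient_and_call(-pc1, act)       # already aligned -> unchanged
  expect_equal(tr2$pc1, -pc1)
  expect_error(orient_and_call(pc1, rep(2, 4)), "zero-variance")
})

test_that("PC1 state recovers planted plaid labels end to end", {
  sim <- simulate_contact_matrix(sim_config(seed = 3, n_bins = 300))
  oe <- observed_over_expected(balance_matrix(mask_low_coverage(sim$matrix)))
  tr <- call_compartments(oe, sim$activity)
  truth <- ifelse(sim$truth$v > 0, "A", "B")
  ok <- !is.na(tr$state)
  expect_gt(mean(as.character(tr$state)[ok] == truth[ok]), 0.95)
})

test_that("compartment strength matches the generative saddle ratio", {
  ones <- contact_matrix(matrix(1, 40, 40), resolution = 2e5)
  tr <- make_track(rep(c(0.5, -0.5), 20))
  expect_equal(compartment_strength(ones, tr), 1, tolerance = 1e-12)

  # exact plaid O/E: within 2, between 0.5 -> strength 4
  v <- rep(c(1, -1), each = 20)
  plaid <- contact_matrix(2^outer(v, v) + 0, resolution = 2e5)
  trv <- make_track(v / 2)
  expect_equal(compartment_strength(plaid, trv), 4, tolerance = 0.4)

  stronger <- contact_matrix(3^outer(v, v) + 0, resolution = 2e5)
  expect_gt(compartment_strength(stronger, trv),
            compartment_strength(plaid, trv))
  expect_error(compartment_strength(plaid, trv, n_quantiles = 1), ">= 2")

  # monotone in the planted within/between ratio through the full pipeline
  s_at <- function(w) {
    sim <- simulate_contact_matrix(sim_config(seed = 13, n_bins = 200,
                                              within_enrich = w))
    oe <- observed_over_expected(balance_matrix(mask_low_coverage(sim$matrix)))
    compartment_strength(oe, call_compartments(oe, sim$activity))
  }
  s <- vapply(c(1.3, 1.7, 2.2), s_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("switch calling follows the sign rules and merges regions", {
  cc <- make_track(c(-0.5, -0.5, 0.5, 0.4, -0.3, 0.2))
  f1 <- make_track(c(0.4, 0.4, 0.4, -0.4, -0.3, 0.3))
  f2 <- make_track(c(0.4, 0.4, 0.4, -0.5, 0.2, 0.4))  # bin 5 disagrees
  nt <- make_track(c(0.3, 0.3, 0.4, -0.4, -0.2, 0.25))
  sw <- call_switches(cc, list(nt, nt), list(f1, f2))
  expect_equal(sw$bins$transition,
               c("B-to-A", "B-to-A", "stable", "A-to-B", NA, "stable"))
  # bins 1-2 merge into one B-to-A region
  bta <- sw$regions[sw$regions$transition == "B-to-A", ]
  expect_equal(nrow(bta), 1L)
  expect_equal(bta$n_bins, 2L)
  # percentages over defined bins only (5 defined)
  expect_equal(unname(sw$percent["B-to-A"]), 40)
  expect_equal(unname(sw$percent["A-to-B"]), 20)
})

test_that("planted switch fractions are recovered within one percentage point", {
  cfg <- sim_config(seed = 2, switch_frac = 0.2,
                    dynamics_props = c(Repro = 1, Partial = 0, Hyper = 0,
                                       Resis = 0))
  ser <- simulate_condition_series(cfg)
  tracks <- lapply(ser$matrices, function(m)
    call_compartments(observed_over_expected(
      balance_matrix(mask_low_coverage(m))), ser$activity))
  sw <- call_switches(tracks$CC, tracks[c("NT5", "NT6")],
                      tracks[c("F35", "F40")])
  blocks <- ser$truth$blocks
  tr_bin <- rep("stable", cfg$n_bins)
  for (k in which(blocks$class != "stable"))
    tr_bin[blocks$start_bin[k]:blocks$end_bin[k]] <-
      if (blocks$donor_sign[k] < 0) "B-to-A" else "A-to-B"
  planted <- 100 * table(factor(tr_bin, c("A-to-B", "B-to-A", "stable"))) /
    cfg$n_bins
  expect_lt(abs(sw$percent["B-to-A"] - planted["B-to-A"]), 1)
  expect_lt(abs(sw$percent["A-to-B"] - planted["A-to-B"]), 1)
})

test_that("dynamics classification implements the r-statistic rules", {
  rec <- data.frame(cc_pc1 = c(-0.6, -0.6, -0.6, -0.6),
                    nt_pc1 = c(0.59, -0.55, 0.15, 0.95),
                    f_pc1 = c(0.6, 0.6, 0.6, 0.6))
  cl <- classify_dynamics(rec, delta = 0.15)
  expect_equal(as.character(cl$class),
               c("Repro", "Resis", "Partial", "Hyper"))
  expect_equal(cl$r[1], (0.59 + 0.6) / 1.2, tolerance = 1e-12)

  # totality: every record gets exactly one class
  rec2 <- simulate_dynamics_records(n_regions = 150, seed = 4)
  cl2 <- classify_dynamics(rec2)
  expect_false(anyNA(cl2$class))
  expect_equal(sum(attr(cl2, "counts")), 150)

  # undefined trajectory skipped with a warning
  rec3 <- data.frame(cc_pc1 = -0.5, nt_pc1 = 0, f_pc1 = -0.5)
  expect_warning(cl3 <- classify_dynamics(rec3), "skipped")
  expect_true(is.na(cl3$class[1]))
  expect_error(classify_dynamics(rec, delta = 0.7), "delta")
})

test_that("planted four-class records are recovered at >= 90%", {
  rec <- simulate_dynamics_records(n_regions = 200, sigma = 0.05, seed = 11)
  cl <- classify_dynamics(rec, delta = 0.15)
  expect_gt(mean(as.character(cl$class) == as.character(rec$class)), 0.9)
})

test_that("process comparison applies the donor/method-specific taxonomy", {
  # CC=B, MEF=A, nt=A, iPSC=A, ESC=A -> NT-specific, donor-specific
  # CC=B, MEF=B, nt=A, iPSC=B, ESC=A -> NT-specific, method-specific
  # CC=B, MEF=B, nt=A, iPSC=A, ESC=A -> common
  cc <- make_track(c(-0.5, -0.5, -0.5))
  mef <- make_track(c(0.5, -0.5, -0.5))
  nt <- make_track(c(0.5, 0.5, 0.5))
  ip <- make_track(c(0.5, -0.5, 0.5))
  esc <- make_track(c(0.5, 0.5, 0.5))
  cp <- compare_processes(cc, mef, nt, ip, esc)
  expect_equal(cp$bins$category,
               c("NT-specific", "NT-specific", "common"))
  expect_equal(cp$bins$specificity,
               c("donor-specific", "method-specific", NA))
  expect_error(compare_processes(cc, NULL, nt, ip, esc), "missing")
})

test_that("planted five-condition categories are recovered exactly", {
  cfg <- sim_config(seed = 12, n_bins = 400, switch_frac = 0.3,
                    dynamics_props = c(Repro = 0.7, Partial = 0,
                                       Hyper = 0.1, Resis = 0.2))
  ser <- simulate_condition_series(
    cfg, conditions = c("CC", "NT5", "NT6", "F35", "F40", "MEF", "iPSC",
                        "E14"))
  tracks <- lapply(ser$matrices, function(m)
    call_compartments(observed_over_expected(
      balance_matrix(mask_low_coverage(m))), ser$activity))
  esc <- consensus_track(consensus_track(tracks$F35, tracks$F40),
                         tracks$E14)
  ntc <- consensus_track(tracks$NT5, tracks$NT6)
  cp <- compare_processes(tracks$CC, tracks$MEF, ntc, tracks$iPSC, esc)

  # truth-level categories per bin
  b <- ser$truth$blocks
  expand <- function(x) {
    v <- numeric(cfg$n_bins)
    for (k in seq_len(nrow(b))) v[b$start_bin[k]:b$end_bin[k]] <- x[k]
    v
  }
  cc_s <- expand(b$donor_sign); esc_s <- expand(b$esc_sign)
  mef_s <- expand(b$mef_sign); ip_s <- expand(b$ipsc_sign)
  nt_s <- expand(sign(b$nt_value))
  nt_sw <- cc_s != esc_s & nt_s == esc_s
  ip_sw <- mef_s != esc_s & ip_s == esc_s
  truth_cat <- rep(NA_character_, cfg$n_bins)
  truth_cat[nt_sw & ip_sw] <- "common"
  truth_cat[nt_sw & !ip_sw] <- "NT-specific"
  truth_cat[!nt_sw & ip_sw] <- "iPSC-specific"
  ok <- !is.na(cp$bins$category) | !is.na(truth_cat)
  expect_gt(mean((cp$bins$category == truth_cat)[ok], na.rm = TRUE), 0.95)
  # categories partition the switching set
  expect_equal(sum(!is.na(cp$bins$category)),
               sum(cp$bins$category %in%
                     c("common", "NT-specific", "iPSC-specific"),
                   na.rm = TRUE))
})

test_that("PC1 is scale invariant up to sign and orientation fixes it", {
  raw <- random_symmetric(20, seed = 6)
  oe <- observed_over_expected(contact_matrix(raw, resolution = 2e5))
  p1 <- compute_pc1(pearson_oe_matrix(oe))
  oe2 <- contact_matrix(7 * oe$counts, resolution = 2e5)
  p2 <- compute_pc1(pearson_oe_matrix(oe2))
  expect_equal(abs(stats::cor(p1, p2)), 1, tolerance = 1e-9)
  act <- p1 + stats::rnorm(20, 0, 0.01)
  t1 <- orient_and_call(p1, act)
  t2 <- orient_and_call(p2, act)
  expect_equal(sign(t1$pc1), sign(t2$pc1))
})
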