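test_that("normalization identities hold in both modes", {
  g <- small_genome()
  vals <- rep(100, nrow(make_bin_track(g, 2e5)))
  case <- fake_corrected(vals, g)
  # case identical to reference -> log2R identically 0
  prof <- normalize_profile(case, case, mode = "control")
  expect_true(all(abs(prof$log2r[prof$included]) < 1e-12))
  # self mode on a flat profile -> log2R identically 0
  prof2 <- normalize_profile(case, mode = "self")
  expect_true(all(abs(prof2$log2r[prof2$included]) < 1e-12))
  expect_equal(mean(prof2$log2r[prof2$included]), 0, tolerance = 1e-12)
})

test_that("a region at coverage ratio 0.8 lands at log2R = -0.322", {
  g <- small_genome()
  track <- make_bin_track(g, 2e5)
  vals <- rep(100, nrow(track))
  region <- track$chrom == "chr1" & track$start < 2e6
  case_vals <- vals
  case_vals[region] <- 80
  prof <- normalize_profile(fake_corrected(case_vals, g),
                            fake_corrected(vals, g), mode = "control")
  expect_equal(mean(prof$log2r[region & prof$included]), log2(0.8),
               tolerance = 0.01)
  expect_equal(median(prof$log2r[!region & prof$included]), 0,
               tolerance = 0.01)
})

test_that("zero-reference bins are excluded with a warning", {
  g <- small_genome()
  vals <- rep(100, nrow(make_bin_track(g, 2e5)))
  ref_vals <- vals
  ref_vals[5] <- 0
  expect_warning(
    prof <- normalize_profile(fake_corrected(vals, g),
                              fake_corrected(ref_vals, g), "control"),
    "zero reference")
  expect_false(prof$included[5])
})

test_that("segmentation recovers noiseless steps exactly", {
  x <- c(rep(0, 40), rep(-0.32, 30), rep(0, 30))
  prof <- fake_profile(x)
  seg <- segment_profile(prof)
  expect_equal(nrow(seg$segments), 3)
  expect_equal(seg$segments$start_bin, c(1, 41, 71))
  expect_equal(seg$segments$mean, c(0, -0.32, 0), tolerance = 1e-12)
})

test_that("flat noisy profiles stay unsegmented almost always", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    prof <- fake_profile(rnorm(120, 0, 0.05))
    nrow(segment_profile(prof)$segments)
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.95)
})

test_that("a -0.32 step in noise is found with near-exact breakpoints", {
  found <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- rnorm(120, 0, 0.05)
    x[41:80] <- x[41:80] - 0.32
    seg <- segment_profile(fake_profile(x))$segments
    nrow(seg) == 3 && abs(seg$start_bin[2] - 41) <= 3 &&
      abs(seg$start_bin[3] - 81) <= 3
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("tMAD equals the median absolute segmented deviation from zero", {
  # worked examples: median over per-bin segmented |log2R|
  seg1 <- segment_profile(fake_profile(c(rep(0, 4), rep(0.2, 6))),
                          penalty = 0.001, min_size = 2)
  expect_equal(compute_tmad(seg1), 0.2)
  seg2 <- segment_profile(fake_profile(c(rep(0, 6), rep(0.2, 4))),
                          penalty = 0.001, min_size = 2)
  expect_equal(compute_tmad(seg2), 0)
})

test_that("tMAD matches a brute-force oracle on random segmented profiles", {
  # oracle: assign each bin its segment mean, take median(|values|)
  for (s in 1:200) {
    set.seed(s)
    n_seg <- sample(2:4, 1)
    lens <- sample(5:12, n_seg, replace = TRUE)
    means <- round(rnorm(n_seg, 0, 0.3), 3)
    x <- rep(means, lens) + rnorm(sum(lens), 0, 1e-4)
    seg <- segment_profile(fake_profile(x))
    # independent route: bin-weighted median over the segment table
    oracle <- median(abs(rep(seg$segments$mean, seg$segments$n_bins)))
    expect_equal(compute_tmad(seg), oracle)
  }
})

test_that("the detection threshold is the cohort maximum", {
  expect_equal(detection_threshold_from_controls(c(0.004, 0.015, 0.01)),
               0.015)
  expect_equal(detection_threshold_from_controls(c(0.015, 0.004, 0.01)),
               0.015)
  expect_equal(detection_threshold_from_controls(c(0, 0)), 0)
  expect_error(detection_threshold_from_controls(0.01), "2 control")
})

test_that("detection is strict: at the threshold is negative, above is positive", {
  # mirrors the published rule: scores above 0.015 indicate SCNA
  thr <- detection_threshold_from_controls(c(0.004, 0.015))
  expect_false(0.015 > thr)
  expect_true(0.0151 > thr)
})

test_that("downsampling is exact, seeded, and identity at full size", {
  fr <- data.frame(chrom = "chr1", start = 1:5 * 100, end = 1:5 * 100 + 50)
  expect_identical(downsample_fragments(fr, 5, seed = 1), fr)
  a <- downsample_fragments(fr, 2, seed = 7)
  b <- downsample_fragments(fr, 2, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 2)
  expect_warning(downsample_fragments(fr, 10, seed = 1), "exceeds")
})

test_that("the full tMAD assay is deterministic and detects strong SCNA", {
  g <- small_genome()
  ctrl_cfg <- simulation_config(0, 1e5, gc_bias_strength = 0.3, seed = 1)
  ctrls <- simulate_control_cohort(5, ctrl_cfg, g, seed = 11)
  coh <- tmad_cohort(ctrls, g, bin_bp = 2e5, downsample_n = 1e5)
  cfg <- simulation_config(0.2, 1e5, rcc_like_scna(g),
                           gc_bias_strength = 0.3, seed = 2)
  fr <- simulate_sample(cfg, g)
  r1 <- run_tmad_assay(fr, coh, g, seed = 3)
  r2 <- run_tmad_assay(fr, coh, g, seed = 3)
  expect_equal(r1$tmad, r2$tmad)
  expect_true(r1$detected)
  expect_equal(r1$detected, r1$tmad > r1$threshold)
})

test_that("tMAD is monotone in tumor fraction for a fixed architecture", {
  g <- small_genome()
  ctrl_cfg <- simulation_config(0, 1e5, gc_bias_strength = 0.3, seed = 1)
  ctrls <- simulate_control_cohort(4, ctrl_cfg, g, seed = 19)
  coh <- tmad_cohort(ctrls, g, bin_bp = 2e5, downsample_n = 1e5)
  scna <- rcc_like_scna(g)
  tfs <- c(0, 0.05, 0.1, 0.2, 0.4)
  means <- vapply(tfs, function(tf) {
    mean(vapply(1:5, function(s) {
      cfg <- simulation_config(tf, 1e5, scna, gc_bias_strength = 0.3,
                               seed = 1000 * s + round(tf * 100))
      run_tmad_assay(simulate_sample(cfg, g), coh, g, seed = s)$tmad
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(means, tfs, method = "spearman"), 1)
})
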