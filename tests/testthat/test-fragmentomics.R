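test_that("size selection keeps both endpoints and is idempotent", {
  fr <- data.frame(chrom = "chr1", start = 0, end = c(89, 90, 150, 151),
                   length = c(89, 90, 150, 151))
  sel <- size_select(fr)
  expect_equal(sel$length, c(90, 150))
  expect_identical(size_select(sel), sel)
  expect_equal(nrow(size_select(fr[0, ])), 0)
  expect_error(size_select(fr, 150, 90), "below")
})

test_that("size selection enriches tumor-derived fragments", {
  g <- small_genome()
  cfg <- simulation_config(0.1, 1e5, seed = 41)
  fr <- simulate_sample(cfg, g)
  before <- mean(fr$source == "tumor")
  after <- mean(size_select(fr)$source == "tumor")
  expect_gt(after, before)
  expect_gt(after, 0.1)
})

test_that("range proportions use inclusive bounds", {
  h <- length_histogram(rep(100L, 100))
  expect_equal(proportion_in_range(h, 20, 150), 1.0)
  h2 <- length_histogram(c(rep(100L, 50), rep(200L, 50)))
  expect_equal(proportion_in_range(h2, 20, 150), 0.5)
  h3 <- length_histogram(rep(160:180, 1))
  expect_equal(proportion_in_range(h3, 163, 169), 7 / 21)
  expect_error(proportion_in_range(length_histogram(integer(0)), 20, 150),
               "empty")
})

test_that("amplitude_10bp reads the comb and ignores smooth shapes", {
  L <- 20:700
  # gently unimodal, comb-free: amplitude ~ 0
  smooth_counts <- round(1e5 * exp(-(L - 130)^2 / (2 * 30^2)))
  h_smooth <- structure(setNames(smooth_counts, L),
                        total = sum(smooth_counts),
                        class = "length_histogram")
  expect_lt(amplitude_10bp(h_smooth), 0.01)
  # analytic comb with amplitude 0.3
  comb_counts <- round(1e6 * (1 + 0.3 * cos(2 * pi * L / 10)))
  h_comb <- structure(setNames(comb_counts, L), total = sum(comb_counts),
                      class = "length_histogram")
  expect_equal(amplitude_10bp(h_comb), 0.3, tolerance = 0.05 * 0.3)
})

test_that("simulated periodicity raises the amplitude feature", {
  g <- small_genome()
  amps <- vapply(c(0, 0.2), function(a) {
    cfg <- simulation_config(0, 1e5,
                             length_model = fragment_length_model(
                               periodicity_amplitude = a),
                             seed = 47)
    amplitude_10bp(length_histogram(simulate_sample(cfg, g)))
  }, numeric(1))
  expect_gt(amps[2], amps[1])
})

test_that("the feature vector has the ten canonical features in order", {
  g <- small_genome()
  cfg <- simulation_config(0, 5e4, seed = 53)
  fr <- simulate_sample(cfg, g)
  feats <- compute_fragmentomics(fr, tmad = 0.01)
  expect_identical(names(feats), fragmentomics_feature_names())
  props <- unlist(feats[grep("^p_", names(feats))])
  expect_true(all(props >= 0 & props <= 1))
  # the mono-nucleosomal peak dominates a healthy sample
  expect_equal(names(props)[which.max(props)], "p_160_180")
  expect_identical(feats, compute_fragmentomics(fr, tmad = 0.01))
})

test_that("zero denominators produce a capped sentinel with a flag", {
  fr <- data.frame(chrom = "chr1", start = 0, end = 100,
                   length = rep(100L, 2000))
  feats <- compute_fragmentomics(fr, tmad = 0)
  expect_equal(feats$ratio_20_150_over_160_180, 1e6)
  expect_true("ratio_20_150_over_160_180" %in% attr(feats, "sentinel"))
})

test_that("triage model is seeded, separable on separated classes, and strict at 0.5", {
  set.seed(99)
  n <- 25
  high <- data.frame(matrix(rnorm(n * 10, mean = 2), n, 10))
  low <- data.frame(matrix(rnorm(n * 10, mean = 0), n, 10))
  names(high) <- names(low) <- fragmentomics_feature_names()
  tab <- rbind(low, high)
  labels <- rep(c("control", "cancer"), each = n)
  m1 <- train_triage_model(tab, factor(labels, c("control", "cancer")),
                           seed = 5)
  m2 <- train_triage_model(tab, factor(labels, c("control", "cancer")),
                           seed = 5)
  p1 <- predict_triage(m1, tab)
  expect_identical(p1, predict_triage(m2, tab))
  expect_true(all(p1$probability_cancer[(n + 1):(2 * n)] > 0.5))
  # the flag is exactly the strict rule
  expect_identical(p1$triaged_positive, p1$probability_cancer > 0.5)
  expect_false(isTRUE(0.5 > 0.5))
})

test_that("triage training rejects degenerate inputs", {
  tab <- data.frame(matrix(rnorm(400), 40, 10))
  names(tab) <- fragmentomics_feature_names()
  expect_error(train_triage_model(tab, rep("a", 40), seed = 1), "two classes")
  expect_error(train_triage_model(tab, rep(c("a", "b"), c(35, 5)), seed = 1),
               "per class")
})

test_that("size-selected tMAD applies the eligibility gate exactly", {
  g <- small_genome()
  fr <- data.frame(chrom = "chr1", start = 0, end = 100,
                   length = rep(100L, 5000))
  # below the floor: ineligible, no score
  res <- size_selected_tmad(fr, list(), g, min_fragments = 5001)
  expect_false(res$eligible)
  expect_null(res$result)
  expect_equal(res$n_selected, 5000)
  # the default floor is the 2-million-read rule
  expect_equal(formals(size_selected_tmad)$min_fragments, 2e6)
})
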