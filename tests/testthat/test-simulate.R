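test_that("simulation emits exactly n_fragments and honors tf = 0", {
  g <- small_genome()
  cfg <- simulation_config(tumor_fraction = 0, n_fragments = 20000, seed = 3)
  fr <- simulate_sample(cfg, g)
  expect_equal(nrow(fr), 20000)
  expect_true(all(fr$source == "normal"))
  expect_true(all(fr$length == fr$end - fr$start))
  expect_true(all(fr$length >= 20))
  expect_true(all(fr$start >= 0))
})

test_that("identical config and seed give byte-identical fragment tables", {
  g <- small_genome()
  cfg <- simulation_config(0.2, 10000, rcc_like_scna(g), seed = 9)
  expect_identical(simulate_sample(cfg, g), simulate_sample(cfg, g))
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(simulate_sample(cfg, g), simulate_sample(cfg2, g)))
})

test_that("segment coverage follows the ctDNA dilution law", {
  g <- small_genome()
  scna <- data.frame(chrom = "chr1", start = 0, end = 3e6, copies = 1)
  n <- 5e5
  cfg <- simulation_config(0.4, n, scna, seed = 21)
  fr <- simulate_sample(cfg, g)
  mid <- (fr$start + fr$end) / 2
  inseg <- fr$chrom == "chr1" & mid < 3e6
  rate_seg <- sum(inseg) / 3e6
  rate_dip <- sum(!inseg) / (genome_length(g) - 3e6)
  # expected ratio (2*0.6 + 1*0.4)/2 = 0.8; allow 3 binomial SDs
  p_seg <- 3e6 * 0.8 / (3e6 * 0.8 + (genome_length(g) - 3e6))
  se <- sqrt(p_seg * (1 - p_seg) / n)
  expect_lt(abs(rate_seg / rate_dip - 0.8), 3 * se / p_seg * 0.8 + 0.02)
})

test_that("tumor fragments dominate the short-size window beyond tf", {
  g <- small_genome()
  cfg <- simulation_config(0.1, 2e5, seed = 13)
  fr <- simulate_sample(cfg, g)
  short <- fr[fr$length >= 90 & fr$length <= 150, ]
  expect_gt(mean(short$source == "tumor"), 0.1)
  # analytic check: the short-window tumor share implied by the mixture
  m <- cfg$length_model
  pt <- length_component_mass(m, "tumor", 90, 150)
  pn <- length_component_mass(m, "normal", 90, 150)
  expected_share <- 0.1 * pt / (0.1 * pt + 0.9 * pn)
  expect_equal(mean(short$source == "tumor"), expected_share,
               tolerance = 0.15)
})

test_that("target loci pick up alt alleles only from tumor fragments", {
  g <- small_genome()
  loci <- make_loci(5, seed = 2)
  loci$tissue_maf <- 1  # every tumor fragment over a locus carries alt
  cfg <- simulation_config(0.3, 1e5, target_loci = loci,
                           background_error = 0, seed = 31)
  fr <- simulate_sample(cfg, g)
  tagged <- fr[fr$locus_alleles != "", ]
  expect_gt(nrow(tagged), 0)
  alleles <- sub("^[0-9]+:", "", tagged$locus_alleles)
  expect_true(all(alleles %in% c("C", "T")))
  expect_true(all(alleles[tagged$source == "normal"] == "C"))
  expect_true(all(alleles[tagged$source == "tumor"] == "T"))
})

test_that("control cohorts are tumor-free, seeded, and need >= 2 members", {
  g <- small_genome()
  cfg <- simulation_config(0.5, 5000, rcc_like_scna(g), seed = 1)
  ctrls <- simulate_control_cohort(3, cfg, g, seed = 42)
  expect_length(ctrls, 3)
  for (x in ctrls) expect_true(all(x$source == "normal"))
  ctrls2 <- simulate_control_cohort(3, cfg, g, seed = 42)
  expect_identical(ctrls, ctrls2)
  expect_error(simulate_control_cohort(1, cfg, g, seed = 1), "cohort")
})

test_that("simulation_config validates its inputs", {
  expect_error(simulation_config(tumor_fraction = 0.1, seed = NULL),
               "seed")
  expect_error(simulation_config(tumor_fraction = 1.2, seed = 1), "0, 1")
  expect_error(simulation_config(0.1, n_fragments = 0, seed = 1),
               "n_fragments")
  overlapping <- data.frame(chrom = "chr1", start = c(0, 5e5),
                            end = c(1e6, 2e6), copies = c(1, 3))
  expect_error(simulation_config(0.1, 1000, overlapping, seed = 1),
               "overlap")
})

test_that("multi-region simulation builds the requested clonal structure", {
  m <- simulate_multiregion_tumor(10, n_truncal = 3, n_shared = 4,
                                  n_private_per_region = 5, seed = 5)
  expect_equal(sum(m$region_count == 1), 50)
  expect_equal(sum(m$region_count == 10), 3)
  truth <- attr(m, "truth")
  expect_true(all(m$region_count[truth$class == "truncal"] == 10))
  expect_true(all(m$region_count[truth$class == "private"] == 1))
  # determinism
  m2 <- simulate_multiregion_tumor(10, 3, 4, 5, seed = 5)
  expect_identical(m$matrix, m2$matrix)
  expect_error(simulate_multiregion_tumor(1, seed = 1), "n_regions")
})

test_that("fluid AF is the tf-scaled mixing-weighted mean of regional AFs", {
  m <- simulate_multiregion_tumor(4, n_truncal = 2, n_shared = 0,
                                  n_private_per_region = 1,
                                  af_range = c(0.4, 0.4),
                                  fluid_tf = c(plasma = 0.05),
                                  constant_af = TRUE, seed = 8)
  truth <- attr(m, "truth")
  truncal_cols <- which(truth$class == "truncal")
  # equal regional AF a with equal weights: fluid AF = a * tf
  expect_equal(unname(m$matrix["plasma", truncal_cols]),
               rep(0.4 * 0.05, 2), tolerance = 1e-12)
  private_cols <- which(truth$class == "private")
  expect_equal(unname(m$matrix["plasma", private_cols]),
               rep(0.4 * 0.05 / 4, 4), tolerance = 1e-12)
})
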