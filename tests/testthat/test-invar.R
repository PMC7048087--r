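make_reads <- function(families) {
  # families: list of character vectors of member bases, all at one locus
  do.call(rbind, lapply(seq_along(families), function(i) {
    data.frame(locus_id = 1L, umi = sprintf("U%d", i),
               base = families[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("UMI collapse applies the family-size and majority rules", {
  reads <- make_reads(list(
    "A",                       # size 1: dropped
    c("A", "A", "C"),          # 66.7% majority: discarded
    c(rep("A", 9), "C"),       # 90% exactly: consensus A (inclusive)
    c("T", "T")                # unanimous pair: consensus T
  ))
  cons <- collapse_umi(reads)
  expect_equal(nrow(cons), 2)
  expect_setequal(cons$consensus, c("A", "T"))
  expect_equal(sort(cons$n_members), c(2, 10))
})

test_that("consensus pileups count depth and mutant families per locus", {
  loci <- make_loci(2, seed = 3)
  reads <- rbind(
    data.frame(locus_id = 1L, umi = c("a", "a", "b", "b"),
               base = c("T", "T", "C", "C")),
    data.frame(locus_id = 2L, umi = c("c", "c"), base = c("C", "C"))
  )
  pil <- pileup_consensus(collapse_umi(reads), loci)
  expect_equal(pil$d, c(2, 1))
  expect_equal(pil$m, c(1, 0))
})

test_that("background rates pool by context class with a depth-based floor", {
  pil <- fake_pileups(d = c(60000, 40000), m = c(1, 1))
  bg <- estimate_background(pil)
  expect_equal(bg$rate[bg$context_class == "ACA>T"], 2e-5)
  # error-free class floored at half an error, not zero
  pil0 <- fake_pileups(d = c(60000, 40000), m = c(0, 0))
  bg0 <- estimate_background(pil0)
  expect_equal(bg0$rate, 0.5 / 1e5)
  # shallow classes fall back to the global rate and are flagged
  mix <- rbind(fake_pileups(50000, 5), fake_pileups(100, 1, context = "TCT"))
  bgm <- estimate_background(mix)
  expect_true(bgm$fallback[bgm$context_class == "TCT>T"])
  expect_equal(bgm$rate[bgm$context_class == "TCT>T"],
               attr(bgm, "global_rate"))
  expect_error(estimate_background(fake_pileups(0, 0)), "zero")
})

test_that("injected error rates are recovered within binomial error", {
  loci <- make_loci(40, seed = 11)
  loci$true_af <- 0
  pils <- lapply(1:6, function(s) {
    r <- simulate_targeted_reads(loci, 800, c(0, 0.5, 0.5),
                                 per_read_error = 0.02, seed = 400 + s,
                                 exact_depth = TRUE)
    pileup_consensus(collapse_umi(r), loci)
  })
  bg <- estimate_background(pils)
  d_tot <- sum(vapply(pils, function(p) sum(p$d), numeric(1)))
  m_tot <- sum(vapply(pils, function(p) sum(p$m), numeric(1)))
  # consensus-level expectation for the alt base: a unanimous pair of
  # matching errors, (e/3)^2, from the size-2 families (half of them)
  expected <- 0.5 * (0.02 / 3)^2
  se <- sqrt(expected / d_tot)
  expect_lt(abs(m_tot / d_tot - expected), 3 * se + 1e-6)
})

test_that("locus significance equals the exact binomial tail", {
  expect_equal(locus_significance(100, 0, 1e-4), 1)
  expect_equal(locus_significance(100, 1, 0), 0)
  # independent enumeration oracle for d <= 50
  enum_tail <- function(d, m, e) {
    sum(vapply(m:d, function(k) choose(d, k) * e^k * (1 - e)^(d - k),
               numeric(1)))
  }
  set.seed(9)
  for (i in 1:200) {
    d <- sample(1:50, 1)
    m <- sample(0:d, 1)
    e <- runif(1, 0, 0.2)
    expect_equal(locus_significance(d, m, e), enum_tail(d, m, e),
                 tolerance = 1e-10)
  }
  # the deep-locus worked example
  expect_equal(locus_significance(1e4, 10, 1e-4), 1.1102e-7,
               tolerance = 1e-3)
})

test_that("the aggregate likelihood is zero on null data and grows with evidence", {
  bg <- estimate_background(fake_pileups(50000, 1))
  null_pil <- fake_pileups(d = rep(1000, 10), m = rep(0, 10))
  agg0 <- aggregate_likelihood(null_pil, bg)
  expect_equal(agg0$score, 0)
  expect_equal(agg0$f_hat, 0)
  # single positive locus: profile likelihood finds f near m/d
  pos <- fake_pileups(d = 1e4, m = 10)
  agg1 <- aggregate_likelihood(pos, bg)
  expect_gt(agg1$score, 0)
  expect_equal(agg1$f_hat, 1e-3, tolerance = 0.5)
  # doubling depth and mutants at the same AF strengthens the evidence
  agg2 <- aggregate_likelihood(fake_pileups(2e4, 20), bg)
  expect_gt(agg2$score, agg1$score)
})

test_that("the profile-likelihood maximizer matches a dense-grid oracle", {
  bg <- estimate_background(fake_pileups(50000, 1))
  e <- background_rates(fake_pileups(1, 0), bg)
  pil <- fake_pileups(d = c(1e4, 8000), m = c(10, 6))
  agg <- aggregate_likelihood(pil, bg)
  dense <- seq(1e-6, 5e-3, by = 1e-6)
  ll <- vapply(dense, function(f) {
    sum(dbinom(pil$m, pil$d, e + f, log = TRUE))
  }, numeric(1))
  f_star <- dense[which.max(ll)]
  expect_equal(agg$f_hat, f_star, tolerance = 0.15)
})

test_that("the ROC threshold hits the requested specificity", {
  expect_equal(roc_threshold(rep(0, 20), 0.99), 0)
  scores <- c(rep(0, 90), seq(0.1, 1, 0.1))
  expect_equal(roc_threshold(scores, 1.0), max(scores))
  thr <- roc_threshold(scores, 0.99)
  expect_gte(mean(scores <= thr), 0.99)
  expect_error(roc_threshold(1:5), "at least 10")
})

test_that("gmAF subtracts the depth-weighted background and floors at zero", {
  bg0 <- estimate_background(fake_pileups(1e6, 0))  # floored tiny rate
  pil <- fake_pileups(d = c(1000, 1000), m = c(10, 0))
  expect_equal(compute_gmaf(pil, bg0), 10 / 2000, tolerance = 1e-3)
  bg1 <- estimate_background(fake_pileups(1e6, 1000))  # e = 1e-3
  expect_equal(compute_gmaf(pil, bg1), (10 - 2) / 2000, tolerance = 1e-6)
  # exactly at background: zero
  pil2 <- fake_pileups(d = 1000, m = 1)
  expect_equal(compute_gmaf(pil2, bg1), 0)
  expect_error(compute_gmaf(fake_pileups(0, 0), bg1), "zero")
})

test_that("the informative-read gate fails strictly below 20,000", {
  pil_ok <- fake_pileups(d = rep(100, 200), m = rep(0, 200))
  gate <- informative_reads(pil_ok)
  expect_equal(gate$ir, 20000)
  expect_false(gate$technical_fail)
  pil_fail <- fake_pileups(d = c(rep(100, 199), 99), m = rep(0, 200))
  expect_true(informative_reads(pil_fail)$technical_fail)
  expect_warning(informative_reads(fake_pileups(rep(300, 99), rep(0, 99))),
                 "99")
})

test_that("the full targeted assay detects spiked signal and not null samples", {
  loci <- make_loci(50, seed = 21)
  null_loci <- loci; null_loci$true_af <- 0
  bg_pils <- lapply(1:5, function(s) {
    r <- simulate_targeted_reads(null_loci, 500, c(0, 0.5, 0.5),
                                 seed = 600 + s, exact_depth = TRUE)
    pileup_consensus(collapse_umi(r), null_loci)
  })
  bg <- estimate_background(bg_pils)
  ctrl_scores <- vapply(bg_pils, function(p) {
    aggregate_likelihood(p, bg)$score
  }, numeric(1))
  thr <- max(ctrl_scores) + 0.5
  case_loci <- loci; case_loci$true_af <- 5e-3
  reads <- simulate_targeted_reads(case_loci, 500, c(0, 0.5, 0.5),
                                   seed = 33, exact_depth = TRUE)
  res <- run_invar(reads, case_loci, bg, thr)
  expect_true(res$detected)
  expect_gt(res$gmaf, 1e-3)
  expect_equal(res$ir, sum(res$pileups$d))
  null_reads <- simulate_targeted_reads(null_loci, 500, c(0, 0.5, 0.5),
                                        seed = 34, exact_depth = TRUE)
  res0 <- run_invar(null_reads, null_loci, bg, thr)
  expect_false(res0$detected)
})
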