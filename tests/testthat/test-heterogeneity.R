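test_that("the matrix builder computes region counts from tumor regions only", {
  calls <- rbind(
    data.frame(sample = "T1", mutation_id = c("m1", "m2"), af = c(0.3, 0.2)),
    data.frame(sample = "T2", mutation_id = "m1", af = 0.25),
    data.frame(sample = "plasma", mutation_id = c("m1", "m2"),
               af = c(0.01, 0))
  )
  mrm <- build_multiregion_matrix(calls, regions = c("T1", "T2"),
                                  fluids = "plasma")
  expect_equal(unname(mrm$region_count[c("m1", "m2")]), c(2, 1))
  # measured fluid zero stays 0 (covered), unreported region entry is 0
  expect_equal(mrm$matrix["plasma", "m2"], 0)
  expect_equal(mrm$matrix["T2", "m2"], 0)
})

test_that("uncovered fluid loci are missing, not zero", {
  calls <- rbind(
    data.frame(sample = "T1", mutation_id = c("m1", "m2"), af = c(0.3, 0.2),
               covered = TRUE),
    data.frame(sample = "plasma", mutation_id = c("m1", "m2"),
               af = c(0.01, 0), covered = c(TRUE, FALSE))
  )
  mrm <- build_multiregion_matrix(calls, regions = "T1", fluids = "plasma")
  expect_true(is.na(mrm$matrix["plasma", "m2"]))
  expect_true(mrm$missing["plasma", "m2"])
  expect_false(mrm$missing["plasma", "m1"])
})

test_that("mutation clustering separates truncal from private clones", {
  m <- simulate_multiregion_tumor(6, n_truncal = 5, n_shared = 0,
                                  n_private_per_region = 3,
                                  af_range = c(0.3, 0.5), seed = 14)
  cl <- cluster_mutations(m)
  truth <- attr(m, "truth")
  # cutting the tree at two clusters isolates the truncal block
  k2 <- stats::cutree(cl$hclust, k = 2)
  truncal_groups <- unique(k2[truth$class == "truncal"])
  expect_length(truncal_groups, 1)
  expect_true(all(k2[truth$class == "private"] != truncal_groups))
  # identical columns merge at height 0
  mm <- m
  mm$matrix[, 2] <- mm$matrix[, 1]
  cl2 <- cluster_mutations(mm)
  expect_equal(min(cl2$hclust$height), 0)
})

test_that("clustering is invariant to column permutation", {
  m <- simulate_multiregion_tumor(5, 3, 2, 2, seed = 25)
  cl <- cluster_mutations(m)
  perm <- sample(ncol(m$matrix))
  mp <- m
  mp$matrix <- m$matrix[, perm]
  mp$region_count <- m$region_count[perm]
  clp <- cluster_mutations(mp)
  expect_equal(sort(cl$hclust$height), sort(clp$hclust$height),
               tolerance = 1e-12)
})

test_that("fluid representation counts regions with detected mutations", {
  m <- simulate_multiregion_tumor(10, n_truncal = 3, n_shared = 0,
                                  n_private_per_region = 2, seed = 30)
  # everything detectable: full representation
  rep_all <- fluid_representation(m, "plasma")
  expect_equal(rep_all$fraction, 1.0)
  expect_equal(rep_all$fraction_private, 1.0)
  # silence every mutation: nothing represented
  none <- fluid_representation(m, "plasma",
                               detected = rep(FALSE, ncol(m$matrix)))
  expect_equal(none$fraction, 0)
  # silence exactly one region's private mutations: 9/10 by private calls
  truth <- attr(m, "truth")
  det <- m$matrix["plasma", ] > 0
  det[truth$presence["T4", ] & m$region_count == 1] <- FALSE
  partial <- fluid_representation(m, "plasma", detected = det)
  expect_equal(partial$fraction_private, 0.9)
  expect_equal(partial$fraction, 1.0)  # truncal calls still cover T4
})

test_that("adding a detected mutation never reduces representation", {
  m <- simulate_multiregion_tumor(8, 2, 5, 2, seed = 44)
  set.seed(7)
  det <- runif(ncol(m$matrix)) < 0.3
  base <- suppressWarnings(fluid_representation(m, "plasma", detected = det))
  for (j in which(!det)[1:5]) {
    det2 <- det; det2[j] <- TRUE
    more <- suppressWarnings(fluid_representation(m, "plasma",
                                                  detected = det2))
    expect_gte(more$fraction, base$fraction)
  }
})

test_that("the region-count trend test flags a constructed monotone signal", {
  set.seed(3)
  n_per <- 30
  calls <- do.call(rbind, lapply(1:3, function(k) {
    muts <- sprintf("rc%d_m%d", k, seq_len(n_per))
    regions <- do.call(rbind, lapply(seq_len(k), function(r) {
      data.frame(sample = paste0("T", r), mutation_id = muts, af = 0.3)
    }))
    fluid <- data.frame(sample = "plasma", mutation_id = muts,
                        af = k * 1e-3 + runif(n_per, 0, 2e-4))
    rbind(regions, fluid)
  }))
  mrm <- build_multiregion_matrix(calls, regions = paste0("T", 1:3),
                                  fluids = "plasma")
  tr <- af_by_region_count_trend(mrm, "plasma")
  expect_equal(tr$region_count, 1:3)
  expect_true(all(diff(tr$median_af) > 0))
  expect_true(all(tr$p_value[-1] < 0.05))
})

test_that("undersized groups are skipped with a note", {
  calls <- rbind(
    data.frame(sample = "T1", mutation_id = paste0("m", 1:5), af = 0.3),
    data.frame(sample = "T2", mutation_id = "m1", af = 0.3),
    data.frame(sample = "plasma", mutation_id = paste0("m", 1:5),
               af = runif(5, 0, 1e-3))
  )
  mrm <- build_multiregion_matrix(calls, regions = c("T1", "T2"),
                                  fluids = "plasma")
  expect_message(tr <- af_by_region_count_trend(mrm, "plasma"), "skipped")
  expect_true(all(is.na(tr$p_value[tr$region_count == 2])))
})
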