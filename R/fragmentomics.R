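#' In-silico fragment size selection
#'
#' Keeps fragments whose length lies in `[lo, hi]`, inclusive at both ends.
#' Because tumor-derived cfDNA fragments are shorter than the ~167 bp
#' mono-nucleosomal mode of healthy cfDNA, selecting 90-150 bp fragments
#' enriches the tumor-derived proportion.
#'
#' @param fragments fragment table with a `length` column.
#' @param lo,hi inclusive length bounds in bp (defaults 90 and 150).
#' @return the filtered fragment table.
#' @export
size_select <- function(fragments, lo = 90, hi = 150) {
  if (lo >= hi) stop_invalid("`lo` must be below `hi`")
  fragments[fragments$length >= lo & fragments$length <= hi, , drop = FALSE]
}

#' Fragment length histogram
#'
#' Counts fragments per 1-bp length bin over 20-700 bp.
#'
#' @param fragments fragment table with a `length` column, or a numeric
#'   vector of lengths.
#' @return an object of class `length_histogram`: integer counts named by
#'   length, with attribute `total`.
#' @export
length_histogram <- function(fragments) {
  lens <- if (is.numeric(fragments)) fragments else fragments$length
  lens <- lens[lens >= 20 & lens <= 700]
  h <- tabulate(lens - 19L, nbins = 681L)
  names(h) <- 20:700
  attr(h, "total") <- sum(h)
  class(h) <- "length_histogram"
  h
}

#' Proportion of fragments in a length range
#'
#' @param hist a [length_histogram()].
#' @param lo,hi inclusive bounds in bp.
#' @return `count(lo..hi) / total`.
#' @export
proportion_in_range <- function(hist, lo, hi) {
  stopifnot(inherits(hist, "length_histogram"))
  total <- attr(hist, "total")
  if (total == 0) stop_invalid("empty histogram")
  lens <- as.integer(names(hist))
  sum(hist[lens >= lo & lens <= hi]) / total
}

#' Amplitude of the 10-bp fragment length oscillation
#'
#' Measures the relative amplitude of the 10-bp periodicity in the fragment
#' length distribution over 76-150 bp. The histogram is divided by a 10-bp
#' centered moving average (which exactly annihilates a period-10 cosine),
#' leaving the relative oscillation; the amplitude is twice the magnitude of
#' the discrete Fourier component at frequency 1/10 bp^-1 of that residual,
#' clipped to [0, 1]. A comb-free smooth density scores approximately zero;
#' a density proportional to `1 + A cos(2 pi L / 10)` scores approximately
#' `A`.
#'
#' @param hist a [length_histogram()].
#' @param lo,hi analysis window in bp (defaults 76 and 150).
#' @return the amplitude in [0, 1].
#' @export
amplitude_10bp <- function(hist, lo = 76, hi = 150) {
  stopifnot(inherits(hist, "length_histogram"))
  lens <- as.integer(names(hist))
  sel <- lens >= lo & lens <= hi
  h <- as.numeric(hist[sel])
  L <- lens[sel]
  if (sum(h) == 0) stop_invalid("no fragments in the analysis window")
  # 10-point centered moving average as the smooth trend
  n <- length(h)
  trend <- stats::filter(h, rep(1 / 10, 10), sides = 2)
  valid <- which(!is.na(trend) & trend > 0)
  if (length(valid) < 20) return(0)
  # truncate to whole periods so a pure comb is measured without leakage
  valid <- valid[seq_len(10 * floor(length(valid) / 10))]
  z <- h[valid] / trend[valid] - 1
  w <- exp(-2i * pi * L[valid] / 10)
  amp <- 2 * Mod(sum(z * w)) / length(valid)
  min(1, max(0, amp))
}

#' The ten fragmentation features
#'
#' Computes the feature vector used by the random-forest triage model:
#' the tMAD score, the 10-bp oscillation amplitude, and proportions and
#' ratios of fragments in defined length windows (all bounds inclusive):
#' P(20-150), P(160-180), P(20-150)/P(160-180), P(100-150),
#' P(100-150)/P(163-169), P(180-220), P(250-320), P(20-150)/P(180-220).
#' A ratio whose denominator is zero is set to a capped sentinel
#' (numerator / 1e-12, capped at 1e6) and flagged in the `sentinel`
#' attribute so the feature matrix stays rectangular.
#'
#' @param fragments fragment table (>= 1 fragment; at least ~1000 for
#'   stable features).
#' @param tmad the sample's tMAD score from the unselected assay (a
#'   `tmad_result` or a bare number).
#' @return a one-row data.frame with the 10 features in canonical order:
#'   t_mad, amplitude_10bp, p_20_150, p_160_180, ratio_20_150_over_160_180,
#'   p_100_150, ratio_100_150_over_163_169, p_180_220, p_250_320,
#'   ratio_20_150_over_180_220.
#' @export
compute_fragmentomics <- function(fragments, tmad) {
  if (inherits(tmad, "tmad_result")) tmad <- tmad$tmad
  h <- length_histogram(fragments)
  p <- function(lo, hi) proportion_in_range(h, lo, hi)
  sentinel <- character(0)
  ratio <- function(num, den, label) {
    if (den == 0) {
      sentinel <<- c(sentinel, label)
      return(min(num / 1e-12, 1e6))
    }
    num / den
  }
  p20_150 <- p(20, 150); p160_180 <- p(160, 180)
  p100_150 <- p(100, 150); p163_169 <- p(163, 169)
  p180_220 <- p(180, 220); p250_320 <- p(250, 320)
  out <- data.frame(
    t_mad = tmad,
    amplitude_10bp = amplitude_10bp(h),
    p_20_150 = p20_150,
    p_160_180 = p160_180,
    ratio_20_150_over_160_180 = ratio(p20_150, p160_180,
                                      "ratio_20_150_over_160_180"),
    p_100_150 = p100_150,
    ratio_100_150_over_163_169 = ratio(p100_150, p163_169,
                                       "ratio_100_150_over_163_169"),
    p_180_220 = p180_220,
    p_250_320 = p250_320,
    ratio_20_150_over_180_220 = ratio(p20_150, p180_220,
                                      "ratio_20_150_over_180_220")
  )
  attr(out, "sentinel") <- sentinel
  out
}

#' Canonical fragmentomics feature names
#' @return character vector of the 10 feature names in canonical order.
#' @export
fragmentomics_feature_names <- function() {
  c("t_mad", "amplitude_10bp", "p_20_150", "p_160_180",
    "ratio_20_150_over_160_180", "p_100_150",
    "ratio_100_150_over_163_169", "p_180_220", "p_250_320",
    "ratio_20_150_over_180_220")
}

#' Size-selected tMAD re-analysis
#'
#' The short-fragment re-analysis pipeline: size-select case and controls to
#' `[lo, hi]` bp, downsample to a common read count, and run the tMAD assay
#' on coarse bins against the similarly size-selected control cohort. A
#' sample whose post-selection fragment count falls below `min_fragments` is
#' ineligible and gets no score. When the unselected tMAD score is supplied
#' the enrichment factor (selected / unselected score) is reported.
#'
#' @param fragments case fragment table (unselected).
#' @param controls list of control fragment tables (unselected), or a
#'   `tmad_cohort` built from already size-selected controls.
#' @param genome a `genome_model`.
#' @param lo,hi size-selection window (default 90-150 bp).
#' @param bin_bp bin width for the re-analysis (default 500000).
#' @param downsample_n common read count (default 2e6).
#' @param min_fragments eligibility floor on post-selection fragments
#'   (default 2e6).
#' @param unselected_tmad optional unselected tMAD score (number or
#'   `tmad_result`) for the enrichment factor.
#' @param penalty,seed passed to the tMAD assay.
#' @return an object of class `size_selected_tmad`: list with `eligible`,
#'   `result` (a `tmad_result` or NULL when ineligible), `n_selected`, and
#'   `enrichment` (NA when undefined).
#' @export
size_selected_tmad <- function(fragments, controls, genome, lo = 90, hi = 150,
                               bin_bp = 5e5, downsample_n = 2e6,
                               min_fragments = 2e6, unselected_tmad = NULL,
                               penalty = 3, seed = 1) {
  sel <- size_select(fragments, lo, hi)
  n_selected <- nrow(sel)
  if (inherits(unselected_tmad, "tmad_result")) {
    unselected_tmad <- unselected_tmad$tmad
  }
  if (n_selected < min_fragments) {
    return(structure(list(eligible = FALSE, result = NULL,
                          n_selected = n_selected, enrichment = NA_real_),
                     class = "size_selected_tmad"))
  }
  if (!inherits(controls, "tmad_cohort")) {
    controls <- lapply(controls, size_select, lo = lo, hi = hi)
    controls <- tmad_cohort(controls, genome, bin_bp = bin_bp,
                            downsample_n = downsample_n, penalty = penalty,
                            seed = seed)
  }
  res <- run_tmad_assay(sel, controls, genome, mode = "control", seed = seed)
  enrichment <- if (!is.null(unselected_tmad) && unselected_tmad > 0) {
    res$tmad / unselected_tmad
  } else NA_real_
  structure(list(eligible = TRUE, result = res, n_selected = n_selected,
                 enrichment = enrichment),
            class = "size_selected_tmad")
}

#' @export
print.size_selected_tmad <- function(x, ...) {
  cat("Size-selected tMAD re-analysis\n")
  if (!x$eligible) {
    cat(sprintf("  ineligible: %s fragments after selection (< threshold)\n",
                format(x$n_selected, big.mark = ",")))
  } else {
    cat(sprintf("  tMAD %.4f (threshold %.4f), enrichment %.2f-fold\n",
                x$result$tmad, x$result$threshold, x$enrichment))
  }
  invisible(x)
}

#' Train the random-forest triage model
#'
#' Fits a seeded random forest on a table of fragmentomics features with
#' binary labels (cancer vs control / high vs low ctDNA). The triage
#' probability of a sample is the fraction of trees voting for the cancer
#' class; a sample is triage-positive when that probability strictly
#' exceeds 0.5.
#'
#' @param feature_table data.frame whose columns include the 10 canonical
#'   features (extra columns are ignored); >= 20 samples per class.
#' @param labels factor or vector coercible to a two-level factor; the
#'   second level is treated as the positive (cancer) class.
#' @param seed integer seed.
#' @param ntree number of trees (default 500).
#' @param min_per_class minimum samples per class (default 20).
#' @return an object of class `triage_model` wrapping the forest.
#' @export
train_triage_model <- function(feature_table, labels, seed, ntree = 500,
                               min_per_class = 20) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) {
    stop_invalid("`labels` must have exactly two classes")
  }
  if (min(table(labels)) < min_per_class) {
    stop_invalid("need at least %d samples per class", min_per_class)
  }
  feats <- feature_table[, fragmentomics_feature_names(), drop = FALSE]
  set.seed(seed)
  rf <- randomForest::randomForest(x = feats, y = labels, ntree = ntree)
  structure(list(forest = rf, positive_class = levels(labels)[2],
                 seed = seed, version = "ctdnalite-rf-1"),
            class = "triage_model")
}

#' Predict triage status for new samples
#'
#' @param model a [train_triage_model()] result.
#' @param features data.frame of fragmentomics features (one or more rows).
#' @return an object of class `triage_result`: data.frame with
#'   `probability_cancer` and `triaged_positive` (strictly greater than
#'   0.5) per row.
#' @export
predict_triage <- function(model, features) {
  stopifnot(inherits(model, "triage_model"))
  feats <- features[, fragmentomics_feature_names(), drop = FALSE]
  prob <- predict(model$forest, newdata = feats, type = "prob")
  p <- prob[, model$positive_class]
  out <- data.frame(probability_cancer = as.numeric(p),
                    triaged_positive = as.numeric(p) > 0.5)
  class(out) <- c("triage_result", "data.frame")
  out
}

#' @export
print.triage_model <- function(x, ...) {
  cat(sprintf("Fragmentomics triage model (%s): %d trees, positive class '%s'\n",
              x$version, x$forest$ntree, x$positive_class))
  invisible(x)
}
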