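#' Tumor fraction by grid search over copy states
#'
#' A deliberately simple segment-level tumor-fraction estimator: for each
#' candidate tumor fraction `t` on a grid, every segment is assigned the
#' integer total copy state `c` in `{0, ..., 4}` whose expected log ratio
#' `log2((2 (1 - t) + c t) / 2)` is closest to the observed segment mean;
#' the bin-weighted total squared error is minimized over `t`, with ties
#' broken toward smaller `t` (so an all-neutral profile is assigned
#' `t = 0`).
#'
#' The fit is regularized by a small diploid-parsimony penalty,
#' `copy_penalty * sum(n_bins * (c - 2)^2)`, because the model is otherwise
#' exactly degenerate: a one-copy loss at fraction `t` produces the same
#' expected log ratio as a homozygous loss at `t / 2` (and a one-copy gain
#' mimics a two-copy gain at half the fraction). The penalty prefers copy
#' states near diploid, resolving the degeneracy toward the larger, more
#' parsimonious fraction, and incidentally suppresses copy calls on
#' segments whose deviation is within noise of zero. The flip side is that
#' true homozygous deletions and high-level amplifications, which are not
#' modeled here, would be absorbed into milder states at inflated
#' fractions. Samples with an estimated fraction below 0.03 — the
#' conventional lower limit of detection for tumor-fraction calling from
#' ultra-low-pass WGS — are considered ctDNA negative.
#'
#' @param segments a [segment_profile()] result, or a data.frame with
#'   columns chrom, start, end, mean and n_bins.
#' @param t_grid candidate tumor fractions (default `seq(0, 0.95, 0.01)`).
#' @param max_copies largest copy state modeled (default 4).
#' @param copy_penalty diploid-parsimony regularization weight per bin per
#'   squared copy-state deviation from 2 (default 2e-4, small enough that fractions at the 0.03 detection floor remain resolvable).
#' @param detection_floor minimum detectable tumor fraction (default 0.03,
#'   inclusive).
#' @return an object of class `tf_estimate`: `tf_hat`, per-segment
#'   `copy_state`, `fit_score` (total weighted squared error), `detected`
#'   (`tf_hat >= detection_floor`), `rescue_rule_applied = FALSE`.
#' @export
estimate_tumor_fraction <- function(segments, t_grid = seq(0, 0.95, 0.01),
                                    max_copies = 4, copy_penalty = 2e-4,
                                    detection_floor = 0.03) {
  seg <- if (inherits(segments, "segmented_profile")) segments$segments
         else segments
  stopifnot(all(c("mean", "n_bins") %in% names(seg)))
  copies <- 0:max_copies
  best_err <- Inf
  best_t <- 0
  best_states <- rep(2L, nrow(seg))
  for (t in t_grid) {
    ratio <- (2 * (1 - t) + copies * t) / 2
    exp_log2r <- log2(pmax(ratio, 1e-6))
    # per segment, the copy state minimizing penalized squared deviation
    d2 <- outer(seg$mean, exp_log2r, function(m, e) (m - e)^2)
    d2 <- sweep(d2, 2, copy_penalty * (copies - 2)^2, `+`)
    state_idx <- max.col(-d2, ties.method = "first")
    err <- sum(seg$n_bins * d2[cbind(seq_len(nrow(seg)), state_idx)])
    if (err < best_err - 1e-12) {  # strict improvement: ties keep smaller t
      best_err <- err
      best_t <- t
      best_states <- copies[state_idx]
    }
  }
  structure(list(
    tf_hat = best_t,
    segments = cbind(seg, copy_state = best_states),
    fit_score = best_err,
    detected = best_t >= detection_floor,
    rescue_rule_applied = FALSE,
    detection_floor = detection_floor
  ), class = "tf_estimate")
}

#' Default frequent-SCNA list for renal cell carcinoma
#'
#' The arm-level copy-number alterations most frequently reported in RCC:
#' loss of 3p and 8p, gain of 3q and 8q. On a synthetic genome, supply a
#' table mapping those roles onto the synthetic arms instead.
#'
#' @return data.frame with columns chrom, arm, direction.
#' @export
frequent_scna_rcc <- function() {
  data.frame(
    chrom = c("chr3", "chr8", "chr3", "chr8"),
    arm = c("p", "p", "q", "q"),
    direction = c("loss", "loss", "gain", "gain"),
    stringsAsFactors = FALSE
  )
}

#' Frequent-SCNA rescue rule for low-read size-selected samples
#'
#' When a size-selected sample retains fewer than 2 million reads, a
#' tumor-fraction call alone is unreliable; such samples are considered
#' positive only when an inferred non-neutral segment matches a copy-number
#' alteration frequently found in the tumor type (for RCC: 3p/8p loss,
#' 3q/8q gain), covering more than half of the arm in the stated direction.
#'
#' @param tf_estimate a [estimate_tumor_fraction()] result.
#' @param genome a `genome_model` (for arm boundaries).
#' @param frequent_set data.frame with columns chrom, arm ("p"/"q"),
#'   direction ("loss"/"gain"); default [frequent_scna_rcc()].
#' @param min_arm_fraction minimum fraction of the arm a matching segment
#'   must cover (default 0.5, strict).
#' @return TRUE when at least one inferred aberration matches the frequent
#'   set.
#' @export
frequent_scna_rescue <- function(tf_estimate, genome,
                                 frequent_set = frequent_scna_rcc(),
                                 min_arm_fraction = 0.5) {
  stopifnot(inherits(tf_estimate, "tf_estimate"))
  seg <- tf_estimate$segments
  aberrant <- seg[seg$copy_state != 2, , drop = FALSE]
  if (nrow(aberrant) == 0) return(FALSE)
  for (i in seq_len(nrow(frequent_set))) {
    fs <- frequent_set[i, ]
    if (!fs$chrom %in% genome$chromosomes$name) next
    ab <- genome$arm_boundary[[fs$chrom]]
    len <- genome$chromosomes$length[genome$chromosomes$name == fs$chrom]
    arm_lo <- if (fs$arm == "p") 0 else ab
    arm_hi <- if (fs$arm == "p") ab else len
    cand <- aberrant[aberrant$chrom == fs$chrom, , drop = FALSE]
    if (!nrow(cand)) next
    dir_ok <- if (fs$direction == "loss") cand$copy_state < 2
              else cand$copy_state > 2
    cand <- cand[dir_ok, , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmax(0, pmin(cand$end, arm_hi) - pmax(cand$start, arm_lo))
    if (sum(ov) > min_arm_fraction * (arm_hi - arm_lo)) return(TRUE)
  }
  FALSE
}

#' Tumor-fraction call with low-read gating
#'
#' Applies the detection rule: `tf_hat >= 0.03` declares ctDNA positive,
#' except that samples with fewer than `low_read_threshold` reads (e.g.
#' after size selection) additionally require a frequent-SCNA match via
#' [frequent_scna_rescue()].
#'
#' @param segments segmented profile (see [estimate_tumor_fraction()]).
#' @param n_reads number of reads behind the profile.
#' @param genome a `genome_model` (needed when the rescue rule is
#'   consulted).
#' @param frequent_set frequent-SCNA table (default [frequent_scna_rcc()]).
#' @param low_read_threshold read count below which the rescue rule gates
#'   detection (default 2e6).
#' @param ... passed to [estimate_tumor_fraction()].
#' @return a `tf_estimate` with `detected` and `rescue_rule_applied` set.
#' @export
call_tumor_fraction <- function(segments, n_reads, genome = NULL,
                                frequent_set = frequent_scna_rcc(),
                                low_read_threshold = 2e6, ...) {
  est <- estimate_tumor_fraction(segments, ...)
  if (n_reads < low_read_threshold) {
    if (is.null(genome)) {
      stop_invalid("the low-read rescue rule needs a `genome`")
    }
    est$rescue_rule_applied <- TRUE
    est$detected <- est$detected &&
      frequent_scna_rescue(est, genome, frequent_set)
  }
  est
}

#' @export
print.tf_estimate <- function(x, ...) {
  cat("Tumor fraction estimate (grid search over integer copy states)\n")
  cat(sprintf("  tf_hat = %.2f; %s%s\n", x$tf_hat,
              ifelse(x$detected, "ctDNA POSITIVE", "ctDNA negative"),
              ifelse(x$rescue_rule_applied, " (low-read rescue rule applied)",
                     "")))
  ab <- x$segments[x$segments$copy_state != 2, , drop = FALSE]
  cat(sprintf("  aberrant segments: %d of %d\n", nrow(ab), nrow(x$segments)))
  invisible(x)
}
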