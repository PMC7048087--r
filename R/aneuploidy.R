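#' Per-arm fragment counts and fractions
#'
#' Partitions fragments by the chromosome arm containing their midpoint
#' (p arm before the arm boundary, q arm from it onward) and normalizes
#' counts to fractions over the included arms. Arms in `exclude_arms`
#' (e.g. acrocentric p arms on a real genome) are removed from both the
#' counts and the denominator.
#'
#' @param fragments fragment table.
#' @param genome a `genome_model` with arm boundaries.
#' @param exclude_arms character vector of arm names like `"chr1p"`.
#' @param min_fragments warn below this total (default 1e5, the customary
#'   minimum read count for arm-level aneuploidy scoring).
#' @return an object of class `arm_counts`: data.frame with arm, chrom,
#'   count, fraction.
#' @export
arm_read_counts <- function(fragments, genome, exclude_arms = character(0),
                            min_fragments = 1e5) {
  stopifnot(inherits(genome, "genome_model"))
  if (nrow(fragments) < min_fragments) {
    warning(sprintf("only %d fragments (< %g): arm fractions will be noisy",
                    nrow(fragments), min_fragments))
  }
  mid <- floor((fragments$start + fragments$end) / 2)
  ab <- genome$arm_boundary[fragments$chrom]
  arm <- paste0(fragments$chrom, ifelse(mid < ab, "p", "q"))
  all_arms <- as.vector(t(outer(genome$chromosomes$name, c("p", "q"),
                                paste0)))
  counts <- table(factor(arm, levels = all_arms))
  out <- data.frame(
    arm = all_arms,
    chrom = rep(genome$chromosomes$name, each = 2),
    count = as.vector(counts),
    stringsAsFactors = FALSE
  )
  out$included <- !out$arm %in% exclude_arms
  out$fraction <- NA_real_
  out$fraction[out$included] <- out$count[out$included] /
    sum(out$count[out$included])
  class(out) <- c("arm_counts", "data.frame")
  out
}

#' Per-arm z-scores against a control cohort
#'
#' For each included arm, `z = (f_case - mean(f_controls)) /
#' sd(f_controls)` with the unbiased standard deviation. Arms with zero
#' control variance are excluded with a warning.
#'
#' @param case an [arm_read_counts()] result.
#' @param controls list of `arm_counts` on the identical arm set.
#' @return named numeric vector of z-scores (NA for excluded arms).
#' @export
arm_zscores <- function(case, controls) {
  stopifnot(inherits(case, "arm_counts"))
  if (length(controls) < 3) stop_invalid("need at least 3 controls")
  for (ctl in controls) {
    if (!identical(ctl$arm, case$arm)) stop_invalid("mismatched arm sets")
  }
  fmat <- vapply(controls, function(x) x$fraction, numeric(nrow(case)))
  mu <- rowMeans(fmat)
  sdv <- apply(fmat, 1, sd)
  z <- (case$fraction - mu) / sdv
  bad <- case$included & (is.na(sdv) | sdv == 0)
  if (any(bad)) {
    warning(sprintf("%d arm(s) with zero control variance excluded", sum(bad)))
    z[bad] <- NA_real_
  }
  z[!case$included] <- NA_real_
  names(z) <- case$arm
  z
}

#' Genome-wide aneuploidy z-score
#'
#' Aggregates per-arm z-scores into a single genome-wide score: the case
#' statistic is the sum of squared arm z-scores, standardized against the
#' distribution of the same statistic in the (leave-one-out) control
#' cohort. Detection is declared at a genome-wide z of at least 3.
#'
#' @param case_z per-arm z vector for the case.
#' @param control_z matrix of per-arm control z-scores (arms x controls),
#'   each column a control scored leave-one-out against the rest.
#' @return list with `genomewide_z`, `detected` (inclusive `>= 3`),
#'   `statistic` (case sum of squares).
#' @export
genomewide_zscore <- function(case_z, control_z) {
  s_case <- sum(case_z^2, na.rm = TRUE)
  s_ctrl <- colSums(control_z^2, na.rm = TRUE)
  sdv <- sd(s_ctrl)
  if (!is.finite(sdv) || sdv == 0) {
    stop_invalid("degenerate control variance in genome-wide statistic")
  }
  gz <- (s_case - mean(s_ctrl)) / sdv
  list(genomewide_z = gz, detected = gz >= 3, statistic = s_case)
}

#' Preprocess an aneuploidy control cohort
#'
#' Computes arm counts for every control and the leave-one-out per-arm
#' z-score matrix (each control scored against the remaining controls), so
#' many cases can be scored against one cohort.
#'
#' @param controls list of control fragment tables.
#' @param genome a `genome_model`.
#' @param exclude_arms arms excluded from scoring.
#' @return an object of class `aneuploidy_cohort`.
#' @export
aneuploidy_cohort <- function(controls, genome, exclude_arms = character(0)) {
  if (length(controls) < 4) stop_invalid("need at least 4 controls")
  ac <- lapply(controls, arm_read_counts, genome = genome,
               exclude_arms = exclude_arms, min_fragments = 0)
  loo_z <- vapply(seq_along(ac), function(i) {
    arm_zscores(ac[[i]], ac[-i])
  }, numeric(nrow(ac[[1]])))
  rownames(loo_z) <- ac[[1]]$arm
  structure(list(arm_counts = ac, loo_z = loo_z,
                 exclude_arms = exclude_arms),
            class = "aneuploidy_cohort")
}

#' Run the arm-level aneuploidy z-score assay
#'
#' @param fragments case fragment table.
#' @param cohort an [aneuploidy_cohort()] (or list of control fragment
#'   tables, converted internally).
#' @param genome a `genome_model`.
#' @param exclude_arms arms excluded from scoring.
#' @return an object of class `aneuploidy_scores`: per-arm z, genome-wide z,
#'   `detected` (genome-wide z >= 3), and the number of controls.
#' @export
run_aneuploidy_assay <- function(fragments, cohort, genome,
                                 exclude_arms = character(0)) {
  if (!inherits(cohort, "aneuploidy_cohort")) {
    cohort <- aneuploidy_cohort(cohort, genome, exclude_arms)
  }
  case <- arm_read_counts(fragments, genome,
                          exclude_arms = cohort$exclude_arms)
  z <- arm_zscores(case, cohort$arm_counts)
  gw <- genomewide_zscore(z, cohort$loo_z)
  structure(list(
    arm_z = z, genomewide_z = gw$genomewide_z, detected = gw$detected,
    statistic = gw$statistic, n_controls = length(cohort$arm_counts)
  ), class = "aneuploidy_scores")
}

#' @export
print.aneuploidy_scores <- function(x, ...) {
  cat("Arm-level aneuploidy assay\n")
  cat(sprintf("  genome-wide z = %.2f (%d controls): %s\n",
              x$genomewide_z, x$n_controls,
              ifelse(x$detected, "DETECTED (z >= 3)", "not detected")))
  top <- sort(abs(x$arm_z), decreasing = TRUE)
  top <- top[!is.na(top)][seq_len(min(4, sum(!is.na(top))))]
  cat("  largest |arm z|:",
      paste(sprintf("%s=%.2f", names(top), x$arm_z[names(top)]),
            collapse = ", "), "\n")
  invisible(x)
}
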