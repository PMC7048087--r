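#' Collapse UMI read families to consensus molecules
#'
#' Groups raw reads by (locus, UMI) and keeps a family only when it has at
#' least `min_family_size` members and a single base reaches at least the
#' `majority` fraction of members (both bounds inclusive); the family then
#' contributes one consensus molecule with that base. Families failing
#' either rule are discarded entirely.
#'
#' @param reads data.table/data.frame of raw reads with columns locus_id,
#'   umi, base (plus locus annotation columns carried through).
#' @param min_family_size minimum members per family (default 2).
#' @param majority required majority fraction (default 0.9, inclusive).
#' @return a data.table of consensus molecules: locus_id, umi, consensus
#'   base, n_members.
#' @export
collapse_umi <- function(reads, min_family_size = 2, majority = 0.9) {
  dt <- data.table::as.data.table(reads)
  stopifnot(all(c("locus_id", "umi", "base") %in% names(dt)))
  per_base <- dt[, .N, by = .(locus_id, umi, base)]
  data.table::setorder(per_base, locus_id, umi, base)  # ties -> first base
  fam <- per_base[, {
    top <- which.max(N)
    list(n_members = sum(N), consensus = base[top], maxn = N[top])
  }, by = .(locus_id, umi)]
  fam <- fam[n_members >= min_family_size & maxn / n_members >= majority]
  fam[, maxn := NULL]
  fam[]
}

#' Build per-locus consensus pileups
#'
#' Tallies consensus molecules into per-locus pileups: consensus depth `d`
#' (number of surviving families) and mutant consensus count `m` (families
#' whose consensus equals the locus alt allele). Loci with no surviving
#' families get `d = 0`.
#'
#' @param consensus a [collapse_umi()] result.
#' @param loci data.frame of loci with columns chrom, pos, ref, alt,
#'   context and (optionally) tissue_maf; row order defines `locus_id`.
#' @return an object of class `locus_pileups`: data.frame with locus_id,
#'   chrom, pos, ref, alt, context, context_class, tissue_maf, d, m.
#' @export
pileup_consensus <- function(consensus, loci) {
  dt <- data.table::as.data.table(consensus)
  d <- dt[, .N, by = locus_id]
  m <- dt[consensus == loci$alt[locus_id], .N, by = locus_id]
  out <- data.frame(
    locus_id = seq_len(nrow(loci)),
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    context = loci$context,
    context_class = paste0(loci$context, ">", loci$alt),
    tissue_maf = loci$tissue_maf %||% rep(1, nrow(loci)),
    d = 0L, m = 0L, stringsAsFactors = FALSE
  )
  out$d[d$locus_id] <- d$N
  if (nrow(m)) out$m[m$locus_id] <- m$N
  class(out) <- c("locus_pileups", "data.frame")
  out
}

#' Estimate the trinucleotide background error model
#'
#' Pools control consensus pileups (controls carry no true mutant signal at
#' these loci) and estimates, per trinucleotide substitution class, the
#' background error rate `e = sum(m) / sum(d)`. Classes with pooled depth
#' below `min_class_depth` fall back to the globally pooled rate and are
#' flagged. A class observed error-free is floored at half an error
#' (`0.5 / depth`) rather than exactly zero, keeping downstream
#' likelihood ratios finite.
#'
#' @param control_pileups a `locus_pileups` table, or list of them, from
#'   control samples (or non-matched patients' loci).
#' @param min_class_depth minimum pooled consensus depth per class
#'   (default 10000).
#' @return an object of class `background_error_model`: data.frame of
#'   classes with d, m, rate, fallback flag; attribute `global_rate`.
#' @export
estimate_background <- function(control_pileups, min_class_depth = 10000) {
  if (is.data.frame(control_pileups)) {
    control_pileups <- list(control_pileups)
  }
  pooled <- do.call(rbind, lapply(control_pileups, function(p) {
    p[, c("context_class", "d", "m")]
  }))
  if (sum(pooled$d) == 0) stop_invalid("zero pooled consensus depth")
  agg <- stats::aggregate(cbind(d, m) ~ context_class, pooled, sum)
  # half-a-pseudo-error floor: a class observed error-free at depth d is
  # assigned rate 0.5/d rather than exactly 0, keeping likelihoods finite
  global_rate <- max(sum(agg$m), 0.5) / sum(agg$d)
  agg$fallback <- agg$d < min_class_depth
  agg$rate <- ifelse(agg$fallback, global_rate,
                     pmax(agg$m, 0.5) / agg$d)
  model <- agg[, c("context_class", "d", "m", "rate", "fallback")]
  attr(model, "global_rate") <- global_rate
  class(model) <- c("background_error_model", "data.frame")
  model
}

#' Look up background error rates for pileup loci
#'
#' @param pileups a `locus_pileups` table.
#' @param error_model a [estimate_background()] result.
#' @return numeric vector of per-locus background rates (global fallback for
#'   unseen classes).
#' @export
background_rates <- function(pileups, error_model) {
  idx <- match(pileups$context_class, error_model$context_class)
  e <- error_model$rate[idx]
  e[is.na(e)] <- attr(error_model, "global_rate")
  e
}

#' Per-locus significance of mutant signal
#'
#' One-sided binomial tail probability of observing at least `m` mutant
#' consensus molecules among `d` at the locus' background error rate:
#' `P(X >= m | n = d, p = e)`.
#'
#' @param d consensus depth (vectorized).
#' @param m mutant consensus count.
#' @param e background error rate.
#' @return p-values (1 where `m = 0`; 0 when `e = 0` and `m >= 1`).
#' @export
locus_significance <- function(d, m, e) {
  stopifnot(all(e < 1), all(m <= d))
  pbinom(m - 1, d, e, lower.tail = FALSE)
}

#' Aggregate likelihood score across patient-specific loci
#'
#' The sample-level evidence for ctDNA is a weighted profile-likelihood
#' ratio. A single sample-level allele fraction `f` is profiled over a grid
#' (`{0}` plus log-spaced values); at each `f` the weighted binomial
#' log-likelihood `sum_i w_i log Binom(m_i; d_i, e_i + f)` is evaluated,
#' with weights proportional to each locus' tumor tissue mutant allele
#' fraction (normalized to mean 1), so loci that are clonal in tissue count
#' more. The score is the weighted log-likelihood ratio between the
#' maximizing `f_hat` and `f = 0`; ties break toward smaller `f_hat`, so a
#' signal-free sample scores exactly 0.
#'
#' @param pileups a `locus_pileups` table (loci with `d = 0` contribute
#'   nothing).
#' @param error_model a [estimate_background()] result.
#' @param f_grid candidate allele fractions (default `{0}` plus 61
#'   log-spaced points in 1e-6..1e-1).
#' @return list with `score`, `f_hat`, and the per-locus significance
#'   p-values.
#' @export
aggregate_likelihood <- function(pileups, error_model,
                                 f_grid = c(0, 10^seq(-6, -1,
                                                      length.out = 61))) {
  p <- pileups[pileups$d > 0, , drop = FALSE]
  if (nrow(p) == 0) stop_invalid("no locus with consensus depth > 0")
  e <- background_rates(p, error_model)
  w <- p$tissue_maf
  if (all(is.na(w)) || mean(w) == 0) w <- rep(1, nrow(p))
  w <- w / mean(w)
  ll <- vapply(f_grid, function(f) {
    sum(w * dbinom(p$m, p$d, pmin(e + f, 0.999), log = TRUE))
  }, numeric(1))
  best <- which.max(ll)  # first maximum: ties go to the smaller f
  f_hat <- f_grid[best]
  score <- ll[best] - ll[f_grid == 0][1]
  list(score = score, f_hat = f_hat,
       p_values = locus_significance(p$d, p$m, e))
}

#' ROC-derived detection threshold from non-matched controls
#'
#' Negative control scores come from scoring samples against other
#' patients' mutation lists. The threshold is the smallest control score
#' value achieving at least the target specificity under the strict
#' `score > threshold` detection rule; at target specificity 1 this is the
#' maximum control score.
#'
#' @param control_scores numeric vector of non-matched control scores
#'   (>= 10).
#' @param target_specificity default 0.99.
#' @return the threshold.
#' @export
roc_threshold <- function(control_scores, target_specificity = 0.99) {
  if (length(control_scores) < 10) {
    stop_invalid("need at least 10 non-matched control scores")
  }
  cand <- sort(unique(control_scores))
  spec <- vapply(cand, function(t) mean(control_scores <= t), numeric(1))
  ok <- which(spec >= target_specificity)
  if (!length(ok)) return(max(control_scores))
  cand[ok[1]]
}

#' Background-subtracted global mutant allele fraction
#'
#' `gmAF = max(0, (sum(m) - sum(d * e)) / sum(d))`: the depth-weighted mean
#' mutant allele fraction across patient-specific loci minus the
#' depth-weighted expected background, floored at zero.
#'
#' @param pileups a `locus_pileups` table.
#' @param error_model a [estimate_background()] result.
#' @return the gmAF (>= 0).
#' @export
compute_gmaf <- function(pileups, error_model) {
  if (sum(pileups$d) == 0) stop_invalid("total consensus depth is zero")
  e <- background_rates(pileups, error_model)
  max(0, (sum(pileups$m) - sum(pileups$d * e)) / sum(pileups$d))
}

#' Informative reads and the technical-failure gate
#'
#' Informative reads (IR) are the unique consensus molecules covering
#' patient-specific mutant loci: `IR = sum(d)`. Samples with fewer than
#' 20,000 IR have limited ability to detect ctDNA and are flagged as
#' technical failures (strict `<`); a panel with fewer than 100 loci
#' triggers a warning since few mutations are a common cause of low IR.
#'
#' @param pileups a `locus_pileups` table.
#' @param min_ir technical-failure threshold (default 20000).
#' @param min_loci warning threshold on locus count (default 100).
#' @return list with `ir` and `technical_fail`.
#' @export
informative_reads <- function(pileups, min_ir = 20000, min_loci = 100) {
  if (nrow(pileups) < min_loci) {
    warning(sprintf("only %d patient-specific loci (< %d): expect few informative reads",
                    nrow(pileups), min_loci))
  }
  ir <- sum(pileups$d)
  list(ir = ir, technical_fail = ir < min_ir)
}

#' Run the INVAR-lite targeted detection assay
#'
#' Orchestrates UMI collapse (when raw reads are supplied), per-locus
#' pileups, the aggregate likelihood score, the informative-read gate, and
#' the gmAF. A sample is detected only when it is not a technical failure
#' and its score strictly exceeds the threshold.
#'
#' @param reads raw targeted reads (see [simulate_targeted_reads()]) or an
#'   existing `locus_pileups` table.
#' @param loci the patient's mutation list (ignored when `reads` is already
#'   a pileup table).
#' @param error_model a [estimate_background()] result.
#' @param threshold detection threshold from [roc_threshold()].
#' @param min_ir technical-failure threshold (default 20000).
#' @param ... passed to [collapse_umi()].
#' @return an object of class `invar_result`.
#' @export
run_invar <- function(reads, loci = NULL, error_model, threshold,
                      min_ir = 20000, ...) {
  pileups <- if (inherits(reads, "locus_pileups")) {
    reads
  } else {
    if (is.null(loci)) stop_invalid("`loci` required with raw reads")
    pileup_consensus(collapse_umi(reads, ...), loci)
  }
  gate <- suppressWarnings(informative_reads(pileups, min_ir = min_ir))
  agg <- aggregate_likelihood(pileups, error_model)
  gmaf <- compute_gmaf(pileups, error_model)
  structure(list(
    score = agg$score, f_hat = agg$f_hat, threshold = threshold,
    technical_fail = gate$technical_fail, ir = gate$ir,
    detected = !gate$technical_fail && agg$score > threshold,
    gmaf = gmaf, n_loci = nrow(pileups), pileups = pileups
  ), class = "invar_result")
}

#' @export
print.invar_result <- function(x, ...) {
  cat("INVAR-lite targeted ctDNA detection\n")
  cat(sprintf("  loci %d, informative reads %s%s\n", x$n_loci,
              format(x$ir, big.mark = ","),
              ifelse(x$technical_fail, " (TECHNICAL FAIL: IR < 20,000)", "")))
  cat(sprintf("  aggregate score %.3f vs threshold %.3f -> %s\n",
              x$score, x$threshold,
              ifelse(x$detected, "DETECTED", "not detected")))
  cat(sprintf("  gmAF = %.3g, f_hat = %.3g\n", x$gmaf, x$f_hat))
  invisible(x)
}
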