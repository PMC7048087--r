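#' Build a multi-region mutation matrix
#'
#' Converts long-format allele-fraction measurements into a complete
#' rectangular matrix of samples (tumor regions first, then fluids) by
#' mutations. A fluid locus that was covered but carried no mutant reads is
#' a true 0; an uncovered locus is recorded as missing (NA) and excluded
#' from that fluid's statistics. The per-mutation region count is the
#' number of tumor regions in which the mutation was called; fluids never
#' contribute to it.
#'
#' @param calls long data.frame with columns sample, mutation_id, af and
#'   optionally `covered` (logical, default TRUE) and `called` (logical,
#'   default `af > 0`; only consulted for tumor regions).
#' @param regions character vector naming the tumor-region samples.
#' @param fluids character vector naming the fluid samples.
#' @return an object of class `multiregion_matrix`: list with `matrix`
#'   (samples x mutations, NA = uncovered), `regions`, `fluids`,
#'   `region_count`, `missing` indicator matrix.
#' @export
build_multiregion_matrix <- function(calls, regions, fluids = character(0)) {
  stopifnot(all(c("sample", "mutation_id", "af") %in% names(calls)))
  samples <- c(regions, fluids)
  if (!all(calls$sample %in% samples)) {
    stop_invalid("calls contain samples not named in `regions`/`fluids`")
  }
  muts <- unique(calls$mutation_id)
  mat <- matrix(0, length(samples), length(muts),
                dimnames = list(samples, muts))
  miss <- matrix(FALSE, length(samples), length(muts),
                 dimnames = list(samples, muts))
  covered <- if (is.null(calls$covered)) rep(TRUE, nrow(calls)) else calls$covered
  i <- cbind(match(calls$sample, samples), match(calls$mutation_id, muts))
  mat[i] <- ifelse(covered, calls$af, NA_real_)
  miss[i] <- !covered
  # entries never reported for a fluid are uncovered, for a region 0
  reported <- matrix(FALSE, length(samples), length(muts))
  reported[i] <- TRUE
  if (length(fluids)) {
    frows <- match(fluids, samples)
    unrep <- !reported[frows, , drop = FALSE]
    msub <- miss[frows, , drop = FALSE]; msub[unrep] <- TRUE
    miss[frows, ] <- msub
    asub <- mat[frows, , drop = FALSE]; asub[unrep] <- NA_real_
    mat[frows, ] <- asub
  }
  called <- if (is.null(calls$called)) calls$af > 0 else calls$called
  rc <- integer(length(muts))
  names(rc) <- muts
  reg_calls <- calls[calls$sample %in% regions & called, ]
  tab <- table(factor(reg_calls$mutation_id, levels = muts))
  rc[] <- as.vector(tab)
  structure(list(matrix = mat, regions = regions, fluids = fluids,
                 region_count = rc, missing = miss),
            class = "multiregion_matrix")
}

#' @export
print.multiregion_matrix <- function(x, ...) {
  cat(sprintf("Multi-region mutation matrix: %d regions + %d fluid(s) x %d mutations\n",
              length(x$regions), length(x$fluids), ncol(x$matrix)))
  cat("  region-count distribution:",
      paste(sprintf("%s:%d", names(table(x$region_count)),
                    as.vector(table(x$region_count))), collapse = " "), "\n")
  invisible(x)
}

#' Hierarchically cluster mutations
#'
#' Agglomerative clustering of mutation columns by Euclidean distance
#' (complete linkage by default), leaving sample row order untouched —
#' the standard layout for multi-region allele-fraction heatmaps. Missing
#' entries are treated as 0 for the distance computation.
#'
#' @param mrm a `multiregion_matrix`.
#' @param linkage hclust agglomeration method (default "complete").
#' @return list with `order` (column permutation), `hclust` (the tree), and
#'   the reordered matrix.
#' @export
cluster_mutations <- function(mrm, linkage = "complete") {
  stopifnot(inherits(mrm, "multiregion_matrix"))
  m <- mrm$matrix
  if (ncol(m) < 2) stop_invalid("need at least 2 mutations to cluster")
  m[is.na(m)] <- 0
  hc <- hclust(dist(t(m), method = "euclidean"), method = linkage)
  list(order = hc$order, hclust = hc,
       matrix = mrm$matrix[, hc$order, drop = FALSE])
}

#' Fraction of tumor regions represented in a fluid
#'
#' A tumor region is represented in a fluid when at least one of the
#' mutations called in that region is detected in the fluid. The default
#' detection rule is a positive measured fluid allele fraction at a covered
#' locus; a logical vector (e.g. from targeted-assay per-locus calls) may
#' be supplied instead. Regions with no called mutations are excluded from
#' the denominator with a warning. The same computation restricted to each
#' region's private mutations (region count 1) is returned alongside,
#' since shared mutations cannot distinguish which region a signal came
#' from.
#'
#' @param mrm a `multiregion_matrix`.
#' @param fluid name of the fluid row.
#' @param detected optional logical vector per mutation (TRUE = detected in
#'   the fluid); default `af > 0` at covered loci.
#' @param region_presence optional logical matrix (regions x mutations) of
#'   which mutations are called in which region; default `af > 0`.
#' @return list with `fraction` (regions represented / regions assessable),
#'   `per_region` (logical), `fraction_private`, `per_region_private`.
#' @export
fluid_representation <- function(mrm, fluid, detected = NULL,
                                 region_presence = NULL) {
  stopifnot(inherits(mrm, "multiregion_matrix"), fluid %in% mrm$fluids)
  m <- mrm$matrix
  if (is.null(detected)) {
    f <- m[fluid, ]
    detected <- !is.na(f) & f > 0
  }
  if (is.null(region_presence)) {
    region_presence <- !is.na(m[mrm$regions, , drop = FALSE]) &
      m[mrm$regions, , drop = FALSE] > 0
  }
  assess <- function(presence) {
    has_mut <- rowSums(presence) > 0
    if (any(!has_mut)) {
      warning(sprintf("%d region(s) with no called mutations excluded",
                      sum(!has_mut)))
    }
    rep_ok <- rowSums(presence & rep(detected, each = nrow(presence))) > 0
    list(fraction = sum(rep_ok[has_mut]) / sum(has_mut),
         per_region = rep_ok[has_mut])
  }
  all_m <- assess(region_presence)
  priv <- region_presence &
    rep(mrm$region_count == 1, each = nrow(region_presence))
  prv <- suppressWarnings(assess(priv))
  list(fraction = all_m$fraction, per_region = all_m$per_region,
       fraction_private = prv$fraction, per_region_private = prv$per_region)
}

#' Fluid allele fraction versus region-count trend
#'
#' Groups a fluid's mutant allele fractions by the number of tumor regions
#' each mutation was called in and compares every group against the
#' region-count-1 (private) group with a two-sided rank-sum test. Mutations
#' present in more regions are expected to be more clonal and hence better
#' represented in fluids.
#'
#' @param mrm a `multiregion_matrix`.
#' @param fluid name of the fluid row.
#' @param min_group minimum mutations per compared group (default 3;
#'   undersized groups are skipped with a note).
#' @return an object of class `af_trend`: data.frame per region count with
#'   n, median AF, test statistic and p-value vs the count-1 group (NA for
#'   the reference and skipped groups); attribute `skipped`.
#' @export
af_by_region_count_trend <- function(mrm, fluid, min_group = 3) {
  stopifnot(inherits(mrm, "multiregion_matrix"), fluid %in% mrm$fluids)
  af <- mrm$matrix[fluid, ]
  ok <- !is.na(af)
  af <- af[ok]
  rc <- mrm$region_count[ok]
  counts <- sort(unique(rc))
  baseline <- af[rc == 1]
  skipped <- integer(0)
  rows <- lapply(counts, function(k) {
    grp <- af[rc == k]
    row <- data.frame(region_count = k, n = length(grp),
                      median_af = median(grp), statistic = NA_real_,
                      p_value = NA_real_)
    if (k == 1) return(row)
    if (length(grp) < min_group || length(baseline) < min_group) {
      skipped <<- c(skipped, k)
      return(row)
    }
    wt <- suppressWarnings(wilcox.test(grp, baseline))
    row$statistic <- unname(wt$statistic)
    row$p_value <- wt$p.value
    row
  })
  out <- do.call(rbind, rows)
  if (length(skipped)) {
    message("groups skipped (too few mutations): ",
            paste(skipped, collapse = ", "))
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("af_trend", "data.frame")
  out
}
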