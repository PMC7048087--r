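#' Build a bin track over a genome model
#'
#' Tiles each chromosome with equal-width, non-overlapping bins and
#' aggregates the genome's window-level GC, mappability, and blacklist
#' tracks onto them. The last bin of a chromosome may be short; it is
#' flagged and excluded from analysis. A bin is blacklisted when more than
#' `blacklist_max_fraction` of its span overlaps blacklisted windows.
#'
#' @param genome a `genome_model`.
#' @param bin_bp bin width in bp (e.g. 30000 or 500000).
#' @param blacklist_max_fraction maximum tolerated blacklisted fraction of a
#'   bin before it is excluded (default 0.5).
#' @return an object of class `bin_track`: a data.frame with chrom, start,
#'   end, gc, mappability, blacklist, short; plus attribute `bin_bp`.
#' @export
make_bin_track <- function(genome, bin_bp, blacklist_max_fraction = 0.5) {
  stopifnot(inherits(genome, "genome_model"))
  if (bin_bp <= 0) stop_invalid("`bin_bp` must be positive")
  if (bin_bp %% genome$window_bp != 0) {
    stop_invalid("`bin_bp` must be a multiple of the genome window size (%d)",
                 genome$window_bp)
  }
  out <- vector("list", nrow(genome$chromosomes))
  for (i in seq_len(nrow(genome$chromosomes))) {
    nm <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    starts <- seq(0, len - 1, by = bin_bp)
    ends <- pmin(starts + bin_bp, len)
    w <- genome$windows[genome$windows$chrom == nm, ]
    grp <- findInterval(w$start, starts)
    gc <- tapply(w$gc, grp, mean)
    mp <- tapply(w$mappability, grp, mean)
    blfrac <- tapply(w$blacklist, grp, mean)
    out[[i]] <- data.frame(
      chrom = nm, start = starts, end = ends,
      gc = as.vector(gc), mappability = as.vector(mp),
      blacklist = as.vector(blfrac) > blacklist_max_fraction,
      short = (ends - starts) < bin_bp,
      stringsAsFactors = FALSE
    )
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  attr(bins, "bin_bp") <- bin_bp
  class(bins) <- c("bin_track", "data.frame")
  bins
}

#' Count fragments in bins by midpoint
#'
#' Each fragment is assigned to the bin containing its midpoint
#' (`floor((start + end) / 2)`); a midpoint falling exactly on a bin edge
#' belongs to the bin starting there (half-open convention). Fragments on
#' contigs absent from the track, or beyond chromosome ends, are tallied as
#' rejects rather than failing.
#'
#' @param fragments a fragment table (chrom, start, end).
#' @param bin_track a [make_bin_track()] result.
#' @return an object of class `bin_counts`: the bin track plus a `count`
#'   column; attributes `total_fragments` (fragments used) and `rejected`.
#' @export
count_fragments_in_bins <- function(fragments, bin_track) {
  stopifnot(inherits(bin_track, "bin_track"))
  bin_bp <- attr(bin_track, "bin_bp")
  mid <- floor((fragments$start + fragments$end) / 2)
  # bins tile each chromosome from 0 at equal width, so the bin index is
  # floor(mid / bin_bp) offset by the chromosome's first bin
  chroms <- unique(bin_track$chrom)
  offset <- c(0, cumsum(tabulate(match(bin_track$chrom, chroms),
                                 length(chroms))))[seq_along(chroms)]
  n_bins_chrom <- tabulate(match(bin_track$chrom, chroms), length(chroms))
  ci <- match(fragments$chrom, chroms)
  within <- floor(mid / bin_bp) + 1
  bad <- is.na(ci) | mid < 0 | within > n_bins_chrom[ci]
  bad[is.na(bad)] <- TRUE
  idx <- offset[ci] + within
  counts <- tabulate(idx[!bad], nbins = nrow(bin_track))
  rejected <- sum(bad)
  res <- bin_track
  res$count <- counts
  attr(res, "total_fragments") <- nrow(fragments) - rejected
  attr(res, "rejected") <- rejected
  class(res) <- c("bin_counts", "bin_track", "data.frame")
  res
}

#' GC and mappability correction of bin counts
#'
#' Corrects raw per-bin counts by GC decile: each count is divided by the
#' median count of bins in the same GC decile and rescaled by the overall
#' median, then divided by the bin's mappability. Bins with mappability
#' below `min_mappability`, blacklisted bins, and short terminal bins are
#' excluded. Empty deciles are merged into their neighbor with a warning.
#'
#' @param bin_counts a [count_fragments_in_bins()] result.
#' @param min_mappability exclusion threshold (default 0.5).
#' @return an object of class `corrected_bins`: the bin table with `value`
#'   (corrected) and `included` columns.
#' @export
correct_gc_mappability <- function(bin_counts, min_mappability = 0.5,
                                   min_group_size = 40) {
  stopifnot(inherits(bin_counts, "bin_counts"))
  b <- bin_counts
  included <- !b$blacklist & !b$short & b$mappability >= min_mappability
  value <- rep(NA_real_, nrow(b))
  gc <- b$gc[included]
  cnt <- b$count[included]
  if (!length(cnt)) stop_invalid("no analyzable bins")
  n_groups <- max(2, min(10, length(cnt) %/% min_group_size))
  qs <- unique(quantile(gc, probs = seq(0, 1, 1 / n_groups),
                        names = FALSE))
  if (length(qs) < 2) qs <- range(gc) + c(-1e-9, 1e-9)
  grp <- findInterval(gc, qs, rightmost.closed = TRUE, all.inside = TRUE)
  med_all <- median(cnt)
  med_grp <- tapply(cnt, grp, median)
  if (any(med_grp == 0)) {
    warning("GC group(s) with zero median count merged into the global median")
    med_grp[med_grp == 0] <- med_all
  }
  corr <- cnt / as.vector(med_grp[as.character(grp)]) * med_all
  corr <- corr / b$mappability[included]
  value[included] <- corr
  res <- b
  res$value <- value
  res$included <- included
  class(res) <- c("corrected_bins", "bin_track", "data.frame")
  res
}

#' Build a cohort reference profile
#'
#' Combines corrected control profiles into a single reference: either the
#' per-bin median of the cohort (default; robust to an aberrant control) or
#' a single designated control. Each profile is scaled to unit total over
#' jointly included bins before combining.
#'
#' @param corrected_controls list of `corrected_bins` on an identical track.
#' @param method `"median"` or `"single"`.
#' @param which index of the control used when `method = "single"`.
#' @return a `corrected_bins` reference profile.
#' @export
cohort_reference <- function(corrected_controls, method = c("median", "single"),
                             which = 1L) {
  method <- match.arg(method)
  stopifnot(length(corrected_controls) >= 1)
  if (method == "single") return(corrected_controls[[which]])
  inc <- Reduce(`&`, lapply(corrected_controls, function(x) x$included))
  vals <- vapply(corrected_controls, function(x) {
    v <- x$value
    v / sum(v[inc])
  }, numeric(nrow(corrected_controls[[1]])))
  ref <- corrected_controls[[1]]
  ref$value <- apply(vals, 1, median)
  ref$included <- inc
  ref
}
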