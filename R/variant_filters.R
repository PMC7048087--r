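#' Callable-region mask from germline depth
#'
#' Retains positions whose matched-germline depth is strictly greater than
#' `min_depth` (default 20x) and merges consecutive retained positions into
#' intervals.
#'
#' @param germline_depths data.frame with chrom, pos (1-based), depth.
#' @param min_depth strict lower bound (default 20).
#' @return data.frame of intervals (chrom, start, end; 0-based half-open).
#' @export
callable_mask <- function(germline_depths, min_depth = 20) {
  keep <- germline_depths[germline_depths$depth > min_depth, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  keep <- keep[order(keep$chrom, keep$pos), ]
  out <- list()
  for (nm in unique(keep$chrom)) {
    p <- keep$pos[keep$chrom == nm]
    brk <- c(0, which(diff(p) > 1), length(p))
    for (i in seq_len(length(brk) - 1)) {
      s <- p[brk[i] + 1]; e <- p[brk[i + 1]]
      out[[length(out) + 1]] <- data.frame(chrom = nm, start = s - 1, end = e,
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Keep calls inside a callable mask
#'
#' @param calls variant table with chrom and pos (1-based).
#' @param mask interval set from [callable_mask()].
#' @return the calls inside the mask, with removed calls flagged in the
#'   attached [filter_report()].
#' @export
filter_callable <- function(calls, mask) {
  inside <- vapply(seq_len(nrow(calls)), function(i) {
    p0 <- calls$pos[i] - 1
    any(mask$chrom == calls$chrom[i] & mask$start <= p0 & mask$end > p0)
  }, logical(1))
  add_filter_report(calls[inside, , drop = FALSE], calls, "callable_mask",
                    input = nrow(calls), removed = sum(!inside))
}

#' Population allele frequency filter
#'
#' Removes likely germline polymorphisms: calls with a population allele
#' frequency strictly above the threshold (default 0.02). Unannotated calls
#' (NA) are treated as frequency 0 and retained.
#'
#' @param calls variant table with a `pop_af` column (NA allowed).
#' @param threshold strict upper bound (default 0.02).
#' @return filtered calls.
#' @export
filter_population_af <- function(calls, threshold = 0.02) {
  af <- calls$pop_af
  if (is.null(af)) af <- rep(NA_real_, nrow(calls))
  af[is.na(af)] <- 0
  keep <- af <= threshold
  add_filter_report(calls[keep, , drop = FALSE], calls, "population_af",
                    input = nrow(calls), removed = sum(!keep))
}

#' Normal-adjacent tissue filter
#'
#' Removes any call with allele fraction greater than zero in any
#' normal-adjacent tissue sample. With no normal-adjacent samples the call
#' set is returned unchanged and flagged "NAT-unscreened".
#'
#' @param calls variant table.
#' @param nat_afs matrix or data.frame of per-call allele fractions in each
#'   normal-adjacent sample (rows aligned to `calls`), or NULL.
#' @return filtered calls.
#' @export
filter_normal_adjacent <- function(calls, nat_afs = NULL) {
  if (is.null(nat_afs) || NCOL(nat_afs) == 0) {
    out <- add_filter_report(calls, calls, "normal_adjacent",
                             input = nrow(calls), removed = 0L)
    attr(out, "nat_unscreened") <- TRUE
    return(out)
  }
  nat <- as.matrix(nat_afs)
  stopifnot(nrow(nat) == nrow(calls))
  remove <- apply(nat > 0, 1, any, na.rm = TRUE)
  add_filter_report(calls[!remove, , drop = FALSE], calls, "normal_adjacent",
                    input = nrow(calls), removed = sum(remove))
}

#' FFPE sequence-context artifact filter
#'
#' Formalin fixation produces an excess of C:G>A:T artifacts with a
#' characteristic context: the artifactual C>A calls are typically preceded
#' by C or T, and their reverse-strand images, G>T calls, are preceded by G
#' or A. For FFPE-derived call sets this filter removes exactly those
#' calls — C>A with preceding base in {C, T} and G>T with preceding base in
#' {G, A} — and leaves every other call untouched. Non-FFPE call sets pass
#' through unchanged. Contexts are given on the reference strand as 3-base
#' strings with the middle base equal to the reference allele.
#'
#' @param calls variant table with chrom, pos, ref, alt, context.
#' @param sample_is_ffpe logical; the filter only applies to FFPE samples.
#' @return filtered calls.
#' @export
ffpe_context_filter <- function(calls, sample_is_ffpe) {
  if (!sample_is_ffpe) {
    return(add_filter_report(calls, calls, "ffpe_context",
                             input = nrow(calls), removed = 0L))
  }
  is_ca <- calls$ref == "C" & calls$alt == "A"
  is_gt <- calls$ref == "G" & calls$alt == "T"
  needs_ctx <- is_ca | is_gt
  ctx <- calls$context
  if (any(needs_ctx & (is.na(ctx) | nchar(ctx) != 3))) {
    stop_invalid("C>A/G>T call without trinucleotide context in an FFPE sample")
  }
  prev <- substr(ctx, 1, 1)
  remove <- (is_ca & prev %in% c("C", "T")) | (is_gt & prev %in% c("G", "A"))
  add_filter_report(calls[!remove, , drop = FALSE], calls, "ffpe_context",
                    input = nrow(calls), removed = sum(remove))
}

#' Duplicate-replicate concordance filter
#'
#' Only variants identified in both technical replicates are considered
#' real; the reported allele fraction of a retained variant is the mean of
#' the replicate allele fractions.
#'
#' @param calls_rep1,calls_rep2 variant tables with chrom, pos, ref, alt and
#'   (optionally) af.
#' @return the intersection keyed by (chrom, pos, ref, alt), with `af` set
#'   to the replicate mean.
#' @export
replicate_concordance <- function(calls_rep1, calls_rep2) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  k1 <- key(calls_rep1); k2 <- key(calls_rep2)
  keep <- k1 %in% k2
  out <- calls_rep1[keep, , drop = FALSE]
  if (nrow(out) && !is.null(calls_rep1$af) && !is.null(calls_rep2$af)) {
    out$af <- (calls_rep1$af[keep] +
                 calls_rep2$af[match(k1[keep], k2)]) / 2
  }
  add_filter_report(out, calls_rep1, "replicate_concordance",
                    input = nrow(calls_rep1), removed = sum(!keep))
}

#' Panel annotation filters
#'
#' Targeted-panel post-filters: removes synonymous variants and variants
#' with population minor allele frequency strictly above 1% (treated as
#' polymorphisms).
#'
#' @param calls variant table with logical `synonymous` and numeric
#'   `pop_af` columns (NA treated as FALSE / 0).
#' @param popaf_threshold strict upper bound (default 0.01).
#' @return filtered calls.
#' @export
panel_annotation_filters <- function(calls, popaf_threshold = 0.01) {
  syn <- calls$synonymous
  if (is.null(syn)) syn <- rep(FALSE, nrow(calls))
  syn[is.na(syn)] <- FALSE
  af <- calls$pop_af
  if (is.null(af)) af <- rep(0, nrow(calls))
  af[is.na(af)] <- 0
  remove <- syn | af > popaf_threshold
  add_filter_report(calls[!remove, , drop = FALSE], calls, "panel_annotation",
                    input = nrow(calls), removed = sum(remove))
}

# --- filter report plumbing ---------------------------------------------

add_filter_report <- function(out, prev, filter_name, input, removed) {
  rep_tab <- attr(prev, "filter_report")
  row <- data.frame(filter = filter_name, input = input, removed = removed,
                    retained = input - removed, stringsAsFactors = FALSE)
  attr(out, "filter_report") <- rbind(rep_tab, row)
  out
}

#' Per-filter accounting of a filtered call set
#'
#' @param calls a call set that has passed through one or more filters.
#' @return data.frame with one row per filter: input, removed, retained
#'   counts (input = removed + retained at every stage).
#' @export
filter_report <- function(calls) {
  rep_tab <- attr(calls, "filter_report")
  if (is.null(rep_tab)) {
    return(data.frame(filter = character(0), input = integer(0),
                      removed = integer(0), retained = integer(0)))
  }
  rep_tab
}
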