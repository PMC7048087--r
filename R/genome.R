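#' Build a synthetic genome model
#'
#' Constructs a desk-scale stand-in for a reference genome: a handful of
#' chromosomes with a centromere (arm boundary), a smooth autocorrelated GC
#' track, a mappability track, and a sparse clustered blacklist of windows to
#' exclude from copy-number analysis. All downstream assays (binning, arm
#' z-scores, GC correction) consume this object, so the bin sizes used on
#' real genomes (e.g. 30 kb or 500 kb) remain expressible on smaller
#' chromosomes.
#'
#' @param n_chroms number of chromosomes (>= 1).
#' @param chrom_length_bp length of each chromosome in bp; must be a multiple
#'   of `window_bp`.
#' @param window_bp width of the GC/mappability windows (default 1000).
#' @param seed integer seed; the model is deterministic given the seed.
#' @param blacklist_fraction approximate fraction of windows blacklisted
#'   (default 0.01); blacklisted windows occur in short clustered runs, as
#'   real assembly artifact regions do.
#'
#' @return an object of class `genome_model`: a list with `chromosomes`
#'   (data.frame of name/length), `arm_boundary` (named vector, bp position of
#'   the p/q boundary), `window_bp`, and `windows` (data.frame with chrom,
#'   start, end, gc, mappability, blacklist). All coordinates are 0-based
#'   half-open.
#' @export
build_genome_model <- function(n_chroms = 2, chrom_length_bp = 50e6,
                               window_bp = 1000, seed = 1,
                               blacklist_fraction = 0.01) {
  if (!is.numeric(n_chroms) || n_chroms < 1) {
    stop_invalid("`n_chroms` must be >= 1")
  }
  if (chrom_length_bp <= 0 || window_bp <= 0) {
    stop_invalid("chromosome and window sizes must be positive")
  }
  if (chrom_length_bp %% window_bp != 0) {
    stop_invalid("`window_bp` must divide `chrom_length_bp`")
  }
  n_chroms <- as.integer(n_chroms)
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chroms))
  n_win <- as.integer(chrom_length_bp / window_bp)

  win_list <- vector("list", n_chroms)
  arm_boundary <- numeric(n_chroms)
  names(arm_boundary) <- chrom_names
  for (i in seq_len(n_chroms)) {
    # AR(1) GC track, clipped to [0.3, 0.7]
    phi <- 0.995
    eps <- rnorm(n_win, 0, 0.01)
    g <- numeric(n_win)
    g[1] <- 0.5 + rnorm(1, 0, 0.05)
    for (k in seq_len(n_win)[-1]) g[k] <- 0.5 + phi * (g[k - 1] - 0.5) + eps[k]
    g <- pmin(0.7, pmax(0.3, g))
    # mappability: mostly near 1, ~1% of windows poorly mappable
    m <- pmin(1, pmax(0, 0.97 + rnorm(n_win, 0, 0.015)))
    low <- runif(n_win) < 0.01
    m[low] <- runif(sum(low), 0.1, 0.5)
    # clustered blacklist runs (mean run ~20 windows)
    bl <- rep(FALSE, n_win)
    run_starts <- which(runif(n_win) < blacklist_fraction / 20)
    for (s in run_starts) {
      len <- 1L + stats::rgeom(1, 1 / 20)
      bl[s:min(n_win, s + len - 1L)] <- TRUE
    }
    starts <- (seq_len(n_win) - 1) * window_bp
    win_list[[i]] <- data.frame(
      chrom = chrom_names[i], start = starts, end = starts + window_bp,
      gc = g, mappability = m, blacklist = bl,
      stringsAsFactors = FALSE
    )
    arm_boundary[i] <- floor(chrom_length_bp * runif(1, 0.45, 0.55) /
                               window_bp) * window_bp
  }
  model <- list(
    chromosomes = data.frame(
      name = chrom_names,
      length = rep(chrom_length_bp, n_chroms),
      stringsAsFactors = FALSE
    ),
    arm_boundary = arm_boundary,
    window_bp = window_bp,
    windows = do.call(rbind, win_list)
  )
  class(model) <- "genome_model"
  validate_genome_model(model)
  model
}

validate_genome_model <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  for (i in seq_len(nrow(model$chromosomes))) {
    nm <- model$chromosomes$name[i]
    len <- model$chromosomes$length[i]
    ab <- model$arm_boundary[[nm]]
    if (!(ab > 0 && ab < len)) {
      stop_invalid("arm boundary of %s must lie strictly inside the chromosome", nm)
    }
    w <- model$windows[model$windows$chrom == nm, ]
    if (nrow(w) * model$window_bp != len) {
      stop_invalid("windows do not tile chromosome %s", nm)
    }
  }
  if (any(model$windows$gc < 0 | model$windows$gc > 1)) {
    stop_invalid("gc track out of [0,1]")
  }
  invisible(model)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic genome model\n")
  cat(sprintf("  %d chromosome(s), %s bp each; %d-bp windows\n",
              nrow(x$chromosomes),
              format(x$chromosomes$length[1], big.mark = ","),
              x$window_bp))
  cat(sprintf("  blacklisted windows: %d (%.2f%%)\n",
              sum(x$windows$blacklist),
              100 * mean(x$windows$blacklist)))
  invisible(x)
}

#' Total genome length of a genome model
#' @param genome a `genome_model`.
#' @return total length in bp.
#' @export
genome_length <- function(genome) {
  sum(genome$chromosomes$length)
}
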