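# Shared desk-scale fixtures, built in code. The small genome keeps unit
# tests fast; acceptance tests build their own larger instances.

small_genome <- function() {
  if (is.null(.fixture_env$genome)) {
    .fixture_env$genome <- build_genome_model(n_chroms = 2,
                                              chrom_length_bp = 10e6,
                                              window_bp = 1000, seed = 101)
  }
  .fixture_env$genome
}

.fixture_env <- new.env(parent = emptyenv())

# the standard desk-scale genome (2 x 50 Mb): GC varies slowly relative to
# coarse bins, as on a real genome, so decile-based GC correction does not
# entangle with segment-scale copy-number signal
std_genome <- function() {
  if (is.null(.fixture_env$std_genome)) {
    .fixture_env$std_genome <- build_genome_model(n_chroms = 2,
                                                  chrom_length_bp = 50e6,
                                                  window_bp = 1000, seed = 11)
  }
  .fixture_env$std_genome
}

make_loci <- function(n, seed, chrom = "chr1", ref = "C", alt = "T") {
  set.seed(seed)
  data.frame(
    chrom = chrom,
    pos = seq(5000, by = 2000, length.out = n),
    ref = ref, alt = alt,
    context = paste0(sample(c("A", "C", "G", "T"), n, TRUE), ref,
                     sample(c("A", "C", "G", "T"), n, TRUE)),
    tissue_maf = runif(n, 0.1, 0.6),
    stringsAsFactors = FALSE
  )
}

# corrected-profile stand-in on an arbitrary bin track, for tests that
# exercise normalization/segmentation without the simulator
fake_corrected <- function(values, genome = small_genome(), bin_bp = 2e5) {
  track <- make_bin_track(genome, bin_bp)
  stopifnot(length(values) == nrow(track))
  track$count <- rep(100L, nrow(track))
  attr(track, "total_fragments") <- sum(track$count)
  attr(track, "rejected") <- 0L
  class(track) <- c("bin_counts", "bin_track", "data.frame")
  res <- track
  res$value <- values
  res$included <- !track$blacklist & !track$short & track$mappability >= 0.5
  class(res) <- c("corrected_bins", "bin_track", "data.frame")
  res
}

# minimal normalized profile from a bare log2r vector (all bins included)
fake_profile <- function(log2r, chrom = rep("chr1", length(log2r))) {
  res <- data.frame(
    chrom = chrom,
    start = (seq_along(log2r) - 1) * 1000,
    end = seq_along(log2r) * 1000,
    gc = 0.5, mappability = 1, blacklist = FALSE, short = FALSE,
    log2r = log2r, included = !is.na(log2r),
    stringsAsFactors = FALSE
  )
  attr(res, "mode") <- "control"
  class(res) <- c("normalized_profile", "data.frame")
  res
}

fake_pileups <- function(d, m, tissue_maf = NULL, context = "ACA",
                         alt = "T") {
  n <- length(d)
  out <- data.frame(
    locus_id = seq_len(n), chrom = "chr1", pos = seq_len(n) * 1000,
    ref = "C", alt = alt, context = context,
    context_class = paste0(context, ">", alt),
    tissue_maf = tissue_maf %||% rep(0.3, n),
    d = d, m = m, stringsAsFactors = FALSE
  )
  class(out) <- c("locus_pileups", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
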