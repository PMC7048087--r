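#' Simulation configuration for a synthetic cfDNA sample
#'
#' Bundles everything needed to draw one sample: tumor fraction, fragment
#' count, the somatic copy-number architecture of the tumor, the fragment
#' length model, patient-specific target loci with tissue mutant allele
#' fractions, per-context background error rates, and the GC bias strength.
#' A seed is mandatory: there is no unseeded simulation path.
#'
#' @param tumor_fraction proportion of cfDNA molecules of tumor origin, in
#'   [0, 1].
#' @param n_fragments number of fragments to emit (exact).
#' @param scna_segments data.frame with columns chrom, start, end (0-based
#'   half-open) and copies (integer total tumor copy number; diploid
#'   background is 2). May be NULL/empty for a flat genome.
#' @param length_model a [fragment_length_model()].
#' @param target_loci data.frame of patient-specific SNVs with columns chrom,
#'   pos (1-based), ref, alt, context (trinucleotide, middle base = ref) and
#'   tissue_maf. May be NULL.
#' @param background_error scalar background error rate used at target loci
#'   for non-mutant fragments, or a named vector by context class
#'   (`"ACA>T"` style); default 1e-4.
#' @param gc_bias_strength slope of the linear GC acceptance bias (0 = no
#'   bias).
#' @param seed integer seed (required).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(tumor_fraction = 0, n_fragments = 1e5,
                              scna_segments = NULL,
                              length_model = fragment_length_model(),
                              target_loci = NULL,
                              background_error = 1e-4,
                              gc_bias_strength = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop_invalid("`seed` is mandatory: there is no unseeded simulation path")
  }
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop_invalid("`tumor_fraction` must be in [0, 1]")
  }
  if (n_fragments < 1) stop_invalid("`n_fragments` must be >= 1")
  if (any(background_error < 0) || any(background_error >= 1)) {
    stop_invalid("background error rates must be in [0, 1)")
  }
  if (gc_bias_strength < 0 || gc_bias_strength > 1) {
    stop_invalid("`gc_bias_strength` must be in [0, 1]")
  }
  if (!is.null(scna_segments) && nrow(scna_segments)) {
    stopifnot(all(c("chrom", "start", "end", "copies") %in%
                    names(scna_segments)))
    if (any(scna_segments$copies < 0)) {
      stop_invalid("tumor copy numbers must be >= 0")
    }
    ov <- by(scna_segments, scna_segments$chrom, function(s) {
      s <- s[order(s$start), ]
      nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])
    })
    if (any(unlist(ov))) stop_invalid("scna_segments must not overlap")
  }
  structure(list(
    tumor_fraction = tumor_fraction,
    n_fragments = as.integer(n_fragments),
    scna_segments = scna_segments,
    length_model = length_model,
    target_loci = target_loci,
    background_error = background_error,
    gc_bias_strength = gc_bias_strength,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# per-window total tumor copy number given the SCNA architecture
window_copy_number <- function(genome, scna_segments) {
  w <- genome$windows
  copies <- rep(2, nrow(w))
  if (!is.null(scna_segments) && nrow(scna_segments)) {
    mid <- (w$start + w$end) / 2
    for (i in seq_len(nrow(scna_segments))) {
      seg <- scna_segments[i, ]
      hit <- w$chrom == seg$chrom & mid >= seg$start & mid < seg$end
      copies[hit] <- seg$copies
    }
  }
  copies
}

gc_acceptance <- function(gc, strength) {
  pmin(1, pmax(0.2, 1 + (gc - 0.5) * strength))
}

#' Simulate one cfDNA sample at fragment level
#'
#' Draws exactly `n_fragments` fragments. The expected coverage of a genomic
#' window carrying `c` tumor copies at tumor fraction `tf` is proportional to
#' the standard ctDNA mixing law `(2 * (1 - tf) + c * tf) / 2`, further
#' modulated by a linear GC acceptance bias. Each fragment is tumor-origin
#' with probability `c * tf / (2 * (1 - tf) + c * tf)` given its window;
#' tumor fragments draw lengths from the tumor length component, normal
#' fragments from the normal component. Fragments overlapping a target locus
#' carry the alt allele if they are tumor-origin and the locus samples mutant
#' under its tissue mutant allele fraction; otherwise they carry an error
#' base at the context's background error rate, else the reference base.
#'
#' @param config a [simulation_config()].
#' @param genome a [build_genome_model()] result covering all SCNA segments.
#' @return a data.table with columns chrom, start, end, length, source
#'   ("tumor"/"normal"), umi (NA for whole-genome fragments) and
#'   locus_alleles (";"-separated `locusindex:allele` entries, "" when the
#'   fragment covers no target locus). Coordinates 0-based half-open; rows
#'   grouped by genomic window in ascending chromosome/position order.
#' @export
simulate_sample <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "genome_model"))
  if (nrow(genome$windows) == 0) stop_invalid("empty genome")
  set.seed(config$seed)
  tf <- config$tumor_fraction
  w <- genome$windows
  copies <- window_copy_number(genome, config$scna_segments)
  dilution <- (2 * (1 - tf) + copies * tf) / 2
  weight <- dilution * gc_acceptance(w$gc, config$gc_bias_strength)
  n <- config$n_fragments

  counts <- as.vector(stats::rmultinom(1, n, weight))
  p_tumor <- ifelse(dilution > 0, copies * tf / (2 * dilution), 0)
  tumor_counts <- rbinom(length(counts), counts, p_tumor)

  win_idx <- rep.int(seq_along(counts), counts)
  n_tum <- rep.int(tumor_counts, counts)
  # within each window the first `tumor_counts` fragments are tumor; fragment
  # order is randomized afterwards so this leaves no positional structure
  offset <- sequence(counts)
  is_tumor <- offset <= n_tum

  chrom <- w$chrom[win_idx]
  start <- w$start[win_idx] + floor(runif(n) * genome$window_bp)
  len <- integer(n)
  len[is_tumor] <- sample_fragment_lengths(config$length_model,
                                           sum(is_tumor), "tumor")
  len[!is_tumor] <- sample_fragment_lengths(config$length_model,
                                            sum(!is_tumor), "normal")
  # keep fragments inside the chromosome
  chrom_len <- genome$chromosomes$length[match(chrom, genome$chromosomes$name)]
  start <- pmin(start, chrom_len - len)
  start <- pmax(start, 0)

  frag <- data.table::setDT(list(
    chrom = chrom, start = as.numeric(start),
    end = as.numeric(start + len), length = as.integer(len),
    source = c("normal", "tumor")[is_tumor + 1L],
    umi = rep(NA_character_, n), locus_alleles = rep("", n)
  ))

  loci <- config$target_loci
  if (!is.null(loci) && nrow(loci)) {
    err <- config$background_error
    for (i in seq_len(nrow(loci))) {
      pos0 <- loci$pos[i] - 1  # internal coordinates are 0-based half-open
      ov <- which(frag$chrom == loci$chrom[i] & frag$start <= pos0 &
                    frag$end > pos0)
      if (!length(ov)) next
      cls <- paste0(loci$context[i], ">", loci$alt[i])
      e <- if (length(err) > 1 && cls %in% names(err)) err[[cls]] else err[[1]]
      mutant <- frag$source[ov] == "tumor" & runif(length(ov)) < loci$tissue_maf[i]
      allele <- ifelse(mutant, loci$alt[i],
                       ifelse(runif(length(ov)) < e, "E", loci$ref[i]))
      tag <- paste0(i, ":", allele)
      frag$locus_alleles[ov] <- ifelse(frag$locus_alleles[ov] == "", tag,
                                       paste(frag$locus_alleles[ov], tag,
                                             sep = ";"))
    }
  }
  # rows are already grouped by genomic window in ascending order; a full
  # positional sort is unnecessary for any downstream assay
  frag[]
}

#' A renal-tumor-like SCNA architecture for a synthetic genome
#'
#' Builds the canonical two-arm copy-number architecture used throughout
#' the examples and tests: a one-copy loss over the first 60% of the first
#' chromosome and a one-copy gain over the last 60% of the second,
#' mirroring the paired arm-level loss/gain pattern (3p loss with 3q/8q
#' gain) typical of renal cell carcinoma. The balanced design keeps the
#' genome-wide median log ratio anchored in the neutral state while
#' placing a majority of analyzable bins inside aberrant segments, so the
#' tMAD median responds to tumor fraction.
#'
#' @param genome a `genome_model` with at least 2 chromosomes.
#' @param fraction fraction of each chromosome covered (default 0.6).
#' @return data.frame of SCNA segments (chrom, start, end, copies).
#' @export
rcc_like_scna <- function(genome, fraction = 0.6) {
  stopifnot(nrow(genome$chromosomes) >= 2)
  l1 <- genome$chromosomes$length[1]
  l2 <- genome$chromosomes$length[2]
  data.frame(
    chrom = genome$chromosomes$name[1:2],
    start = c(0, floor(l2 * (1 - fraction))),
    end = c(floor(l1 * fraction), l2),
    copies = c(1L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a healthy control cohort
#'
#' Controls are tumor-free (`tf = 0`) samples drawn with per-sample seeds
#' derived from the master seed and mild per-sample jitter of the GC bias
#' strength, giving the inter-individual variability a real control cohort
#' shows.
#'
#' @param n_controls number of controls (>= 2; a detection threshold needs a
#'   cohort).
#' @param config_template a [simulation_config()]; its tumor fraction and
#'   SCNA segments are ignored (forced to the null).
#' @param genome a `genome_model`.
#' @param seed master seed for the cohort.
#' @param gc_jitter multiplicative range of per-sample GC-bias jitter
#'   (default 0.25 means strengths vary by +/-25%).
#' @return a list of fragment tables.
#' @export
simulate_control_cohort <- function(n_controls, config_template, genome,
                                    seed, gc_jitter = 0.25) {
  if (n_controls < 2) {
    stop_invalid("`n_controls` must be >= 2: a detection threshold needs a cohort")
  }
  set.seed(seed)
  jit <- runif(n_controls, 1 - gc_jitter, 1 + gc_jitter)
  lapply(seq_len(n_controls), function(i) {
    cfg <- config_template
    cfg$tumor_fraction <- 0
    cfg$scna_segments <- NULL
    cfg$gc_bias_strength <- min(1, config_template$gc_bias_strength * jit[i])
    cfg$seed <- derive_seed(seed, i)
    simulate_sample(cfg, genome)
  })
}
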