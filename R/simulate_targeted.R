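#' Simulate targeted UMI-tagged reads at patient-specific loci
#'
#' Emulates deep targeted capture sequencing at a panel of patient-specific
#' mutant loci. Each original molecule gets a unique UMI and a family of raw
#' reads whose size is drawn from a configurable family-size distribution;
#' within-family base errors are injected at a per-read error rate so that
#' UMI consensus collapsing is genuinely exercised. A molecule carries the
#' mutant allele with probability equal to the locus' expected allele
#' fraction in the fluid (typically `tumor_fraction * tissue_maf`).
#'
#' @param loci data.frame with columns chrom, pos (1-based), ref, alt,
#'   context, and either `true_af` (expected fluid mutant allele fraction
#'   per molecule) or `tissue_maf` plus a `tumor_fraction` argument.
#' @param mean_depth expected number of original molecules per locus (> 0).
#'   Molecule counts are Poisson around this unless `exact_depth = TRUE`.
#' @param family_sizes probability vector over family sizes 1, 2, ...;
#'   default `c(0.2, 0.3, 0.3, 0.2)` (sizes 1-4).
#' @param per_read_error probability that a raw read miscalls its molecule's
#'   base (uniformly to one of the three other bases); default 0.01, a
#'   typical raw sequencing substitution rate, which after consensus
#'   collapsing leaves a residual background around 1e-5 per consensus
#'   molecule.
#' @param tumor_fraction used with `loci$tissue_maf` when `true_af` is
#'   absent: per-molecule mutant probability is
#'   `tumor_fraction * tissue_maf`.
#' @param seed integer seed (required).
#' @param exact_depth if TRUE each locus gets exactly `mean_depth` molecules.
#' @return a data.table of raw reads with columns locus_id, chrom, pos, ref,
#'   alt, context, tissue_maf, umi, base.
#' @export
simulate_targeted_reads <- function(loci, mean_depth,
                                    family_sizes = c(0.2, 0.3, 0.3, 0.2),
                                    per_read_error = 0.01,
                                    tumor_fraction = NULL,
                                    seed, exact_depth = FALSE) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  if (is.null(loci) || nrow(loci) == 0) stop_invalid("`loci` must be non-empty")
  if (mean_depth <= 0) stop_invalid("`mean_depth` must be > 0")
  if (abs(sum(family_sizes) - 1) > 1e-8 || any(family_sizes < 0)) {
    stop_invalid("`family_sizes` must be a probability vector over sizes 1..k")
  }
  if (is.null(loci$true_af)) {
    if (is.null(loci$tissue_maf) || is.null(tumor_fraction)) {
      stop_invalid("supply `loci$true_af`, or `loci$tissue_maf` with `tumor_fraction`")
    }
    loci$true_af <- tumor_fraction * loci$tissue_maf
  }
  if (is.null(loci$tissue_maf)) loci$tissue_maf <- loci$true_af
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    n_mol <- if (exact_depth) as.integer(mean_depth) else rpois(1, mean_depth)
    if (n_mol == 0) next
    mutant <- runif(n_mol) < loci$true_af[i]
    true_base <- ifelse(mutant, loci$alt[i], loci$ref[i])
    fam <- sample.int(length(family_sizes), n_mol, replace = TRUE,
                      prob = family_sizes)
    mol_idx <- rep.int(seq_len(n_mol), fam)
    base <- rep.int(true_base, fam)
    flip <- runif(length(base)) < per_read_error
    if (any(flip)) {
      base[flip] <- vapply(base[flip], function(b) {
        sample(setdiff(bases, b), 1)
      }, character(1))
    }
    out[[i]] <- data.table::data.table(
      locus_id = i, chrom = loci$chrom[i], pos = loci$pos[i],
      ref = loci$ref[i], alt = loci$alt[i],
      context = loci$context[i], tissue_maf = loci$tissue_maf[i],
      umi = sprintf("L%d.M%d", i, mol_idx), base = base
    )
  }
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0) {
    stop_invalid("no molecules drawn; increase `mean_depth`")
  }
  out[]
}

#' Simulate a multi-region tumor mutation matrix
#'
#' Builds a mutations-by-samples allele fraction matrix for a tumor sampled
#' at several spatially distinct regions, with truncal mutations present in
#' every region, shared mutations in a random subset, and private mutations
#' in exactly one region. Fluid (plasma/urine) allele fractions are the
#' mixing-weighted mean of the regional allele fractions scaled by the
#' fluid's tumor fraction.
#'
#' @param n_regions number of tumor regions (>= 2).
#' @param n_truncal,n_shared,n_private_per_region mutation counts per
#'   privacy class (>= 0).
#' @param af_range range of regional allele fractions (uniform draw).
#' @param fluid_tf named vector of fluid tumor fractions, e.g.
#'   `c(plasma = 0.02, urine = 0.01)`.
#' @param mixing_weights per-region fluid mixing weights (default equal);
#'   normalized to sum to 1.
#' @param constant_af if TRUE every present mutation takes the midpoint of
#'   `af_range` in every region it occupies (useful for exact checks).
#' @param seed integer seed (required).
#' @return a `multiregion_matrix` object (see [build_multiregion_matrix()]);
#'   the truth (privacy class per mutation, mixing weights) is attached as
#'   attribute `truth`.
#' @export
simulate_multiregion_tumor <- function(n_regions, n_truncal = 10,
                                       n_shared = 10,
                                       n_private_per_region = 5,
                                       af_range = c(0.1, 0.5),
                                       fluid_tf = c(plasma = 0.02,
                                                    urine = 0.01),
                                       mixing_weights = NULL,
                                       constant_af = FALSE,
                                       seed) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  if (n_regions < 2) stop_invalid("`n_regions` must be >= 2")
  if (min(n_truncal, n_shared, n_private_per_region) < 0) {
    stop_invalid("mutation counts must be >= 0")
  }
  set.seed(seed)
  regions <- paste0("T", seq_len(n_regions))
  if (is.null(mixing_weights)) mixing_weights <- rep(1, n_regions)
  mixing_weights <- mixing_weights / sum(mixing_weights)

  n_mut <- n_truncal + n_shared + n_regions * n_private_per_region
  if (n_mut == 0) stop_invalid("no mutations requested")
  presence <- matrix(FALSE, n_regions, n_mut,
                     dimnames = list(regions, NULL))
  class_of <- character(n_mut)
  j <- 0
  for (k in seq_len(n_truncal)) {
    j <- j + 1; presence[, j] <- TRUE; class_of[j] <- "truncal"
  }
  for (k in seq_len(n_shared)) {
    j <- j + 1
    n_in <- sample(2:max(2, n_regions - 1), 1)
    presence[sample(n_regions, n_in), j] <- TRUE
    class_of[j] <- "shared"
  }
  for (r in seq_len(n_regions)) {
    for (k in seq_len(n_private_per_region)) {
      j <- j + 1; presence[r, j] <- TRUE; class_of[j] <- "private"
    }
  }
  af <- matrix(0, n_regions, n_mut, dimnames = dimnames(presence))
  draw <- if (constant_af) {
    function(n) rep(mean(af_range), n)
  } else {
    function(n) runif(n, af_range[1], af_range[2])
  }
  af[presence] <- draw(sum(presence))

  mutation_ids <- sprintf("chr1:%d:C:T", seq_len(n_mut) * 1000L)
  colnames(af) <- mutation_ids

  fluid_af <- t(vapply(names(fluid_tf), function(f) {
    as.vector(fluid_tf[[f]] * (mixing_weights %*% af))
  }, numeric(n_mut)))
  rownames(fluid_af) <- names(fluid_tf)

  mat <- rbind(af, fluid_af)
  obj <- structure(list(
    matrix = mat,
    regions = regions,
    fluids = names(fluid_tf),
    region_count = colSums(presence),
    missing = matrix(FALSE, nrow(mat), n_mut, dimnames = dimnames(mat))
  ), class = "multiregion_matrix")
  attr(obj, "truth") <- list(class = class_of, presence = presence,
                             mixing_weights = mixing_weights,
                             fluid_tf = fluid_tf)
  obj
}
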