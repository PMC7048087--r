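#' Combine detection calls across assays and fluids
#'
#' A patient's combined ctDNA status over a scope of assays/fluids is the
#' logical OR of the in-scope detection flags. Technical-failure records
#' carry no information and are excluded both from the OR and from any
#' denominator; a patient whose in-scope records all failed technically is
#' unscorable (NA).
#'
#' @param records data.frame with columns assay, fluid, detected (logical),
#'   technical_fail (logical, optional).
#' @param assays,fluids optional character vectors restricting the scope
#'   (default: everything present).
#' @return TRUE/FALSE, or NA when no valid in-scope record exists.
#' @export
combine_detection <- function(records, assays = NULL, fluids = NULL) {
  if (nrow(records) == 0) stop_invalid("no records")
  sel <- rep(TRUE, nrow(records))
  if (!is.null(assays)) sel <- sel & records$assay %in% assays
  if (!is.null(fluids)) sel <- sel & records$fluid %in% fluids
  tf <- records$technical_fail
  if (is.null(tf)) tf <- rep(FALSE, nrow(records))
  sel <- sel & !tf
  if (!any(sel)) return(NA)
  any(records$detected[sel])
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact conditional test with the two-sided p-value defined as the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. Degenerate margins give p = 1
#' with a flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `p_value`, `odds_ratio` (conditional MLE), and
#'   `degenerate`.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  ft <- fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       degenerate = FALSE)
}

#' Two-sided Mann-Whitney U (rank-sum) test
#'
#' Wraps the two-sample Wilcoxon rank-sum test, exact for small samples
#' without ties and using the tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return list with `statistic` (U for the first group) and `p_value`.
#' @export
mannwhitney_u <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop_invalid("both groups must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Cohort-level detection report
#'
#' Summarizes a per-(patient, fluid, assay) detection table into the
#' statistics a cohort analysis reports: detection rates per assay and
#' fluid with explicit numerators and denominators (technical failures
#' excluded from both), the combined-detection rate, Fisher's exact
#' association of combined detection with a binary covariate (e.g. venous
#' tumor thrombus), a rank-sum comparison of a continuous covariate (e.g.
#' tumor size) between detected and not-detected patients, and the Spearman
#' correlation of plasma versus urine gmAF where both are measured.
#'
#' @param table data.frame with columns patient, fluid, assay, detected,
#'   and optionally technical_fail, gmaf, plus per-patient covariate
#'   columns `tumor_size_cm` and `thrombus`.
#' @return an object of class `cohort_report`.
#' @export
cohort_report <- function(table) {
  stopifnot(all(c("patient", "fluid", "assay", "detected") %in% names(table)))
  if (is.null(table$technical_fail)) table$technical_fail <- FALSE
  valid <- !table$technical_fail
  rate_by <- function(split_col) {
    parts <- split(table[valid, ], table[[split_col]][valid])
    do.call(rbind, lapply(names(parts), function(nm) {
      x <- parts[[nm]]
      data.frame(group = nm, detected = sum(x$detected), n = nrow(x),
                 rate = sum(x$detected) / nrow(x), stringsAsFactors = FALSE)
    }))
  }
  patients <- unique(table$patient)
  combined <- vapply(patients, function(p) {
    combine_detection(table[table$patient == p, , drop = FALSE])
  }, logical(1))
  usable <- !is.na(combined)
  out <- list(
    per_assay = rate_by("assay"),
    per_fluid = rate_by("fluid"),
    combined = data.frame(detected = sum(combined[usable]),
                          n = sum(usable),
                          rate = mean(combined[usable])),
    excluded_patients = patients[!usable]
  )
  per_patient <- data.frame(patient = patients, detected = combined,
                            stringsAsFactors = FALSE)
  cov <- unique(table[, intersect(c("patient", "tumor_size_cm", "thrombus"),
                                  names(table)), drop = FALSE])
  per_patient <- merge(per_patient, cov, by = "patient", all.x = TRUE)
  if ("thrombus" %in% names(per_patient)) {
    pp <- per_patient[usable & !is.na(per_patient$thrombus), ]
    tab <- table(factor(pp$detected, c(TRUE, FALSE)),
                 factor(pp$thrombus, c(TRUE, FALSE)))
    out$thrombus_fisher <- fisher_2x2(tab)
  }
  if ("tumor_size_cm" %in% names(per_patient)) {
    pp <- per_patient[usable & !is.na(per_patient$tumor_size_cm), ]
    if (any(pp$detected) && any(!pp$detected)) {
      out$size_test <- mannwhitney_u(pp$tumor_size_cm[pp$detected],
                                     pp$tumor_size_cm[!pp$detected])
    }
  }
  if ("gmaf" %in% names(table)) {
    wide <- lapply(c("plasma", "urine"), function(fl) {
      x <- table[table$fluid == fl & !is.na(table$gmaf), ]
      stats::setNames(tapply(x$gmaf, x$patient, max), unique(x$patient))
    })
    shared <- intersect(names(wide[[1]]), names(wide[[2]]))
    if (length(shared) >= 3) {
      out$plasma_urine_spearman <- suppressWarnings(
        cor(wide[[1]][shared], wide[[2]][shared], method = "spearman"))
    }
  }
  out$per_patient <- per_patient
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort detection report\n")
  cat(sprintf("  combined detection: %d/%d (%.1f%%)\n",
              x$combined$detected, x$combined$n, 100 * x$combined$rate))
  for (nm in c("per_assay", "per_fluid")) {
    for (i in seq_len(nrow(x[[nm]]))) {
      r <- x[[nm]][i, ]
      cat(sprintf("    %-12s %d/%d (%.1f%%)\n", r$group, r$detected, r$n,
                  100 * r$rate))
    }
  }
  if (!is.null(x$thrombus_fisher)) {
    cat(sprintf("  thrombus association: Fisher p = %.3g\n",
                x$thrombus_fisher$p_value))
  }
  if (!is.null(x$size_test)) {
    cat(sprintf("  tumor size vs detection: Mann-Whitney p = %.3g\n",
                x$size_test$p_value))
  }
  if (!is.null(x$plasma_urine_spearman)) {
    cat(sprintf("  plasma-urine gmAF Spearman rho = %.2f\n",
                x$plasma_urine_spearman))
  }
  invisible(x)
}
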