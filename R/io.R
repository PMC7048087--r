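#' Read and write fragment tables
#'
#' Fragment tables are TSV files with header
#' `chrom start end length source umi locus_alleles`, 0-based half-open
#' coordinates (BED-compatible first three columns), `.` for missing UMIs
#' and locus annotations. Gzip-compressed files are handled transparently.
#' Round trips are lossless on the canonical form.
#'
#' @param path file path (`.tsv` or `.tsv.gz`).
#' @return [read_fragments()]: a data.table of fragments.
#' @export
read_fragments <- function(path) {
  if (grepl("\\.gz$", path)) {
    # route gzip through a base connection; fread reads plain text fastest
    dt <- data.table::as.data.table(
      utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                        colClasses = c(chrom = "character",
                                       umi = "character",
                                       locus_alleles = "character"),
                        stringsAsFactors = FALSE))
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c("chrom", "umi",
                                                            "locus_alleles")))
  }
  required <- c("chrom", "start", "end", "length", "source", "umi",
                "locus_alleles")
  if (!all(required %in% names(dt))) {
    stop_invalid("fragment table must have columns: %s",
                 paste(required, collapse = " "))
  }
  bad <- which(dt$end <= dt$start)
  if (length(bad)) {
    stop_invalid("end <= start at line %d of %s", bad[1] + 1L, path)
  }
  bad_len <- which(dt$length != dt$end - dt$start)
  if (length(bad_len)) {
    stop_invalid("length != end - start at line %d of %s", bad_len[1] + 1L,
                 path)
  }
  dt[umi == ".", umi := NA_character_]
  dt[locus_alleles == ".", locus_alleles := ""]
  dt[]
}

#' @rdname read_fragments
#' @param fragments fragment table to write.
#' @return [write_fragments()]: the path, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  out <- data.table::as.data.table(fragments)
  out <- out[, c("chrom", "start", "end", "length", "source", "umi",
                 "locus_alleles"), with = FALSE]
  out[is.na(umi), umi := "."]
  out[locus_alleles == "", locus_alleles := "."]
  data.table::fwrite(out, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a patient mutation list from VCF
#'
#' Reads single-nucleotide variants from a VCF 4.x file into a mutation
#' list. Multi-allelic records are split into one record per alternate
#' allele; indels are skipped and counted in the `skipped_indels`
#' attribute. The trinucleotide context and tissue mutant allele fraction
#' are read from the `CTX` and `TMAF` INFO keys when present (the
#' convention [write_vcf_mutations()] uses). Positions are 1-based at this
#' boundary — the only 1-based surface in the package.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return an object of class `mutation_list`: data.frame with chrom, pos,
#'   ref, alt, context, tissue_maf.
#' @export
read_vcf_mutations <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    val <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]+"),
                                             info))) > 0
    val[hit] <- sub(paste0("^;?", key, "="), "", m)
    val
  }
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (nchar(fix$REF[i]) != 1L || nchar(alt) != 1L) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
        ref = fix$REF[i], alt = alt, stringsAsFactors = FALSE
      )
    }
  }
  if (skipped) warning(sprintf("%d non-SNV allele(s) skipped", skipped))
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  }
  ctx <- info_field(fix$INFO, "CTX")
  tmaf <- suppressWarnings(as.numeric(info_field(fix$INFO, "TMAF")))
  snv_row <- integer(0)
  k <- 0
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (nchar(fix$REF[i]) == 1L && nchar(alt) == 1L) {
        k <- k + 1
        snv_row[k] <- i
      }
    }
  }
  out$context <- ctx[snv_row]
  out$tissue_maf <- tmaf[snv_row]
  attr(out, "skipped_indels") <- skipped
  class(out) <- c("mutation_list", "data.frame")
  out
}

#' Write a mutation list to VCF
#'
#' Writes SNVs with `CTX` (trinucleotide context) and `TMAF` (tissue mutant
#' allele fraction) INFO keys. Output is gzip-compressed (use a `.vcf.gz`
#' path).
#'
#' @param mutations a mutation list (chrom, pos, ref, alt, and optionally
#'   context, tissue_maf).
#' @param path output path ending in `.vcf.gz`.
#' @return the path, invisibly.
#' @export
write_vcf_mutations <- function(mutations, path) {
  n <- nrow(mutations)
  parts <- vapply(seq_len(n), function(i) {
    p <- character(0)
    if (!is.null(mutations$context) && !is.na(mutations$context[i])) {
      p <- c(p, paste0("CTX=", mutations$context[i]))
    }
    if (!is.null(mutations$tissue_maf) && !is.na(mutations$tissue_maf[i])) {
      p <- c(p, paste0("TMAF=", format(mutations$tissue_maf[i],
                                       scientific = FALSE)))
    }
    if (length(p)) paste(p, collapse = ";") else "."
  }, character(1))
  fix <- cbind(
    CHROM = as.character(mutations$chrom),
    POS = as.character(as.integer(mutations$pos)),
    ID = rep(".", n), REF = mutations$ref, ALT = mutations$alt,
    QUAL = rep(".", n), FILTER = rep("PASS", n), INFO = parts
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide context (middle base = REF)\">",
    "##INFO=<ID=TMAF,Number=1,Type=Float,Description=\"Tissue mutant allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta[-length(meta)], fix = fix,
                    gt = matrix(character(0), nrow = 0, ncol = 0))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a BED interval track
#'
#' Reads BED3+ intervals (0-based half-open), sorts them, and optionally
#' merges overlapping or adjacent intervals. Negative coordinates are an
#' error; intervals extending beyond a supplied genome's chromosome ends
#' are a validation error.
#'
#' @param path BED path (gzip accepted).
#' @param merge merge overlapping intervals (default TRUE).
#' @param genome optional `genome_model` for bounds checking.
#' @return data.frame with chrom, start, end (0-based half-open), sorted.
#' @export
read_bed_track <- function(path, merge = TRUE, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (merge) gr <- GenomicRanges::reduce(gr)
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1, end = df$end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$start < 0)) stop_invalid("negative coordinates in %s", path)
  if (!is.null(genome)) {
    lim <- genome$chromosomes$length[match(out$chrom,
                                           genome$chromosomes$name)]
    if (any(is.na(lim)) || any(out$end > lim)) {
      stop_invalid("interval beyond chromosome bounds in %s", path)
    }
  }
  out
}

#' Write a BED interval track
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed_track <- function(intervals, path) {
  data.table::fwrite(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Assemble a result record
#'
#' One row per (sample, assay): the assay statistic, its threshold, the
#' detection flag (consistency with `statistic > threshold` is enforced for
#' the standard greater-than rule), and free-form ancillary metrics.
#'
#' @param sample_id,assay identifiers.
#' @param statistic,threshold assay statistic and decision threshold.
#' @param detected logical.
#' @param technical_fail logical (default FALSE).
#' @param ... ancillary scalar metrics appended as columns.
#' @return one-row data.frame of class `result_record`.
#' @export
result_record <- function(sample_id, assay, statistic, threshold, detected,
                          technical_fail = FALSE, ...) {
  out <- data.frame(sample_id = sample_id, assay = assay,
                    statistic = statistic, threshold = threshold,
                    detected = detected, technical_fail = technical_fail,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("result_record", "data.frame")
  out
}

#' Write result records as TSV plus a JSON report
#'
#' @param records a data.frame of stacked [result_record()] rows.
#' @param tsv_path,json_path output paths (either may be NULL).
#' @return invisibly, the list written to JSON.
#' @export
write_results <- function(records, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    data.table::fwrite(records, tsv_path, sep = "\t")
  }
  report <- list(schema_version = "1.0", results = records)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
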