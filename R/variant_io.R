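#' Read per-sample allelic depths from a VCF or tab-delimited table
#'
#' Normalizes input into the internal allelic-depth table: one row per
#' biallelic SNP with columns `chrom`, `pos`, `ref`, `alt` and, for every
#' requested sample, `<sample>_ref` and `<sample>_alt` read counts taken from
#' the VCF `AD` field. Multiallelic sites, indels (or any non-ACGT allele) and
#' sites with a missing `AD` value in a requested sample are skipped and
#' tallied in the `skip_counts` attribute, so that
#' `n_records + n_skipped_multiallelic + n_skipped_indel + n_skipped_missing_ad`
#' equals the number of VCF body lines.
#'
#' @param path VCF (`.vcf`) or TSV file. TSV must follow the dialect written by
#'   [write_depth_table()]: columns `chrom`, `pos`, `ref`, `alt`,
#'   `<sample>_ref`, `<sample>_alt`.
#' @param samples character vector of sample ids that must be present.
#' @return data.frame of class `allelic_depths`, ordered by `(chrom, pos)`,
#'   with attributes `samples` and `skip_counts`.
#' @export
read_allelic_depths <- function(path, samples) {
  if (!file.exists(path)) abort_data(sprintf("input file not found: %s", path))
  if (length(samples) < 1) abort_config("at least one sample id is required")
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    read_allelic_depths_vcf(path, samples)
  } else {
    read_depth_table(path, samples)
  }
}

read_allelic_depths_vcf <- function(path, samples) {
  vcf <- tryCatch(VariantAnnotation::readVcf(path, genome = "unknown"),
                  error = function(e) abort_data(sprintf("cannot read VCF %s: %s",
                                                         path, conditionMessage(e))))
  missing <- setdiff(samples, colnames(vcf))
  if (length(missing) > 0) {
    abort_config(sprintf("sample(s) not in VCF header: %s",
                         paste(missing, collapse = ", ")))
  }
  n_body <- nrow(vcf)
  if (n_body == 0) {
    return(empty_depths(samples,
                        counts = list(n_records = 0L, n_skipped_multiallelic = 0L,
                                      n_skipped_indel = 0L, n_skipped_missing_ad = 0L,
                                      n_body_lines = 0L)))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(S4Vectors::decode(GenomeInfoDb::seqnames(rr)))
  pos <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  multi <- n_alt != 1L
  alt1 <- rep(NA_character_, n_body)
  if (any(!multi)) alt1[!multi] <- as.character(unlist(altl[!multi]))
  bases <- c("A", "C", "G", "T")
  is_snv <- !multi & refs %in% bases & alt1 %in% bases
  n_indel <- sum(!multi & !is_snv)

  g <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(g)) {
    # no AD anywhere: every (non-multiallelic, SNV) site lacks allelic depth
    return(empty_depths(samples,
                        counts = list(n_records = 0L,
                                      n_skipped_multiallelic = sum(multi),
                                      n_skipped_indel = n_indel,
                                      n_skipped_missing_ad = sum(is_snv),
                                      n_body_lines = n_body)))
  }
  ad <- g$AD
  ref_mat <- matrix(NA_integer_, nrow = n_body, ncol = length(samples),
                    dimnames = list(NULL, samples))
  alt_mat <- ref_mat
  for (s in samples) {
    col <- ad[, s]
    ok <- vapply(col, function(v) length(v) >= 2 && !anyNA(v[1:2]), logical(1))
    ref_mat[ok, s] <- vapply(col[ok], function(v) as.integer(v[1]), integer(1))
    alt_mat[ok, s] <- vapply(col[ok], function(v) as.integer(v[2]), integer(1))
  }
  has_ad <- rowSums(is.na(ref_mat)) == 0
  n_missing_ad <- sum(is_snv & !has_ad)
  keep <- is_snv & has_ad

  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    ref = refs[keep], alt = alt1[keep],
                    stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0(s, "_ref")]] <- ref_mat[keep, s]
    out[[paste0(s, "_alt")]] <- alt_mat[keep, s]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  as_allelic_depths(out, samples,
                    counts = list(n_records = sum(keep),
                                  n_skipped_multiallelic = sum(multi),
                                  n_skipped_indel = n_indel,
                                  n_skipped_missing_ad = n_missing_ad,
                                  n_body_lines = n_body))
}

#' Read the tab-delimited allelic-depth dialect
#'
#' @inheritParams read_allelic_depths
#' @return see [read_allelic_depths()]
#' @export
read_depth_table <- function(path, samples) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt",
            paste0(rep(samples, each = 2), c("_ref", "_alt")))
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort_config(sprintf("depth table %s lacks column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  x <- x[order(x$chrom, x$pos), need, drop = FALSE]
  rownames(x) <- NULL
  validate_depths(x, samples)
  as_allelic_depths(x, samples,
                    counts = list(n_records = nrow(x), n_skipped_multiallelic = 0L,
                                  n_skipped_indel = 0L, n_skipped_missing_ad = 0L,
                                  n_body_lines = nrow(x)))
}

validate_depths <- function(x, samples) {
  if (any(x$pos < 1)) abort_data("positions must be >= 1 (1-based)")
  if (any(x$ref == x$alt)) abort_data("ref and alt alleles must differ")
  cnt <- unlist(x[paste0(rep(samples, each = 2), c("_ref", "_alt"))])
  if (any(cnt < 0, na.rm = TRUE)) abort_data("read counts must be non-negative")
  invisible(x)
}

as_allelic_depths <- function(x, samples, counts) {
  attr(x, "samples") <- samples
  attr(x, "skip_counts") <- counts
  class(x) <- c("allelic_depths", "data.frame")
  x
}

empty_depths <- function(samples, counts) {
  out <- data.frame(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0(s, "_ref")]] <- integer()
    out[[paste0(s, "_alt")]] <- integer()
  }
  as_allelic_depths(out, samples, counts)
}

#' Write the internal allelic-depth table as TSV
#'
#' Round-trip safe with [read_depth_table()].
#'
#' @param x `allelic_depths` data.frame
#' @param path output file
#' @export
write_depth_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Chromosome-arm boundary map
#'
#' Reads arm boundaries from a UCSC-style 5-column cytoband file (arms are
#' delimited by the `acen` bands) or a 3-column `chrom  p_end  q_start` table
#' (with or without a header line). With `path = NULL` a built-in hg19 chr18
#' default is returned, derived from the hg19 cytoBand acen rows
#' (p11.1: 15,400,000-17,200,000; q11.1: 17,200,000-19,000,000), i.e.
#' `p_end = 15400000`, `q_start = 19000001`. Positions are 1-based; the p arm
#' is `[1, p_end]`, the q arm `[q_start, chrom_end]`, and positions strictly
#' between are centromeric.
#'
#' @param path file path, or NULL for the built-in hg19 chr18 default.
#' @return data.frame of class `arm_map` with columns `chrom`, `p_end`,
#'   `q_start`.
#' @export
read_arm_map <- function(path = NULL) {
  if (is.null(path)) {
    return(new_arm_map(data.frame(chrom = "chr18", p_end = 15400000,
                                  q_start = 19000001,
                                  stringsAsFactors = FALSE),
                       source = "builtin-hg19-cytoband-acen"))
  }
  if (!file.exists(path)) abort_data(sprintf("arm map file not found: %s", path))
  first <- readLines(path, n = 1)
  ncol1 <- length(strsplit(first, "\t|[ ]+")[[1]])
  if (ncol1 >= 5) {
    cb <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "band", "stain"))
    acen <- cb[cb$stain == "acen", , drop = FALSE]
    if (nrow(acen) == 0) abort_data("cytoband file has no acen rows")
    sp <- split(acen, acen$chrom)
    out <- do.call(rbind, lapply(sp, function(a) {
      # cytoband starts are 0-based: the last p-arm bp is the acen start itself
      data.frame(chrom = a$chrom[1], p_end = min(a$start),
                 q_start = max(a$end) + 1, stringsAsFactors = FALSE)
    }))
  } else {
    has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t|[ ]+")[[1]][2])))
    out <- utils::read.table(path, header = has_header,
                             stringsAsFactors = FALSE)
    names(out) <- c("chrom", "p_end", "q_start")
  }
  rownames(out) <- NULL
  new_arm_map(out, source = path)
}

new_arm_map <- function(x, source) {
  if (any(x$p_end >= x$q_start)) {
    abort_data("arm map invalid: p_end must be < q_start for every chromosome")
  }
  attr(x, "source") <- source
  class(x) <- c("arm_map", "data.frame")
  x
}

#' Assign positions to chromosome arms
#'
#' @param arms `arm_map`
#' @param chrom,pos parallel vectors of chromosome names and 1-based positions
#' @return character vector: `"p"`, `"q"` or `"cen"` (centromeric positions are
#'   excluded from arm-level statistics but kept whole-chromosome).
#' @export
arm_of <- function(arms, chrom, pos) {
  i <- match(chrom, arms$chrom)
  if (anyNA(i)) {
    abort_config(sprintf("chromosome(s) missing from arm map: %s",
                         paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  ifelse(pos <= arms$p_end[i], "p", ifelse(pos >= arms$q_start[i], "q", "cen"))
}

#' Write pipeline result tables and run summary
#'
#' Emits deterministic, byte-stable TSVs (informative SNPs, per-tumor
#' profiles, pairwise concordances) plus `patient.json` and `summary.json`.
#' Running twice on identical inputs produces identical bytes.
#'
#' @param result list as returned by [map_patient()]
#' @param out_dir output directory (created if needed)
#' @param summary_extra named list merged into the run summary (thresholds,
#'   seeds, config hash, ...)
#' @return invisibly, the vector of files written
#' @export
write_results <- function(result, out_dir, summary_extra = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort_data(sprintf("cannot write to output directory: %s", out_dir))
  }
  files <- character()
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv_stable(x, p)
    files <<- c(files, p)
  }
  w(result$informative, "informative_snps.tsv")
  # one row per retained tumor profile; per-stage tallies for every tumor
  # (including dropped ones) live in the summary JSON
  prof <- do.call(rbind, lapply(Filter(function(p) p$retained, result$profiles),
                                function(p) {
    data.frame(tumor_id = p$tumor_id, n_het = p$counts$n_het,
               n_tested = p$counts$n_tested,
               n_informative = p$counts$n_informative,
               retained = p$retained, stringsAsFactors = FALSE)
  }))
  if (is.null(prof)) {
    prof <- data.frame(tumor_id = character(), n_het = integer(),
                       n_tested = integer(), n_informative = integer(),
                       retained = logical())
  }
  w(prof, "tumor_profiles.tsv")
  w(result$pattern$pairs, "pair_concordance.tsv")
  if (!is.null(result$cnv)) w(result$cnv, "cnv_calls.tsv")

  pj <- file.path(out_dir, "patient.json")
  jsonlite::write_json(unclass(result$pattern[c("patient_id", "pattern", "groups",
                                                "n_common_sites", "notes")]),
                       pj, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  files <- c(files, pj)

  summary <- c(list(
    pipeline = "lohmapr",
    version = as.character(utils::packageVersion("lohmapr")),
    pattern = result$pattern$pattern,
    n_tumors = length(result$profiles),
    n_retained = sum(vapply(result$profiles, `[[`, logical(1), "retained")),
    stage_counts = lapply(result$profiles, `[[`, "counts"),
    skip_counts = result$skip_counts
  ), summary_extra)
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(files, sj))
}
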