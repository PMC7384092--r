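#' Filtering and testing thresholds
#'
#' Defaults follow the LOH-mapping procedure: germline heterozygous SNPs are
#' sites with normal read depth strictly greater than `min_depth` and variant
#' allele frequency within `[vaf_lo, vaf_hi]` (inclusive); tumors are tested at
#' the same strict depth bound; SNPs with Benjamini-Hochberg adjusted binomial
#' p below `fdr_alpha` are LOH-informative; a tumor sample is retained when it
#' carries at least `min_informative_wgs` (WGS) or `min_informative_wes` (WES)
#' informative SNPs.
#'
#' @param min_depth strict lower bound on read depth (site is used iff
#'   depth > `min_depth`), both normal and tumor side. Default 10.
#' @param vaf_lo,vaf_hi inclusive VAF window for the normal-sample het call.
#'   Defaults 0.4 and 0.6.
#' @param fdr_alpha FDR cutoff (q < `fdr_alpha`). Default 0.1.
#' @param min_informative_wgs,min_informative_wes retention thresholds
#'   ("at least N informative SNPs"). Defaults 1000 and 100.
#' @param mode `"WGS"` or `"WES"`; selects which retention threshold applies.
#' @return object of class `loh_thresholds`
#' @export
loh_thresholds <- function(min_depth = 10, vaf_lo = 0.4, vaf_hi = 0.6,
                           fdr_alpha = 0.1, min_informative_wgs = 1000,
                           min_informative_wes = 100,
                           mode = c("WGS", "WES")) {
  mode <- match.arg(mode)
  if (!(vaf_lo >= 0 && vaf_lo < vaf_hi && vaf_hi <= 1)) {
    abort_config("require 0 <= vaf_lo < vaf_hi <= 1")
  }
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) abort_config("require 0 < fdr_alpha < 1")
  if (min_depth < 0) abort_config("min_depth must be >= 0")
  if (min_informative_wgs < 1 || min_informative_wes < 1) {
    abort_config("retention thresholds must be >= 1")
  }
  structure(list(min_depth = min_depth, vaf_lo = vaf_lo, vaf_hi = vaf_hi,
                 fdr_alpha = fdr_alpha,
                 min_informative_wgs = min_informative_wgs,
                 min_informative_wes = min_informative_wes, mode = mode),
            class = "loh_thresholds")
}

min_informative <- function(thr) {
  if (thr$mode == "WGS") thr$min_informative_wgs else thr$min_informative_wes
}

#' Call germline heterozygous SNPs from normal-sample read counts
#'
#' A site is heterozygous when its normal read depth is strictly greater than
#' `thr$min_depth` and its VAF (alt / depth) lies in `[vaf_lo, vaf_hi]`.
#' Genotype fields are never consulted; only read counts decide.
#'
#' @param records `allelic_depths` table
#' @param normal normal sample id
#' @param thr [loh_thresholds()]
#' @return data.frame `chrom, pos, ref, alt, normal_ref, normal_alt,
#'   normal_vaf`, sorted by `(chrom, pos)`
#' @export
call_het_snps <- function(records, normal, thr = loh_thresholds()) {
  rc <- paste0(normal, "_ref"); ac <- paste0(normal, "_alt")
  if (!all(c(rc, ac) %in% names(records))) {
    abort_config(sprintf("normal sample '%s' not present in records", normal))
  }
  dep <- records[[rc]] + records[[ac]]
  vaf <- ifelse(dep > 0, records[[ac]] / dep, NA_real_)
  keep <- !is.na(vaf) & dep > thr$min_depth &
    vaf >= thr$vaf_lo & vaf <= thr$vaf_hi
  out <- data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
                    ref = records$ref[keep], alt = records$alt[keep],
                    normal_ref = records[[rc]][keep],
                    normal_alt = records[[ac]][keep],
                    stringsAsFactors = FALSE)
  out$normal_vaf <- out$normal_alt / (out$normal_ref + out$normal_alt)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact two-sided binomial test p-value against 0.5
#'
#' For `X ~ Binomial(n, 0.5)`, returns
#' `min(1, 2 * min(P[X <= k], P[X >= k]))`. Under the symmetric null this
#' equals the minimum-likelihood two-sided p-value (the sum of probabilities of
#' all outcomes no more likely than `k`). Vectorized over `k` and `n`.
#'
#' @param k_alt observed alt-read count(s)
#' @param n total read count(s), `n >= 1`
#' @return p-value(s) in (0, 1]
#' @export
binomial_two_sided_p <- function(k_alt, n) {
  if (length(k_alt) != length(n)) {
    r <- max(length(k_alt), length(n))
    k_alt <- rep_len(k_alt, r); n <- rep_len(n, r)
  }
  if (any(n < 1) || any(k_alt < 0) || any(k_alt > n)) {
    abort_data("binomial test requires 0 <= k_alt <= n and n >= 1")
  }
  lo <- stats::pbinom(k_alt, n, 0.5)
  hi <- stats::pbinom(k_alt - 1, n, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q(i) = min_{j >= i} m * p(j) / j` over the ascending sort, capped at 1 and
#' returned in the input order. Ties share one adjusted value.
#'
#' @param p_values numeric vector in `[0, 1]`
#' @return adjusted values, same length and order
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort_data("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

#' Assign the retained allele from tumor read counts
#'
#' REF when the reference count exceeds the alternative count, ALT otherwise.
#' Equal counts give a binomial p of 1 and can never pass the FDR filter, so a
#' tie among informative SNPs indicates an internal inconsistency and raises an
#' error.
#'
#' @param ref_count,alt_count tumor read counts at informative SNPs
#' @return character vector of `"REF"` / `"ALT"`
#' @export
assign_retained_allele <- function(ref_count, alt_count) {
  if (any(ref_count == alt_count)) {
    abort_data("tied read counts at an informative SNP: p = 1 cannot pass the FDR filter")
  }
  ifelse(ref_count > alt_count, "REF", "ALT")
}

#' Select LOH-informative SNPs for one tumor and decide sample retention
#'
#' At every germline het SNP with tumor depth strictly greater than
#' `thr$min_depth`, tests the tumor alt count against Binomial(depth, 0.5),
#' adjusts all p-values of this tumor jointly (one FDR family per tumor
#' sample), keeps SNPs with `q < fdr_alpha` as LOH-informative and assigns
#' their retained allele. The tumor is retained when it has at least the
#' mode-specific minimum number of informative SNPs.
#'
#' @param records `allelic_depths` table containing the tumor's counts
#' @param tumor tumor sample id
#' @param het_snps output of [call_het_snps()]
#' @param thr [loh_thresholds()]
#' @return object of class `loh_profile`: list with `tumor_id`, `snps`
#'   (informative-SNP data.frame), `retained` flag, `counts`
#'   (`n_het`, `n_depth_pass`, `n_tested`, `n_informative`)
#' @export
select_informative <- function(records, tumor, het_snps, thr = loh_thresholds()) {
  rc <- paste0(tumor, "_ref"); ac <- paste0(tumor, "_alt")
  if (!all(c(rc, ac) %in% names(records))) {
    abort_config(sprintf("tumor sample '%s' not present in records", tumor))
  }
  i <- match(site_key(het_snps$chrom, het_snps$pos),
             site_key(records$chrom, records$pos))
  ok <- !is.na(i)
  ref_n <- records[[rc]][i[ok]]
  alt_n <- records[[ac]][i[ok]]
  het <- het_snps[ok, , drop = FALSE]
  dep <- ref_n + alt_n
  pass <- dep > thr$min_depth
  n_depth_pass <- sum(pass)

  tested <- data.frame(chrom = het$chrom[pass], pos = het$pos[pass],
                       ref = het$ref[pass], alt = het$alt[pass],
                       tumor_id = if (n_depth_pass) tumor else character(0),
                       ref_count = ref_n[pass], alt_count = alt_n[pass],
                       stringsAsFactors = FALSE)
  if (nrow(tested) > 0) {
    tested$p_value <- binomial_two_sided_p(tested$alt_count,
                                           tested$ref_count + tested$alt_count)
    tested$q_value <- bh_adjust(tested$p_value)
  } else {
    tested$p_value <- numeric(0)
    tested$q_value <- numeric(0)
  }
  inf <- tested[tested$q_value < thr$fdr_alpha, , drop = FALSE]
  inf$retained_allele <- if (nrow(inf) > 0) {
    assign_retained_allele(inf$ref_count, inf$alt_count)
  } else character(0)
  rownames(inf) <- NULL
  counts <- list(n_het = nrow(het_snps), n_depth_pass = n_depth_pass,
                 n_tested = nrow(tested), n_informative = nrow(inf))
  loh_profile(tumor, inf, retained = nrow(inf) >= min_informative(thr),
              counts = counts)
}

#' Construct a tumor LOH profile
#'
#' @param tumor_id tumor sample id
#' @param snps informative-SNP data.frame (`chrom`, `pos`, `retained_allele`,
#'   plus bookkeeping columns)
#' @param retained logical: did the tumor meet the informative-SNP minimum
#' @param counts per-stage tallies
#' @return `loh_profile` object
#' @export
loh_profile <- function(tumor_id, snps, retained, counts = list()) {
  structure(list(tumor_id = tumor_id, snps = snps, retained = retained,
                 counts = counts),
            class = "loh_profile")
}

#' @export
print.loh_profile <- function(x, ...) {
  cat(sprintf("<loh_profile> %s: %d informative SNPs, retained = %s\n",
              x$tumor_id, nrow(x$snps), x$retained))
  invisible(x)
}
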