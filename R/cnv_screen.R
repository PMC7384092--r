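#' Per-bin log2 copy ratios from binned read counts
#'
#' Library-size-normalized ratio per bin:
#' `log2((tumor_b / T_total) / (normal_b / N_total))`, with totals taken over
#' unmasked bins. Bins with zero normal reads (or a TRUE `mask` column) are
#' masked rather than producing infinities. For a mostly diploid genome the
#' normalization puts the genome-wide median near 0, so a hemizygous loss at
#' tumor purity rho is expected at `log2(1 - rho/2)`.
#'
#' This screen deliberately performs no GC or mappability correction and no
#' segmentation; it is a simplified stand-in for full allele-specific
#' copy-number callers, adequate for whole-chromosome / whole-arm calls.
#'
#' @param bins data.frame with columns `chrom`, `bin_start`, `bin_end`,
#'   `tumor_count`, `normal_count` and optionally logical `mask`
#' @return the input with logical `masked` and numeric `log2_ratio`
#'   (NA where masked) columns appended
#' @export
bin_log2_ratios <- function(bins) {
  need <- c("chrom", "bin_start", "bin_end", "tumor_count", "normal_count")
  missing <- setdiff(need, names(bins))
  if (length(missing) > 0) {
    abort_config(sprintf("bin table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (any(bins$bin_end < bins$bin_start)) abort_data("bin_end must be >= bin_start")
  if (any(bins$tumor_count < 0 | bins$normal_count < 0)) {
    abort_data("bin counts must be non-negative")
  }
  masked <- bins$normal_count == 0
  if (!is.null(bins$mask)) masked <- masked | as.logical(bins$mask)
  t_tot <- sum(bins$tumor_count[!masked])
  n_tot <- sum(bins$normal_count[!masked])
  if (n_tot == 0) abort_data("all normal bin counts are zero")
  if (t_tot == 0) abort_data("all tumor bin counts are zero")
  lr <- rep(NA_real_, nrow(bins))
  ok <- !masked
  lr[ok] <- log2((bins$tumor_count[ok] / t_tot) / (bins$normal_count[ok] / n_tot))
  lr[ok][bins$tumor_count[ok] == 0] <- -Inf
  out <- bins
  out$masked <- masked
  out$log2_ratio <- lr
  out
}

#' Call chromosome / arm loss from binned log2 ratios
#'
#' Groups bins by chromosome or by chromosome arm (bin midpoint decides the
#' arm; centromeric bins are skipped in arm mode), takes the median log2 ratio
#' per group and calls `LOSS` when the median is strictly below
#' `loss_threshold` — the hemizygous-loss criterion `log2(CN/2) < -0.1`.
#' Groups with fewer than `min_bins` unmasked bins are reported `NO_CALL`.
#'
#' @param ratios output of [bin_log2_ratios()]
#' @param loss_threshold default -0.1
#' @param min_bins minimum unmasked bins per group (default 20)
#' @param by `"chrom"` or `"arm"`
#' @param arms [read_arm_map()] result, required for `by = "arm"`
#' @return data.frame `group, chrom, n_bins, median_log2, call` with call in
#'   `LOSS`, `NEUTRAL_OR_GAIN`, `NO_CALL`
#' @export
call_chromosome_loss <- function(ratios, loss_threshold = -0.1, min_bins = 20,
                                 by = c("chrom", "arm"), arms = NULL) {
  by <- match.arg(by)
  x <- ratios[!ratios$masked, , drop = FALSE]
  if (by == "arm") {
    if (is.null(arms)) abort_config("by = 'arm' requires an arm map")
    mid <- floor((x$bin_start + x$bin_end) / 2)
    # chromosomes without arm definitions fall back to whole-chromosome groups
    known <- x$chrom %in% arms$chrom
    arm <- rep("", nrow(x))
    arm[known] <- arm_of(arms, x$chrom[known], mid[known])
    x <- x[arm != "cen", , drop = FALSE]
    key <- paste0(x$chrom, arm[arm != "cen"])
  } else {
    key <- x$chrom
  }
  groups <- sort(unique(key))
  out <- do.call(rbind, lapply(groups, function(gname) {
    lr <- x$log2_ratio[key == gname]
    n <- length(lr)
    med <- if (n >= min_bins) stats::median(lr) else NA_real_
    data.frame(group = gname, chrom = x$chrom[key == gname][1], n_bins = n,
               median_log2 = med,
               call = if (n < min_bins) "NO_CALL"
                      else if (med < loss_threshold) "LOSS"
                      else "NEUTRAL_OR_GAIN",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a binned read-count table
#'
#' 5- or 6-column TSV with header: `chrom, bin_start, bin_end, tumor_count,
#' normal_count[, mask]`.
#'
#' @param path TSV file
#' @return data.frame suitable for [bin_log2_ratios()]
#' @export
read_bin_counts <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("bin-count file not found: %s", path))
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x
}
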