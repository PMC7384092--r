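#' Configuration of a synthetic multifocal-tumor patient
#'
#' The generator emulates the data-generating setting the LOH-mapping analysis
#' assumes: germline heterozygous SNPs on one target chromosome, a matched
#' normal at ~30x, tumors at ~60x (WGS) or ~80x (WES, with ~10x sparser SNP
#' density), and each tumor a purity mixture of a 1-copy LOH clone with 2-copy
#' normal cells. Depths are negative-binomial (over-dispersed relative to
#' Poisson), alt counts binomial. Every random quantity derives from `seed`,
#' so identical configs give byte-identical data.
#'
#' @param seed integer RNG seed
#' @param n_tumors number of tumor samples
#' @param purity scalar or per-tumor vector in `[0, 1]` (default 0.6, a
#'   typical fresh-frozen tumor purity)
#' @param loh_spec list (length `n_tumors`) of per-tumor specs as produced by
#'   [plant_pattern()]; alternatively give `pattern` to plant one
#' @param pattern `"SAME_ALLELE"`, `"OPPOSITE_ALLELES"` or `"ARM_DISCORDANT"`;
#'   used with [plant_pattern()] when `loh_spec` is not given
#' @param fraction_with_loh passed to [plant_pattern()] when planting
#' @param mode `"WGS"` or `"WES"`; sets depth (60x vs 80x tumor), read length
#'   (151 vs 76 bp) and default SNP density
#' @param n_snps germline het SNPs on the target chromosome. Defaults: 20000
#'   (WGS; a 30x genome yields tens of thousands of het SNPs on an 80 Mb
#'   chromosome) or 2000 (WES, 1/10 density)
#' @param chrom,chrom_length target chromosome (default chr18, hg19 length)
#' @param arm_map [read_arm_map()] result (default built-in hg19 chr18)
#' @param normal_mean_depth,tumor_mean_depth mean site depths; tumor default
#'   60 (WGS) / 80 (WES)
#' @param depth_dispersion negative-binomial size for site depths (default 10)
#' @param error_rate per-read substitution error (default 0.001)
#' @param copy_neutral simulate copy-neutral LOH (2 copies of the retained
#'   haplotype) instead of hemizygous loss; default FALSE
#' @param n_bins bins on the target chromosome for the copy-number screen
#'   (default 1000; 0 disables bin simulation)
#' @param background_genome_length diploid background represented in the bin
#'   table so library normalization is anchored (default hg19 genome minus
#'   chr18)
#' @param bin_overdispersion variance of bin counts as a multiple of Poisson
#'   (default 3, typical for clean WGS bins of ~100 kb)
#' @return `sim_config` object
#' @export
sim_config <- function(seed, n_tumors = 5, purity = 0.6, loh_spec = NULL,
                       pattern = NULL, fraction_with_loh = 0.6,
                       mode = c("WGS", "WES"), n_snps = NULL,
                       chrom = "chr18", chrom_length = 78077248,
                       arm_map = read_arm_map(),
                       normal_mean_depth = 30, tumor_mean_depth = NULL,
                       depth_dispersion = 10, error_rate = 0.001,
                       copy_neutral = FALSE, n_bins = 1000,
                       background_genome_length = 3095677412 - 78077248,
                       bin_overdispersion = 3) {
  mode <- match.arg(mode)
  n_snps <- n_snps %||% if (mode == "WGS") 20000L else 2000L
  tumor_mean_depth <- tumor_mean_depth %||% if (mode == "WGS") 60 else 80
  purity <- rep_len(purity, n_tumors)
  if (any(purity < 0 | purity > 1)) abort_config("purity must lie in [0, 1]")
  if (normal_mean_depth <= 0 || tumor_mean_depth <= 0) {
    abort_config("mean depths must be positive")
  }
  if (is.null(loh_spec)) {
    if (is.null(pattern)) abort_config("give either loh_spec or pattern")
    loh_spec <- plant_pattern(pattern, n_tumors, fraction_with_loh)
  }
  if (length(loh_spec) != n_tumors) {
    abort_config("loh_spec must have one entry per tumor")
  }
  ab <- arm_map[arm_map$chrom == chrom, , drop = FALSE]
  if (nrow(ab) != 1) abort_config(sprintf("arm map lacks %s", chrom))
  structure(list(seed = as.integer(seed), n_tumors = n_tumors, purity = purity,
                 loh_spec = loh_spec, pattern = pattern, mode = mode,
                 n_snps = as.integer(n_snps), chrom = chrom,
                 chrom_length = chrom_length, p_end = ab$p_end,
                 q_start = ab$q_start, normal_mean_depth = normal_mean_depth,
                 tumor_mean_depth = tumor_mean_depth,
                 depth_dispersion = depth_dispersion, error_rate = error_rate,
                 copy_neutral = copy_neutral, n_bins = as.integer(n_bins),
                 background_genome_length = background_genome_length,
                 bin_overdispersion = bin_overdispersion,
                 read_length = if (mode == "WGS") 151 else 76),
            class = "sim_config")
}

#' Plant a patient-level LOH pattern
#'
#' Deterministically assigns per-tumor LOH specs realizing one of the three
#' cross-tumor patterns; the remaining tumors carry no chr-wide LOH, matching
#' the observation that not every primary shows the loss. Haplotypes are
#' labeled H1/H2 (parental identity is arbitrary).
#' \describe{
#'   \item{SAME_ALLELE}{every LOH tumor retains H1}
#'   \item{OPPOSITE_ALLELES}{LOH tumors split between H1 and H2 (at least one
#'     each), consistent across arms}
#'   \item{ARM_DISCORDANT}{the first LOH tumor retains H1 on the p arm and H2
#'     on the q arm; the others are whole-chromosome, split between H1 and H2}
#' }
#'
#' @param pattern target pattern
#' @param n_tumors total tumors (>= 2 LOH tumors required by every pattern)
#' @param fraction_with_loh fraction of tumors carrying the planted LOH
#'   (default 0.6, comparable to the 27-55% per-patient rates seen in
#'   multifocal ileal NETs); at least the pattern's minimum is always planted
#' @return list of per-tumor specs: `list(type = "NONE")`,
#'   `list(type = "WHOLE", retained = "H1")` or
#'   `list(type = "PER_ARM", p = "H1", q = "H2")`
#' @export
plant_pattern <- function(pattern = c("SAME_ALLELE", "OPPOSITE_ALLELES",
                                      "ARM_DISCORDANT"),
                          n_tumors, fraction_with_loh = 0.6) {
  pattern <- match.arg(pattern)
  min_loh <- 2  # every pattern needs >= 2 LOH tumors to be classifiable
  if (pattern == "ARM_DISCORDANT") min_loh <- 2
  n_loh <- max(min_loh, round(fraction_with_loh * n_tumors))
  n_loh <- min(n_loh, n_tumors)
  if (n_loh < min_loh || n_tumors < min_loh) {
    abort_config(sprintf("pattern %s needs at least %d LOH tumors", pattern, min_loh))
  }
  whole <- function(h) list(type = "WHOLE", retained = h)
  specs <- rep(list(list(type = "NONE")), n_tumors)
  if (pattern == "SAME_ALLELE") {
    specs[seq_len(n_loh)] <- rep(list(whole("H1")), n_loh)
  } else if (pattern == "OPPOSITE_ALLELES") {
    n1 <- ceiling(n_loh / 2)
    specs[seq_len(n1)] <- rep(list(whole("H1")), n1)
    specs[(n1 + 1):n_loh] <- rep(list(whole("H2")), n_loh - n1)
  } else {
    specs[[1]] <- list(type = "PER_ARM", p = "H1", q = "H2")
    rest <- n_loh - 1
    n1 <- ceiling(rest / 2)
    if (n1 > 0) specs[1 + seq_len(n1)] <- rep(list(whole("H1")), n1)
    if (rest - n1 > 0) specs[(1 + n1) + seq_len(rest - n1)] <- rep(list(whole("H2")), rest - n1)
  }
  specs
}

# expected tumor alt-read fraction at a het SNP inside an LOH region
# rho: purity; retained: does the alt-bearing haplotype survive in the clone
loh_alt_fraction <- function(rho, alt_retained, copy_neutral = FALSE) {
  if (copy_neutral) {
    if (alt_retained) (1 + rho) / 2 else (1 - rho) / 2
  } else {
    if (alt_retained) 1 / (2 - rho) else (1 - rho) / (2 - rho)
  }
}

#' Simulate one multifocal-tumor patient
#'
#' Draws SNP positions uniformly over the target chromosome (excluding the
#' centromere gap), assigns each SNP's alt allele to haplotype H1 or H2 by a
#' fair coin, and generates read counts:
#' normal depth ~ NegBin(mean = `normal_mean_depth`), normal alt ~
#' Binomial(depth, 1/2); tumor site depth ~ NegBin(mean =
#' `tumor_mean_depth * c/2`) with average copy number
#' `c = 2(1 - rho) + rho * cn` (cn = 1 inside hemizygous LOH, else 2); tumor
#' alt fraction `1/(2 - rho)` when the alt-bearing haplotype is retained,
#' `(1 - rho)/(2 - rho)` when lost, and 1/2 outside LOH. Binned read counts
#' (target chromosome plus a diploid background) are drawn consistently with
#' `c`. A small symmetric read-error rate perturbs the alt fractions.
#'
#' @param cfg [sim_config()]
#' @return list with `depths` (an `allelic_depths` table; samples `N`,
#'   `T1..Tk`), `bins` (named list of per-tumor bin tables, or NULL), `truth`
#'   (planted phase, per-tumor purity and retained haplotypes, pattern),
#'   `normal` and `tumors` sample ids, and the `cfg`
#' @export
simulate_patient <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gap <- cfg$q_start - cfg$p_end - 1
  usable <- cfg$chrom_length - gap
  if (cfg$n_snps > usable) abort_config("n_snps exceeds usable chromosome length")
  u <- sort(sample.int(usable, cfg$n_snps))
  pos <- ifelse(u <= cfg$p_end, u, u + gap)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  alt_hap <- sample(c("H1", "H2"), cfg$n_snps, replace = TRUE)
  arm <- ifelse(pos <= cfg$p_end, "p", "q")

  err <- function(f) f * (1 - cfg$error_rate) + (1 - f) * cfg$error_rate

  depths <- data.frame(chrom = cfg$chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
  n_dep <- rnbinom(cfg$n_snps, size = cfg$depth_dispersion,
                   mu = cfg$normal_mean_depth)
  depths$N_alt <- rbinom(cfg$n_snps, n_dep, err(0.5))
  depths$N_ref <- n_dep - depths$N_alt
  depths <- depths[c("chrom", "pos", "ref", "alt", "N_ref", "N_alt")]

  tumors <- paste0("T", seq_len(cfg$n_tumors))
  truth_tumors <- list()
  for (t in seq_len(cfg$n_tumors)) {
    spec <- cfg$loh_spec[[t]]
    rho <- cfg$purity[t]
    ret_p <- switch(spec$type, NONE = NA_character_, WHOLE = spec$retained,
                    PER_ARM = spec$p)
    ret_q <- switch(spec$type, NONE = NA_character_, WHOLE = spec$retained,
                    PER_ARM = spec$q)
    ret <- ifelse(arm == "p", ret_p, ret_q)
    in_loh <- !is.na(ret)
    cn <- ifelse(in_loh & !cfg$copy_neutral, 2 * (1 - rho) + rho * 1, 2)
    f <- rep(0.5, cfg$n_snps)
    if (any(in_loh)) {
      f_ret <- loh_alt_fraction(rho, TRUE, cfg$copy_neutral)
      f_lost <- loh_alt_fraction(rho, FALSE, cfg$copy_neutral)
      f[in_loh] <- ifelse(alt_hap[in_loh] == ret[in_loh], f_ret, f_lost)
    }
    dep <- rnbinom(cfg$n_snps, size = cfg$depth_dispersion,
                   mu = cfg$tumor_mean_depth * cn / 2)
    a <- rbinom(cfg$n_snps, dep, err(f))
    depths[[paste0(tumors[t], "_ref")]] <- dep - a
    depths[[paste0(tumors[t], "_alt")]] <- a
    truth_tumors[[tumors[t]]] <- list(purity = rho, loh = spec,
                                      retained_p = ret_p, retained_q = ret_q)
  }
  depths <- as_allelic_depths(depths, c("N", tumors),
                              counts = list(n_records = nrow(depths),
                                            n_skipped_multiallelic = 0L,
                                            n_skipped_indel = 0L,
                                            n_skipped_missing_ad = 0L,
                                            n_body_lines = nrow(depths)))

  bins <- NULL
  if (cfg$n_bins > 0) {
    bins <- lapply(seq_len(cfg$n_tumors), function(t) simulate_bins(cfg, t))
    names(bins) <- tumors
  }

  truth <- list(pattern = cfg$pattern %||% "CUSTOM",
                phase = data.frame(chrom = cfg$chrom, pos = pos,
                                   alt_hap = alt_hap, stringsAsFactors = FALSE),
                tumors = truth_tumors)
  list(depths = depths, bins = bins, truth = truth,
       normal = "N", tumors = tumors, cfg = cfg)
}

# binned read counts for one tumor: target chromosome + diploid background
simulate_bins <- function(cfg, t) {
  w <- cfg$chrom_length / cfg$n_bins
  start <- floor(w * (seq_len(cfg$n_bins) - 1)) + 1
  end <- c(start[-1] - 1, cfg$chrom_length)
  mid <- floor((start + end) / 2)
  in_gap <- mid > cfg$p_end & mid < cfg$q_start
  spec <- cfg$loh_spec[[t]]
  rho <- cfg$purity[t]
  arm <- ifelse(mid <= cfg$p_end, "p", "q")
  loh_arm <- switch(spec$type,
                    NONE = c(p = FALSE, q = FALSE),
                    WHOLE = c(p = TRUE, q = TRUE),
                    PER_ARM = c(p = TRUE, q = TRUE))
  in_loh <- !in_gap & loh_arm[arm] & !cfg$copy_neutral
  cn <- ifelse(in_loh, 2 - rho, 2)

  n_bg <- round(cfg$background_genome_length / w)
  bg_start <- floor(w * (seq_len(n_bg) - 1)) + 1
  bg_end <- floor(w * seq_len(n_bg))

  reads_per_bin <- function(mean_depth, c_avg, width) {
    mean_depth * (c_avg / 2) * width / cfg$read_length
  }
  draw <- function(mu) {
    # bin-count overdispersion: variance = bin_overdispersion * Poisson
    size <- mu / max(cfg$bin_overdispersion - 1, 1e-8)
    rnbinom(length(mu), size = size, mu = mu)
  }
  wdt <- end - start + 1
  mu_t <- reads_per_bin(cfg$tumor_mean_depth, cn, wdt)
  mu_n <- reads_per_bin(cfg$normal_mean_depth, 2, wdt)
  wbg <- bg_end - bg_start + 1
  mu_t_bg <- reads_per_bin(cfg$tumor_mean_depth, 2, wbg)
  mu_n_bg <- reads_per_bin(cfg$normal_mean_depth, 2, wbg)
  out <- data.frame(
    chrom = c(rep(cfg$chrom, cfg$n_bins), rep("background", n_bg)),
    bin_start = c(start, bg_start), bin_end = c(end, bg_end),
    tumor_count = c(draw(mu_t), draw(mu_t_bg)),
    normal_count = c(draw(mu_n), draw(mu_n_bg)),
    mask = c(in_gap, rep(FALSE, n_bg)),
    stringsAsFactors = FALSE)
  out
}

#' Write a simulated cohort as VCF + truth JSON (+ bin tables)
#'
#' The VCF carries per-sample `AD` (ref,alt) fields and is readable by
#' [read_allelic_depths()]; the truth JSON records the planted pattern,
#' per-SNP phase and per-tumor retained haplotypes for recovery tests.
#'
#' @param sim result of [simulate_patient()]
#' @param out_dir output directory
#' @return invisibly, the files written
#' @export
write_sim_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(out_dir, "cohort.vcf")
  write_sim_vcf(sim, vcf)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, tj, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  files <- c(vcf, tj)
  if (!is.null(sim$bins)) {
    for (t in names(sim$bins)) {
      p <- file.path(out_dir, sprintf("bins_%s.tsv", t))
      write_tsv_stable(sim$bins[[t]], p)
      files <- c(files, p)
    }
  }
  invisible(files)
}

#' Write an allelic-depth table as VCF v4.2 with AD genotype fields
#'
#' @param sim result of [simulate_patient()]
#' @param path output `.vcf`
#' @export
write_sim_vcf <- function(sim, path) {
  d <- sim$depths
  samples <- attr(d, "samples")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lohmapr-simulate",
           sprintf("##contig=<ID=%s,length=%d>", sim$cfg$chrom,
                   as.integer(sim$cfg$chrom_length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  cols <- lapply(samples, function(s) {
    gt <- if (s == sim$normal) "0/1" else "./."
    paste0(gt, ":", d[[paste0(s, "_ref")]], ",", d[[paste0(s, "_alt")]])
  })
  body <- do.call(paste, c(list(d$chrom, d$pos, ".", d$ref, d$alt, ".", ".",
                                ".", "GT:AD"), cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
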