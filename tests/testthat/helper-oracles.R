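`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used by the unit and acceptance suites.
# They deliberately share no code with the implementation under test.

# Minimum-likelihood two-sided binomial p at p0 = 0.5: sum the probabilities
# of every outcome no more likely than the observed one. Coincides with the
# tail-doubling definition by symmetry of Binomial(n, 1/2).
oracle_binom_p <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[k + 1] * (1 + 1e-9)])
}

# Literal Benjamini-Hochberg step-up definition: after ascending sort,
# q(i) = min(1, min_{j >= i} m p(j) / j), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m),
              function(i) min(1, min(m * ps[i:m] / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Minimal tumor profile for pattern tests: positions + retained-allele vector.
make_profile <- function(id, pos, alleles, chrom = "chr18", retained = TRUE) {
  lohmapr::loh_profile(
    id,
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G", tumor_id = id,
               ref_count = ifelse(alleles == "REF", 40L, 2L),
               alt_count = ifelse(alleles == "REF", 2L, 40L),
               p_value = 1e-9, q_value = 1e-8,
               retained_allele = alleles, stringsAsFactors = FALSE),
    retained = retained,
    counts = list(n_het = length(pos), n_depth_pass = length(pos),
                  n_tested = length(pos), n_informative = length(pos)))
}

# default hg19 chr18 arm map used throughout
arms18 <- lohmapr::read_arm_map()

# positions guaranteed on each arm of chr18 (hg19 boundaries)
p_arm_pos <- function(n) 1000000 + seq_len(n) * 1000
q_arm_pos <- function(n) 20000000 + seq_len(n) * 1000

# small multi-sample VCF exercising the skip rules:
# 4 body lines -> 1 usable SNP record, 1 multiallelic, 1 indel, 1 missing AD
write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr18,length=78077248>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "NORM", "TUM"), collapse = "\t"),
    "chr18\t1000\t.\tA\tG\t.\t.\t.\tGT:AD\t0/1:15,14\t./.:20,4",
    "chr18\t2000\t.\tA\tG,T\t.\t.\t.\tGT:AD\t0/1:10,9,1\t./.:12,5,0",
    "chr18\t3000\t.\tAT\tA\t.\t.\t.\tGT:AD\t0/1:11,12\t./.:14,6",
    "chr18\t4000\t.\tC\tT\t.\t.\t.\tGT:AD\t0/1:13,12\t.:."),
    path)
  path
}
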