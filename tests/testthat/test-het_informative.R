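test_that("binomial two-sided p matches frozen exact values", {
  expect_equal(binomial_two_sided_p(10, 20), 1)
  # 2 * (C(30,27)+C(30,28)+C(30,29)+C(30,30)) / 2^30 = 9052 / 2^30
  expect_equal(binomial_two_sided_p(27, 30), 9052 / 2^30, tolerance = 1e-12)
  expect_equal(binomial_two_sided_p(0, 11), 2 / 2048, tolerance = 1e-15)
  expect_error(binomial_two_sided_p(5, 4), class = "lohmapr_data_error")
  expect_error(binomial_two_sided_p(-1, 4), class = "lohmapr_data_error")
  expect_error(binomial_two_sided_p(0, 0), class = "lohmapr_data_error")
})

test_that("binomial p equals enumeration and binom.test on small n", {
  for (n in c(1, 2, 5, 11, 17, 25)) {
    k <- 0:n
    got <- binomial_two_sided_p(k, rep(n, n + 1))
    want <- vapply(k, oracle_binom_p, numeric(1), n = n)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # independent cross-check against stats::binom.test
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    expect_equal(binomial_two_sided_p(k, n),
                 stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment: frozen example, degenerate cases, permutations", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.37), 0.37)             # m = 1
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))  # ties share one q
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "lohmapr_data_error")

  set.seed(7)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("BH matches the brute-force step-up definition on random vectors", {
  set.seed(99)
  for (i in 1:100) {
    m <- sample(1:200, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("het calling applies the strict depth bound and inclusive VAF window", {
  rec <- data.frame(chrom = "chr18", pos = 1:6 * 1000, ref = "A", alt = "G",
                    N_ref = c(6L, 5L, 35L, 12L, 12L, 0L),
                    N_alt = c(6L, 5L, 15L, 8L, 18L, 0L))
  het <- call_het_snps(rec, "N")
  # depth 12 VAF 0.5 kept; depth 10 excluded (> 10 is strict); VAF 0.3 out;
  # VAF exactly 0.4 and 0.6 kept (inclusive window); zero depth never errors
  expect_equal(het$pos, c(1000, 4000, 5000))
  expect_equal(het$normal_vaf, c(0.5, 0.4, 0.6))
  expect_error(call_het_snps(rec, "missing"), class = "lohmapr_config_error")
})

test_that("informative selection: strict tumor depth, FDR family, retention", {
  n <- 1200
  rec <- data.frame(chrom = "chr18", pos = seq_len(n) * 100,
                    ref = "A", alt = "G",
                    N_ref = 15L, N_alt = 15L,
                    T_ref = c(rep(60L, 999), rep(15L, n - 999)),
                    T_alt = c(rep(0L, 999), rep(15L, n - 999)))
  het <- call_het_snps(rec, "N")
  expect_equal(nrow(het), n)
  thr_wgs <- loh_thresholds(mode = "WGS")
  prof <- select_informative(rec, "T", het, thr_wgs)
  expect_equal(prof$counts$n_informative, 999)
  expect_false(prof$retained)               # 999 < 1000: "at least 1000"
  expect_true(all(prof$snps$retained_allele == "REF"))

  rec$T_ref[1000] <- 60L; rec$T_alt[1000] <- 0L
  prof2 <- select_informative(rec, "T", het, thr_wgs)
  expect_equal(prof2$counts$n_informative, 1000)
  expect_true(prof2$retained)

  # tumor depth exactly 10 is never tested
  rec$T_ref[2] <- 5L; rec$T_alt[2] <- 5L
  prof3 <- select_informative(rec, "T", het, thr_wgs)
  expect_equal(prof3$counts$n_tested, n - 1)
  expect_error(select_informative(rec, "nope", het, thr_wgs),
               class = "lohmapr_config_error")
})

test_that("WES retention threshold is 100", {
  n <- 120
  mk <- function(n_extreme) {
    data.frame(chrom = "chr18", pos = seq_len(n) * 100, ref = "A", alt = "G",
               N_ref = 15L, N_alt = 15L,
               T_ref = c(rep(80L, n_extreme), rep(15L, n - n_extreme)),
               T_alt = 0L + c(rep(0L, n_extreme), rep(15L, n - n_extreme)))
  }
  thr <- loh_thresholds(mode = "WES")
  rec99 <- mk(99)
  expect_false(select_informative(rec99, "T", call_het_snps(rec99, "N"), thr)$retained)
  rec100 <- mk(100)
  expect_true(select_informative(rec100, "T", call_het_snps(rec100, "N"), thr)$retained)
})

test_that("retained-allele assignment follows the count argmax, ties rejected", {
  expect_equal(assign_retained_allele(c(40, 5), c(5, 40)), c("REF", "ALT"))
  expect_error(assign_retained_allele(12, 12), class = "lohmapr_data_error")
})

test_that("pure tumor with whole-chromosome LOH: nearly every tested SNP rejects", {
  cfg <- sim_config(seed = 21, n_tumors = 1, purity = 1,
                    loh_spec = list(list(type = "WHOLE", retained = "H1")),
                    n_snps = 2000, n_bins = 0)
  sim <- simulate_patient(cfg)
  het <- call_het_snps(sim$depths, "N")
  prof <- select_informative(sim$depths, "T1", het)
  expect_gte(prof$counts$n_informative / prof$counts$n_tested, 0.99)
  expect_true(prof$retained)
  # every informative SNP's retained allele equals the argmax of its counts
  expect_true(all(prof$snps$retained_allele ==
                    ifelse(prof$snps$ref_count > prof$snps$alt_count,
                           "REF", "ALT")))
})

test_that("monotonicity: depth bound and FDR level act monotonically", {
  cfg <- sim_config(seed = 22, n_tumors = 1, purity = 0.5,
                    loh_spec = list(list(type = "WHOLE", retained = "H2")),
                    n_snps = 2000, n_bins = 0)
  sim <- simulate_patient(cfg)
  het <- call_het_snps(sim$depths, "N")
  n_tested <- sapply(c(10, 15, 20, 30), function(md) {
    thr <- loh_thresholds(min_depth = md)
    select_informative(sim$depths, "T1", het, thr)$counts$n_tested
  })
  expect_true(all(diff(n_tested) <= 0))
  n_inf <- sapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
    thr <- loh_thresholds(fdr_alpha = a)
    select_informative(sim$depths, "T1", het, thr)$counts$n_informative
  })
  expect_true(all(diff(n_inf) <= 0))
})
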