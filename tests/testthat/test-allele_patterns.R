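test_that("pairwise concordance: identical, complementary and arm-split vectors", {
  pos <- q_arm_pos(200)
  al <- rep(c("REF", "ALT"), 100)
  a <- make_profile("Ta", pos, al)
  b <- make_profile("Tb", pos, al)
  r <- pairwise_concordance(a, b, arms18)
  expect_equal(r$concordance_all, 1)
  expect_equal(r$call, "SAME")

  flip <- ifelse(al == "REF", "ALT", "REF")
  r2 <- pairwise_concordance(a, make_profile("Tc", pos, flip), arms18)
  expect_equal(r2$concordance_all, 0)
  expect_equal(r2$call, "OPPOSITE")

  # agree on all 60 p-arm SNPs, disagree on all 150 q-arm SNPs
  posx <- c(p_arm_pos(60), q_arm_pos(150))
  alx <- rep("REF", 210)
  d <- make_profile("Td", posx, alx)
  e <- make_profile("Te", posx, c(rep("REF", 60), rep("ALT", 150)))
  r3 <- pairwise_concordance(d, e, arms18)
  expect_equal(r3$n_shared_p, 60)
  expect_equal(r3$n_shared_q, 150)
  expect_equal(r3$concordance_p, 1)
  expect_equal(r3$concordance_q, 0)
  expect_equal(r3$call, "ARM_DISCORDANT")
})

test_that("pairwise concordance: empty overlap and min_shared give AMBIGUOUS", {
  a <- make_profile("Ta", q_arm_pos(50), rep("REF", 50))
  b <- make_profile("Tb", q_arm_pos(50) + 7, rep("REF", 50))
  r <- pairwise_concordance(a, b, arms18)
  expect_equal(r$n_shared, 0)
  expect_equal(r$call, "AMBIGUOUS")

  c10 <- make_profile("Tc", q_arm_pos(10), rep("REF", 10))
  d10 <- make_profile("Td", q_arm_pos(10), rep("REF", 10))
  expect_equal(pairwise_concordance(c10, d10, arms18)$call, "AMBIGUOUS")
})

test_that("concordance is symmetric and invariant to REF/ALT relabeling", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(40:200, 1)
    pos <- sort(sample(c(p_arm_pos(5000), q_arm_pos(5000)), n))
    a <- make_profile("Ta", pos, sample(c("REF", "ALT"), n, replace = TRUE))
    b <- make_profile("Tb", pos, sample(c("REF", "ALT"), n, replace = TRUE))
    rij <- pairwise_concordance(a, b, arms18)
    rji <- pairwise_concordance(b, a, arms18)
    expect_equal(rij$concordance_all, rji$concordance_all)
    expect_equal(rij$call, rji$call)

    relabel <- function(p) {
      p$snps$retained_allele <- ifelse(p$snps$retained_allele == "REF",
                                       "ALT", "REF")
      p
    }
    rflip <- pairwise_concordance(relabel(a), relabel(b), arms18)
    expect_equal(rflip$concordance_all, rij$concordance_all)
    expect_equal(rflip$call, rij$call)

    # overall concordance is the arm-count-weighted mean (no centromeric sites)
    expect_equal(rij$concordance_all * rij$n_shared,
                 rij$concordance_p * rij$n_shared_p +
                   rij$concordance_q * rij$n_shared_q)
  }
})

test_that("common informative sites is the multi-profile intersection", {
  a <- make_profile("Ta", c(100, 200, 300), rep("REF", 3), chrom = "chr18")
  b <- make_profile("Tb", c(200, 300, 400), rep("REF", 3), chrom = "chr18")
  expect_equal(common_informative_sites(list(a, b)),
               c("chr18:200", "chr18:300"))
  c_ <- make_profile("Tc", c(900), "REF")
  expect_equal(common_informative_sites(list(a, c_)), character(0))
  expect_equal(common_informative_sites(list(a)),
               c("chr18:100", "chr18:200", "chr18:300"))
})

test_that("patient classification recovers the three patterns from constructed vectors", {
  pos <- c(p_arm_pos(60), q_arm_pos(150))
  H1 <- rep(c("REF", "ALT"), length.out = 210)  # haplotype-1 retention vector
  H2 <- ifelse(H1 == "REF", "ALT", "REF")

  # same parental allele in both tumors
  same <- classify_patient(list(make_profile("T1", pos, H1),
                                make_profile("T2", pos, H1)), arms18)
  expect_equal(same$pattern, "SAME_ALLELE")
  expect_equal(same$groups$group1, c("T1", "T2"))
  expect_equal(same$n_common_sites, 210)

  # four tumors one haplotype, one tumor the other, consistent across arms
  opp <- classify_patient(list(make_profile("T1", pos, H1),
                               make_profile("T6", pos, H1),
                               make_profile("T12", pos, H1),
                               make_profile("T14", pos, H1),
                               make_profile("T9", pos, H2)), arms18)
  expect_equal(opp$pattern, "OPPOSITE_ALLELES")
  expect_equal(opp$groups$group1, c("T1", "T12", "T14", "T6"))
  expect_equal(opp$groups$group2, "T9")

  # six tumors: T2 sides with {T5,T8} on 18p but with {T6,T7,T9} on 18q
  T2vec <- c(H1[1:60], H2[61:210])
  arm_disc <- classify_patient(list(make_profile("T2", pos, T2vec),
                                    make_profile("T5", pos, H1),
                                    make_profile("T8", pos, H1),
                                    make_profile("T6", pos, H2),
                                    make_profile("T7", pos, H2),
                                    make_profile("T9", pos, H2)), arms18)
  expect_equal(arm_disc$pattern, "ARM_DISCORDANT")
  expect_equal(arm_disc$groups$p$group1, c("T2", "T5", "T8"))
  expect_equal(arm_disc$groups$p$group2, c("T6", "T7", "T9"))
  expect_equal(arm_disc$groups$q$group1, c("T2", "T6", "T7", "T9"))
  expect_equal(arm_disc$groups$q$group2, c("T5", "T8"))
})

test_that("degenerate patients are UNDETERMINED, never errors", {
  pos <- q_arm_pos(100)
  one <- make_profile("T1", pos, rep("REF", 100))
  expect_equal(classify_patient(list(one), arms18)$pattern, "UNDETERMINED")

  # non-retained tumors are dropped before classification
  two <- make_profile("T2", pos, rep("REF", 100), retained = FALSE)
  res <- classify_patient(list(one, two), arms18)
  expect_equal(res$pattern, "UNDETERMINED")
  expect_match(paste(res$notes, collapse = " "), "T2")

  # disconnected agreement graph (pairwise overlaps all below min_shared)
  a <- make_profile("Ta", q_arm_pos(100), rep("REF", 100))
  b <- make_profile("Tb", q_arm_pos(100) + 13, rep("REF", 100))
  expect_equal(classify_patient(list(a, b), arms18)$pattern, "UNDETERMINED")
})

test_that("mutually inconsistent pair calls yield UNDETERMINED", {
  # A agrees with B, B agrees with C, but A disagrees with C on a
  # disjoint shared set: the signed graph is not 2-colorable
  sAB <- q_arm_pos(60)
  sBC <- q_arm_pos(60) + 10000000
  sAC <- q_arm_pos(60) + 20000000
  a <- make_profile("A", c(sAB, sAC), rep("REF", 120))
  b <- make_profile("B", c(sAB, sBC), rep("REF", 120))
  c_ <- make_profile("C", c(sBC, sAC), c(rep("REF", 60), rep("ALT", 60)))
  res <- classify_patient(list(a, b, c_), arms18)
  expect_equal(res$pattern, "UNDETERMINED")
  expect_match(paste(res$notes, collapse = " "), "inconsistent")
})
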