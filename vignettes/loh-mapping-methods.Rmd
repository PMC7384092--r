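---
title: "LOH mapping in multifocal tumors: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LOH mapping in multifocal tumors: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohmapr)
```

## The statistical model

At a germline heterozygous SNP, a diploid normal sample yields alternate-allele
read fractions centered on 1/2. A tumor sample is a mixture: a fraction
$\rho$ (the purity) of tumor cells carrying one chromosome copy inside a
hemizygous-loss region, and $1-\rho$ normal cells carrying two. The expected
alternate-read fraction at such a SNP is therefore

$$
f \;=\; \frac{1}{2-\rho} \quad\text{(alt allele on the retained haplotype)},
\qquad
f \;=\; \frac{1-\rho}{2-\rho} \quad\text{(alt allele on the lost haplotype)},
$$

and the average copy number is $c = 2(1-\rho) + \rho$, which depresses local
read depth by the factor $c/2$. Outside LOH, $f = 1/2$ and $c = 2$.

Each tumor/SNP pair is tested with the exact two-sided binomial test of the
alt count $k$ out of depth $n$ against $p_0 = 1/2$:
$p = \min\!\big(1,\, 2\min(P[X \le k], P[X \ge k])\big)$ for
$X \sim \mathrm{Bin}(n, 1/2)$. Because the null is symmetric, this coincides
with the minimum-likelihood definition (sum of all outcomes no more likely
than the observed one); the test suite verifies the identity by enumeration
for all $n \le 60$. P-values are adjusted with the Benjamini–Hochberg step-up
procedure, implemented directly from its definition
($q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1) and verified against a
brute-force oracle. SNPs with $q < 0.1$ are LOH-informative; the retained
allele is the count argmax (a tie gives $p = 1$ and can never be informative,
so the argmax is always defined).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 | strict bound: a site is used iff depth > 10 (normal and tumor side). The printed inequality is strict, and the package follows it; depth exactly 10 is excluded. |
| `vaf_lo`, `vaf_hi` | 0.40, 0.60 | normal-VAF window for the het call, unitless fractions. Whether the endpoints are inclusive is not specified anywhere authoritative; **inclusive** was chosen (a VAF of exactly 0.4 passes) and is exposed in configuration. |
| `fdr_alpha` | 0.1 | BH cutoff, $q < 0.1$ strictly. |
| `min_informative_wgs/wes` | 1000 / 100 | retention: a tumor enters pattern analysis with *at least* this many informative SNPs; 999 fails, 1000 passes. Selected by `mode`, never inferred from the data. |
| `hi`, `lo` | 0.95, 0.05 | pair-concordance margins. Informative SNPs are individually significant imbalance calls, so same-haplotype pairs concentrate near concordance 1 and opposite-haplotype pairs near 0; the margins absorb rare misassignments at low purity. No published threshold exists for this step — these are this package's formalization. |
| `min_shared`, `min_arm` | 30, 10 | minimum shared informative SNPs for any pair call / for an arm to enter the call. |
| `loss_threshold` | −0.1 | median log2 copy-ratio below which a chromosome/arm is called LOSS. |

## The FDR family

Adjustment is performed **per tumor sample**, across all of that tumor's
tested SNPs on the chromosome set under analysis (default chr18). Whether the
original analysis pooled tumors of a patient before adjusting is not stated;
per-tumor adjustment was chosen because retention (the ≥ 1000/100 rule) is a
per-tumor decision, and the choice is recorded in the run summary. Under the
global null (purity 0) BH bounds the probability of *any* false informative
SNP in a tumor by $\alpha$; the discreteness of binomial p-values makes it
conservative in practice, which the 500-replicate null-calibration test
demonstrates.

## Pattern classification

Pairs are called SAME / OPPOSITE / ARM_DISCORDANT / AMBIGUOUS from overall and
per-arm concordance. The patient-level call builds a signed graph (SAME = +,
OPPOSITE = −) over retained tumors and 2-colors it; the two color classes are
the haplotype groups, reported as group1/group2 only — without trio data,
parental haplotypes are identified up to relabeling, and every statistic is
invariant under a global REF/ALT swap (property-tested). Decisions taken where
the design was genuinely open:

* **ARM_DISCORDANT dominates**: the pattern is arm-discordant as soon as one
  pair call is, and groups are then reported per arm.
* **Arms below `min_arm` shared SNPs are uninformative, not blocking**: a
  strictly literal reading of "both arms concordant" would leave sparse WES
  pairs permanently AMBIGUOUS when one arm has too few shared SNPs (chr18p
  carries few exome targets). Such arms simply do not participate in the
  SAME/OPPOSITE condition; ARM_DISCORDANT, by contrast, always requires both
  arms to meet `min_arm`.
* **Non-2-colorable or disconnected graphs yield UNDETERMINED** rather than a
  forced partition; refusing to guess is safer than inventing a grouping.
* **"Common" informative SNPs** are the intersection over *all* retained
  tumors (reported as `n_common_sites`), while pair calls use pairwise
  intersections for power; both counts appear in the outputs.

## Coordinates and arm assignment

VCF positions stay 1-based everywhere. Arms are closed intervals
$[1, p_{end}]$ and $[q_{start}, \text{chrom end}]$; positions strictly between
are centromeric — excluded from arm statistics but kept in whole-chromosome
statistics. The built-in hg19 chr18 boundary ($p_{end} = 15{,}400{,}000$,
$q_{start} = 19{,}000{,}001$) derives from the hg19 cytoBand acen rows; any
cytoband file or explicit 3-column table can replace it.

## The copy-number screen and its approximation

The screen computes library-size-normalized per-bin ratios
$\log_2\!\frac{t_b/T}{n_b/N}$ and takes the **median** per chromosome or arm
(robust to focal events; the original study used full allele-specific
copy-number pipelines, for which this module is an explicitly simplified
stand-in). The published criterion $\log_2(\mathrm{CN}/2) < -0.1$ refers to an
absolute, purity-corrected copy number; equating it with the raw read-depth
ratio is this module's documented approximation, under which a hemizygous loss
appears at $\log_2(1-\rho/2)$ and the criterion's detection boundary sits at
$\rho^\* = 2(1 - 2^{-0.1}) \approx 0.134$. The acceptance suite verifies the
boundary by a purity sweep (detected at every $\rho \ge 0.2$, never at
$\rho \le 0.05$, across 50 replicates each). No GC or mappability correction
is attempted — a real-data limitation stated here deliberately.

## What the generator emulates — and what it does not

`simulate_patient()` draws SNP positions uniformly over the chromosome minus
the centromere gap, phases each SNP's alt allele onto haplotype H1/H2 by a
fair coin, and generates negative-binomial depths (size 10 by default —
over-dispersed coverage typical of real WGS) with binomial allele counts at
the mixture fractions above: normal 30×, tumor 60× (WGS, 151 bp reads) or 80×
(WES, 76 bp reads, SNP density thinned 10-fold). Defaults chosen once where no
value was stated:

* **n_snps = 20,000 (WGS)** — a realistic desk-scale count of germline het
  SNPs on an ~80 Mb chromosome (real 30× WGS gives ~40k); WES defaults to
  2,000 via the 1/10 thinning. Compute-bound tests scale down to 8,000, which
  still leaves well over 2,000 het-filter-passing SNPs.
* **purity 0.6** where one value is needed — typical for fresh-frozen
  neuroendocrine tumor tissue; recovery tests draw purities Uniform(0.4, 0.9)
  per tumor.
* **LOH copy number fixed at 1** (hemizygous deletion); copy-neutral LOH is
  available (`copy_neutral = TRUE`, $f = (1\pm\rho)/2$, $c = 2$) but off by
  default since the loss criterion is depth-based.
* **read error 0.001** symmetric substitutions at het sites.
* **bin counts**: expected reads per bin $= \text{depth}\times\text{bin
  width}/\text{read length}$, variance 3× Poisson (typical for clean ~100 kb
  WGS bins after no correction), plus a diploid background representing the
  rest of the genome so that library normalization is anchored the way it is
  on real data.

Not emulated: GC/mappability bias, mapping artifacts, subclonal copy-number
mixtures, linked-read barcodes, and real LD/phasing structure. A green
recovery test therefore establishes that the *inference machinery* is correct
under the stated mixture model — not that the pipeline is robust to every
real-data artifact; the upstream depth table is assumed to come from a
competent caller/pileup.

## Numerical and degenerate-input choices

* Zero-depth sites never divide by zero (VAF is NA, site excluded).
* Tied tumor counts cannot pass the FDR filter ($p = 1$); the retained-allele
  assigner still guards against them defensively.
* Equal p-values share one BH-adjusted value (stable step-up; no randomized
  tie-breaking).
* Bins with zero normal reads are masked, not infinite; a tumor count of zero
  in an unmasked bin gives −Inf, which the median tolerates.
* Empty pair overlap is AMBIGUOUS with `n_shared = 0`, not an error; every
  degenerate patient input yields UNDETERMINED, reserving errors for broken
  configuration or data.
* All float output is printed at 6 significant digits and all JSON at full
  precision, making reruns byte-identical (tested).

## Known limitations

The pattern classifier assumes whole-arm (or whole-chromosome) LOH; focal or
segmental LOH would dilute concordance toward AMBIGUOUS rather than produce a
wrong call. The copy-number screen cannot detect copy-neutral LOH (the
allelic route can). Patient-level frequencies reported for the original
cohorts cannot be recomputed without the original raw data, which is why the
package's acceptance criteria are properties of the method, validated on
planted synthetic truth, rather than reproduced headline numbers.
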