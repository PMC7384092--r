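#' Concordance-call configuration
#'
#' Informative SNPs are individually significant allelic-imbalance calls, so
#' two tumors that kept the same haplotype should agree at essentially every
#' shared site and two tumors that kept opposite haplotypes should disagree at
#' essentially every shared site. The `hi`/`lo` margins absorb sequencing noise
#' and rare misassignments; the minimum shared-SNP counts guard against calls
#' from a handful of sites.
#'
#' @param hi concordance at or above which two tumors are called SAME
#'   (default 0.95)
#' @param lo concordance at or below which they are called OPPOSITE
#'   (default 0.05)
#' @param min_shared minimum shared informative SNPs for any non-AMBIGUOUS
#'   call (default 30)
#' @param min_arm minimum shared informative SNPs on an arm for that arm to
#'   enter the call (default 10)
#' @return `concordance_config` object
#' @export
concordance_config <- function(hi = 0.95, lo = 0.05, min_shared = 30, min_arm = 10) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) abort_config("require 0 <= lo < hi <= 1")
  structure(list(hi = hi, lo = lo, min_shared = min_shared, min_arm = min_arm),
            class = "concordance_config")
}

#' Retained-allele concordance between two tumors
#'
#' Intersects the two tumors' informative-SNP sets by site, computes the
#' fraction of shared SNPs at which both tumors retained the same allele —
#' overall and per chromosome arm — and calls the pair:
#' \describe{
#'   \item{SAME}{overall and every sufficiently covered arm at or above `hi`}
#'   \item{OPPOSITE}{overall and every sufficiently covered arm at or below `lo`}
#'   \item{ARM_DISCORDANT}{one arm at or above `hi`, the other at or below
#'     `lo`, both arms meeting `min_arm`}
#'   \item{AMBIGUOUS}{anything else, or fewer than `min_shared` shared SNPs}
#' }
#' The call is symmetric in the two tumors. Centromeric shared SNPs count in
#' the overall concordance but in neither arm.
#'
#' @param p_i,p_j [loh_profile()] objects (both must be retained)
#' @param arms [read_arm_map()] result
#' @param cfg [concordance_config()]
#' @return one-row data.frame: `tumor_i, tumor_j, n_shared, n_shared_p,
#'   n_shared_q, concordance_all, concordance_p, concordance_q, call`
#' @export
pairwise_concordance <- function(p_i, p_j, arms, cfg = concordance_config()) {
  a <- p_i$snps; b <- p_j$snps
  m <- match(site_key(a$chrom, a$pos), site_key(b$chrom, b$pos))
  sh <- !is.na(m)
  n_shared <- sum(sh)
  res <- data.frame(tumor_i = p_i$tumor_id, tumor_j = p_j$tumor_id,
                    n_shared = n_shared, n_shared_p = 0L, n_shared_q = 0L,
                    concordance_all = NA_real_, concordance_p = NA_real_,
                    concordance_q = NA_real_, call = "AMBIGUOUS",
                    stringsAsFactors = FALSE)
  if (n_shared == 0) return(res)
  agree <- a$retained_allele[sh] == b$retained_allele[m[sh]]
  arm <- arm_of(arms, a$chrom[sh], a$pos[sh])
  res$concordance_all <- mean(agree)
  res$n_shared_p <- sum(arm == "p")
  res$n_shared_q <- sum(arm == "q")
  if (res$n_shared_p > 0) res$concordance_p <- mean(agree[arm == "p"])
  if (res$n_shared_q > 0) res$concordance_q <- mean(agree[arm == "q"])
  res$call <- concordance_call(res, cfg)
  res
}

concordance_call <- function(res, cfg) {
  if (res$n_shared < cfg$min_shared) return("AMBIGUOUS")
  ok_p <- res$n_shared_p >= cfg$min_arm
  ok_q <- res$n_shared_q >= cfg$min_arm
  hi_p <- ok_p && res$concordance_p >= cfg$hi
  lo_p <- ok_p && res$concordance_p <= cfg$lo
  hi_q <- ok_q && res$concordance_q >= cfg$hi
  lo_q <- ok_q && res$concordance_q <= cfg$lo
  if ((hi_p && lo_q) || (lo_p && hi_q)) return("ARM_DISCORDANT")
  # arms without min_arm shared SNPs are uninformative and do not block a call
  if (res$concordance_all >= cfg$hi && (!ok_p || hi_p) && (!ok_q || hi_q)) {
    return("SAME")
  }
  if (res$concordance_all <= cfg$lo && (!ok_p || lo_p) && (!ok_q || lo_q)) {
    return("OPPOSITE")
  }
  "AMBIGUOUS"
}

#' Sites informative in every given profile
#'
#' @param profiles list of [loh_profile()] objects
#' @return character vector of `"chrom:pos"` site keys (the single profile's
#'   own sites if only one profile is given)
#' @export
common_informative_sites <- function(profiles) {
  keys <- lapply(profiles, function(p) site_key(p$snps$chrom, p$snps$pos))
  Reduce(intersect, keys)
}

# 2-coloring of a signed graph: edges sign +1 (same group) / -1 (opposite).
# Returns ok (consistency), connected, and a 0/1 coloring per node.
two_color_signed <- function(nodes, edges) {
  color <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]; j <- edges$j[r]; s <- edges$sign[r]
      adj[[i]] <- rbind(adj[[i]], data.frame(to = j, sign = s))
      adj[[j]] <- rbind(adj[[j]], data.frame(to = i, sign = s))
    }
  }
  ok <- TRUE
  n_comp <- 0L
  for (start in nodes) {
    if (!is.na(color[start])) next
    n_comp <- n_comp + 1L
    color[start] <- 0L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        want <- if (nb$sign[r] > 0) color[v] else 1L - color[v]
        u <- nb$to[r]
        if (is.na(color[u])) {
          color[u] <- want
          queue <- c(queue, u)
        } else if (color[u] != want) {
          ok <- FALSE
        }
      }
    }
  }
  list(ok = ok, connected = n_comp <= 1L, color = color)
}

groups_from_color <- function(color) {
  g1 <- sort(names(color)[color == 0L])
  g2 <- sort(names(color)[color == 1L])
  # canonical order: group containing the lexicographically first tumor first
  if (length(g2) > 0 && (length(g1) == 0 || g2[1] < g1[1])) {
    list(group1 = g2, group2 = g1)
  } else {
    list(group1 = g1, group2 = g2)
  }
}

arm_edges <- function(pairs, arm, cfg) {
  conc <- pairs[[paste0("concordance_", arm)]]
  n <- pairs[[paste0("n_shared_", arm)]]
  usable <- n >= cfg$min_arm & !is.na(conc) & (conc >= cfg$hi | conc <= cfg$lo)
  data.frame(i = pairs$tumor_i[usable], j = pairs$tumor_j[usable],
             sign = ifelse(conc[usable] >= cfg$hi, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Classify the patient-level pattern of parental-allele loss
#'
#' Compares retained alleles between all pairs of retained tumors, builds a
#' signed agreement graph (SAME edges / OPPOSITE edges) and 2-colors it into
#' haplotype groups. The pattern is:
#' \describe{
#'   \item{ARM_DISCORDANT}{at least one pair call is ARM_DISCORDANT; haplotype
#'     groups are then reported separately for the p and q arms}
#'   \item{OPPOSITE_ALLELES}{a consistent 2-coloring with two non-empty groups}
#'   \item{SAME_ALLELE}{all retained tumors in one group}
#'   \item{UNDETERMINED}{fewer than two retained tumors, an inconsistent
#'     (non-2-colorable) graph, or a graph too ambiguous/disconnected to relate
#'     all retained tumors}
#' }
#' Parental haplotypes are identified only up to relabeling: groups are
#' reported as group1/group2, never maternal/paternal.
#'
#' @param profiles list of [loh_profile()] objects (non-retained ones are
#'   dropped with a note)
#' @param arms [read_arm_map()] result
#' @param cfg [concordance_config()]
#' @param patient_id label carried into the report
#' @return object of class `patient_pattern`: list with `patient_id`,
#'   `pattern`, `groups` (whole-chromosome, or `$p`/`$q` when arm-discordant),
#'   `pairs` data.frame, `n_common_sites`, `notes`
#' @export
classify_patient <- function(profiles, arms, cfg = concordance_config(),
                             patient_id = "patient") {
  retained <- Filter(function(p) isTRUE(p$retained), profiles)
  notes <- character()
  dropped <- setdiff(vapply(profiles, `[[`, character(1), "tumor_id"),
                     vapply(retained, `[[`, character(1), "tumor_id"))
  if (length(dropped) > 0) {
    notes <- c(notes, sprintf("tumors below the informative-SNP minimum: %s",
                              paste(dropped, collapse = ", ")))
  }
  empty_pairs <- data.frame(tumor_i = character(), tumor_j = character(),
                            n_shared = integer(), n_shared_p = integer(),
                            n_shared_q = integer(),
                            concordance_all = numeric(),
                            concordance_p = numeric(),
                            concordance_q = numeric(), call = character(),
                            stringsAsFactors = FALSE)
  if (length(retained) < 2) {
    return(patient_pattern(patient_id, "UNDETERMINED", groups = NULL,
                           pairs = empty_pairs,
                           n_common_sites = if (length(retained) == 1)
                             length(common_informative_sites(retained)) else 0L,
                           notes = c(notes, "fewer than two retained tumors")))
  }
  ids <- vapply(retained, `[[`, character(1), "tumor_id")
  combos <- utils::combn(seq_along(retained), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(c2) {
    pairwise_concordance(retained[[combos[1, c2]]], retained[[combos[2, c2]]],
                         arms, cfg)
  }))
  n_common <- length(common_informative_sites(retained))

  if (any(pairs$call == "ARM_DISCORDANT")) {
    grp <- lapply(c(p = "p", q = "q"), function(arm) {
      col <- two_color_signed(ids, arm_edges(pairs, arm, cfg))
      if (!col$ok) return(NULL)
      groups_from_color(col$color[!is.na(col$color)])
    })
    if (is.null(grp$p) || is.null(grp$q)) {
      notes <- c(notes, "per-arm grouping inconsistent; groups omitted")
      grp <- NULL
    }
    return(patient_pattern(patient_id, "ARM_DISCORDANT", groups = grp,
                           pairs = pairs, n_common_sites = n_common,
                           notes = notes))
  }

  informative_pairs <- pairs[pairs$call %in% c("SAME", "OPPOSITE"), , drop = FALSE]
  edges <- data.frame(i = informative_pairs$tumor_i,
                      j = informative_pairs$tumor_j,
                      sign = ifelse(informative_pairs$call == "SAME", 1L, -1L),
                      stringsAsFactors = FALSE)
  col <- two_color_signed(ids, edges)
  if (!col$ok) {
    return(patient_pattern(patient_id, "UNDETERMINED", groups = NULL,
                           pairs = pairs, n_common_sites = n_common,
                           notes = c(notes, "mutually inconsistent pair calls (not 2-colorable)")))
  }
  if (!col$connected) {
    return(patient_pattern(patient_id, "UNDETERMINED", groups = NULL,
                           pairs = pairs, n_common_sites = n_common,
                           notes = c(notes, "pair calls too ambiguous to relate all retained tumors")))
  }
  grp <- groups_from_color(col$color)
  pattern <- if (length(grp$group2) == 0) "SAME_ALLELE" else "OPPOSITE_ALLELES"
  patient_pattern(patient_id, pattern, groups = grp, pairs = pairs,
                  n_common_sites = n_common, notes = notes)
}

patient_pattern <- function(patient_id, pattern, groups, pairs,
                            n_common_sites, notes) {
  structure(list(patient_id = patient_id, pattern = pattern, groups = groups,
                 pairs = pairs, n_common_sites = n_common_sites,
                 notes = notes),
            class = "patient_pattern")
}

#' @export
print.patient_pattern <- function(x, ...) {
  cat(sprintf("<patient_pattern> %s: %s (%d common informative SNPs)\n",
              x$patient_id, x$pattern, x$n_common_sites))
  if (!is.null(x$groups)) {
    if (!is.null(x$groups$p)) {
      cat("  p arm: {", paste(x$groups$p$group1, collapse = ","), "} vs {",
          paste(x$groups$p$group2, collapse = ","), "}\n")
      cat("  q arm: {", paste(x$groups$q$group1, collapse = ","), "} vs {",
          paste(x$groups$q$group2, collapse = ","), "}\n")
    } else {
      cat("  groups: {", paste(x$groups$group1, collapse = ","), "} vs {",
          paste(x$groups$group2, collapse = ","), "}\n")
    }
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
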