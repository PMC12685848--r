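#' Variant-allele frequency from genotype counts
#'
#' Standard gene-counting estimate `(2 * n_alt_hom + n_het) / (2 * total)`;
#' missing genotypes are excluded from the denominator (listwise per variant).
#'
#' @param n_ref_hom,n_het,n_alt_hom non-negative genotype class counts.
#' @return variant-allele frequency in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(228, 182, 99) # 0.3733
allele_frequency <- function(n_ref_hom, n_het, n_alt_hom) {
  check_counts(n_ref_hom, n_het, n_alt_hom)
  n <- n_ref_hom + n_het + n_alt_hom
  (2 * n_alt_hom + n_het) / (2 * n)
}

check_counts <- function(a, b, c) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (any(c(a, b, c) < 0)) stop("genotype counts must be non-negative")
  if (a + b + c == 0) stop("no genotyped samples")
  invisible(NULL)
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' One-degree-of-freedom chi-square comparing the three genotype classes with
#' their Hardy-Weinberg expectations at the estimated allele frequency. No
#' continuity correction is applied by default (the comparison baseline of the
#' exact-test literature); set `correct = TRUE` for the Yates-corrected
#' statistic. A monomorphic variant (an expected class count of 0) leaves the
#' test undefined: it returns `chi2_stat = 0`, `p = 1` with a warning.
#'
#' @inheritParams allele_frequency
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2_stat` and `p`.
#' @export
#' @examples
#' hwe_chisq(228, 182, 99)
hwe_chisq <- function(n_ref_hom, n_het, n_alt_hom, correct = FALSE) {
  check_counts(n_ref_hom, n_het, n_alt_hom)
  n <- n_ref_hom + n_het + n_alt_hom
  p <- (2 * n_ref_hom + n_het) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expd == 0)) {
    warning("monomorphic variant: chi-square test undefined, returning p = 1")
    return(list(chi2_stat = 0, p = 1))
  }
  obs <- c(n_ref_hom, n_het, n_alt_hom)
  dev <- abs(obs - expd)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / expd)
  list(chi2_stat = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions: the p-value sums, over
#' all heterozygote counts attainable with the observed allele counts, the
#' conditional probabilities no greater than that of the observed
#' heterozygote count. The conditional distribution is evaluated by the
#' numerically stable two-directional recurrence from its mode, so the test
#' scales to thousands of samples; the normalised probabilities over the
#' support sum to 1 to within 1e-9. Monomorphic variants return 1.
#'
#' @inheritParams allele_frequency
#' @return exact p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact(228, 182, 99)
hwe_exact <- function(n_ref_hom, n_het, n_alt_hom) {
  check_counts(n_ref_hom, n_het, n_alt_hom)
  n <- n_ref_hom + n_het + n_alt_hom
  hom_r <- min(n_ref_hom, n_alt_hom)
  rare <- 2L * hom_r + n_het   # copies of the rarer allele
  if (rare == 0L) return(1)

  probs <- numeric(rare + 1L)  # index: het count + 1
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  probs[mid + 1L] <- 1

  het <- mid
  homr <- (rare - mid) / 2
  homc <- n - het - homr
  while (het >= 2L) {
    probs[het - 1L] <- probs[het + 1L] * het * (het - 1) /
      (4 * (homr + 1) * (homc + 1))
    het <- het - 2L
    homr <- homr + 1
    homc <- homc + 1
  }
  het <- mid
  homr <- (rare - mid) / 2
  homc <- n - het - homr
  while (het <= rare - 2L) {
    probs[het + 3L] <- probs[het + 1L] * 4 * homr * homc /
      ((het + 2) * (het + 1))
    het <- het + 2L
    homr <- homr - 1
    homc <- homc - 1
  }
  probs <- probs / sum(probs)
  p_obs <- probs[n_het + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control: `alpha / n_tests`, applied per gene based on the
#' number of variants tested.
#'
#' @param alpha nominal significance level.
#' @param n_tests number of tests in the family (>= 1).
#' @return corrected threshold.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 8) # 0.00625
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(n_tests < 1)) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Inbreeding coefficient (heterozygote deficit)
#'
#' `F = 1 - H_obs / H_exp` with `H_obs = n_het / total` and
#' `H_exp = 2 p (1 - p)`. Positive values quantify the heterozygote deficit
#' that pooling sub-populations with divergent allele frequencies produces
#' (the Wahlund effect). Undefined (returns `NA`) for monomorphic variants.
#'
#' @inheritParams allele_frequency
#' @return F in `[-1, 1]`, or `NA` when monomorphic.
#' @export
#' @examples
#' inbreeding_coefficient(228, 182, 99) # about 0.236
inbreeding_coefficient <- function(n_ref_hom, n_het, n_alt_hom) {
  check_counts(n_ref_hom, n_het, n_alt_hom)
  n <- n_ref_hom + n_het + n_alt_hom
  p <- allele_frequency(n_ref_hom, n_het, n_alt_hom)
  h_exp <- 2 * p * (1 - p)
  if (h_exp == 0) return(NA_real_)
  1 - (n_het / n) / h_exp
}

#' Minimum sample size for estimating a single proportion
#'
#' Infinite-population formula `n = ceiling(Z^2 * p * (1 - p) / d^2)` for an
#' anticipated prevalence `p` estimated to absolute precision `d` at the
#' confidence level implied by `Z`.
#'
#' @param p anticipated prevalence, in (0, 1).
#' @param d absolute precision, in (0, 1).
#' @param z standard-normal quantile for the confidence level (1.96 for 95%).
#' @return integer sample size.
#' @export
#' @examples
#' sample_size_single_proportion(0.052, 0.02) # 474
sample_size_single_proportion <- function(p, d, z = 1.96) {
  stopifnot(p > 0, p < 1, d > 0, d < 1, z > 0)
  as.integer(ceiling(z^2 * p * (1 - p) / d^2))
}

#' Genotype class counts per variant
#'
#' Tabulates ref-hom / het / alt-hom / missing calls per gene and rsID from a
#' genotype-call table.
#'
#' @param genotypes data.frame with `sample_id`, `gene`, `rsid`, `call`.
#' @return data.frame with `gene`, `rsid`, `n_ref_hom`, `n_het`, `n_alt_hom`,
#'   `n_missing`.
#' @export
genotype_counts <- function(genotypes) {
  stopifnot(all(c("gene", "rsid", "call") %in% names(genotypes)))
  combos <- unique(genotypes[, c("gene", "rsid")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- genotypes[genotypes$gene == combos$gene[i] &
                     genotypes$rsid == combos$rsid[i], ]
    data.frame(gene = combos$gene[i], rsid = combos$rsid[i],
               n_ref_hom = sum(g$call == "0/0"),
               n_het = sum(g$call == "0/1"),
               n_alt_hom = sum(g$call == "1/1"),
               n_missing = sum(g$call == "NOCALL"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-variant population-genetic summary
#'
#' For every variant: allele frequency, Hardy-Weinberg chi-square and exact
#' tests, per-gene Bonferroni-corrected threshold, deviation verdict (exact
#' p-value below the corrected threshold) and inbreeding coefficient. Missing
#' genotypes are excluded listwise per variant.
#'
#' @param genotypes genotype-call table, or a pre-tabulated count table from
#'   [genotype_counts()].
#' @param alpha nominal family-wise significance level.
#' @param n_tests optional named vector of per-gene test counts for the
#'   Bonferroni correction; defaults to the number of variants observed per
#'   gene.
#' @return data.frame with one row per variant: counts, `maf`, `chi2_stat`,
#'   `chi2_p`, `exact_p`, `alpha_corrected`, `deviates`, `f_inbreeding`.
#' @export
variant_stats <- function(genotypes, alpha = 0.05, n_tests = NULL) {
  counts <- if ("call" %in% names(genotypes)) genotype_counts(genotypes)
            else genotypes
  need <- c("gene", "rsid", "n_ref_hom", "n_het", "n_alt_hom")
  stopifnot(all(need %in% names(counts)))
  if (is.null(counts$n_missing)) counts$n_missing <- 0L

  per_gene <- table(counts$gene)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    nt <- if (!is.null(n_tests) && x$gene %in% names(n_tests)) {
      n_tests[[x$gene]]
    } else {
      as.integer(per_gene[[x$gene]])
    }
    chs <- suppressWarnings(hwe_chisq(x$n_ref_hom, x$n_het, x$n_alt_hom))
    ex <- hwe_exact(x$n_ref_hom, x$n_het, x$n_alt_hom)
    ac <- bonferroni_threshold(alpha, nt)
    data.frame(x,
               maf = allele_frequency(x$n_ref_hom, x$n_het, x$n_alt_hom),
               chi2_stat = chs$chi2_stat, chi2_p = chs$p, exact_p = ex,
               alpha_corrected = ac, deviates = ex < ac,
               f_inbreeding = inbreeding_coefficient(x$n_ref_hom, x$n_het,
                                                     x$n_alt_hom),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
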