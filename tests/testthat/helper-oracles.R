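# Independent brute-force oracle for the Hardy-Weinberg exact test: full
# enumeration of all genotype tables with the observed allele counts, weighted
# by the conditional (multivariate hypergeometric) distribution of the
# heterozygote count.
hwe_exact_enum <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  rare <- 2L * min(n_ref_hom, n_alt_hom) + n_het
  if (rare == 0L) return(1)
  hs <- seq(rare %% 2L, rare, by = 2L)
  hs <- hs[(rare - hs) / 2 >= 0 & (n - hs - (rare - hs) / 2) >= 0]
  logp <- vapply(hs, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
      h * log(2) -
      (lfactorial(2 * n) - lfactorial(rare) - lfactorial(2 * n - rare))
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[hs == n_het]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

panel_rsids_of <- function(gene, defs = pgx_allele_definitions()) {
  pgxcohort:::panel_rsids(defs, gene)
}

# Build a truth data.frame row by hand (for driving the emitters directly).
truth_row <- function(sample_id, gene, a1, a2, c1 = 1L, c2 = 1L, deme = 1L) {
  data.frame(sample_id = sample_id, gene = gene, allele1 = a1, allele2 = a2,
             copies1 = as.integer(c1), copies2 = as.integer(c2),
             deme = as.integer(deme), stringsAsFactors = FALSE)
}

# Canonical label of a truth row, via the package's own renderer.
truth_label <- function(truth, defs = pgx_allele_definitions()) {
  vapply(seq_len(nrow(truth)), function(i) render_diplotype(
    list(gene = truth$gene[i],
         allele = c(truth$allele1[i], truth$allele2[i]),
         copies = c(truth$copies1[i], truth$copies2[i])), defs), "")
}

# Does a truth row's copy configuration match the default duplication policy
# (all extra copies on the highest-activity allele, ties to the higher label)?
policy_concordant <- function(truth, defs = pgx_allele_definitions()) {
  vapply(seq_len(nrow(truth)), function(i) {
    a <- c(truth$allele1[i], truth$allele2[i])
    cp <- c(truth$copies1[i], truth$copies2[i])
    if (all(cp <= 1L) || a[1] == a[2]) return(TRUE)
    r <- pgxcohort:::allele_rank(defs, truth$gene[i], a)
    dup <- order(-r$activity, -r$label_num)[1]
    cp[dup] > 1L && cp[-dup] == 1L
  }, logical(1))
}

# Metabolizer category implied by a truth row, bypassing the caller.
truth_category <- function(truth, defs = pgx_allele_definitions()) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- list(gene = truth$gene[i],
              allele = c(truth$allele1[i], truth$allele2[i]),
              copies = c(truth$copies1[i], truth$copies2[i]))
    if (truth$gene[i] == "CYP2D6") cyp2d6_phenotype(activity_score(d, defs))
    else cyp2c19_phenotype(d, defs)
  }, "")
}

# A phenotype-assignment table with given per-category counts for one gene,
# for feeding printed cohort tables into the aggregation layer.
phenotype_table <- function(gene, counts, offset = 0L) {
  categories <- rep(names(counts), counts)
  data.frame(sample_id = sprintf("P%04d", offset + seq_along(categories)),
             gene = gene, diplotype = NA_character_,
             activity_score = NA_real_, category = categories,
             actionable = ifelse(categories == "NM", FALSE, TRUE),
             stringsAsFactors = FALSE)
}
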