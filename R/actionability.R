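#' Look up the CPIC recommendation for a gene, phenotype and drug
#'
#' Exact-match lookup in the rule table. A drug present in the table but
#' without a rule for this phenotype yields the `standard` action (with a
#' logged note); a drug absent from the table yields an explicit
#' `unknown_drug` result, never a silent `standard`.
#'
#' @param gene gene identifier.
#' @param phenotype metabolizer category (`PM`, `IM`, `NM`, `RM`, `UM`).
#' @param drug drug name.
#' @param rules rule table ([cpic_rules()]).
#' @return one-row data.frame with `gene`, `phenotype`, `drug`, `action`,
#'   `strength`.
#' @export
#' @examples
#' recommend_action("CYP2D6", "UM", "paroxetine")
recommend_action <- function(gene, phenotype, drug, rules = cpic_rules()) {
  if (!drug %in% rules$drug) {
    return(data.frame(gene = gene, phenotype = phenotype, drug = drug,
                      action = "unknown_drug", strength = NA_character_,
                      stringsAsFactors = FALSE))
  }
  hit <- rules[rules$gene == gene & rules$phenotype == phenotype &
                 rules$drug == drug, ]
  if (nrow(hit) == 0L) {
    pgx_log("NOTE", "no rule for (%s, %s, %s): standard dosing",
            gene, phenotype, drug)
    return(data.frame(gene = gene, phenotype = phenotype, drug = drug,
                      action = "standard", strength = NA_character_,
                      stringsAsFactors = FALSE))
  }
  rownames(hit) <- NULL
  hit
}

#' Is an individual's phenotype profile clinically actionable?
#'
#' `TRUE` iff any gene's metabolizer category is non-normal (IM, PM, RM or
#' UM), the categories for which prescribing guidelines recommend deviating
#' from standard dosing. `NA` when every category is indeterminate.
#'
#' @param categories character vector of the individual's per-gene categories.
#' @return logical (or `NA`).
#' @export
#' @examples
#' actionable_flag(c(CYP2D6 = "NM", CYP2C19 = "RM")) # TRUE
actionable_flag <- function(categories) {
  if (length(categories) == 0L) stop("no phenotype assignments")
  known <- categories[categories != "indeterminate" & !is.na(categories)]
  if (length(known) == 0L) return(NA)
  any(known %in% c("IM", "PM", "RM", "UM"))
}

#' Combined actionable prevalence under cross-gene independence
#'
#' One minus the probability of being a normal metabolizer at every locus:
#' `1 - prod(p_nm)`. Assumes independence between the genes (CYP2D6 on
#' chromosome 22, CYP2C19 on chromosome 10).
#'
#' @param p_nm_by_gene vector of per-gene normal-metabolizer proportions.
#' @return combined actionable proportion.
#' @export
#' @examples
#' combined_actionable_prevalence(c(0.538, 0.257)) # 0.8617
combined_actionable_prevalence <- function(p_nm_by_gene) {
  if (length(p_nm_by_gene) == 0L) stop("empty proportion list")
  stopifnot(all(p_nm_by_gene >= 0), all(p_nm_by_gene <= 1))
  1 - prod(p_nm_by_gene)
}

#' Cohort drug exposure by substrate gene
#'
#' Sums per-drug exposure proportions by the metabolising gene each drug maps
#' to, giving the share of the cohort prescribed at least one substrate of
#' each gene (exact when each individual receives a single drug, the design
#' this summary targets). Drugs missing from the map are summed under
#' `"unmapped"` with a warning.
#'
#' @param drug_proportions named numeric vector of per-drug exposure
#'   proportions.
#' @param map drug-gene map ([drug_gene_map()]).
#' @return named numeric vector of per-gene substrate exposure proportions.
#' @export
#' @examples
#' substrate_exposure(c(sertraline = 0.341, escitalopram = 0.282))
substrate_exposure <- function(drug_proportions, map = drug_gene_map()) {
  stopifnot(!is.null(names(drug_proportions)))
  genes <- unique(map$gene)
  out <- setNames(numeric(length(genes)), genes)
  unmapped <- 0
  for (drug in names(drug_proportions)) {
    g <- map$gene[map$drug == drug]
    if (length(g) == 0L) {
      unmapped <- unmapped + drug_proportions[[drug]]
    } else {
      # a drug metabolised by several genes counts toward each
      out[g] <- out[g] + drug_proportions[[drug]]
    }
  }
  if (unmapped > 0) {
    warning("drugs without a gene mapping account for ",
            format(unmapped), " of exposure")
    out <- c(out, unmapped = unmapped)
  }
  out
}

#' Cohort-level actionability report
#'
#' Aggregates per-sample phenotype assignments (and optionally prescriptions)
#' into the cohort summary: per-gene phenotype proportions (indeterminate
#' assignments are excluded from the denominator and reported separately),
#' per-gene non-NM proportions, the combined actionable prevalence both as a
#' direct count of individuals with at least one actionable phenotype and via
#' the independence formula (on NM proportions rounded to 3 decimals, making
#' the rounding convention of published estimates explicit), the share of the
#' cohort triggering each recommendation rule, and drug-exposure proportions.
#'
#' @param phenotypes phenotype table from [assign_phenotypes()].
#' @param prescriptions optional data.frame with `sample_id`, `drug`.
#' @param rules rule table ([cpic_rules()]).
#' @param map drug-gene map ([drug_gene_map()]).
#' @return a list of class `pgx_report`; every proportion carries its
#'   numerator and denominator.
#' @export
cohort_report <- function(phenotypes, prescriptions = NULL,
                          rules = cpic_rules(), map = drug_gene_map()) {
  stopifnot(all(c("sample_id", "gene", "category") %in% names(phenotypes)))

  genes <- unique(phenotypes$gene)
  per_gene <- lapply(genes, function(g) {
    ph <- phenotypes[phenotypes$gene == g, ]
    det <- ph[ph$category != "indeterminate", ]
    n <- nrow(det)
    cats <- sort(unique(det$category))
    prop <- lapply(cats, function(cc) {
      k <- sum(det$category == cc)
      list(count = k, denominator = n, proportion = k / n)
    })
    names(prop) <- cats
    non_nm <- sum(det$category != "NM")
    list(n_assigned = nrow(ph), n_determinate = n,
         n_indeterminate = nrow(ph) - n,
         phenotype = prop,
         non_nm = list(count = non_nm, denominator = n,
                       proportion = non_nm / n),
         nm_proportion = 1 - non_nm / n)
  })
  names(per_gene) <- genes

  # direct count: individuals with >= 1 actionable category
  by_sample <- split(phenotypes$category, phenotypes$sample_id)
  flags <- vapply(by_sample, actionable_flag, logical(1))
  n_det <- sum(!is.na(flags))
  count_based <- list(count = sum(flags, na.rm = TRUE), denominator = n_det,
                      proportion = if (n_det > 0) sum(flags, na.rm = TRUE) / n_det
                                   else NA_real_)
  p_nm <- vapply(per_gene, function(x) round(x$nm_proportion, 3), numeric(1))
  independence <- combined_actionable_prevalence(p_nm)

  # share of the cohort whose (gene, phenotype) triggers each rule row
  rule_prop <- vapply(seq_len(nrow(rules)), function(i) {
    g <- rules$gene[i]
    if (!g %in% genes) return(NA_real_)
    pg <- per_gene[[g]]
    hit <- pg$phenotype[[rules$phenotype[i]]]
    if (is.null(hit)) 0 else hit$proportion
  }, numeric(1))
  rule_table <- cbind(rules, cohort_proportion = rule_prop)

  exposure <- NULL
  if (!is.null(prescriptions)) {
    stopifnot(all(c("sample_id", "drug") %in% names(prescriptions)))
    missing_pheno <- setdiff(prescriptions$sample_id, phenotypes$sample_id)
    if (length(missing_pheno) > 0L) {
      pgx_log("WARN", "%d prescribed sample(s) lack phenotype assignments",
              length(missing_pheno))
    }
    n_rx <- length(unique(prescriptions$sample_id))
    drug_n <- table(prescriptions$drug)
    drug_prop <- setNames(as.numeric(drug_n) / n_rx, names(drug_n))
    exposure <- list(n_prescribed = n_rx,
                     by_drug = as.list(drug_prop),
                     by_gene = as.list(substrate_exposure(drug_prop, map)),
                     coverage_gap = missing_pheno)
  }

  out <- list(genes = per_gene,
              combined_actionable = list(count_based = count_based,
                                         independence = independence,
                                         nm_proportions_used = as.list(p_nm)),
              rules = rule_table,
              exposure = exposure)
  class(out) <- "pgx_report"
  out
}

#' @export
print.pgx_report <- function(x, ...) {
  cat("Cohort actionability report\n")
  for (g in names(x$genes)) {
    pg <- x$genes[[g]]
    cats <- vapply(names(pg$phenotype), function(cc)
      sprintf("%s %.1f%%", cc, 100 * pg$phenotype[[cc]]$proportion), "")
    cat(sprintf("  %s (n = %d determinate): %s; non-NM %.1f%%\n",
                g, pg$n_determinate, paste(cats, collapse = ", "),
                100 * pg$non_nm$proportion))
  }
  ca <- x$combined_actionable
  cat(sprintf("  combined actionable: %.1f%% (count), %.1f%% (independence)\n",
              100 * ca$count_based$proportion, 100 * ca$independence))
  if (!is.null(x$exposure)) {
    bg <- unlist(x$exposure$by_gene)
    cat(sprintf("  substrate exposure: %s\n",
                paste(sprintf("%s %.1f%%", names(bg), 100 * bg),
                      collapse = ", ")))
  }
  invisible(x)
}
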