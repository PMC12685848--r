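#' CYP2D6 activity score of a diplotype
#'
#' The CPIC activity-score system sums, over both alleles, the allele's
#' activity value times its copy count: normal-function alleles (*1, *2)
#' contribute 1 per copy, decreased-function alleles *41 and *10 contribute
#' 0.5 and 0.25, and non-functional alleles (*3, *4, *5, *6) contribute 0.
#'
#' @param diplotype list with `gene`, `allele`, `copies` (as from
#'   [parse_diplotype()]) or a one-row data.frame with `gene`,
#'   `allele1`/`allele2`, `copies1`/`copies2`.
#' @param defs allele definition table.
#' @return numeric activity score, or `NA` if any allele lacks an activity
#'   value.
#' @export
#' @examples
#' activity_score(parse_diplotype("*2/*41", "CYP2D6"))   # 1.5
#' activity_score(parse_diplotype("*1/*10x3", "CYP2D6")) # 1.75
activity_score <- function(diplotype, defs = pgx_allele_definitions()) {
  if (is.data.frame(diplotype)) {
    diplotype <- list(gene = diplotype$gene,
                      allele = c(diplotype$allele1, diplotype$allele2),
                      copies = c(diplotype$copies1, diplotype$copies2))
  }
  star <- canonical_star(diplotype$allele)
  i <- match(paste(diplotype$gene, star), paste(defs$gene, defs$star))
  if (anyNA(i)) stop("unknown allele: ", paste(star[is.na(i)], collapse = ", "))
  act <- defs$activity_value[i]
  if (anyNA(act)) return(NA_real_)
  sum(act * diplotype$copies)
}

#' CYP2D6 metabolizer category from an activity score
#'
#' CPIC bins, with both range bounds inclusive as published: poor metabolizer
#' (PM) at an activity score of exactly 0; intermediate (IM) for 0.25-1.0;
#' normal (NM) for 1.25-2.25; ultrarapid (UM) above 2.25. Scores in the gaps
#' (0, 0.25) and (1.0, 1.25) — unreachable with the shipped allele values but
#' possible with custom tables — map to `indeterminate` rather than to the
#' nearest bin, failing loudly on unsupported extensions.
#'
#' @param activity_score non-negative activity score(s); `NA` gives
#'   `indeterminate`.
#' @return character category in `PM`, `IM`, `NM`, `UM`, `indeterminate`.
#' @export
#' @examples
#' cyp2d6_phenotype(c(0, 0.75, 2.25, 4))
cyp2d6_phenotype <- function(activity_score) {
  if (any(!is.na(activity_score) & activity_score < 0)) {
    stop("activity score must be non-negative")
  }
  eps <- 1e-9
  ifelse(is.na(activity_score), "indeterminate",
  ifelse(abs(activity_score) < eps, "PM",
  ifelse(activity_score >= 0.25 - eps & activity_score <= 1.0 + eps, "IM",
  ifelse(activity_score >= 1.25 - eps & activity_score <= 2.25 + eps, "NM",
  ifelse(activity_score > 2.25, "UM", "indeterminate")))))
}

#' CYP2C19 metabolizer category from allele function classes
#'
#' CYP2C19 has no activity-score system; the phenotype follows from the pair
#' of allele function classes: two non-functional alleles PM; one
#' non-functional with a normal or increased-function allele IM; two normal
#' NM; normal plus increased RM; two increased UM.
#'
#' @param diplotype as in [activity_score()] (copy counts are ignored:
#'   CYP2C19 has no CNV channel).
#' @inheritParams activity_score
#' @return character category in `PM`, `IM`, `NM`, `RM`, `UM`,
#'   `indeterminate`.
#' @export
#' @examples
#' cyp2c19_phenotype(parse_diplotype("*1/*2", "CYP2C19"))   # IM
#' cyp2c19_phenotype(parse_diplotype("*17/*17", "CYP2C19")) # UM
cyp2c19_phenotype <- function(diplotype, defs = pgx_allele_definitions()) {
  if (is.data.frame(diplotype)) {
    diplotype <- list(gene = diplotype$gene,
                      allele = c(diplotype$allele1, diplotype$allele2))
  }
  star <- canonical_star(diplotype$allele)
  i <- match(paste(diplotype$gene, star), paste(defs$gene, defs$star))
  if (anyNA(i)) stop("unknown allele: ", paste(star[is.na(i)], collapse = ", "))
  fun <- sort(defs$function_class[i])
  if (any(!fun %in% c("none", "normal", "increased"))) return("indeterminate")
  pair <- paste(fun, collapse = "+")
  switch(pair,
         "none+none" = "PM",
         "none+normal" = "IM",
         "increased+none" = "IM",
         "normal+normal" = "NM",
         "increased+normal" = "RM",
         "increased+increased" = "UM",
         "indeterminate")
}

#' Assign metabolizer phenotypes to a diplotype table
#'
#' CYP2D6 rows are phenotyped through the activity score, CYP2C19 rows through
#' allele-function rules. A phenotype is actionable when the category is
#' non-normal (IM, PM, RM or UM); indeterminate rows (including samples with a
#' rejected copy-number call) carry `NA`.
#'
#' @param diplotypes diplotype table from [call_diplotypes()].
#' @inheritParams activity_score
#' @return data.frame with `sample_id`, `gene`, `diplotype`,
#'   `activity_score` (CYP2D6 only), `category`, `actionable`.
#' @export
assign_phenotypes <- function(diplotypes, defs = pgx_allele_definitions()) {
  rows <- lapply(seq_len(nrow(diplotypes)), function(i) {
    d <- diplotypes[i, ]
    if (is.na(d$allele1)) {
      score <- NA_real_
      cat <- "indeterminate"
    } else if (d$gene == "CYP2D6") {
      score <- activity_score(d, defs)
      cat <- cyp2d6_phenotype(score)
    } else {
      score <- NA_real_
      cat <- cyp2c19_phenotype(d, defs)
    }
    data.frame(sample_id = d$sample_id, gene = d$gene,
               diplotype = d$diplotype, activity_score = score,
               category = cat,
               actionable = if (cat == "indeterminate") NA else cat != "NM",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
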