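#' Star-allele definition table
#'
#' Loads the allele-definition table: one row per star allele with its gene,
#' tag rsIDs, functional class and (for CYP2D6) CPIC activity value. The
#' shipped default covers the AMP Tier 1 panel used throughout the package:
#' CYP2D6 *1, *2 (rs16947), *3 (rs35742686), *4 (rs3892097 + rs1065852),
#' *5 (whole-gene deletion, no SNP tag), *6 (rs5030655), *10 (rs1065852),
#' *41 (rs28371725 + rs16947) and CYP2C19 *1, *2 (rs4244285), *3 (rs4986893),
#' *17 (rs12248560).
#'
#' `tag_rsids` is a comma-separated list; the *first* rsID is the allele's
#' defining tag (the variant that distinguishes it within the panel), any
#' further rsIDs are carried on the same haplotype (e.g. *41 also carries the
#' rs16947 variant of its *2 backbone). The default allele (*1) and the
#' deletion allele (*5) have empty tag sets. CYP2C19 alleles have no activity
#' value: that gene is phenotyped by allele function, not activity score.
#'
#' `*2A` is accepted on input as an alias of `*2` (same tag, same normal
#' function); the table keeps a single canonical `*2` entry.
#'
#' @param path optional path to a user-extended TSV with the same columns
#'   (`gene`, `star`, `tag_rsids`, `function_class`, `activity_value`,
#'   `deletion`). Defaults to the table shipped with the package.
#' @return data.frame of allele definitions.
#' @export
#' @examples
#' defs <- pgx_allele_definitions()
#' subset(defs, gene == "CYP2D6")
pgx_allele_definitions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "allele_definitions.tsv",
                                package = "pgxcohort", mustWork = TRUE)
  defs <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("gene", "star", "tag_rsids", "function_class",
                "activity_value", "deletion")
  if (!all(required %in% names(defs))) {
    stop("allele definition table must have columns: ",
         paste(required, collapse = ", "))
  }
  defs$tag_rsids[is.na(defs$tag_rsids)] <- ""
  bad <- !defs$function_class %in% c("normal", "decreased", "none", "increased")
  if (any(bad)) {
    stop("unknown function_class: ", paste(unique(defs$function_class[bad]),
                                           collapse = ", "))
  }
  # tag sets must be unique within a gene (the *1 / *5 empty sets excepted)
  tagged <- defs[nzchar(defs$tag_rsids), ]
  key <- paste(tagged$gene, tagged$tag_rsids)
  if (anyDuplicated(key)) {
    stop("duplicate tag set within a gene: ", key[duplicated(key)][1])
  }
  defs
}

# split the comma-joined tag list of one definition row
allele_tags <- function(def_row) {
  if (!nzchar(def_row$tag_rsids)) character(0)
  else strsplit(def_row$tag_rsids, ",", fixed = TRUE)[[1]]
}

# all panel rsIDs for a gene
panel_rsids <- function(defs, gene) {
  unique(unlist(lapply(which(defs$gene == gene), function(i)
    allele_tags(defs[i, ]))))
}

# map label aliases to canonical labels (*2A -> *2)
canonical_star <- function(star) {
  ifelse(star == "*2A", "*2", star)
}

# ordering key for canonical diplotype rendering: activity descending, then
# numeric label ascending. CYP2C19 alleles have no activity value; their
# function class stands in (increased > normal > decreased > none).
allele_rank <- function(defs, gene, star) {
  i <- match(paste(gene, star), paste(defs$gene, defs$star))
  if (anyNA(i)) stop("unknown allele for ", gene, ": ",
                     paste(star[is.na(i)], collapse = ", "))
  act <- defs$activity_value[i]
  fun_rank <- c(increased = 1.5, normal = 1, decreased = 0.5, none = 0)
  act[is.na(act)] <- fun_rank[defs$function_class[i][is.na(act)]]
  num <- as.numeric(sub("^\\*(\\d+).*$", "\\1", star))
  list(activity = act, label_num = num)
}

#' CPIC recommendation rule table
#'
#' Loads the (gene, metabolizer phenotype, drug) -> (action, strength) rule
#' table. The shipped default transcribes the CPIC antidepressant
#' recommendations for the eight drugs covered by the analysis: paroxetine,
#' venlafaxine, vortioxetine, fluvoxamine, amitriptyline and nortriptyline
#' keyed to CYP2D6 phenotypes, and escitalopram, sertraline and amitriptyline
#' keyed to CYP2C19 phenotypes. Actions are one of `standard`,
#' `lower_start_slower_titration`, `reduce_25`, `reduce_50`,
#' `alternative_drug`, `consider_higher_or_alternative`; strengths are
#' `strong`, `moderate` or `optional`. The table is data, not code: users can
#' supply an updated TSV as guidelines evolve.
#'
#' @param path optional path to a rules TSV (`gene`, `phenotype`, `drug`,
#'   `action`, `strength`).
#' @return data.frame of recommendation rules.
#' @export
cpic_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cpic_rules.tsv",
                                package = "pgxcohort", mustWork = TRUE)
  rules <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "phenotype", "drug", "action", "strength")
  if (!all(required %in% names(rules))) {
    stop("rule table must have columns: ", paste(required, collapse = ", "))
  }
  key <- paste(rules$gene, rules$phenotype, rules$drug)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, phenotype, drug) rule: ", key[duplicated(key)][1])
  }
  rules
}

#' Drug to metabolising-gene map
#'
#' Maps each drug to the pharmacogene(s) relevant for its prescribing
#' recommendations, used to aggregate cohort drug exposure by substrate gene.
#' A drug may map to more than one gene (amitriptyline is metabolised by both
#' CYP2D6 and CYP2C19).
#'
#' @param path optional path to a TSV with columns `drug`, `gene`.
#' @return data.frame with columns `drug`, `gene`.
#' @export
drug_gene_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_genes.tsv",
                                package = "pgxcohort", mustWork = TRUE)
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "gene") %in% names(map))) {
    stop("drug-gene map must have columns: drug, gene")
  }
  map
}
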