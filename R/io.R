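# TSV (tab-delimited, UTF-8, header row, "NA" missing sentinel) is the
# interchange dialect; JSON for nested reports.

write_pgx_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_pgx_tsv <- function(path, required) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                  check.names = FALSE)
  if (!all(required %in% names(x))) {
    stop(basename(path), " must have columns: ",
         paste(required, collapse = ", "))
  }
  x
}

#' Read a genotype-call table
#'
#' TSV with header `sample_id`, `gene`, `rsid`, `call`; calls in `0/0`, `0/1`,
#' `1/1`, `NOCALL`. Phase separators (`0|1`) are tolerated and discarded
#' (the calls are unphased by contract) and `1/0` is normalised to `0/1`.
#' Duplicate sample-by-rsID rows are a hard error naming the line; rsIDs
#' outside the allele-definition panel are kept but reported with counts.
#'
#' @param path TSV file path.
#' @param defs allele definitions used to recognise panel rsIDs.
#' @return validated genotype-call data.frame.
#' @export
read_genotype_table <- function(path, defs = pgx_allele_definitions()) {
  gt <- read_pgx_tsv(path, c("sample_id", "gene", "rsid", "call"))
  gt$call <- gsub("|", "/", gt$call, fixed = TRUE)
  gt$call[gt$call == "1/0"] <- "0/1"
  ok <- gt$call %in% c("0/0", "0/1", "1/1", "NOCALL")
  if (any(!ok)) {
    stop("malformed call token '", gt$call[!ok][1], "' at line ",
         which(!ok)[1] + 1L)
  }
  key <- paste(gt$sample_id, gt$gene, gt$rsid)
  if (anyDuplicated(key)) {
    stop("duplicate sample x rsid row at line ", which(duplicated(key))[1] + 1L)
  }
  known <- unlist(lapply(unique(gt$gene), function(g) panel_rsids(defs, g)))
  n_unknown <- sum(!gt$rsid %in% known)
  if (n_unknown > 0L) {
    pgx_log("WARN", "%d genotype row(s) at rsIDs outside the panel", n_unknown)
  }
  gt
}

#' Read a Ct measurement table
#'
#' TSV with header `sample_id`, `assay` (`CYP2D6_ex9` / `RNaseP`),
#' `replicate`, `ct`; the literal `NA` is the no-amplification sentinel.
#'
#' @param path TSV file path.
#' @return Ct data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read_pgx_tsv(path, c("sample_id", "assay", "replicate", "ct"))
  ct$ct <- as.numeric(ct$ct)
  ct$replicate <- as.integer(ct$replicate)
  bad <- setdiff(unique(ct$assay), c("CYP2D6_ex9", "RNaseP"))
  if (length(bad) > 0L) stop("unknown assay label(s): ",
                             paste(bad, collapse = ", "))
  ct
}

#' Read a minimal VCF into genotype calls
#'
#' Optional VCF ingestion (requires the vcfR package): biallelic records whose
#' ID matches a panel rsID are converted to the same record type as
#' [read_genotype_table()] using the GT subfield only (phase discarded).
#' Multi-allelic and unmatched records are skipped with a logged count.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param defs allele definitions providing the panel rsIDs and their genes.
#' @return genotype-call data.frame.
#' @export
read_vcf_minimal <- function(path, defs = pgx_allele_definitions()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_minimal requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fmt <- vcf@gt[, "FORMAT"]
  if (length(fmt) == 0L || !all(vapply(strsplit(fmt, ":", fixed = TRUE),
                                       function(f) "GT" %in% f, logical(1)))) {
    stop("VCF has no GT format subfield")
  }
  panel <- unique(unlist(lapply(unique(defs$gene), function(g)
    panel_rsids(defs, g))))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  matched <- fix[, "ID"] %in% panel & !multi
  n_skip <- sum(!matched)
  if (n_skip > 0L) {
    pgx_log("WARN", "skipped %d VCF record(s): multi-allelic or not in panel",
            n_skip)
  }
  if (!any(matched)) {
    warning("no panel rsIDs matched in ", basename(path))
    return(data.frame(sample_id = character(0), gene = character(0),
                      rsid = character(0), call = character(0)))
  }
  gt <- vcfR::extract.gt(vcf[matched, ], element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(matched),
                                     dimnames = list(NULL, names(gt)))
  rsid_gene <- unique(do.call(rbind, lapply(seq_len(nrow(defs)), function(i)
    if (nzchar(defs$tag_rsids[i]))
      data.frame(rsid = allele_tags(defs[i, ]), gene = defs$gene[i],
                 stringsAsFactors = FALSE) else NULL)))
  rec <- expand.grid(rsid = fix[matched, "ID"], sample_id = colnames(gt),
                     stringsAsFactors = FALSE)
  rec$call <- as.vector(gt)
  rec$call <- gsub("|", "/", rec$call, fixed = TRUE)
  rec$call[is.na(rec$call) | rec$call == "./."] <- "NOCALL"
  rec$call[rec$call == "1/0"] <- "0/1"
  rec$gene <- rsid_gene$gene[match(rec$rsid, rsid_gene$rsid)]
  rec[, c("sample_id", "gene", "rsid", "call")]
}

#' Read a diplotype table
#' @param path TSV path with `sample_id`, `gene`, `allele1`, `allele2`,
#'   `copies1`, `copies2`, `total_cn`, `diplotype`, `flags`.
#' @return data.frame.
#' @export
read_diplotype_table <- function(path) {
  x <- read_pgx_tsv(path, c("sample_id", "gene", "diplotype", "flags"))
  x$flags[is.na(x$flags)] <- ""
  x
}

#' Read a phenotype table
#' @param path TSV path with `sample_id`, `gene`, `diplotype`,
#'   `activity_score`, `category`, `actionable`.
#' @return data.frame.
#' @export
read_phenotype_table <- function(path) {
  read_pgx_tsv(path, c("sample_id", "gene", "category", "actionable"))
}

#' Read a prescription table
#' @param path TSV path with `sample_id`, `drug`.
#' @return data.frame.
#' @export
read_prescription_table <- function(path) {
  read_pgx_tsv(path, c("sample_id", "drug"))
}

#' Write any of the package's tables as TSV
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pgx_table <- function(x, path) write_pgx_tsv(x, path)

#' Write a cohort summary as JSON
#'
#' Nested summaries (the [cohort_report()] output, [run_pipeline()] summary)
#' are serialised as pretty-printed JSON with scalars unboxed and full
#' numeric precision.
#'
#' @param summary a list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: copy-number calling (when Ct data are supplied),
#' diplotype resolution, phenotype translation, per-variant population
#' statistics and the actionability report, logging each stage to stderr and
#' optionally writing per-stage artefact TSVs plus a summary JSON. Identical
#' inputs produce byte-identical summaries (no timestamps are recorded).
#'
#' @param genotypes genotype-call data.frame or path to a genotype TSV.
#' @param ct optional Ct data.frame or path to a Ct TSV; omit for cohorts
#'   without the CYP2D6 CNV channel.
#' @param prescriptions optional prescription data.frame or TSV path.
#' @param calibrator calibrator sample_id in the Ct table.
#' @param defs,rules,map configuration tables.
#' @param alpha nominal significance level for Hardy-Weinberg testing.
#' @param n_tests optional per-gene Bonferroni test counts (see
#'   [variant_stats()]).
#' @param policy duplication policy (see [call_diplotypes()]).
#' @param out_dir optional output directory (created if absent) for artefact
#'   files `copy_numbers.tsv`, `diplotypes.tsv`, `phenotypes.tsv`,
#'   `variant_stats.tsv` and `summary.json`.
#' @return the cohort summary list (invisibly written to `out_dir` if given):
#'   elements `provenance`, `cnv` (class counts and drift flag), `variants`,
#'   `diplotypes`, `phenotypes`, `report`.
#' @export
run_pipeline <- function(genotypes, ct = NULL, prescriptions = NULL,
                         calibrator = "CALIBRATOR",
                         defs = pgx_allele_definitions(),
                         rules = cpic_rules(), map = drug_gene_map(),
                         alpha = 0.05, n_tests = NULL,
                         policy = "highest_activity", out_dir = NULL) {
  if (is.character(genotypes)) genotypes <- read_genotype_table(genotypes, defs)
  if (is.character(ct)) ct <- read_ct_table(ct)
  if (is.character(prescriptions)) {
    prescriptions <- read_prescription_table(prescriptions)
  }

  cn_calls <- NULL
  cnv_block <- NULL
  if (!is.null(ct)) {
    pgx_log("STAGE", "copy-number calling (%d samples)",
            length(unique(ct$sample_id)) - 1L)
    cn_calls <- call_copy_numbers(ct, calibrator = calibrator)
    keep <- cn_calls$sample_id != calibrator
    cnv_block <- list(
      class_counts = as.list(table(cn_calls$cnv_class[keep])),
      qc_counts = as.list(table(cn_calls$qc_status[keep])),
      calibrator_drift = attr(cn_calls, "calibrator_drift"))
  }

  pgx_log("STAGE", "diplotype resolution")
  diplotypes <- call_diplotypes(genotypes, cn_calls = cn_calls,
                                policy = policy, defs = defs)

  pgx_log("STAGE", "phenotype translation")
  phenotypes <- assign_phenotypes(diplotypes, defs)

  pgx_log("STAGE", "population statistics")
  variants <- variant_stats(genotypes, alpha = alpha, n_tests = n_tests)

  pgx_log("STAGE", "actionability report")
  report <- cohort_report(phenotypes, prescriptions = prescriptions,
                          rules = rules, map = map)

  summary <- list(
    provenance = list(package = "pgxcohort",
                      version = as.character(packageVersion("pgxcohort")),
                      alpha = alpha, calibrator = calibrator,
                      policy = if (length(policy) == 1L) policy else "per-sample",
                      n_samples = length(unique(genotypes$sample_id))),
    cnv = cnv_block,
    variants = variants,
    diplotype_counts = lapply(split(diplotypes$diplotype, diplotypes$gene),
                              function(d) as.list(table(d))),
    phenotype_counts = lapply(split(phenotypes$category, phenotypes$gene),
                              function(p) as.list(table(p))),
    report = unclass(report))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cn_calls)) {
      write_pgx_tsv(cn_calls, file.path(out_dir, "copy_numbers.tsv"))
    }
    write_pgx_tsv(diplotypes, file.path(out_dir, "diplotypes.tsv"))
    write_pgx_tsv(phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_pgx_tsv(variants, file.path(out_dir, "variant_stats.tsv"))
    write_cohort_summary(summary, file.path(out_dir, "summary.json"))
    pgx_log("STAGE", "artefacts written to %s", out_dir)
  }
  summary
}
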