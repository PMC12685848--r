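#' Decompose per-rsID variant doses into star-allele haplotype counts
#'
#' Unphased biallelic calls at the panel rsIDs are converted to variant-allele
#' doses (0, 1, 2) and decomposed greedily into star-allele counts by a
#' documented containment hierarchy: alleles with larger tag sets are resolved
#' first, so each *41 consumes one rs28371725 dose and one rs16947 dose (its
#' *2 backbone) and each *4 consumes one rs3892097 and one rs1065852 dose;
#' residual rs16947 doses become *2, residual rs1065852 doses become *10, and
#' remaining haplotype slots default to *1. This codifies the standard
#' PharmVar-guided manual curation of tag-SNP panels; unphased data cannot
#' distinguish cis from trans tag combinations, so conflicts are flagged, not
#' hidden.
#'
#' Flags: any `NOCALL` on a panel rsID flags the sample `ambiguous`; a dose
#' bookkeeping conflict (a consumed tag with insufficient dose, or more than
#' two haplotypes implied) flags it `inconsistent`.
#'
#' @param calls data.frame of one sample's calls for one gene, with columns
#'   `rsid` and `call` (`0/0`, `0/1`, `1/1`, `NOCALL`); panel rsIDs missing
#'   from the table count as `NOCALL`.
#' @param gene gene identifier.
#' @param defs allele definition table ([pgx_allele_definitions()]).
#' @return list with `counts` (named integer vector of haplotype counts
#'   summing to 2 when unflagged) and `flags` (character vector).
#' @export
#' @examples
#' calls <- data.frame(rsid = c("rs16947", "rs28371725"),
#'                     call = c("1/1", "0/1"))
#' resolve_allele_counts(calls, "CYP2D6")  # one *2, one *41
resolve_allele_counts <- function(calls, gene, defs = pgx_allele_definitions()) {
  rsids <- panel_rsids(defs, gene)
  if (length(rsids) == 0L) stop("gene ", gene, " has no panel rsIDs")
  flags <- character(0)

  dose <- setNames(rep(NA_integer_, length(rsids)), rsids)
  if (nrow(calls) > 0L) {
    known <- calls[calls$rsid %in% rsids, ]
    d <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, NOCALL = NA_integer_)
    bad <- !known$call %in% names(d)
    if (any(bad)) stop("malformed call token: ", known$call[bad][1])
    dose[known$rsid] <- d[known$call]
  }
  if (anyNA(dose)) flags <- c(flags, "ambiguous")
  dose[is.na(dose)] <- 0L

  gdefs <- defs[defs$gene == gene & nzchar(defs$tag_rsids), ]
  ntags <- vapply(seq_len(nrow(gdefs)), function(i)
    length(allele_tags(gdefs[i, ])), integer(1))
  gdefs <- gdefs[order(-ntags, gdefs$star), ]

  counts <- integer(0)
  for (i in seq_len(nrow(gdefs))) {
    tags <- allele_tags(gdefs[i, ])
    k <- dose[tags[1]]  # the defining tag
    if (k == 0L) next
    counts[gdefs$star[i]] <- k
    for (t in tags) {
      if (dose[t] < k) flags <- c(flags, "inconsistent")
      dose[t] <- max(0L, dose[t] - k)
    }
  }
  if (any(dose > 0L)) flags <- c(flags, "inconsistent")

  total <- sum(counts)
  if (total > 2L) {
    flags <- c(flags, "inconsistent")
  } else if (total < 2L) {
    default <- defs$star[defs$gene == gene & !nzchar(defs$tag_rsids) &
                           !defs$deletion][1]
    have <- if (default %in% names(counts)) counts[[default]] else 0L
    counts[default] <- have + (2L - total)
  }
  list(counts = counts, flags = unique(flags))
}

#' Call a star-allele diplotype from haplotype counts and a copy-number call
#'
#' Combines the resolved haplotype counts with the integer gene copy number:
#' two copies keep the two resolved haplotypes; one copy sets the second
#' allele to the deletion label (the resolved calls must then look homozygous,
#' since a hemizygote presents as homozygous — two distinct non-deletion
#' haplotypes are flagged `inconsistent`); zero copies give a homozygous
#' deletion; three or more copies annotate one allele with the extra copies.
#'
#' Which allele carries a duplication is undetectable by a single-probe CNV
#' assay. The default policy duplicates the highest-activity resolved allele
#' (ties go to the higher-numbered label); a per-sample override can name the
#' duplicated allele. Every duplication call is flagged `ambiguous` because
#' the assignment is an assumption, never an observation.
#'
#' @param resolved output of [resolve_allele_counts()].
#' @param cn_call optional one-row data.frame/list with `cn_integer` and
#'   `qc_status` for this sample; `NULL` (genes without a CNV channel) fixes
#'   the copy number at 2. A `reject` QC status yields no diplotype, only the
#'   `cnv_rejected` flag.
#' @param policy `"highest_activity"` or a star-allele label naming the
#'   duplicated allele.
#' @inheritParams resolve_allele_counts
#' @return one-row data.frame: `gene`, `allele1`, `allele2`, `copies1`,
#'   `copies2`, `total_cn`, `diplotype` (canonical label), `flags`
#'   (comma-joined).
#' @export
call_diplotype <- function(resolved, cn_call = NULL,
                           policy = "highest_activity", gene,
                           defs = pgx_allele_definitions()) {
  flags <- resolved$flags
  del <- defs$star[defs$gene == gene & defs$deletion]
  del <- if (length(del) > 0L) del[1] else "*5"

  empty <- function(flags) data.frame(
    gene = gene, allele1 = NA_character_, allele2 = NA_character_,
    copies1 = NA_integer_, copies2 = NA_integer_, total_cn = NA_integer_,
    diplotype = NA_character_, flags = join_flags(flags),
    stringsAsFactors = FALSE)

  if (!is.null(cn_call) && cn_call$qc_status == "reject") {
    return(empty(c(flags, "cnv_rejected")))
  }
  cn <- if (is.null(cn_call)) 2L else as.integer(cn_call$cn_integer)

  haps <- rep(names(resolved$counts), resolved$counts)
  if (length(haps) > 2L) haps <- haps[1:2]  # already flagged inconsistent

  if (cn == 0L) {
    a <- c(del, del); cp <- c(0L, 0L)
    flags <- setdiff(flags, "ambiguous")  # the no-calls are explained
  } else if (cn == 1L) {
    if (haps[1] != haps[2]) flags <- c(flags, "inconsistent")
    a <- c(haps[1], del); cp <- c(1L, 0L)
  } else if (cn == 2L) {
    a <- haps; cp <- c(1L, 1L)
  } else {
    extra <- cn - 2L
    rank <- allele_rank(defs, gene, haps)
    if (policy != "highest_activity" && policy %in% haps) {
      dup <- match(policy, haps)
    } else {
      # highest activity, ties toward the higher-numbered label
      dup <- order(-rank$activity, -rank$label_num)[1]
    }
    cp <- c(1L, 1L)
    cp[dup] <- 1L + extra
    a <- haps
    flags <- c(flags, "ambiguous")
  }

  d <- canonical_diplotype(gene, a, cp, defs)
  data.frame(gene = gene, allele1 = d$allele[1], allele2 = d$allele[2],
             copies1 = d$copies[1], copies2 = d$copies[2],
             total_cn = sum(d$copies),
             diplotype = render_diplotype(list(gene = gene, allele = d$allele,
                                               copies = d$copies), defs),
             flags = join_flags(unique(flags)), stringsAsFactors = FALSE)
}

# order the two alleles canonically: activity descending, then label
# ascending, then copies descending (so equal-label diplotypes render
# deterministically, multiplied allele first)
canonical_diplotype <- function(gene, allele, copies, defs) {
  rank <- allele_rank(defs, gene, allele)
  o <- order(-rank$activity, rank$label_num, -copies)
  list(allele = allele[o], copies = as.integer(copies[o]))
}

#' Render a diplotype as its canonical text label
#'
#' Alleles are ordered by activity descending then label ascending; an allele
#' carried in K > 1 copies on one chromosome-equivalent is written `xK`
#' (total gene copies are K plus the partner's copies). The deletion allele
#' (0 copies) is written plain. [parse_diplotype()] is the exact inverse.
#'
#' @param diplotype list with `gene`, `allele` (2 labels), `copies`
#'   (2 integers), or a one-row data.frame with `gene`, `allele1`, `allele2`,
#'   `copies1`, `copies2`.
#' @inheritParams resolve_allele_counts
#' @return character label, e.g. `"*1/*2x3"`.
#' @export
#' @examples
#' render_diplotype(list(gene = "CYP2D6", allele = c("*1", "*2"),
#'                       copies = c(1L, 3L)))
render_diplotype <- function(diplotype, defs = pgx_allele_definitions()) {
  if (is.data.frame(diplotype)) {
    diplotype <- list(gene = diplotype$gene,
                      allele = c(diplotype$allele1, diplotype$allele2),
                      copies = c(diplotype$copies1, diplotype$copies2))
  }
  d <- canonical_diplotype(diplotype$gene, diplotype$allele, diplotype$copies,
                           defs)
  part <- ifelse(d$copies > 1L, paste0(d$allele, "x", d$copies), d$allele)
  paste(part, collapse = "/")
}

#' Parse a canonical diplotype label
#'
#' Exact inverse of [render_diplotype()]. The published `"X >= 3"` notation
#' (`x>=3`, `X ≥ 3`) is accepted and mapped to the minimum consistent
#' copy count K = 3 with an `ambiguous` flag; the `*2A` alias maps to `*2`.
#'
#' @param label diplotype label, e.g. `"*4/*10"` or `"*1/*2x3"`.
#' @param gene gene identifier.
#' @inheritParams resolve_allele_counts
#' @return list with `gene`, `allele`, `copies`, `flags`.
#' @export
parse_diplotype <- function(label, gene, defs = pgx_allele_definitions()) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("not a diplotype label: ", label)
  flags <- character(0)
  one <- function(p) {
    p <- gsub(" ", "", p)
    m <- regmatches(p, regexec("^(\\*[0-9]+[A-Za-z]*)(?:[xX](≥|>=)?([0-9]+))?$",
                               p))[[1]]
    if (length(m) == 0L) stop("cannot parse allele: ", p)
    star <- canonical_star(m[2])
    atleast <- nzchar(m[3])
    k <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    if (atleast) flags <<- c(flags, "ambiguous")
    known <- defs$star[defs$gene == gene]
    if (!star %in% known) stop("unknown allele for ", gene, ": ", star)
    if (defs$deletion[defs$gene == gene & defs$star == star]) k <- 0L
    list(star = star, copies = k)
  }
  a <- lapply(parts, one)
  d <- canonical_diplotype(gene, vapply(a, `[[`, "", "star"),
                           vapply(a, `[[`, 1L, "copies"), defs)
  list(gene = gene, allele = d$allele, copies = d$copies, flags = unique(flags))
}

#' Call diplotypes for a whole genotype table
#'
#' Runs [resolve_allele_counts()] and [call_diplotype()] per sample and gene.
#' Copy-number calls (when supplied) apply to the gene with the CNV channel
#' (CYP2D6); genes without one have copy counts fixed at 1 per allele. Samples
#' whose copy-number call was rejected by QC are emitted with the
#' `cnv_rejected` flag and no diplotype, and never contribute downstream.
#'
#' @param genotypes genotype-call table (`sample_id`, `gene`, `rsid`, `call`).
#' @param cn_calls optional output of [call_copy_numbers()].
#' @param cnv_gene gene the copy-number calls refer to.
#' @param policy duplication policy (see [call_diplotype()]); either a single
#'   value or a named character vector of per-sample overrides.
#' @inheritParams resolve_allele_counts
#' @return data.frame with one row per sample and gene: `sample_id`, `gene`,
#'   `allele1`, `allele2`, `copies1`, `copies2`, `total_cn`, `diplotype`,
#'   `flags`.
#' @export
call_diplotypes <- function(genotypes, cn_calls = NULL, cnv_gene = "CYP2D6",
                            policy = "highest_activity",
                            defs = pgx_allele_definitions()) {
  stopifnot(all(c("sample_id", "gene", "rsid", "call") %in% names(genotypes)))
  combos <- unique(genotypes[, c("sample_id", "gene")])
  combos <- combos[order(combos$gene, combos$sample_id), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    id <- combos$sample_id[i]
    g <- combos$gene[i]
    calls <- genotypes[genotypes$sample_id == id & genotypes$gene == g,
                       c("rsid", "call")]
    resolved <- resolve_allele_counts(calls, g, defs)
    cn_call <- NULL
    if (!is.null(cn_calls) && g == cnv_gene) {
      j <- match(id, cn_calls$sample_id)
      if (is.na(j)) stop("no copy-number call for sample ", id)
      cn_call <- cn_calls[j, ]
    }
    pol <- if (length(policy) > 1L || !is.null(names(policy))) {
      policy[id] %||% "highest_activity"
    } else policy
    if (is.na(pol)) pol <- "highest_activity"
    cbind(data.frame(sample_id = id, stringsAsFactors = FALSE),
          call_diplotype(resolved, cn_call, policy = pol, gene = g,
                         defs = defs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
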