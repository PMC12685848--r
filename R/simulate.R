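#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of the truth-known cohort simulator.
#' Defaults emulate the study conditions the package targets: a cohort of 509
#' diploid individuals drawn under Hardy-Weinberg random mating from the
#' published star-allele frequencies, with CYP2D6 whole-gene deletion (*5)
#' carried at 4.2% and duplications at 4.1% haplotype frequency, modest
#' genotyping no-call/error rates and Gaussian Ct noise.
#'
#' Substructure: `demes` is a list of sub-populations, each a
#' `list(weight = w, gene_panels = <per-gene frequency vector>)`. Individuals
#' are assigned to demes by weight and their two haplotypes are drawn i.i.d.
#' from the deme's frequency vector (random union of gametes, i.e. HWE within
#' demes). Pooling divergent demes produces the heterozygote deficit of the
#' Wahlund effect. The default is a single deme built from `gene_panels`.
#'
#' @param cohort_size number of individuals.
#' @param gene_panels named list (per gene) of named haplotype frequency
#'   vectors summing to 1. Haplotype frequencies — not per-SNP minor allele
#'   frequencies — are the generative unit; per-rsID frequencies arise
#'   downstream as observables.
#' @param demes optional list of demes as described above; default one deme
#'   with `gene_panels`. Weights must be non-negative and sum to 1; every deme
#'   must define the same genes.
#' @param duplication_rate named per-gene probability that a (non-deleted)
#'   haplotype carries extra gene copies. Deletion and duplication are treated
#'   as mutually exclusive within an individual: a duplication opposite a
#'   deleted allele is copy-number neutral and undetectable by a single-probe
#'   assay, so the generator excludes it.
#' @param duplication_copies integer vector of possible copy counts for a
#'   duplicated haplotype (sampled uniformly); default `c(2L, 3L)` so total
#'   gene copy number reaches 3 or 4.
#' @param nocall_rate probability a genotype call is replaced by `NOCALL`.
#' @param genotype_error_rate probability of a symmetric single-allele flip.
#' @param ct_noise_sd Gaussian noise sd (cycles) added to every Ct value.
#' @param calibrator_ct_target,calibrator_ct_reference noise-free Ct (cycles)
#'   of the calibrator sample on the target and reference assays.
#' @param replicates_per_sample qPCR replicates per sample and assay.
#' @param seed global integer seed; all randomness is derived from it via
#'   [split_seed()].
#' @return a validated list of class `pgx_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(cohort_size = 50, seed = 7)
#' str(cfg$gene_panels)
simulation_config <- function(cohort_size = 509L,
                              gene_panels = list(
                                CYP2D6 = c("*1" = 0.089, "*2" = 0.300,
                                           "*3" = 0.057, "*4" = 0.104,
                                           "*5" = 0.042, "*6" = 0.019,
                                           "*10" = 0.216, "*41" = 0.173),
                                CYP2C19 = c("*1" = 0.443, "*2" = 0.373,
                                            "*3" = 0.023, "*17" = 0.161)),
                              demes = NULL,
                              duplication_rate = c(CYP2D6 = 0.041, CYP2C19 = 0),
                              duplication_copies = c(2L, 3L),
                              nocall_rate = 0.01,
                              genotype_error_rate = 0.005,
                              ct_noise_sd = 0.1,
                              calibrator_ct_target = 26,
                              calibrator_ct_reference = 25,
                              replicates_per_sample = 3L,
                              seed = 1L) {
  stopifnot(cohort_size >= 1, replicates_per_sample >= 1, ct_noise_sd >= 0,
            nocall_rate >= 0, nocall_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            all(duplication_copies >= 2))
  if (is.null(demes)) demes <- list(list(weight = 1, gene_panels = gene_panels))
  w <- vapply(demes, function(d) d$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("deme weights must be non-negative and sum to 1")
  }
  genes <- names(demes[[1]]$gene_panels)
  for (d in demes) {
    if (!identical(sort(names(d$gene_panels)), sort(genes))) {
      stop("all demes must define the same genes")
    }
    for (g in genes) {
      f <- d$gene_panels[[g]]
      if (is.null(names(f)) || any(!nzchar(names(f)))) {
        stop("frequency vectors must be named by allele label")
      }
      if (length(f) == 0L) stop("empty frequency vector for ", g)
      if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
        stop("frequencies for ", g, " must be non-negative and sum to 1")
      }
    }
  }
  cfg <- list(cohort_size = as.integer(cohort_size),
              gene_panels = demes[[1]]$gene_panels,
              genes = genes,
              demes = demes,
              duplication_rate = duplication_rate,
              duplication_copies = as.integer(duplication_copies),
              nocall_rate = nocall_rate,
              genotype_error_rate = genotype_error_rate,
              ct_noise_sd = ct_noise_sd,
              calibrator_ct_target = calibrator_ct_target,
              calibrator_ct_reference = calibrator_ct_reference,
              replicates_per_sample = as.integer(replicates_per_sample),
              seed = as.integer(seed))
  class(cfg) <- "pgx_sim_config"
  cfg
}

# deme assignment is drawn once per cohort so it is shared across genes
sample_demes <- function(config) {
  set.seed(split_seed(config$seed, "demes"))
  if (length(config$demes) == 1L) {
    rep(1L, config$cohort_size)
  } else {
    w <- vapply(config$demes, function(d) d$weight, numeric(1))
    sample.int(length(config$demes), config$cohort_size, replace = TRUE,
               prob = w)
  }
}

#' Sample true star-allele diplotypes for one gene
#'
#' Draws each individual's two haplotypes i.i.d. from its deme's frequency
#' vector (HWE random union of gametes within demes), then assigns per-allele
#' copy counts: deletion alleles contribute 0 copies, duplicated haplotypes
#' carry 2 or more. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param gene gene identifier present in the configured panels.
#' @param demes optional integer deme assignment per individual; drawn from
#'   the configured weights (deterministically, shared across genes) if
#'   omitted.
#' @param defs allele definitions; used to identify deletion alleles.
#' @return data.frame with columns `sample_id`, `gene`, `allele1`, `allele2`,
#'   `copies1`, `copies2`, `deme`. Total gene copy number is
#'   `copies1 + copies2`, between 0 and 6.
#' @export
#' @examples
#' cfg <- simulation_config(cohort_size = 5, seed = 1)
#' sample_diplotypes(cfg, "CYP2C19")
sample_diplotypes <- function(config, gene, demes = NULL,
                              defs = pgx_allele_definitions()) {
  stopifnot(inherits(config, "pgx_sim_config"))
  if (!gene %in% config$genes) stop("unknown gene: ", gene)
  n <- config$cohort_size
  demes <- demes %||% sample_demes(config)
  stopifnot(length(demes) == n)

  set.seed(split_seed(config$seed, paste0("diplotypes:", gene)))
  a1 <- character(n)
  a2 <- character(n)
  for (d in seq_along(config$demes)) {
    sel <- which(demes == d)
    if (length(sel) == 0L) next
    freq <- config$demes[[d]]$gene_panels[[gene]]
    draws <- sample(names(freq), 2L * length(sel), replace = TRUE, prob = freq)
    a1[sel] <- draws[seq_along(sel)]
    a2[sel] <- draws[length(sel) + seq_along(sel)]
  }

  del_labels <- defs$star[defs$gene == gene & defs$deletion]
  c1 <- ifelse(a1 %in% del_labels, 0L, 1L)
  c2 <- ifelse(a2 %in% del_labels, 0L, 1L)
  dup_rate <- unname(config$duplication_rate[gene])
  if (!is.na(dup_rate) && length(dup_rate) == 1L && dup_rate > 0) {
    # a haplotype can be duplicated only if neither allele is deleted
    eligible <- c1 == 1L & c2 == 1L
    dup1 <- eligible & runif(n) < dup_rate
    dup2 <- eligible & runif(n) < dup_rate
    if (any(dup1)) c1[dup1] <- sample(config$duplication_copies, sum(dup1),
                                      replace = TRUE)
    if (any(dup2)) c2[dup2] <- sample(config$duplication_copies, sum(dup2),
                                      replace = TRUE)
  }

  data.frame(sample_id = sprintf("S%05d", seq_len(n)),
             gene = gene, allele1 = a1, allele2 = a2,
             copies1 = as.integer(c1), copies2 = as.integer(c2),
             deme = as.integer(demes), stringsAsFactors = FALSE)
}

#' Emit a tag-SNP genotype-call table from simulated truth
#'
#' Converts true diplotypes into the biallelic calls a cluster-calling
#' genotyping assay would report at each panel rsID: a haplotype contributes
#' its tag variants (a *41 haplotype sets both rs28371725 and rs16947), a
#' deleted allele emits no SNP signal (a hemizygote therefore presents as
#' homozygous, a homozygous deletion as `NOCALL`), and copy multiplication
#' does not change the categorical call. No-calls and symmetric single-allele
#' flip errors are injected at the configured rates. Deterministic given
#' `config$seed`.
#'
#' @inheritParams sample_diplotypes
#' @param truth data.frame as returned by [sample_diplotypes()] (one or more
#'   genes row-bound).
#' @return data.frame with columns `sample_id`, `gene`, `rsid`,
#'   `call` in `0/0`, `0/1`, `1/1`, `NOCALL`.
#' @export
emit_genotype_table <- function(truth, config, defs = pgx_allele_definitions()) {
  stopifnot(inherits(config, "pgx_sim_config"))
  key <- paste(defs$gene, defs$star)
  unknown <- setdiff(unique(paste(truth$gene, c(truth$allele1, truth$allele2))),
                     key)
  if (length(unknown) > 0L) {
    stop("truth contains alleles without a definition: ",
         paste(unknown, collapse = ", "))
  }

  out <- vector("list", length(unique(truth$gene)))
  for (gi in seq_along(unique(truth$gene))) {
    g <- unique(truth$gene)[gi]
    rsids <- panel_rsids(defs, g)
    if (length(rsids) == 0L) next
    tr <- truth[truth$gene == g, ]
    gdefs <- defs[defs$gene == g, ]
    # star label -> logical vector over panel rsIDs ("does this hap carry it")
    tagmat <- vapply(rsids, function(r)
      vapply(seq_len(nrow(gdefs)), function(i) r %in% allele_tags(gdefs[i, ]),
             logical(1)), logical(nrow(gdefs)))
    if (is.null(dim(tagmat))) tagmat <- matrix(tagmat, nrow = nrow(gdefs))
    rownames(tagmat) <- gdefs$star
    colnames(tagmat) <- rsids

    h1 <- tr$copies1 >= 1L
    h2 <- tr$copies2 >= 1L
    calls <- matrix("", nrow = nrow(tr), ncol = length(rsids))
    for (j in seq_along(rsids)) {
      v1 <- tagmat[tr$allele1, j] & h1
      v2 <- tagmat[tr$allele2, j] & h2
      dose <- as.integer(v1) + as.integer(v2)
      call <- c("0/0", "0/1", "1/1")[dose + 1L]
      # homozygous deletion: no template, no call; hemizygote presents as
      # homozygous for the surviving haplotype
      call[!h1 & !h2] <- "NOCALL"
      call[xor(h1, h2)] <- ifelse((v1 | v2)[xor(h1, h2)], "1/1", "0/0")
      calls[, j] <- call
    }
    out[[gi]] <- data.frame(
      sample_id = rep(tr$sample_id, times = length(rsids)),
      gene = g,
      rsid = rep(rsids, each = nrow(tr)),
      call = as.vector(calls), stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, out)
  rownames(gt) <- NULL

  set.seed(split_seed(config$seed, "genotype_noise"))
  callable <- gt$call != "NOCALL"
  drop <- callable & runif(nrow(gt)) < config$nocall_rate
  gt$call[drop] <- "NOCALL"
  callable <- gt$call != "NOCALL"
  flip <- callable & runif(nrow(gt)) < config$genotype_error_rate
  if (any(flip)) {
    cur <- gt$call[flip]
    new <- cur
    new[cur == "0/0"] <- "0/1"
    new[cur == "1/1"] <- "0/1"
    het <- cur == "0/1"
    if (any(het)) new[het] <- sample(c("0/0", "1/1"), sum(het), replace = TRUE)
    gt$call[flip] <- new
  }
  gt
}

#' Simulate a qPCR Ct plate for the copy-number assay
#'
#' Generative inverse of the comparative delta-delta-Ct caller: per sample and
#' replicate the target-assay Ct is
#' `calibrator_ct_target - log2(CN/2) + N(0, ct_noise_sd)` and the
#' reference-assay Ct is `calibrator_ct_reference + N(0, ct_noise_sd)`. The
#' calibrator sample is emitted with a true copy number of 2; samples with
#' zero copies produce the no-amplification sentinel (`NA`) on the target
#' assay. Deterministic given `config$seed`.
#'
#' @inheritParams emit_genotype_table
#' @param gene gene with the CNV channel (default `"CYP2D6"`); must be present
#'   in `truth`.
#' @param calibrator_id sample identifier for the emitted calibrator rows.
#' @return data.frame with columns `sample_id`, `assay`
#'   (`CYP2D6_ex9`/`RNaseP`), `replicate`, `ct` (`NA` = no amplification).
#' @export
simulate_ct_plate <- function(truth, config, gene = "CYP2D6",
                              calibrator_id = "CALIBRATOR") {
  stopifnot(inherits(config, "pgx_sim_config"))
  tr <- truth[truth$gene == gene, ]
  if (nrow(tr) == 0L) stop("truth contains no rows for gene ", gene)
  cn <- tr$copies1 + tr$copies2
  ids <- c(tr$sample_id, calibrator_id)
  cn <- c(cn, 2L)

  set.seed(split_seed(config$seed, "ct"))
  reps <- config$replicates_per_sample
  n <- length(ids)
  target_mu <- ifelse(cn == 0L, NA_real_,
                      config$calibrator_ct_target - log2(cn / 2))
  plate <- data.frame(
    sample_id = rep(ids, each = 2L * reps),
    assay = rep(rep(c("CYP2D6_ex9", "RNaseP"), each = reps), times = n),
    replicate = rep(seq_len(reps), times = 2L * n),
    stringsAsFactors = FALSE)
  mu <- as.vector(vapply(seq_len(n), function(i)
    c(rep(target_mu[i], reps), rep(config$calibrator_ct_reference, reps)),
    numeric(2L * reps)))
  noise <- rnorm(length(mu), 0, config$ct_noise_sd)
  plate$ct <- mu + ifelse(is.na(mu), 0, noise)
  plate$ct[is.na(mu)] <- NA_real_
  plate
}

#' Simulate a complete truth-known cohort
#'
#' Draws deme assignments once, samples true diplotypes for every configured
#' gene, and emits the genotype-call table plus (when a CYP2D6 panel is
#' configured) the copy-number Ct plate. The returned truth channel enables
#' exact recovery tests of every downstream stage.
#'
#' @inheritParams sample_diplotypes
#' @param calibrator_id sample identifier for the Ct plate calibrator.
#' @return list with elements `truth`, `genotypes`, `ct` (or `NULL`), `demes`
#'   and the `config` used.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(cohort_size = 20, seed = 3))
#' head(cohort$truth)
simulate_cohort <- function(config = simulation_config(),
                            defs = pgx_allele_definitions(),
                            calibrator_id = "CALIBRATOR") {
  demes <- sample_demes(config)
  truth <- do.call(rbind, lapply(config$genes, function(g)
    sample_diplotypes(config, g, demes = demes, defs = defs)))
  genotypes <- emit_genotype_table(truth, config, defs = defs)
  ct <- NULL
  if ("CYP2D6" %in% config$genes) {
    ct <- simulate_ct_plate(truth, config, gene = "CYP2D6",
                            calibrator_id = calibrator_id)
  }
  list(truth = truth, genotypes = genotypes, ct = ct, demes = demes,
       config = config)
}
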