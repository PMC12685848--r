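defs <- pgx_allele_definitions()

one_gene_config <- function(freq, n, seed = 1, ...) {
  simulation_config(cohort_size = n, gene_panels = list(CYP2D6 = freq),
                    duplication_rate = c(CYP2D6 = 0), seed = seed, ...)
}

test_that("a degenerate frequency vector yields only wild-type homozygotes", {
  cfg <- one_gene_config(c("*1" = 1), 10)
  tr <- sample_diplotypes(cfg, "CYP2D6")
  expect_equal(nrow(tr), 10L)
  expect_true(all(tr$allele1 == "*1" & tr$allele2 == "*1"))
  expect_true(all(tr$copies1 == 1L & tr$copies2 == 1L))
})

test_that("single-deme sampling is Hardy-Weinberg: heterozygosity matches 2pq", {
  cfg <- one_gene_config(c("*1" = 0.5, "*4" = 0.5), 10000, seed = 4)
  tr <- sample_diplotypes(cfg, "CYP2D6")
  het <- mean(tr$allele1 != tr$allele2)
  expect_lt(abs(het - 0.5), 0.02)
})

test_that("pooling divergent demes produces the Wahlund heterozygote deficit", {
  p1 <- list(CYP2D6 = c("*1" = 0.9, "*4" = 0.1))
  p2 <- list(CYP2D6 = c("*1" = 0.1, "*4" = 0.9))
  cfg <- simulation_config(cohort_size = 10000, gene_panels = p1,
                           demes = list(list(weight = 0.5, gene_panels = p1),
                                        list(weight = 0.5, gene_panels = p2)),
                           duplication_rate = c(CYP2D6 = 0), seed = 11)
  tr <- sample_diplotypes(cfg, "CYP2D6")
  het <- mean(tr$allele1 != tr$allele2)
  # expected heterozygosity 2 * 0.9 * 0.1 = 0.18 vs 0.5 under pooled HWE
  expect_lt(abs(het - 0.18), 0.02)
  f <- inbreeding_coefficient(sum(tr$allele1 == "*1" & tr$allele2 == "*1"),
                              sum(tr$allele1 != tr$allele2),
                              sum(tr$allele1 == "*4" & tr$allele2 == "*4"))
  # Wahlund F = Var(p) / (p_bar * q_bar) = 0.16 / 0.25 = 0.64
  expect_lt(abs(f - 0.64), 0.05)
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- simulation_config(cohort_size = 40, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$ct, b$ct)
  c2 <- simulate_cohort(simulation_config(cohort_size = 40, seed = 124))
  expect_false(identical(a$truth, c2$truth))
})

test_that("config validation rejects malformed frequency vectors and weights", {
  expect_error(one_gene_config(c("*1" = 0.6, "*4" = 0.5), 10), "sum to 1")
  expect_error(one_gene_config(c("*1" = 1.2, "*4" = -0.2), 10), "non-negative")
  p <- list(CYP2D6 = c("*1" = 1))
  expect_error(simulation_config(demes = list(list(weight = 0.6, gene_panels = p),
                                              list(weight = 0.6, gene_panels = p))),
               "weights")
  expect_error(sample_diplotypes(simulation_config(cohort_size = 5), "CYP3A4"),
               "unknown gene")
})

noise_free <- function(n = 1, seed = 1) {
  simulation_config(cohort_size = n, nocall_rate = 0, genotype_error_rate = 0,
                    ct_noise_sd = 0, seed = seed)
}

test_that("genotype emission reflects haplotype tag composition", {
  cfg <- noise_free()
  gt <- function(truth) {
    g <- emit_genotype_table(truth, cfg, defs)
    setNames(g$call, g$rsid)
  }
  wt <- gt(truth_row("a", "CYP2D6", "*1", "*1"))
  expect_true(all(wt == "0/0"))

  g241 <- gt(truth_row("a", "CYP2D6", "*2", "*41"))
  expect_equal(unname(g241["rs16947"]), "1/1")     # *41 carries the *2 backbone
  expect_equal(unname(g241["rs28371725"]), "0/1")
  expect_equal(unname(g241["rs3892097"]), "0/0")

  # hemizygote presents as homozygous; homozygous deletion has no template
  g45 <- gt(truth_row("a", "CYP2D6", "*4", "*5", 1L, 0L))
  expect_equal(unname(g45["rs3892097"]), "1/1")
  expect_equal(unname(g45["rs1065852"]), "1/1")
  expect_equal(unname(g45["rs16947"]), "0/0")
  g55 <- gt(truth_row("a", "CYP2D6", "*5", "*5", 0L, 0L))
  expect_true(all(g55 == "NOCALL"))

  expect_error(emit_genotype_table(truth_row("a", "CYP2D6", "*99", "*1"), cfg),
               "without a definition")
})

test_that("nocall_rate 1 blanks every call", {
  cfg <- simulation_config(cohort_size = 5, nocall_rate = 1, seed = 2)
  co <- simulate_cohort(cfg)
  expect_true(all(co$genotypes$call == "NOCALL"))
})

test_that("noise-free Ct plates encode copy number as -log2(CN/2) cycles", {
  cfg <- noise_free()
  truth <- rbind(truth_row("cn1", "CYP2D6", "*1", "*5", 1L, 0L),
                 truth_row("cn2", "CYP2D6", "*1", "*1", 1L, 1L),
                 truth_row("cn4", "CYP2D6", "*1", "*1", 3L, 1L),
                 truth_row("cn0", "CYP2D6", "*5", "*5", 0L, 0L))
  plate <- simulate_ct_plate(truth, cfg)
  tgt <- plate[plate$assay == "CYP2D6_ex9", ]
  ct_of <- function(id) unique(tgt$ct[tgt$sample_id == id])
  cal <- cfg$calibrator_ct_target
  expect_equal(ct_of("cn1"), cal + 1)
  expect_equal(ct_of("cn2"), cal)
  expect_equal(ct_of("cn4"), cal - 1)
  expect_true(all(is.na(ct_of("cn0"))))
  expect_equal(ct_of("CALIBRATOR"), cal)
  expect_equal(sum(plate$sample_id == "cn2"), 2L * cfg$replicates_per_sample)
  expect_true(all(plate$ct[plate$assay == "RNaseP"] ==
                    cfg$calibrator_ct_reference))
})

test_that("estimated allele frequencies are calibrated against the truth", {
  p <- 0.373
  n <- 120
  se <- sqrt(p * (1 - p) / (2 * n))
  cover <- vapply(1:200, function(s) {
    cfg <- simulation_config(cohort_size = n,
                             gene_panels = list(
                               CYP2C19 = c("*1" = 1 - p, "*2" = p)),
                             duplication_rate = c(CYP2C19 = 0), seed = s)
    tr <- sample_diplotypes(cfg, "CYP2C19")
    phat <- mean(c(tr$allele1, tr$allele2) == "*2")
    abs(phat - p) <= 1.96 * se
  }, logical(1))
  expect_gt(mean(cover), 0.89)
  expect_lte(mean(cover), 1)
})

test_that("exact-test rejection of substructure grows with deme divergence", {
  reject_rate <- function(p1, p2, seeds = 1:60) {
    d1 <- list(CYP2D6 = c("*1" = 1 - p1, "*4" = p1))
    d2 <- list(CYP2D6 = c("*1" = 1 - p2, "*4" = p2))
    mean(vapply(seeds, function(s) {
      cfg <- simulation_config(cohort_size = 200, gene_panels = d1,
                               demes = list(list(weight = 0.5, gene_panels = d1),
                                            list(weight = 0.5, gene_panels = d2)),
                               duplication_rate = c(CYP2D6 = 0), seed = s)
      tr <- sample_diplotypes(cfg, "CYP2D6")
      p <- hwe_exact(sum(tr$allele1 == "*1" & tr$allele2 == "*1"),
                     sum(tr$allele1 != tr$allele2),
                     sum(tr$allele1 == "*4" & tr$allele2 == "*4"))
      p < 0.05
    }, logical(1)))
  }
  r0 <- reject_rate(0.5, 0.5)    # no divergence: nominal level
  r1 <- reject_rate(0.4, 0.6)
  r2 <- reject_rate(0.25, 0.75)
  r3 <- reject_rate(0.1, 0.9)
  expect_lt(r0, 0.12)
  expect_true(r1 <= r2 && r2 <= r3)
  expect_gt(r3, 0.95)
})
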