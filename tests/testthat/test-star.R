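defs <- pgx_allele_definitions()

calls_df <- function(...) {
  x <- c(...)
  data.frame(rsid = names(x), call = unname(x), stringsAsFactors = FALSE)
}

test_that("tag-dose decomposition follows the containment hierarchy", {
  # rs16947 hom + rs28371725 het: one dose is the *41 backbone, one is *2
  r <- resolve_allele_counts(calls_df(rs16947 = "1/1", rs28371725 = "0/1",
                                      rs35742686 = "0/0", rs3892097 = "0/0",
                                      rs5030655 = "0/0", rs1065852 = "0/0"),
                             "CYP2D6", defs)
  expect_equal(r$counts[["*2"]], 1L)
  expect_equal(r$counts[["*41"]], 1L)
  expect_length(r$flags, 0)

  # rs3892097 het consumes one rs1065852 dose; the residual dose is *10
  r <- resolve_allele_counts(calls_df(rs16947 = "0/0", rs28371725 = "0/0",
                                      rs35742686 = "0/0", rs3892097 = "0/1",
                                      rs5030655 = "0/0", rs1065852 = "1/1"),
                             "CYP2D6", defs)
  expect_equal(r$counts[["*4"]], 1L)
  expect_equal(r$counts[["*10"]], 1L)

  r <- resolve_allele_counts(calls_df(rs16947 = "0/0", rs28371725 = "0/0",
                                      rs35742686 = "0/0", rs3892097 = "0/0",
                                      rs5030655 = "0/0", rs1065852 = "0/0"),
                             "CYP2D6", defs)
  expect_equal(r$counts[["*1"]], 2L)
})

test_that("every allele pair is identifiable from its emitted tag pattern", {
  cfg <- simulation_config(cohort_size = 1, nocall_rate = 0,
                           genotype_error_rate = 0, seed = 1)
  stars <- setdiff(defs$star[defs$gene == "CYP2D6" & !defs$deletion], character(0))
  pairs <- expand.grid(a = stars, b = stars, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    truth <- truth_row("s", "CYP2D6", pairs$a[i], pairs$b[i])
    gt <- emit_genotype_table(truth, cfg, defs)
    r <- resolve_allele_counts(gt[, c("rsid", "call")], "CYP2D6", defs)
    want <- table(c(pairs$a[i], pairs$b[i]))
    expect_length(r$flags, 0)
    expect_equal(sum(r$counts), 2L)
    for (s in names(want)) expect_equal(r$counts[[s]], unname(want[[s]]))
  }
})

test_that("no-calls flag ambiguity and dose conflicts flag inconsistency", {
  r <- resolve_allele_counts(calls_df(rs16947 = "NOCALL"), "CYP2D6", defs)
  expect_true("ambiguous" %in% r$flags)
  # missing panel rows count as NOCALL too
  expect_true("ambiguous" %in%
                resolve_allele_counts(calls_df(rs16947 = "0/0"),
                                      "CYP2D6", defs)$flags)
  # a *41 tag without its *2 backbone cannot come from two clean haplotypes
  r <- resolve_allele_counts(calls_df(rs16947 = "0/0", rs28371725 = "0/1",
                                      rs35742686 = "0/0", rs3892097 = "0/0",
                                      rs5030655 = "0/0", rs1065852 = "0/0"),
                             "CYP2D6", defs)
  expect_true("inconsistent" %in% r$flags)
  expect_error(resolve_allele_counts(calls_df(rs16947 = "2/1"), "CYP2D6", defs),
               "malformed")
})

test_that("copy number disambiguates hemizygotes and assigns duplications", {
  res <- function(...) resolve_allele_counts(calls_df(...), "CYP2D6", defs)
  full <- function(a, b, d6 = "0/0", d10 = "0/0")
    res(rs16947 = a, rs28371725 = b, rs35742686 = "0/0", rs3892097 = d6,
        rs5030655 = "0/0", rs1065852 = d10)
  cn <- function(k, qc = "high_confidence") list(cn_integer = k, qc_status = qc)

  d <- call_diplotype(full("0/0", "0/0"), cn(2L), gene = "CYP2D6", defs = defs)
  expect_equal(d$diplotype, "*1/*1")

  # cn = 3 with *2 + *41 resolved: extra copy goes to the higher activity *2
  d <- call_diplotype(full("1/1", "0/1"), cn(3L), gene = "CYP2D6", defs = defs)
  expect_equal(d$diplotype, "*2x2/*41")
  expect_equal(d$total_cn, 3L)
  expect_true(has_flag(d$flags, "ambiguous"))

  # per-sample policy override
  d <- call_diplotype(full("1/1", "0/1"), cn(3L), policy = "*41",
                      gene = "CYP2D6", defs = defs)
  expect_equal(d$diplotype, "*2/*41x2")

  # hemizygous *4 presents as homozygous; CN = 1 resolves it over a deletion
  d <- call_diplotype(full("0/0", "0/0", d6 = "1/1", d10 = "1/1"), cn(1L),
                      gene = "CYP2D6", defs = defs)
  expect_equal(d$diplotype, "*4/*5")
  expect_equal(d$total_cn, 1L)

  # CN = 1 with two distinct non-deletion haplotypes is impossible
  d <- call_diplotype(full("0/1", "0/0"), cn(1L), gene = "CYP2D6", defs = defs)
  expect_true(has_flag(d$flags, "inconsistent"))

  d <- call_diplotype(full("0/0", "0/0"), cn(0L), gene = "CYP2D6", defs = defs)
  expect_equal(d$diplotype, "*5/*5")
  expect_equal(d$total_cn, 0L)

  # rejected CNV: no diplotype, only the flag
  d <- call_diplotype(full("0/0", "0/0"), cn(2L, "reject"),
                      gene = "CYP2D6", defs = defs)
  expect_true(is.na(d$diplotype))
  expect_true(has_flag(d$flags, "cnv_rejected"))
})

test_that("rendering is canonical and parsing is its exact inverse", {
  expect_equal(render_diplotype(list(gene = "CYP2D6", allele = c("*1", "*2"),
                                     copies = c(1L, 3L)), defs), "*1/*2x3")
  expect_equal(render_diplotype(list(gene = "CYP2D6", allele = c("*5", "*5"),
                                     copies = c(0L, 0L)), defs), "*5/*5")
  # activity-descending order: *2 (normal) precedes *41 (decreased)
  expect_equal(render_diplotype(list(gene = "CYP2D6", allele = c("*41", "*2"),
                                     copies = c(1L, 1L)), defs), "*2/*41")

  stars <- defs$star[defs$gene == "CYP2D6"]
  for (a in stars) for (b in stars) for (k in 1:3) {
    ca <- if (a == "*5") 0L else k
    cb <- if (b == "*5") 0L else 1L
    d <- list(gene = "CYP2D6", allele = c(a, b), copies = c(ca, cb))
    p <- parse_diplotype(render_diplotype(d, defs), "CYP2D6", defs)
    canon <- pgxcohort:::canonical_diplotype("CYP2D6", d$allele, d$copies, defs)
    expect_equal(p$allele, canon$allele)
    expect_equal(p$copies, canon$copies)
  }
})

test_that("published 'X >= 3' notation parses to 3 copies with a flag", {
  p <- parse_diplotype("*2X ≥ 3/*1", "CYP2D6", defs)
  expect_equal(sort(p$allele), c("*1", "*2"))
  expect_equal(max(p$copies), 3L)
  expect_true("ambiguous" %in% p$flags)
  p2 <- parse_diplotype("*1/*2x>=3", "CYP2D6", defs)
  expect_equal(max(p2$copies), 3L)
  # *2A is an alias of *2
  expect_equal(parse_diplotype("*2A/*1", "CYP2D6", defs)$allele[2], "*2")
  expect_error(parse_diplotype("*9/*1", "CYP2D6", defs), "unknown allele")
})

test_that("whole-table calling covers both genes and fixes CYP2C19 at 2 copies", {
  cfg <- simulation_config(cohort_size = 30, nocall_rate = 0,
                           genotype_error_rate = 0, ct_noise_sd = 0, seed = 5)
  co <- simulate_cohort(cfg)
  cn <- suppressMessages(call_copy_numbers(co$ct))
  d <- call_diplotypes(co$genotypes, cn_calls = cn)
  c19 <- d[d$gene == "CYP2C19", ]
  expect_true(all(c19$total_cn == 2L))
  expect_true(all(c19$copies1 == 1L & c19$copies2 == 1L))
  lab <- truth_label(co$truth)
  m <- match(paste(d$sample_id, d$gene),
             paste(co$truth$sample_id, co$truth$gene))
  pol <- policy_concordant(co$truth)[m]
  expect_true(all(d$diplotype[pol] == lab[m][pol]))
})
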