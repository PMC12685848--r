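ct_rows <- function(id, target, reference) {
  data.frame(sample_id = id,
             assay = rep(c("CYP2D6_ex9", "RNaseP"),
                         c(length(target), length(reference))),
             replicate = c(seq_along(target), seq_along(reference)),
             ct = c(target, reference), stringsAsFactors = FALSE)
}

test_that("replicate aggregation pairs delta-Ct by replicate index", {
  agg <- aggregate_replicates(ct_rows("a", c(26, 26), c(25, 25)))
  expect_equal(agg$delta_ct_mean, 1)
  expect_equal(agg$delta_ct_sd, 0)

  agg <- aggregate_replicates(ct_rows("a", c(25.9, 26.1), c(25, 25)))
  expect_equal(agg$delta_ct_mean, 1)
  expect_equal(agg$delta_ct_sd, sd(c(0.9, 1.1)), tolerance = 1e-12)

  agg <- aggregate_replicates(ct_rows("a", 27, 25))
  expect_equal(agg$delta_ct_mean, 2)
  expect_equal(agg$delta_ct_sd, 0)
  expect_true(agg$low_replicate)
})

test_that("aggregation validates assays and replicate pairing", {
  m <- ct_rows("a", c(26, 26), c(25, 25))
  expect_error(aggregate_replicates(m[m$assay == "CYP2D6_ex9", ]), "reference")
  bad <- m
  bad$replicate[bad$assay == "RNaseP"] <- c(1, 3)
  expect_error(aggregate_replicates(bad), "pair up")
  bad2 <- m
  bad2$assay[1] <- "EX9"
  expect_error(aggregate_replicates(bad2), "unknown assay")
  bad3 <- m
  bad3$ct[1] <- -1
  expect_error(aggregate_replicates(bad3), "positive")
})

test_that("delta-delta-Ct quantification inverts the fold change", {
  est <- estimate_copy_number(c(1, 2, 0, 1 - 0.585), calibrator_delta_ct = 1)
  expect_equal(est$delta_delta_ct, c(0, 1, -1, -0.585))
  expect_equal(est$cn_estimate[1:3], c(2, 1, 4))
  expect_equal(est$cn_estimate[4], 3, tolerance = 1e-3)
  # no-amplification sentinel
  est0 <- estimate_copy_number(NA_real_, 1)
  expect_equal(est0$cn_estimate, 0)
})

test_that("cn_estimate is strictly decreasing in delta-delta-Ct", {
  ddct <- seq(-3, 3, by = 0.1)
  cn <- estimate_copy_number(ddct + 1, 1)$cn_estimate
  expect_true(all(diff(cn) < 0))
})

test_that("z-score bands split calls at 1.75 and 2.5", {
  # choose sd so that z = dev / (cn * ln2 * sd) hits exactly 1, 2 and 3
  z_for <- function(z) {
    cn_est <- 2.2
    sd <- 0.2 / (z * cn_est * log(2))
    cnv_qc(cn_est, sd)
  }
  expect_equal(z_for(1)$qc_status, "high_confidence")
  expect_equal(z_for(1)$z_score, 1, tolerance = 1e-12)
  expect_equal(z_for(2)$qc_status, "caution")
  expect_equal(z_for(3)$qc_status, "reject")
  expect_equal(z_for(1.75)$qc_status, "caution")   # band edges are inclusive
  expect_equal(z_for(2.5)$qc_status, "caution")
})

test_that("confidence reflects the distance to the rounding boundary", {
  qc <- cnv_qc(2.0, 0.1)
  expect_equal(qc$confidence,
               2 * pnorm(0.5 / (2 * log(2) * 0.1)) - 1, tolerance = 1e-12)
  expect_true(cnv_qc(2.0, 0.01)$confidence > cnv_qc(2.0, 0.5)$confidence)
})

test_that("degenerate dispersion and half-integer ties are banded caution", {
  exact <- cnv_qc(2, 0)
  expect_equal(exact$z_score, 0)
  expect_equal(exact$confidence, 1)
  expect_equal(exact$qc_status, "high_confidence")

  degen <- cnv_qc(2.3, 0)
  expect_equal(degen$qc_status, "caution")
  expect_true(is.na(degen$z_score))

  # ties round away from 2
  expect_equal(cnv_qc(2.5, 0.05)$cn_integer, 3L)
  expect_equal(cnv_qc(1.5, 0.05)$cn_integer, 1L)
  expect_equal(cnv_qc(0.5, 0.05)$cn_integer, 0L)
  expect_equal(cnv_qc(3.5, 0.05)$cn_integer, 4L)
  expect_equal(cnv_qc(2.5, 1e-4)$qc_status, "caution")

  # dynamic-range cap
  capped <- cnv_qc(7.3, 1e-4)
  expect_equal(capped$cn_integer, 6L)
  expect_equal(capped$qc_status, "caution")
})

test_that("integer copy numbers classify as deletion / normal / duplication", {
  expect_equal(classify_cnv(c(0, 1, 2, 3, 4)),
               c("deletion", "deletion", "normal", "duplication", "duplication"))
  expect_error(classify_cnv(-1))
})

test_that("calibrator drift is flagged strictly below confidence 0.5", {
  expect_false(flag_calibrator_drift(list(confidence = 0.9)))
  expect_false(flag_calibrator_drift(list(confidence = 0.5)))
  expect_true(suppressMessages(flag_calibrator_drift(list(confidence = 0.49))))
})

test_that("noise-free plates are called back to the exact copy number", {
  cfg <- simulation_config(cohort_size = 1, ct_noise_sd = 0, seed = 1)
  truth <- do.call(rbind, lapply(0:4, function(k) {
    cp <- if (k == 0) c(0L, 0L) else if (k <= 2) c(k - 1L, 1L) else c(k - 1L, 1L)
    a <- if (k == 0) c("*5", "*5") else if (k == 1) c("*5", "*1") else c("*1", "*1")
    truth_row(paste0("cn", k), "CYP2D6", a[1], a[2], cp[1], cp[2])
  }))
  plate <- simulate_ct_plate(truth, cfg)
  calls <- suppressMessages(call_copy_numbers(plate))
  m <- match(truth$sample_id, calls$sample_id)
  expect_equal(calls$cn_integer[m], truth$copies1 + truth$copies2)
  expect_true(all(calls$qc_status[m] == "high_confidence"))
  expect_false(attr(calls, "calibrator_drift"))
})

test_that("a missing calibrator is a hard error", {
  plate <- ct_rows("a", c(26, 26), c(25, 25))
  expect_error(call_copy_numbers(plate), "calibrator")
})

test_that("rejected copy-number calls never reach diplotypes or phenotypes", {
  gt <- rbind(
    data.frame(sample_id = "a", gene = "CYP2D6",
               rsid = panel_rsids_of("CYP2D6"), call = "0/0"),
    data.frame(sample_id = "b", gene = "CYP2D6",
               rsid = panel_rsids_of("CYP2D6"), call = "0/0"))
  cn <- data.frame(sample_id = c("a", "b"), cn_integer = c(2L, 2L),
                   qc_status = c("reject", "high_confidence"),
                   stringsAsFactors = FALSE)
  d <- call_diplotypes(gt, cn_calls = cn)
  expect_true(has_flag(d$flags[d$sample_id == "a"], "cnv_rejected"))
  expect_true(is.na(d$diplotype[d$sample_id == "a"]))
  expect_equal(d$diplotype[d$sample_id == "b"], "*1/*1")

  ph <- assign_phenotypes(d)
  expect_equal(ph$category[ph$sample_id == "a"], "indeterminate")
  rep <- cohort_report(ph)
  expect_equal(rep$genes$CYP2D6$n_determinate, 1L)
  expect_equal(rep$genes$CYP2D6$n_indeterminate, 1L)
})
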