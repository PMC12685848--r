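#' Aggregate qPCR replicates into per-sample delta-Ct statistics
#'
#' Pairs target and reference Ct values by replicate index, forms
#' `dCt_i = Ct_target,i - Ct_reference,i` per replicate, and returns the mean
#' and sample standard deviation of the paired differences (pairing cancels
#' per-replicate well effects; the sd is 0 when only one replicate is
#' available). A sample whose target assay never amplified (all `NA`) is
#' flagged `no_amp`; a partially amplifying sample keeps its numeric pairs.
#'
#' @param measurements data.frame with columns `sample_id`, `assay`
#'   (`CYP2D6_ex9` target / `RNaseP` reference), `replicate`, `ct` (`NA` = no
#'   amplification).
#' @return data.frame with one row per sample: `sample_id`, `n_replicates`,
#'   `delta_ct_mean`, `delta_ct_sd`, `no_amp`, `low_replicate`.
#' @export
#' @examples
#' ct <- data.frame(sample_id = "A",
#'                  assay = rep(c("CYP2D6_ex9", "RNaseP"), each = 2),
#'                  replicate = c(1, 2, 1, 2), ct = c(26.9, 27.1, 26, 26))
#' aggregate_replicates(ct)
aggregate_replicates <- function(measurements) {
  required <- c("sample_id", "assay", "replicate", "ct")
  if (!all(required %in% names(measurements))) {
    stop("Ct table must have columns: ", paste(required, collapse = ", "))
  }
  bad_assay <- setdiff(unique(measurements$assay), c("CYP2D6_ex9", "RNaseP"))
  if (length(bad_assay) > 0L) {
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "))
  }
  if (any(!is.na(measurements$ct) & measurements$ct <= 0)) {
    stop("Ct values must be positive (or NA for no amplification)")
  }
  ids <- unique(measurements$sample_id)
  res <- lapply(ids, function(id) {
    m <- measurements[measurements$sample_id == id, ]
    tgt <- m[m$assay == "CYP2D6_ex9", ]
    ref <- m[m$assay == "RNaseP", ]
    if (nrow(tgt) == 0L || nrow(ref) == 0L) {
      stop("sample ", id, " is missing the ",
           if (nrow(tgt) == 0L) "target" else "reference", " assay")
    }
    if (!setequal(tgt$replicate, ref$replicate) ||
        anyDuplicated(tgt$replicate) || anyDuplicated(ref$replicate)) {
      stop("sample ", id, ": replicate indices of target and reference ",
           "assays do not pair up")
    }
    ref <- ref[match(tgt$replicate, ref$replicate), ]
    if (anyNA(ref$ct)) stop("sample ", id, ": reference assay failed to amplify")
    no_amp <- all(is.na(tgt$ct))
    dct <- tgt$ct - ref$ct
    dct <- dct[!is.na(dct)]
    data.frame(sample_id = id,
               n_replicates = length(tgt$replicate),
               delta_ct_mean = if (no_amp) NA_real_ else mean(dct),
               delta_ct_sd = if (no_amp || length(dct) < 2L) 0 else sd(dct),
               no_amp = no_amp,
               low_replicate = length(tgt$replicate) < 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Copy number from delta-delta-Ct
#'
#' Comparative quantification against a calibrator of known diploid copy
#' number: `ddCt = dCt_sample - dCt_calibrator` and
#' `cn_estimate = 2 * 2^(-ddCt)`. A sample whose target assay never amplified
#' is assigned copy number 0.
#'
#' @param delta_ct_mean per-sample mean delta-Ct (NA when `no_amp`).
#' @param calibrator_delta_ct the calibrator's mean delta-Ct.
#' @param no_amp logical no-amplification sentinel per sample.
#' @return data.frame with `delta_delta_ct` and `cn_estimate`.
#' @export
#' @examples
#' estimate_copy_number(c(1, 2, 0.415), 1)  # cn 2, 1, 3
estimate_copy_number <- function(delta_ct_mean, calibrator_delta_ct,
                                 no_amp = is.na(delta_ct_mean)) {
  stopifnot(length(calibrator_delta_ct) == 1L, is.finite(calibrator_delta_ct))
  ddct <- delta_ct_mean - calibrator_delta_ct
  cn <- 2 * 2^(-ddct)
  cn[no_amp] <- 0
  ddct[no_amp] <- NA_real_
  data.frame(delta_delta_ct = ddct, cn_estimate = cn)
}

# nearest integer with the documented tie rule: an estimate exactly half-way
# between integers rounds away from 2 (half-integer calls are ambiguous, so
# the tie is biased toward flagging a variant for review)
round_cn <- function(cn_estimate) {
  tie <- abs(cn_estimate - floor(cn_estimate) - 0.5) < 1e-9
  k <- ifelse(tie,
              ifelse(cn_estimate < 2, floor(cn_estimate), ceiling(cn_estimate)),
              floor(cn_estimate + 0.5))
  as.integer(k)
}

#' Quality-control banding of a copy-number estimate
#'
#' Computes the z-score, confidence and QC status of a copy-number call. The
#' z-score measures the distance of the continuous estimate from its integer
#' call in units of the call's dispersion, obtained by the delta method from
#' the replicate-level delta-delta-Ct scatter:
#' `sigma_CN = cn_estimate * ln(2) * sd_ddct`. Bands follow the calling
#' thresholds: `|z| < 1.75` high confidence, `1.75 <= |z| <= 2.5` caution,
#' `|z| > 2.5` reject. Confidence is `2 * Phi(gap / sigma_CN) - 1` clipped to
#' `[0, 1]`, where `gap` is the distance from the estimate to the nearest
#' boundary with a neighbouring integer (`0.5 - |cn_estimate - cn_integer|`).
#'
#' Degenerate cases: a zero `sd_ddct` with an integer estimate yields `z = 0`,
#' confidence 1; a zero `sd_ddct` with a non-integer estimate cannot support a
#' confidence claim and is banded `caution`. Ties at half-integers round away
#' from 2 and are banded at most `caution`. Estimates above 6 (the assay's
#' dynamic range) are reported as 6 with `caution`.
#'
#' @param cn_estimate non-negative continuous copy-number estimate(s).
#' @param sd_ddct replicate-level standard deviation of the delta-delta-Ct
#'   (cycles); recycled.
#' @return data.frame with `cn_integer`, `z_score`, `confidence`, `qc_status`.
#' @export
#' @examples
#' cnv_qc(2.1, 0.15)
cnv_qc <- function(cn_estimate, sd_ddct) {
  stopifnot(all(cn_estimate >= 0), all(sd_ddct >= 0))
  n <- length(cn_estimate)
  sd_ddct <- rep_len(sd_ddct, n)
  tie <- abs(cn_estimate - floor(cn_estimate) - 0.5) < 1e-9
  cn_int <- round_cn(cn_estimate)
  capped <- cn_estimate > 6
  cn_int[capped] <- 6L

  sigma <- cn_estimate * log(2) * sd_ddct
  dev <- cn_estimate - cn_int
  z <- ifelse(sigma > 0, dev / sigma,
              ifelse(abs(dev) < 1e-9, 0, NA_real_))
  gap <- pmax(0, 0.5 - abs(dev))
  conf <- ifelse(sigma > 0, pmin(1, pmax(0, 2 * pnorm(gap / sigma) - 1)),
                 ifelse(abs(dev) < 1e-9, 1, NA_real_))

  eps <- 1e-9
  status <- ifelse(is.na(z), "caution",
                   ifelse(abs(z) > 2.5 + eps, "reject",
                          ifelse(abs(z) >= 1.75 - eps, "caution",
                                 "high_confidence")))
  # half-integer ties and dynamic-range caps are definitionally ambiguous
  # calls: banded caution for review, whatever the z-score says
  status[tie | capped] <- "caution"
  data.frame(cn_integer = cn_int, z_score = z, confidence = conf,
             qc_status = status, stringsAsFactors = FALSE)
}

#' Classify an integer copy number
#'
#' `<= 1` copy is a gene deletion, 2 copies normal, `>= 3` copies a
#' duplication.
#'
#' @param cn_integer non-negative integer copy number(s).
#' @return character vector in `deletion`, `normal`, `duplication`.
#' @export
#' @examples
#' classify_cnv(0:4)
classify_cnv <- function(cn_integer) {
  stopifnot(all(cn_integer >= 0))
  ifelse(cn_integer <= 1, "deletion",
         ifelse(cn_integer == 2, "normal", "duplication"))
}

#' Flag calibrator model drift
#'
#' A calibrator confidence strictly below 0.5 — even with the correct copy
#' number and an acceptable z-score — indicates potential model drift or assay
#' inconsistency and is logged.
#'
#' @param calibrator_call a one-row data.frame (or list) with a `confidence`
#'   element, as produced by [call_copy_numbers()] for the calibrator sample.
#' @return logical drift flag.
#' @export
flag_calibrator_drift <- function(calibrator_call) {
  conf <- calibrator_call$confidence
  stopifnot(length(conf) == 1L)
  drift <- !is.na(conf) && conf < 0.5
  if (drift) {
    pgx_log("DRIFT", "calibrator confidence %.3f < 0.5: potential model drift",
            conf)
  }
  drift
}

#' Call copy numbers for a plate of Ct measurements
#'
#' Full copy-number calling pipeline: replicate aggregation, delta-delta-Ct
#' quantification against the calibrator, z-score/confidence QC banding and
#' deletion/normal/duplication classification.
#'
#' The delta-delta-Ct dispersion entering the z-score is estimated at the
#' plate level: within-sample delta-Ct variances are pooled across all
#' multi-replicate samples and the sample and calibrator contributions add, so
#' `sd_ddct = sqrt(2) * sd_pooled`. Pooling gives the denominator many degrees
#' of freedom, and measuring against replicate-level (not mean-level) scatter
#' makes the band a conservative yardstick: only samples whose deviation from
#' an integer copy number exceeds what single replicates show are flagged.
#'
#' @param measurements Ct table (see [aggregate_replicates()]).
#' @param calibrator sample_id of the calibrator (known diploid copy number).
#' @return data.frame with one row per sample (`sample_id`, `n_replicates`,
#'   `delta_ct`, `delta_ct_sd`, `delta_delta_ct`, `cn_estimate`, `cn_integer`,
#'   `z_score`, `confidence`, `qc_status`, `cnv_class`); the calibrator row is
#'   included. Attribute `calibrator_drift` carries the drift flag.
#' @export
call_copy_numbers <- function(measurements, calibrator = "CALIBRATOR") {
  agg <- aggregate_replicates(measurements)
  ci <- which(agg$sample_id == calibrator)
  if (length(ci) != 1L) {
    stop("calibrator sample '", calibrator, "' not found in Ct table")
  }
  if (agg$no_amp[ci]) stop("calibrator target assay failed to amplify")
  if (any(agg$low_replicate)) {
    pgx_log("WARN", "%d sample(s) with a single replicate",
            sum(agg$low_replicate))
  }

  est <- estimate_copy_number(agg$delta_ct_mean, agg$delta_ct_mean[ci],
                              no_amp = agg$no_amp)
  multi <- agg$n_replicates >= 2L & !agg$no_amp
  sd_pooled <- if (any(multi)) sqrt(mean(agg$delta_ct_sd[multi]^2)) else 0
  sd_ddct <- sqrt(2) * sd_pooled
  qc <- cnv_qc(est$cn_estimate, sd_ddct)
  qc$qc_status[agg$low_replicate & qc$qc_status == "high_confidence"] <- "caution"

  out <- data.frame(sample_id = agg$sample_id,
                    n_replicates = agg$n_replicates,
                    delta_ct = agg$delta_ct_mean,
                    delta_ct_sd = agg$delta_ct_sd,
                    delta_delta_ct = est$delta_delta_ct,
                    cn_estimate = est$cn_estimate,
                    cn_integer = qc$cn_integer,
                    z_score = qc$z_score,
                    confidence = qc$confidence,
                    qc_status = qc$qc_status,
                    cnv_class = classify_cnv(qc$cn_integer),
                    stringsAsFactors = FALSE)
  attr(out, "calibrator_drift") <- flag_calibrator_drift(out[ci, ])
  if (any(out$qc_status == "reject")) {
    pgx_log("WARN", "%d copy-number call(s) rejected by QC",
            sum(out$qc_status == "reject"))
  }
  out
}
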