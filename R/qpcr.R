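#' A single qPCR Ct record
#'
#' @param sample_id Sample identifier.
#' @param target_id Assayed transcript (e.g. a miRNA).
#' @param reference_id Normalizer transcript (U6 for miRNAs, GAPDH for
#'   mRNAs by convention).
#' @param ct_target,ct_reference Threshold cycles; must lie in (0, 50).
#' @param calibrator Logical: is this the calibrator (baseline) group?
#' @return One-row data.frame of class `ct_record`.
#' @export
ct_record <- function(sample_id, target_id, reference_id, ct_target,
                      ct_reference, calibrator = FALSE) {
  if (any(c(ct_target, ct_reference) <= 0) ||
      any(c(ct_target, ct_reference) >= 50))
    stop("Ct values must lie in (0, 50)")
  structure(data.frame(sample_id = sample_id, target_id = target_id,
                       reference_id = reference_id, ct_target = ct_target,
                       ct_reference = ct_reference, calibrator = calibrator,
                       stringsAsFactors = FALSE),
            class = c("ct_record", "data.frame"))
}

#' Relative quantification by the comparative Ct method
#'
#' `dCt = Ct(target) - Ct(reference)` within each group;
#' `ddCt = dCt(sample) - dCt(calibrator)`; fold change `2^(-ddCt)`
#' (the Livak convention: positive `ddCt` means down-regulation relative
#' to the calibrator). `negate = FALSE` gives the literal `2^(ddCt)`
#' reading instead.
#'
#' @param sample,calibrator [ct_record]s sharing `target_id` and
#'   `reference_id`.
#' @param negate Use the standard `2^(-ddCt)` convention (default TRUE).
#' @return List with `d_ct_sample`, `d_ct_calibrator`, `dd_ct`, `fold`.
#' @examples
#' s <- ct_record("t1", "miR-18a", "U6", 25, 20)
#' c <- ct_record("n1", "miR-18a", "U6", 28, 20, calibrator = TRUE)
#' delta_delta_ct(s, c)$fold  # 8
#' @export
delta_delta_ct <- function(sample, calibrator, negate = TRUE) {
  if (sample$target_id != calibrator$target_id ||
      sample$reference_id != calibrator$reference_id)
    stop("sample and calibrator must share target and reference assays")
  d_s <- sample$ct_target - sample$ct_reference
  d_c <- calibrator$ct_target - calibrator$ct_reference
  dd <- d_s - d_c
  list(d_ct_sample = d_s, d_ct_calibrator = d_c, dd_ct = dd,
       fold = 2^(if (negate) -dd else dd))
}

#' Amplification efficiency from a standard-curve slope
#'
#' For a standard curve of Ct against log10 template dilution with slope
#' `s < 0`, the per-cycle amplification efficiency is
#' `E = 10^(-1/s) - 1`; a slope of `-1/log10(2) ~ -3.32` corresponds to
#' exact doubling per cycle (E = 1, i.e. 100%).
#'
#' @param slope Regression slope (Ct per log10 dilution), must be
#'   negative.
#' @return Efficiency as a fraction (1 = 100%).
#' @seealso [slope_for_efficiency] for the inverse.
#' @export
standard_curve_efficiency <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative")
  10^(-1 / slope) - 1
}

#' Standard-curve slope giving a desired efficiency
#' @param efficiency Amplification efficiency fraction (> 0).
#' @return The (negative) slope, `-1 / log10(1 + efficiency)`.
#' @export
slope_for_efficiency <- function(efficiency) {
  if (any(efficiency <= 0)) stop("efficiency must be positive")
  -1 / log10(1 + efficiency)
}

#' Summarize replicate fold changes per condition
#'
#' Replicate ddCt values are averaged arithmetically per condition, which
#' corresponds to the geometric mean of the fold changes; the spread is
#' reported as the standard deviation of the replicate log2 folds (i.e.
#' of `-ddCt`).
#'
#' @param dd_ct Numeric vector of replicate ddCt values.
#' @param condition Parallel vector of condition labels.
#' @return data.frame `condition`, `n`, `fold` (geometric mean),
#'   `log2_sd` (NA, with a warning, for single-replicate conditions).
#' @examples
#' summarize_replicates(c(-1, -3), c("a", "a"))$fold  # geometric mean 4
#' @export
summarize_replicates <- function(dd_ct, condition) {
  if (length(dd_ct) != length(condition))
    stop("'dd_ct' and 'condition' must have equal length")
  conds <- unique(condition)
  out <- do.call(rbind, lapply(conds, function(cd) {
    x <- dd_ct[condition == cd]
    data.frame(condition = cd, n = length(x), fold = 2^(-mean(x)),
               log2_sd = if (length(x) > 1L) stats::sd(-x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n < 2L))
    warning("single-replicate condition(s): sd undefined for ",
            paste(out$condition[out$n < 2L], collapse = ", "))
  out
}

#' Fold changes for a full Ct table
#'
#' Computes per-record dCt, subtracts the calibrator group's mean dCt per
#' (target, reference) assay, and returns per-record ddCt and fold
#' changes.
#'
#' @param ct data.frame with columns `sample_id`, `group`, `target_id`,
#'   `reference_id`, `ct_target`, `ct_reference`.
#' @param calibrator_group Label of the calibrator group in `group`;
#'   exactly one calibrator group is used per quantification.
#' @param negate See [delta_delta_ct].
#' @return The input with `d_ct`, `dd_ct`, `fold` columns added
#'   (calibrator rows are referenced to their own group mean).
#' @export
qpcr_fold_changes <- function(ct, calibrator_group, negate = TRUE) {
  need <- c("sample_id", "group", "target_id", "reference_id",
            "ct_target", "ct_reference")
  if (!all(need %in% colnames(ct)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  if (!calibrator_group %in% ct$group)
    stop("calibrator group '", calibrator_group, "' absent from table")
  ct$d_ct <- ct$ct_target - ct$ct_reference
  cal <- ct[ct$group == calibrator_group, , drop = FALSE]
  base <- tapply(cal$d_ct, paste(cal$target_id, cal$reference_id), mean)
  key <- paste(ct$target_id, ct$reference_id)
  if (any(!key %in% names(base)))
    stop("assay without calibrator measurements: ",
         paste(unique(key[!key %in% names(base)]), collapse = ", "))
  ct$dd_ct <- ct$d_ct - as.numeric(base[key])
  ct$fold <- 2^(if (negate) -ct$dd_ct else ct$dd_ct)
  ct
}
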