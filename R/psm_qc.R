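#' Construct a fragment spectrum
#'
#' @param mz Numeric vector of peak mass-to-charge values (Th); must be
#'   strictly increasing.
#' @param intensity Numeric vector of nonnegative intensities; `NA` marks a
#'   predicted ion whose intensity prediction is missing.
#' @param retention_time Retention time in seconds (optional).
#' @param id Spectrum identifier.
#' @param ion Optional character vector of fragment-ion labels.
#' @return A `spectrum` object (list).
#' @export
spectrum <- function(mz, intensity, retention_time = NA_real_,
                     id = NA_character_, ion = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (!is.null(ion)) ion <- ion[o]
    if (any(diff(mz) <= 0)) stop("spectrum m/z values must be strictly increasing")
  }
  if (any(intensity < 0, na.rm = TRUE)) stop("negative peak intensity")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 retention_time = as.numeric(retention_time),
                 id = as.character(id), ion = ion),
            class = "spectrum")
}

#' Match observed peaks to predicted peaks at a ppm tolerance
#'
#' Greedy one-to-one assignment: all (observed, predicted) pairs within
#' `tolerance_ppm` (relative to the predicted m/z, the hypothesis under
#' test) are ranked by ascending ppm difference, ties broken by lower
#' predicted m/z then lower observed m/z, and accepted while neither peak
#' is taken. Pairs whose predicted intensity is `NA` (missing prediction)
#' are reported in the match table but excluded from the matched intensity
#' vectors `M` and `P` that feed the angular similarity.
#'
#' @param observed,predicted `spectrum` objects.
#' @param tolerance_ppm Matching tolerance, default 10 ppm.
#' @return List: `matches` (data frame `obs_idx`, `pred_idx`, `ppm`,
#'   `missing_prediction`), `M` and `P` (matched intensity vectors), `n`
#'   (their length).
#' @export
match_peaks <- function(observed, predicted, tolerance_ppm = 10) {
  no <- length(observed$mz); np <- length(predicted$mz)
  empty <- list(matches = data.frame(obs_idx = integer(0), pred_idx = integer(0),
                                     ppm = numeric(0),
                                     missing_prediction = logical(0)),
                M = numeric(0), P = numeric(0), n = 0L)
  if (no == 0L || np == 0L) return(empty)
  d <- outer(observed$mz, predicted$mz, `-`)
  ppm <- abs(d) / rep(predicted$mz, each = no) * 1e6
  cand <- which(ppm <= tolerance_ppm, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand_ppm <- ppm[cand]
  o <- order(cand_ppm, predicted$mz[cand[, 2L]], observed$mz[cand[, 1L]])
  cand <- cand[o, , drop = FALSE]
  cand_ppm <- cand_ppm[o]
  used_o <- logical(no); used_p <- logical(np)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    oi <- cand[i, 1L]; pi <- cand[i, 2L]
    if (!used_o[oi] && !used_p[pi]) {
      used_o[oi] <- TRUE; used_p[pi] <- TRUE; keep[i] <- TRUE
    }
  }
  m <- data.frame(obs_idx = cand[keep, 1L], pred_idx = cand[keep, 2L],
                  ppm = cand_ppm[keep])
  m <- m[order(m$obs_idx), , drop = FALSE]
  rownames(m) <- NULL
  m$missing_prediction <- is.na(predicted$intensity[m$pred_idx])
  with_int <- !m$missing_prediction
  list(matches = m,
       M = observed$intensity[m$obs_idx[with_int]],
       P = predicted$intensity[m$pred_idx[with_int]],
       n = sum(with_int))
}

#' Scale an observed spectrum onto a prediction
#'
#' Multiplies every observed intensity by the ratio of the median predicted
#' intensity to the median observed intensity, so that the two spectra are
#' on a common scale (used for mirror plots; the angular similarity itself
#' is invariant to positive rescaling). A zero observed median falls back
#' to the mean; if both are zero the spectra cannot be scaled.
#'
#' @param observed,predicted `spectrum` objects.
#' @return The observed `spectrum` with scaled intensities.
#' @export
scale_observed <- function(observed, predicted) {
  med_p <- stats::median(predicted$intensity, na.rm = TRUE)
  med_o <- stats::median(observed$intensity, na.rm = TRUE)
  if (is.na(med_p) || is.na(med_o)) stop("cannot scale: no intensities")
  denom <- med_o
  if (denom == 0) denom <- mean(observed$intensity, na.rm = TRUE)
  if (denom == 0) stop("cannot scale: observed spectrum has zero median and mean intensity")
  observed$intensity <- observed$intensity * med_p / denom
  observed
}

#' Angular similarity of matched peak intensity vectors
#'
#' The cosine similarity of the matched measured and predicted intensities
#' is mapped to `1 - arccos(C)/pi`. For nonnegative intensities the value
#' lies in `[0.5, 1]`: 1 for proportional vectors, 0.5 for orthogonal
#' ones. With no matched peaks the similarity is undefined and `NA` is
#' returned (not 0).
#'
#' @param M,P Equal-length numeric vectors of matched intensities, or a
#'   list with elements `M` and `P` as returned by [match_peaks()].
#' @return Numeric scalar in `[0, 1]`, or `NA` if undefined.
#' @export
angular_similarity <- function(M, P = NULL) {
  if (is.list(M) && is.null(P)) { P <- M$P; M <- M$M }
  stopifnot(length(M) == length(P))
  if (length(M) == 0L) return(NA_real_)
  nm <- sqrt(sum(M^2)); np <- sqrt(sum(P^2))
  if (nm == 0 || np == 0) return(NA_real_)
  C <- sum(M * P) / (nm * np)
  C <- min(1, max(-1, C))
  1 - acos(C) / pi
}

#' Calibrated retention-time deviation
#'
#' Observed and predicted retention times are each centered by the mean and
#' scaled by the standard deviation of the calibration set (typically the
#' PSMs passing the FDR threshold); the deviation of a PSM is the absolute
#' difference of the two z-scores.
#'
#' @param observed_rt,predicted_rt Numeric vectors (seconds) for the PSMs
#'   to score.
#' @param calibration_observed,calibration_predicted Numeric vectors
#'   defining the calibration; default to the scored PSMs themselves. At
#'   least 2 values with nonzero variance are required in each series.
#' @return Nonnegative numeric vector of deviations in scaled units.
#' @export
rt_deviation <- function(observed_rt, predicted_rt,
                         calibration_observed = observed_rt,
                         calibration_predicted = predicted_rt) {
  if (length(calibration_observed) < 2L || length(calibration_predicted) < 2L) {
    stop("calibration set must contain at least 2 PSMs")
  }
  sd_o <- stats::sd(calibration_observed)
  sd_p <- stats::sd(calibration_predicted)
  if (is.na(sd_o) || sd_o == 0) stop("zero variance in observed retention times")
  if (is.na(sd_p) || sd_p == 0) stop("zero variance in predicted retention times")
  z_o <- (observed_rt - mean(calibration_observed)) / sd_o
  z_p <- (predicted_rt - mean(calibration_predicted)) / sd_p
  abs(z_o - z_p)
}

#' Target-decoy q-values and the confident PSM subset
#'
#' The FDR at score `s` is the number of decoy PSMs scoring at least `s`
#' divided by the number of target PSMs scoring at least `s` (simple
#' target-decoy competition; set `estimator = "plus_one"` for the
#' conservative `(#decoys + 1) / #targets` variant). The q-value of a PSM
#' is the minimum FDR over all thresholds at or below its score, capped at
#' 1. The confident subset contains target PSMs with a q-value strictly
#' below `threshold`; peptides matching a contaminant record are removed
#' from it.
#'
#' @param psms Data frame with columns `score` and `label` (`"target"` /
#'   `"decoy"`); an optional logical column `is_contaminant` marks PSMs
#'   whose peptide maps to a contaminant sequence.
#' @param threshold PSM-level FDR threshold, default 0.01.
#' @param estimator `"simple"` or `"plus_one"`.
#' @return `psms` with a `q_value` column and a logical `confident` column.
#' @export
target_decoy_qvalues <- function(psms, threshold = 0.01,
                                 estimator = c("simple", "plus_one")) {
  estimator <- match.arg(estimator)
  stopifnot(all(psms$label %in% c("target", "decoy")))
  if (!any(psms$label == "target")) stop("no target PSMs")
  s <- sort(unique(psms$score))                       # ascending = worst first
  n_t <- length(psms$score[psms$label == "target"])
  # counts of targets / decoys with score >= each threshold
  t_ge <- vapply(s, function(x) sum(psms$score >= x & psms$label == "target"), 1L)
  d_ge <- vapply(s, function(x) sum(psms$score >= x & psms$label == "decoy"), 1L)
  num <- if (estimator == "plus_one") d_ge + 1L else d_ge
  fdr <- ifelse(t_ge == 0L, 1, num / t_ge)
  fdr <- pmin(fdr, 1)
  q_at <- cummin(fdr)                                # min over thresholds <= s
  psms$q_value <- q_at[match(psms$score, s)]
  is_cont <- if (!is.null(psms$is_contaminant)) psms$is_contaminant else FALSE
  psms$confident <- psms$label == "target" & psms$q_value < threshold & !is_cont
  psms
}

#' Annotate observed and predicted peaks for a mirror plot
#'
#' Observed peaks are labeled `matched` (blue), `missing_prediction` (pink:
#' matched to an ion whose intensity prediction is missing), `unmatched`
#' (gray), or `unannotated` when the matched predicted intensity is exactly
#' zero. Predicted peaks are `matched` (green) or `unmatched` (red);
#' missing-intensity predictions are labeled `missing`.
#'
#' @param observed,predicted `spectrum` objects.
#' @param matches Result of [match_peaks()] for the pair.
#' @return List of two character vectors, `observed` and `predicted`.
#' @export
annotate_mirror <- function(observed, predicted, matches) {
  obs_cat <- rep("unmatched", length(observed$mz))
  pred_cat <- rep("unmatched", length(predicted$mz))
  pred_cat[is.na(predicted$intensity)] <- "missing"
  m <- matches$matches
  for (i in seq_len(nrow(m))) {
    pi <- m$pred_idx[i]; oi <- m$obs_idx[i]
    if (m$missing_prediction[i]) {
      obs_cat[oi] <- "missing_prediction"
    } else if (predicted$intensity[pi] == 0) {
      obs_cat[oi] <- "unannotated"
      pred_cat[pi] <- "matched"
    } else {
      obs_cat[oi] <- "matched"
      pred_cat[pi] <- "matched"
    }
  }
  list(observed = obs_cat, predicted = pred_cat)
}

#' Mirror plot of an observed spectrum against its prediction
#'
#' Observed peaks point up, predicted peaks down (after median scaling of
#' the observed spectrum), with the conventional colors: blue matched,
#' pink missing prediction, gray unmatched observed; green matched, red
#' unmatched predicted.
#'
#' @param observed,predicted `spectrum` objects.
#' @param tolerance_ppm Matching tolerance.
#' @param main Plot title.
#' @return Invisibly, the annotation list of [annotate_mirror()].
#' @export
plot_mirror <- function(observed, predicted, tolerance_ppm = 10, main = "") {
  matches <- match_peaks(observed, predicted, tolerance_ppm)
  ann <- annotate_mirror(observed, predicted, matches)
  obs <- scale_observed(observed, predicted)
  obs_col <- c(matched = "#3366CC", missing_prediction = "#CC6699",
               unmatched = "grey60", unannotated = "grey85")[ann$observed]
  pred_col <- c(matched = "#33A02C", unmatched = "#E31A1C",
                missing = "grey85")[ann$predicted]
  pint <- ifelse(is.na(predicted$intensity), 0, predicted$intensity)
  ylim <- c(-1.05 * max(pint, 1e-9), 1.05 * max(obs$intensity, 1e-9))
  graphics::plot(NA, xlim = range(c(obs$mz, predicted$mz)), ylim = ylim,
                 xlab = "m/z", ylab = "intensity", main = main)
  graphics::segments(obs$mz, 0, obs$mz, obs$intensity, col = obs_col)
  graphics::segments(predicted$mz, 0, predicted$mz, -pint, col = pred_col)
  graphics::abline(h = 0, col = "grey40")
  invisible(ann)
}

#' Score a PSM table with all quality-control metrics
#'
#' For every PSM, the observed spectrum is matched at `tolerance_ppm`
#' against the predicted spectrum of its assigned peptide; the angular
#' similarity and matched-peak counts are recorded. Target-decoy q-values
#' are computed from the search scores, the confident subset (q-value below
#' `fdr_threshold`, contaminant matches removed) is used to calibrate the
#' retention-time scaling, and the calibrated absolute deviation is
#' attached to every PSM.
#'
#' @param psms PSM data frame: `spectrum_id`, `peptide`, `score`, `label`,
#'   optionally `sample_id`, `accessions`, `is_contaminant`.
#' @param observed_spectra Named list of `spectrum` objects keyed by
#'   `spectrum_id`.
#' @param predictor A predictor as returned by [toy_predictor()]
#'   (`$predict_spectrum(peptide)`, `$predict_rt(peptide)`).
#' @param tolerance_ppm,fdr_threshold QC parameters (defaults 10 ppm, 1%).
#' @return The PSM table augmented with `q_value`, `confident`,
#'   `angular_similarity`, `n_matched`, `rt_observed`, `rt_predicted`,
#'   `rt_deviation`.
#' @export
qc_psms <- function(psms, observed_spectra, predictor,
                    tolerance_ppm = 10, fdr_threshold = 0.01) {
  ang <- numeric(nrow(psms)); nm <- integer(nrow(psms))
  rt_obs <- numeric(nrow(psms)); rt_pred <- numeric(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    obs <- observed_spectra[[psms$spectrum_id[i]]]
    if (is.null(obs)) stop("no observed spectrum for ", psms$spectrum_id[i])
    pred <- predictor$predict_spectrum(psms$peptide[i])
    mt <- match_peaks(obs, pred, tolerance_ppm)
    ang[i] <- angular_similarity(mt)
    nm[i] <- mt$n
    rt_obs[i] <- obs$retention_time
    rt_pred[i] <- predictor$predict_rt(psms$peptide[i])
  }
  psms$angular_similarity <- ang
  psms$n_matched <- nm
  psms$rt_observed <- rt_obs
  psms$rt_predicted <- rt_pred
  psms <- target_decoy_qvalues(psms, threshold = fdr_threshold)
  cal <- psms$confident & !is.na(psms$rt_observed)
  if (sum(cal) >= 2L &&
      stats::sd(psms$rt_observed[cal]) > 0 &&
      stats::sd(psms$rt_predicted[cal]) > 0) {
    psms$rt_deviation <- rt_deviation(psms$rt_observed, psms$rt_predicted,
                                      psms$rt_observed[cal],
                                      psms$rt_predicted[cal])
  } else {
    psms$rt_deviation <- NA_real_
  }
  psms
}
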