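#' Match observed peaks against predicted fragments
#'
#' Classifies every observed peak. A peak within `tolerance` of any
#' contaminant m/z is classed `contaminant` first (contaminant masking
#' precedes prediction matching). Each remaining peak matches the nearest
#' prediction within `tolerance` -- the boundary is inclusive, so an
#' absolute error exactly equal to the tolerance counts -- with ties broken
#' toward the smaller absolute error, then the smaller predicted m/z. Each
#' peak matches at most one prediction; several peaks may match the same
#' prediction.
#'
#' @param peaks A `peak_list`.
#' @param predictions A `prediction_set` (or a numeric vector of predicted
#'   m/z values).
#' @param tolerance Matching half-window in m/z units; the default 0.25
#'   reflects a typical maximum instrumental calibration error for
#'   unit-resolution EI instruments.
#' @param contaminants Optional contaminant m/z vector
#'   (see [contaminant_list()]).
#' @return A `match_report`: data frame with columns `mz`, `intensity`,
#'   `class` (`matched`/`unmatched`/`contaminant`), `matched_mz`,
#'   `abs_error`, `annotation` (mechanism path of the matched prediction),
#'   and a `tolerance` attribute. The three classes partition the peaks.
#' @export
match_peaks <- function(peaks, predictions, tolerance = 0.25,
                        contaminants = NULL) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("tolerance must be a positive number", call. = FALSE)
  }
  if (inherits(predictions, "prediction_set")) {
    pred_mz <- predictions$mz
    pred_ann <- vapply(predictions$fragments, function(f) {
      if (length(f$path)) paste(f$path, collapse = " > ") else "intact"
    }, "")
  } else {
    pred_mz <- as.numeric(predictions)
    pred_ann <- rep("prediction", length(pred_mz))
  }
  o <- order(pred_mz)
  pred_mz <- pred_mz[o]
  pred_ann <- pred_ann[o]

  n <- nrow(peaks)
  cls <- character(n)
  matched_mz <- rep(NA_real_, n)
  abs_err <- rep(NA_real_, n)
  ann <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- peaks$mz[[i]]
    if (!is.null(contaminants) && length(contaminants) &&
        min(abs(p - contaminants)) <= tolerance) {
      cls[[i]] <- "contaminant"
      next
    }
    err <- abs(p - pred_mz)
    j <- order(err, pred_mz)[1L]
    if (length(err) && err[[j]] <= tolerance) {
      cls[[i]] <- "matched"
      matched_mz[[i]] <- pred_mz[[j]]
      abs_err[[i]] <- err[[j]]
      ann[[i]] <- pred_ann[[j]]
    } else {
      cls[[i]] <- "unmatched"
    }
  }
  structure(data.frame(mz = peaks$mz, intensity = peaks$intensity,
                       class = cls, matched_mz = matched_mz,
                       abs_error = abs_err, annotation = ann,
                       stringsAsFactors = FALSE),
            tolerance = tolerance,
            class = c("match_report", "data.frame"))
}

#' Threshold fitness score of a spectrum against predictions
#'
#' The fitness score is the percentage of peaks at or above an intensity
#' threshold -- expressed as a fraction of the base (most intense) peak --
#' that match a prediction, relative to all peaks meeting the threshold.
#' Contaminant-matched peaks are removed from the analysis before
#' thresholding; the base-peak intensity is taken over the full spectrum.
#' Typical thresholds are 0.05 (permissive, most peaks considered) and
#' 0.25 (only prominent peaks).
#'
#' @inheritParams match_peaks
#' @param threshold_fraction Relative intensity cutoff in (0, 1].
#' @return A `score_report` one-row data frame: `threshold_fraction`,
#'   `n_considered`, `n_matched`, `percent_matched` (NA when no peak meets
#'   the threshold), `mean_abs_error`, `sd_abs_error`.
#' @examples
#' ps <- enumerate_fragments("QFA")
#' pk <- peak_list(ps$mz[1:5], c(5, 4, 3, 2, 1))
#' score_spectrum(pk, ps, threshold_fraction = 0.25)
#' @export
score_spectrum <- function(peaks, predictions, threshold_fraction = 0.05,
                           tolerance = 0.25, contaminants = NULL) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  }
  rep_ <- match_peaks(peaks, predictions, tolerance, contaminants)
  base <- base_peak_intensity(peaks)
  considered <- rep_$class != "contaminant" &
    rep_$intensity >= threshold_fraction * base
  n_cons <- sum(considered)
  n_match <- sum(considered & rep_$class == "matched")
  errs <- rep_$abs_error[considered & rep_$class == "matched"]
  structure(data.frame(
    threshold_fraction = threshold_fraction,
    n_considered = n_cons,
    n_matched = n_match,
    percent_matched = if (n_cons == 0L) NA_real_ else 100 * n_match / n_cons,
    mean_abs_error = if (length(errs)) mean(errs) else NA_real_,
    sd_abs_error = if (length(errs) > 1L) stats::sd(errs) else NA_real_),
    class = c("score_report", "data.frame"))
}

#' Aggregate fitness scores across spectra
#'
#' Reports both natural aggregations of a set of per-spectrum scores:
#' the unweighted mean of per-spectrum match percentages (each spectrum
#' counts equally) and the pooled percentage (all considered peaks pooled).
#'
#' @param scores Data frame of rows produced by [score_spectrum()].
#' @return Data frame with one row per aggregation (`mean_of_spectra`,
#'   `pooled`) and the aggregated `percent_matched`.
#' @export
summarize_scores <- function(scores) {
  ok <- !is.na(scores$percent_matched)
  data.frame(
    aggregation = c("mean_of_spectra", "pooled"),
    percent_matched = c(mean(scores$percent_matched[ok]),
                        100 * sum(scores$n_matched) /
                          sum(scores$n_considered)),
    stringsAsFactors = FALSE)
}

#' Write fitness scores as tab-separated text
#'
#' @param scores Data frame of [score_spectrum()] rows.
#' @param path Output file path.
#' @export
write_scores <- function(scores, path) {
  out <- as.data.frame(scores)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) round(v, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
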