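#' Detect peaks in a residual series
#'
#' A peak is an apex sample preceded by at least `min_steps` strictly
#' increasing consecutive steps and followed by at least `min_steps`
#' strictly decreasing consecutive steps. Two counting rules are used
#' throughout the pipeline: `min_steps = 1` counts all peaks (single
#' time-step increase and decrease) and `min_steps = 3` counts only
#' robust peaks. Plateaus break a run (steps must be strict).
#'
#' Peak width is the elapsed time from the start of the monotone rise
#' to the end of the monotone fall, extending outward beyond the
#' qualifying `min_steps` while monotonicity holds.
#'
#' @param residuals a [residual_series()] or a numeric vector.
#' @param min_steps minimum run length on each flank (>= 1).
#' @param step_s sampling step in seconds (taken from the series when
#'   one is given).
#' @return a data frame of peaks in time order: `apex_index`, `height`
#'   (residual value at the apex), `width` (minutes), `rise_steps`,
#'   `fall_steps`. A series too short to hold a peak yields zero rows
#'   with a warning.
#' @export
detect_peaks <- function(residuals, min_steps = 3L, step_s = 30) {
  if (inherits(residuals, "residual_series")) {
    x <- residuals$residuals
    step_s <- residuals$step_s
  } else x <- as.numeric(residuals)
  stopifnot(min_steps >= 1L)
  empty <- data.frame(apex_index = integer(), height = numeric(),
                      width = numeric(), rise_steps = integer(),
                      fall_steps = integer())
  n <- length(x)
  if (n < 2L * min_steps + 1L) {
    warning(sprintf("series of length %d is too short for peaks with min_steps = %d",
                    n, min_steps))
    return(empty)
  }
  d <- diff(x)
  # run of strictly increasing steps ending at each sample, and of
  # strictly decreasing steps starting at each sample
  up <- integer(n)
  for (i in 2:n) up[i] <- if (d[i - 1L] > 0) up[i - 1L] + 1L else 0L
  down <- integer(n)
  for (i in (n - 1L):1L) down[i] <- if (d[i] < 0) down[i + 1L] + 1L else 0L
  apex <- which(up >= min_steps & down >= min_steps)
  if (!length(apex)) return(empty)
  data.frame(apex_index = apex,
             height = x[apex],
             width = (up[apex] + down[apex]) * step_s / 60,
             rise_steps = up[apex],
             fall_steps = down[apex])
}

#' Keep the k largest peaks by height or width
#'
#' Ties are broken by apex time: the earlier peak ranks first. When
#' fewer than `k` peaks exist, all are returned; the feature vector
#' pads the remaining slots with zeros downstream.
#'
#' @param peaks a peak data frame from [detect_peaks()].
#' @param k number of peaks to keep (>= 1).
#' @param key `"height"` or `"width"`.
#' @return the top-`k` rows sorted by decreasing `key`.
#' @export
top_peaks <- function(peaks, k = 5L, key = c("height", "width")) {
  key <- match.arg(key)
  stopifnot(k >= 1L)
  if (nrow(peaks) == 0L) return(peaks)
  ord <- order(-peaks[[key]], peaks$apex_index)
  peaks[ord[seq_len(min(k, nrow(peaks)))], , drop = FALSE]
}

#' Names of the feature vector, by variant
#'
#' The canonical descriptor list counts 20 items: 3 moments, the sums of
#' positive and of negative residuals, 2 peak counts (all peaks and
#' robust peaks, per minute of film), the occurrence of the first robust
#' peak, the 5 highest and 5 widest peak values, and the sums of those
#' two top-5 sets. The feature set used for modelling has 18 values:
#' the default variant drops the two top-5 sums (exact linear functions
#' of the included heights/widths, so no information is lost); the
#' `"drop_counts"` variant instead keeps the sums and drops the two
#' peak counts; `"full"` keeps all 20.
#'
#' @param variant feature-set variant.
#' @return character vector of feature names.
#' @export
feature_names <- function(variant = c("drop_aggregates", "drop_counts", "full")) {
  variant <- match.arg(variant)
  moments <- c("std", "kurtosis", "skewness")
  sums <- c("sum_positive", "sum_negative")
  counts <- c("n_peaks_all_per_length", "n_peaks_robust_per_length")
  occ <- "first_peak_occurrence"
  tops <- c(paste0("height_", 1:5), paste0("width_", 1:5))
  aggs <- c("sum_top5_heights", "sum_top5_widths")
  switch(variant,
         drop_aggregates = c(moments, sums, counts, occ, tops),
         drop_counts = c(moments, sums, occ, tops, aggs),
         full = c(moments, sums, counts, occ, tops, aggs))
}

#' Extract the per-screening feature vector from a residual series
#'
#' Computes the time-independent descriptors used as classifier input:
#' moments of the residual distribution (standard deviation, excess
#' kurtosis, skewness), the sums of positive and negative residuals,
#' peak counts under both counting rules normalized to the film length
#' (peaks per minute), the occurrence of the first robust peak as a
#' fraction of the film length (sentinel 1 when no robust peak exists),
#' and the 5 highest and 5 widest robust peaks (zero-padded, sorted
#' descending).
#'
#' All-constant residuals map kurtosis and skewness to 0 by convention
#' (rather than leaving them undefined) and yield zero peak features.
#'
#' @param residuals a [residual_series()].
#' @param min_steps_robust flank length of the robust peak rule.
#' @param k number of top peaks retained per key.
#' @param variant feature-set variant, see [feature_names()].
#' @return a named numeric vector (18 values for the default variant).
#' @export
extract_features <- function(residuals, min_steps_robust = 3L, k = 5L,
                             variant = c("drop_aggregates", "drop_counts", "full")) {
  variant <- match.arg(variant)
  stopifnot(inherits(residuals, "residual_series"))
  x <- residuals$residuals
  if (!length(x)) stop("residual series is empty")
  L <- residuals$film_length_min

  if (stats::sd(x) == 0) {
    mom <- c(std = 0, kurtosis = 0, skewness = 0)
  } else {
    mom <- c(std = stats::sd(x),
             kurtosis = e1071::kurtosis(x, type = 1),
             skewness = e1071::skewness(x, type = 1))
  }
  sums <- c(sum_positive = sum(x[x > 0]), sum_negative = sum(x[x < 0]))

  all_pk <- suppressWarnings(detect_peaks(residuals, min_steps = 1L))
  rob_pk <- suppressWarnings(detect_peaks(residuals, min_steps = min_steps_robust))
  counts <- c(n_peaks_all_per_length = nrow(all_pk) / L,
              n_peaks_robust_per_length = nrow(rob_pk) / L)

  occ <- 1
  if (nrow(rob_pk) > 0L) {
    first_apex <- min(rob_pk$apex_index)
    occ <- ((first_apex - 1L) * residuals$step_s / 60) / L
  }

  pad <- function(v) { out <- numeric(k); out[seq_along(v)] <- v; out }
  hts <- pad(top_peaks(rob_pk, k, "height")$height)
  wds <- pad(top_peaks(rob_pk, k, "width")$width)
  tops <- c(stats::setNames(hts, paste0("height_", seq_len(k))),
            stats::setNames(wds, paste0("width_", seq_len(k))))
  aggs <- c(sum_top5_heights = sum(hts), sum_top5_widths = sum(wds))

  full <- c(mom, sums, counts, first_peak_occurrence = occ, tops, aggs)
  full[feature_names(variant)]
}
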