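# Quality control, minimum background correction, M/A computation with
# dye-swap resolution, and within-array loess normalization fitted on a
# chosen gene set (all features, ~1000 conserved, or ~100 conserved) and
# applied to all features.

#' Flag low-signal features
#'
#' A feature is flagged \code{low_signal} on an array unless, in both
#' channels, its foreground is strictly more than two background standard
#' deviations above background: passing requires \code{fg - bg > n_sd *
#' bg_sd}, so a feature sitting exactly at the threshold is flagged.
#' Pre-existing \code{technical_error} flags are preserved.
#'
#' @param scan Scan table (\code{\link{read_scan_table}}).
#' @param n_sd Number of background SDs required above background.
#' @return The scan table with updated \code{qc_flag}.
#' @export
apply_qc <- function(scan, n_sd = 2) {
  low <- (scan$fg1 - scan$bg1 <= n_sd * scan$bg1_sd) |
    (scan$fg2 - scan$bg2 <= n_sd * scan$bg2_sd)
  flag <- scan$qc_flag
  flag[low & flag != "technical_error"] <- "low_signal"
  flag[!low & flag == "low_signal"] <- "ok"
  scan$qc_flag <- flag
  scan
}

#' Features analyzable in a species: surviving QC on enough arrays
#'
#' @param scan QC-applied scan table covering all arrays of one species.
#' @param min_arrays Minimum number of arrays with \code{qc_flag == "ok"}.
#' @return Character vector of retained feature ids.
#' @export
filter_min_arrays <- function(scan, min_arrays = 2) {
  n_arrays <- length(unique(scan$array_id))
  if (min_arrays > n_arrays) {
    cgh_stop(sprintf(
      "filter_min_arrays: min_arrays (%d) exceeds number of arrays (%d)",
      min_arrays, n_arrays), "crosscgh_config_error")
  }
  ok <- scan$qc_flag == "ok"
  counts <- table(scan$feature_id[ok])
  sort(names(counts)[counts >= min_arrays])
}

#' Minimum background correction
#'
#' Subtracts background from foreground per channel; within each
#' (array, channel), any corrected value that is zero or negative is replaced
#' by half the minimum positive corrected value of that array and channel, so
#' all corrected intensities are strictly positive.
#'
#' @param scan Scan table.
#' @return The scan table with numeric columns \code{corr1}, \code{corr2}
#'   appended.
#' @export
background_correct_minimum <- function(scan) {
  correct_one <- function(fg, bg, array_id, channel) {
    corr <- fg - bg
    for (a in unique(array_id)) {
      i <- array_id == a
      pos <- corr[i][corr[i] > 0]
      if (length(pos) == 0L) {
        cgh_stop(sprintf(
          "background correction: array %s channel %d has no positive corrected value",
          a, channel), "crosscgh_processing_error")
      }
      repl <- min(pos) / 2
      corr[i][corr[i] <= 0] <- repl
    }
    corr
  }
  scan$corr1 <- correct_one(scan$fg1, scan$bg1, scan$array_id, 1L)
  scan$corr2 <- correct_one(scan$fg2, scan$bg2, scan$array_id, 2L)
  scan
}

#' Compute M and A values with dye-swap resolution
#'
#' With test-channel intensity t and reference-channel intensity r resolved
#' via each array's dye orientation (+1: test in channel 1), \code{M =
#' log2(t/r)} and \code{A = (log2 t + log2 r) / 2}. The sign convention after
#' resolution is that positive M always means excess in the test sample.
#' Features not flagged \code{ok} are marked \code{included = FALSE}.
#'
#' @param scan Background-corrected scan table (needs \code{corr1},
#'   \code{corr2}).
#' @param design Design data frame giving \code{dye_orientation} per array.
#' @return MA data frame: \code{array_id}, \code{feature_id}, \code{M},
#'   \code{A}, \code{included}.
#' @export
compute_ma <- function(scan, design) {
  if (is.null(scan$corr1) || is.null(scan$corr2)) {
    cgh_stop("compute_ma: run background_correct_minimum first",
             "crosscgh_processing_error")
  }
  if (any(scan$corr1 <= 0 | scan$corr2 <= 0)) {
    cgh_stop("compute_ma: corrected intensities must be positive",
             "crosscgh_domain_error")
  }
  ori <- design$dye_orientation[match(scan$array_id, design$array_id)]
  if (any(is.na(ori))) {
    cgh_stop("compute_ma: scan contains arrays absent from the design",
             "crosscgh_validation_error")
  }
  t_int <- ifelse(ori == 1L, scan$corr1, scan$corr2)
  r_int <- ifelse(ori == 1L, scan$corr2, scan$corr1)
  data.frame(array_id = scan$array_id,
             feature_id = scan$feature_id,
             M = log2(t_int / r_int),
             A = (log2(t_int) + log2(r_int)) / 2,
             included = scan$qc_flag == "ok",
             stringsAsFactors = FALSE)
}

#' Within-array loess normalization on a chosen gene set
#'
#' Per array, fits a locally weighted regression of M on A using only the
#' included features of the chosen normalization set (\code{"all"} features,
#' or the conserved subsets from the annotation), then subtracts the fitted
#' curve evaluated at every feature's A from every feature's M — fit on the
#' subset, apply to all. Outside the subset's A range the fitted curve is
#' clamped to its boundary value so the local polynomial does not
#' extrapolate.
#'
#' Anchoring the curve on conserved genes keeps genome-wide ratio depression
#' in a diverged test species from being absorbed into the normalization
#' baseline, which is what inflates false positives under whole-array
#' normalization.
#'
#' @param ma MA data frame from \code{\link{compute_ma}}.
#' @param normalization_set One of \code{"all"}, \code{"conserved_1000"},
#'   \code{"conserved_100"}.
#' @param annotation Feature annotation (needed for the conserved subsets).
#' @param span Loess span (degree 1, symmetric family, 3 robustifying
#'   iterations).
#' @param min_subset Minimum number of included subset features per array.
#' @return The MA data frame with normalized M.
#' @export
loess_normalize <- function(ma, normalization_set = c("conserved_1000", "all",
                                                      "conserved_100"),
                            annotation = NULL, span = 0.4, min_subset = 30) {
  normalization_set <- match.arg(normalization_set)
  if (normalization_set == "all") {
    in_set <- rep(TRUE, nrow(ma))
  } else {
    if (is.null(annotation)) {
      cgh_stop("loess_normalize: annotation required for conserved sets",
               "crosscgh_config_error")
    }
    flag <- annotation[[normalization_set]][match(ma$feature_id,
                                                  annotation$feature_id)]
    if (any(is.na(flag))) {
      cgh_stop("loess_normalize: MA features missing from annotation",
               "crosscgh_validation_error")
    }
    in_set <- flag
  }
  for (a in unique(ma$array_id)) {
    ai <- ma$array_id == a
    fit_i <- ai & in_set & ma$included & is.finite(ma$M) & is.finite(ma$A)
    if (sum(fit_i) < min_subset) {
      cgh_stop(sprintf(
        "loess_normalize: set '%s' has only %d usable features on array %s (need >= %d)",
        normalization_set, sum(fit_i), a, min_subset),
        "crosscgh_processing_error")
    }
    fit <- stats::loess(M ~ A, data = ma[fit_i, ], span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(iterations = 4L,
                                                       surface = "interpolate"))
    a_range <- range(ma$A[fit_i])
    a_eval <- pmin(pmax(ma$A[ai], a_range[1L]), a_range[2L])
    ma$M[ai] <- ma$M[ai] - stats::predict(fit, newdata = data.frame(A = a_eval))
  }
  ma
}

#' Run QC, filtering, background correction, M/A and normalization in order
#'
#' @param scan Raw scan table for one species.
#' @param design Design data frame.
#' @param annotation Feature annotation.
#' @param normalization_set Normalization gene set, see
#'   \code{\link{loess_normalize}}.
#' @param span Loess span.
#' @param min_arrays Minimum QC-ok arrays per analyzable feature.
#' @return List with \code{ma} (normalized MA values) and
#'   \code{analyzable_ids}.
#' @export
preprocess <- function(scan, design, annotation,
                       normalization_set = "conserved_1000", span = 0.4,
                       min_arrays = 2) {
  scan <- apply_qc(scan)
  analyzable <- filter_min_arrays(scan, min_arrays)
  scan <- background_correct_minimum(scan)
  ma <- compute_ma(scan, design)
  ma <- loess_normalize(ma, normalization_set, annotation, span)
  list(ma = ma, analyzable_ids = analyzable)
}
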