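# Ground-truth evaluation: true/false positive accounting over X-linked
# features (the known duplications), divergence-binned detection curves, and
# rule-based classification of erroneous calls into genome-difference
# confounder categories derived from hit tables.

#' Round half-up to whole percent
#'
#' @param frac Fraction in [0, 1] (vectorized).
#' @return Integer percent with ties rounded up (0.165 -> 17).
#' @export
percent_half_up <- function(frac) {
  as.integer(floor(100 * frac + 0.5))
}

#' Evaluation summary from raw counts
#'
#' True positives are called X features, false negatives uncalled X features,
#' false positives autosomal features called in excess. The true positive
#' rate is tp / (tp + fn); the false positive rate is the fraction of all
#' called features that are autosomal, fp / (tp + fp) (0 when nothing is
#' called). An alternative rate, the fraction of autosomal features called,
#' is carried as a secondary column when the autosome total is supplied.
#'
#' @param tp,fp,fn Counts.
#' @param species,normalization Labels.
#' @param n_autosomal Optional number of analyzable autosomal features.
#' @return One-row data frame with counts, fractional rates and whole-percent
#'   roundings (half-up).
#' @export
evaluation_summary <- function(tp, fp, fn, species = NA_character_,
                               normalization = NA_character_,
                               n_autosomal = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  n_x <- tp + fn
  tp_rate <- if (n_x > 0) tp / n_x else NA_real_
  fn_rate <- if (n_x > 0) fn / n_x else NA_real_
  fp_rate <- if (tp + fp > 0) fp / (tp + fp) else 0
  fp_rate_autosomal <- if (!is.na(n_autosomal) && n_autosomal > 0) {
    fp / n_autosomal
  } else {
    NA_real_
  }
  data.frame(species = species, normalization = normalization,
             n_x_analyzed = n_x, tp = tp, fp = fp, fn = fn,
             tp_rate = tp_rate, fp_rate = fp_rate, fn_rate = fn_rate,
             fp_rate_autosomal = fp_rate_autosomal,
             tp_pct = percent_half_up(tp_rate),
             fp_pct = percent_half_up(fp_rate),
             fn_pct = percent_half_up(fn_rate),
             stringsAsFactors = FALSE)
}

#' Summarize excess calls against the X/autosome truth
#'
#' @param results Per-feature results table (from
#'   \code{\link{fit_genomic_excess}}'s \code{results} element) with
#'   \code{feature_id} and \code{called_excess}.
#' @param annotation Feature annotation covering every result feature.
#' @param analyzable_ids Features analyzable in this species; defaults to the
#'   result features.
#' @param species,normalization Labels carried into the summary row.
#' @return One-row data frame, see \code{\link{evaluation_summary}}.
#' @export
summarize_calls <- function(results, annotation,
                            analyzable_ids = results$feature_id,
                            species = NA_character_,
                            normalization = NA_character_) {
  res <- results[results$feature_id %in% analyzable_ids, ]
  idx <- match(res$feature_id, annotation$feature_id)
  if (any(is.na(idx))) {
    cgh_stop("summarize_calls: called feature missing from annotation",
             "crosscgh_validation_error")
  }
  is_x <- annotation$is_x[idx]
  tp <- sum(is_x & res$called_excess)
  fn <- sum(is_x & !res$called_excess)
  fp <- sum(!is_x & res$called_excess)
  evaluation_summary(tp, fp, fn, species, normalization,
                     n_autosomal = sum(!is_x))
}

#' Detection proportion by sequence divergence bin
#'
#' X-linked features with a qualifying heterologous top hit are grouped by
#' divergence (100 - top hit percent identity) into bins of
#' \code{bin_width_pct} starting at \code{exclude_below_pct} (low-divergence
#' features below that threshold are excluded, as in the emulated analysis),
#' and the proportion called in excess is reported per bin. Bins with fewer
#' than 5 features are flagged low-support.
#'
#' @param results Per-feature results with \code{called_excess}.
#' @param profile Divergence profile
#'   (\code{\link{derive_divergence_profile}}).
#' @param annotation Feature annotation (for X linkage).
#' @param bin_width_pct Bin width in percentage points.
#' @param exclude_below_pct Lower divergence cut-off.
#' @return Data frame: \code{bin_lo}, \code{bin_hi}, \code{n},
#'   \code{prop_detected}, \code{low_support}.
#' @export
detection_by_divergence <- function(results, profile, annotation,
                                    bin_width_pct = 1.0,
                                    exclude_below_pct = 1.0) {
  idx <- match(results$feature_id, annotation$feature_id)
  pid <- profile$top_hit_pid[match(results$feature_id, profile$feature_id)]
  keep <- annotation$is_x[idx] & !is.na(pid)
  div <- 100 - pid[keep]
  called <- results$called_excess[keep]
  keep2 <- div >= exclude_below_pct
  div <- div[keep2]; called <- called[keep2]
  if (length(div) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      n = integer(0), prop_detected = numeric(0),
                      low_support = logical(0)))
  }
  bin_lo <- exclude_below_pct +
    floor((div - exclude_below_pct) / bin_width_pct) * bin_width_pct
  agg_n <- table(bin_lo)
  agg_d <- tapply(called, bin_lo, sum)
  lo <- as.numeric(names(agg_n))
  data.frame(bin_lo = lo, bin_hi = lo + bin_width_pct,
             n = as.integer(agg_n),
             prop_detected = as.numeric(agg_d) / as.integer(agg_n),
             low_support = as.integer(agg_n) < 5L,
             stringsAsFactors = FALSE)
}

#' Classify erroneous calls into confounder categories
#'
#' False negatives (X features not called) are attributed to: no heterologous
#' hit (\code{no_hit}), heterologous hits only on autosomes
#' (\code{autosomal_only}), hits to heterochromatin or telomeric windows
#' (\code{tel_het}), no hit to the platform genome itself
#' (\code{ref_not_found}), or more platform than heterologous hit regions
#' (\code{ref_hits_gt_het}, hit ratio < 1). False positives (autosomal
#' features called) are attributed to: a heterologous hit on the X
#' (\code{het_x_hit}), heterochromatin/telomere hits (\code{tel_het}), or
#' more heterologous than platform hits (\code{het_hits_gt_ref}, hit ratio >
#' 1). The total explained is the size of the UNION of the category sets —
#' features in several categories are not double-counted.
#'
#' @param error_ids Feature ids of the errors in the given direction.
#' @param direction \code{"false_negative"} or \code{"false_positive"}.
#' @param annotation Feature annotation.
#' @param profile Divergence profile covering every error feature.
#' @return List of class \code{"confounder_breakdown"}: per-category id sets,
#'   \code{union_count}, \code{total_errors}, \code{explained_fraction},
#'   \code{direction}.
#' @export
classify_error_confounders <- function(error_ids,
                                       direction = c("false_negative",
                                                     "false_positive"),
                                       annotation, profile) {
  direction <- match.arg(direction)
  pi <- match(error_ids, profile$feature_id)
  if (any(is.na(pi))) {
    cgh_stop("classify_error_confounders: error feature missing from profile",
             "crosscgh_internal_error")
  }
  p <- profile[pi, ]
  ai <- match(error_ids, annotation$feature_id)
  is_x <- annotation$is_x[ai]
  if (direction == "false_negative") {
    if (any(!is_x)) {
      cgh_stop("classify_error_confounders: false negatives must be X features",
               "crosscgh_internal_error")
    }
    sets <- list(
      no_hit = error_ids[p$no_hit],
      autosomal_only = error_ids[p$autosomal_only],
      tel_het = error_ids[p$tel_or_het],
      ref_not_found = error_ids[p$ref_not_found],
      ref_hits_gt_het = error_ids[!is.na(p$hit_ratio) & p$hit_ratio < 1])
  } else {
    if (any(is_x)) {
      cgh_stop("classify_error_confounders: false positives must be autosomal features",
               "crosscgh_internal_error")
    }
    sets <- list(
      het_x_hit = error_ids[p$het_x_hit],
      tel_het = error_ids[p$tel_or_het],
      het_hits_gt_ref = error_ids[!is.na(p$hit_ratio) & p$hit_ratio > 1])
  }
  confounder_breakdown(sets, length(error_ids), direction)
}

#' Assemble a confounder breakdown
#'
#' Also usable directly from published-style per-category counts via
#' \code{union_count}: when \code{sets} is NULL the explained union must be
#' given explicitly.
#'
#' @param sets Named list of per-category feature-id vectors (or NULL).
#' @param total_errors Total number of errors in this direction.
#' @param direction Label.
#' @param union_count Explained union size; computed from \code{sets} when
#'   they are given.
#' @return List of class \code{"confounder_breakdown"}.
#' @export
confounder_breakdown <- function(sets = NULL, total_errors,
                                 direction = NA_character_,
                                 union_count = NULL) {
  if (!is.null(sets)) {
    union_count <- length(unique(unlist(sets, use.names = FALSE)))
  }
  if (is.null(union_count)) {
    cgh_stop("confounder_breakdown: need sets or union_count",
             "crosscgh_internal_error")
  }
  if (union_count > total_errors) {
    cgh_stop("confounder_breakdown: explained union exceeds total errors",
             "crosscgh_internal_error")
  }
  structure(list(direction = direction, sets = sets,
                 category_counts = if (is.null(sets)) NULL else lengths(sets),
                 union_count = union_count, total_errors = total_errors,
                 explained_fraction = if (total_errors > 0)
                   union_count / total_errors else NA_real_),
            class = "confounder_breakdown")
}

#' @export
print.confounder_breakdown <- function(x, ...) {
  cat(sprintf("Confounder breakdown (%s): %d of %d explained (%s%%)\n",
              x$direction, x$union_count, x$total_errors,
              if (x$total_errors > 0)
                explained_fraction(x) else "NA"))
  if (!is.null(x$category_counts)) print(x$category_counts)
  invisible(x)
}

#' Explained fraction as a whole percent
#'
#' @param breakdown A \code{"confounder_breakdown"}.
#' @return \code{round(100 * union / total)} half-up; \code{NA} when there
#'   are no errors.
#' @export
explained_fraction <- function(breakdown) {
  if (breakdown$total_errors == 0) return(NA_integer_)
  percent_half_up(breakdown$union_count / breakdown$total_errors)
}

#' Correlation of hybridization ratio with copy-ratio proxy among false
#' negatives
#'
#' Pearson correlation (two-sided p from the t approximation) between the
#' estimated log ratio of false-negative features and a log2 copy-ratio
#' proxy (the heterologous/platform hit-count ratio, or the true copy ratio
#' in simulations).
#'
#' @param coef Estimated mean log2 ratios of the false negatives.
#' @param copy_ratio_proxy Positive copy-ratio proxy (log2 taken internally).
#' @param min_n Minimum number of usable pairs.
#' @return List with \code{r}, \code{p}, \code{n}; \code{r = NA} when not
#'   applicable (too few pairs or zero variance).
#' @export
fn_copy_ratio_correlation <- function(coef, copy_ratio_proxy, min_n = 10) {
  use <- is.finite(coef) & is.finite(copy_ratio_proxy) & copy_ratio_proxy > 0
  x <- coef[use]
  y <- log2(copy_ratio_proxy[use])
  if (length(x) < min_n || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Write evaluation report tables
#'
#' Emits an evaluation-summary table (one row per species x normalization),
#' false-negative and false-positive confounder tables, and the divergence
#' detection curve, all as TSV. Writing is idempotent: identical inputs give
#' byte-identical files.
#'
#' @param summaries Data frame of stacked \code{\link{summarize_calls}} rows.
#' @param fn_breakdown,fp_breakdown \code{"confounder_breakdown"} objects (or
#'   NULL).
#' @param divergence_curve Data frame from
#'   \code{\link{detection_by_divergence}} (or NULL).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
build_report <- function(summaries, fn_breakdown = NULL, fp_breakdown = NULL,
                         divergence_curve = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "evaluation_summary.tsv")
  write_tsv(summaries, p); paths <- c(paths, p)
  breakdown_row <- function(b) {
    cc <- if (is.null(b$category_counts)) list() else as.list(b$category_counts)
    as.data.frame(c(list(direction = b$direction), cc,
                    list(union_explained = b$union_count,
                         total_errors = b$total_errors,
                         explained_pct = explained_fraction(b))),
                  stringsAsFactors = FALSE)
  }
  if (!is.null(fn_breakdown)) {
    p <- file.path(out_dir, "confounders_fn.tsv")
    write_tsv(breakdown_row(fn_breakdown), p); paths <- c(paths, p)
  }
  if (!is.null(fp_breakdown)) {
    p <- file.path(out_dir, "confounders_fp.tsv")
    write_tsv(breakdown_row(fp_breakdown), p); paths <- c(paths, p)
  }
  if (!is.null(divergence_curve)) {
    p <- file.path(out_dir, "divergence_curve.tsv")
    write_tsv(divergence_curve, p); paths <- c(paths, p)
  }
  invisible(paths)
}
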