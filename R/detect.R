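# Per-feature one-sample linear model across replicate arrays with
# empirical-Bayes variance moderation, BH false discovery rate control and
# genomic-excess calls. Dye swap is resolved upstream, so the per-feature
# model is a one-sample mean of orientation-resolved log ratios — equivalent
# to a single-coefficient linear model with a dye-swap design vector.

#' Per-feature means, variances and degrees of freedom
#'
#' @param ma Normalized MA data frame (\code{\link{loess_normalize}}).
#' @param analyzable_ids Features analyzable in this species
#'   (\code{\link{filter_min_arrays}}); every one must be included on at
#'   least two arrays.
#' @return Data frame with \code{feature_id}, \code{coef} (mean log2 ratio),
#'   \code{s2} (unbiased sample variance), \code{df} (arrays used minus 1),
#'   \code{n_arrays} and \code{a_mean} (mean A, for plotting).
#' @export
fit_feature_means <- function(ma, analyzable_ids = unique(ma$feature_id)) {
  use <- ma$included & ma$feature_id %in% analyzable_ids & is.finite(ma$M)
  m <- ma[use, ]
  f <- factor(m$feature_id, levels = sort(unique(m$feature_id)))
  n <- as.integer(table(f))
  if (any(n < 2L)) {
    cgh_stop("fit_feature_means: feature with fewer than 2 included arrays reached the model stage",
             "crosscgh_internal_error")
  }
  sums <- rowsum(m$M, f)
  coef <- as.numeric(sums) / n
  sq <- rowsum(m$M^2, f)
  s2 <- pmax(0, (as.numeric(sq) - n * coef^2) / (n - 1L))
  a_mean <- as.numeric(rowsum(m$A, f)) / n
  data.frame(feature_id = levels(f), coef = coef, s2 = s2,
             df = n - 1L, n_arrays = n, a_mean = a_mean,
             stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Newton iteration solving \code{trigamma(x) = y}, tolerance 1e-8, at most
#' 100 iterations. Used by the moment-matching estimator of the variance
#' prior.
#'
#' @param y Positive target value (vectorized).
#' @return x with \code{trigamma(x) == y}; \code{Inf} for \code{y <= 0}.
#' @export
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y <= 0] <- Inf
  todo <- which(is.finite(y) & y > 0)
  if (length(todo) == 0L) return(out)
  yy <- y[todo]
  # moment-based start: trigamma(x) ~ 1/x + 1/(2 x^2) for large x
  x <- 0.5 + 1 / yy
  for (i in seq_len(100L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  out[todo] <- x
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching of \code{log(s2)} against its theoretical scaled-F /
#' log-chi-square distribution: with true variances drawn from a scaled
#' inverse chi-square prior with \code{d0} degrees of freedom and scale
#' \code{s0_sq}, \code{log s2 - digamma(df/2) + log(df/2)} has mean
#' \code{log s0_sq + digamma(d0/2) - log(d0/2)} and excess variance
#' \code{trigamma(d0/2)} beyond the sampling term \code{trigamma(df/2)}.
#' When the empirical spread does not exceed the sampling variance the prior
#' is degenerate and \code{d0 = Inf}.
#'
#' @param s2 Per-feature sample variances (only \code{s2 > 0} with
#'   \code{df >= 1} are used; at least 50 required).
#' @param df Residual degrees of freedom, recycled if length 1.
#' @return List of class \code{"moderation_prior"} with \code{d0},
#'   \code{s0_sq} and \code{n_used}.
#' @export
estimate_moderation_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  use <- is.finite(s2) & s2 > 0 & df >= 1
  if (all(s2[is.finite(s2)] == 0)) {
    cgh_stop("estimate_moderation_prior: all sample variances are zero",
             "crosscgh_processing_error")
  }
  if (sum(use) < 50L) {
    cgh_stop("estimate_moderation_prior: need at least 50 features with s2 > 0",
             "crosscgh_processing_error")
  }
  z <- log(s2[use])
  d <- df[use]
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1L) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = sum(use)),
            class = "moderation_prior")
}

#' Moderate per-feature variances and compute moderated t and p
#'
#' Posterior variance \code{s2_moderated = (d0 s0_sq + df s2) / (d0 + df)}
#' (\code{s0_sq} when \code{d0 = Inf}), moderated statistic \code{t = coef /
#' sqrt(s2_moderated / n)} and two-sided p from the t distribution with
#' \code{d0 + df} degrees of freedom (normal tail when \code{d0 = Inf}).
#'
#' @param results Data frame from \code{\link{fit_feature_means}}.
#' @param prior A \code{"moderation_prior"}.
#' @param one_sided If TRUE, p is the upper-tail probability (test of excess
#'   only); default two-sided with the direction requirement applied at the
#'   call stage.
#' @return \code{results} with \code{s2_moderated}, \code{t_moderated},
#'   \code{p} appended.
#' @export
moderate <- function(results, prior, one_sided = FALSE) {
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s2m <- rep(prior$s0_sq, nrow(results))
    df_total <- rep(Inf, nrow(results))
  } else if (d0 == 0) {
    s2m <- results$s2
    df_total <- results$df
  } else {
    s2m <- (d0 * prior$s0_sq + results$df * results$s2) / (d0 + results$df)
    df_total <- d0 + results$df
  }
  n <- results$df + 1L
  t_mod <- results$coef / sqrt(s2m / n)
  p <- if (one_sided) {
    stats::pt(t_mod, df = df_total, lower.tail = FALSE)
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  results$s2_moderated <- s2m
  results$t_moderated <- t_mod
  results$p <- p
  results
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment \code{q_(i) = min_(j >= i) p_(j) m / j}, capped at 1,
#' mapped back to input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    cgh_stop("bh_adjust: p-values must lie in [0, 1]", "crosscgh_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call genomic excess
#'
#' A feature is called in genomic excess when its FDR-adjusted q is below
#' \code{alpha} and its coefficient is positive (the test of interest is
#' "greater than zero").
#'
#' @param results Data frame with \code{q} and \code{coef}.
#' @param alpha FDR threshold.
#' @return \code{results} with logical \code{called_excess}.
#' @export
call_excess <- function(results, alpha = 0.1) {
  results$called_excess <- results$q < alpha & results$coef > 0
  results
}

#' Fit the genomic-excess model
#'
#' The central fitting function: per-feature means of orientation-resolved
#' normalized log ratios across replicate arrays, empirical-Bayes variance
#' moderation, moderated-t p-values, BH adjustment and excess calls at the
#' given FDR.
#'
#' @param ma Normalized MA data frame.
#' @param analyzable_ids Features analyzable in this species.
#' @param alpha FDR threshold for calls.
#' @param one_sided Use one-sided (upper-tail) p-values instead of two-sided
#'   with a direction requirement.
#' @return An object of class \code{"cgh_excess_fit"}: list with
#'   \code{results} (per-feature table), \code{prior}, \code{alpha},
#'   \code{one_sided}, and the per-feature M matrix used (\code{m_matrix},
#'   features x arrays, NA where excluded).
#' @seealso \code{\link{summary.cgh_excess_fit}}, \code{\link{gel50}}
#' @export
fit_genomic_excess <- function(ma, analyzable_ids = unique(ma$feature_id),
                               alpha = 0.1, one_sided = FALSE) {
  res <- fit_feature_means(ma, analyzable_ids)
  prior <- estimate_moderation_prior(res$s2, res$df)
  res <- moderate(res, prior, one_sided = one_sided)
  res$q <- bh_adjust(res$p)
  res <- call_excess(res, alpha)

  use <- ma$included & ma$feature_id %in% res$feature_id & is.finite(ma$M)
  m <- ma[use, ]
  mm <- matrix(NA_real_, nrow(res), length(unique(ma$array_id)),
               dimnames = list(res$feature_id, sort(unique(ma$array_id))))
  mm[cbind(match(m$feature_id, res$feature_id),
           match(m$array_id, colnames(mm)))] <- m$M

  structure(list(results = res, prior = prior, alpha = alpha,
                 one_sided = one_sided, m_matrix = mm),
            class = "cgh_excess_fit")
}

#' @export
print.cgh_excess_fit <- function(x, ...) {
  cat("Genomic-excess fit (moderated one-sample t per feature)\n")
  cat(sprintf("  features analyzed : %d\n", nrow(x$results)))
  cat(sprintf("  variance prior    : d0 = %s, s0^2 = %.5g\n",
              format(x$prior$d0, digits = 4), x$prior$s0_sq))
  cat(sprintf("  called in excess  : %d at FDR %s (%s)\n",
              sum(x$results$called_excess), format(x$alpha),
              if (x$one_sided) "one-sided" else "two-sided, coef > 0"))
  invisible(x)
}

#' Summary of a genomic-excess fit
#'
#' @param object A \code{"cgh_excess_fit"}.
#' @param ... Unused.
#' @return A list with the prior, call counts, and quantiles of coef and q.
#' @export
summary.cgh_excess_fit <- function(object, ...) {
  r <- object$results
  out <- list(n_features = nrow(r),
              prior = object$prior,
              alpha = object$alpha,
              n_called = sum(r$called_excess),
              coef_quantiles = stats::quantile(r$coef, c(.05, .25, .5, .75, .95)),
              median_s2 = stats::median(r$s2))
  class(out) <- "summary.cgh_excess_fit"
  out
}

#' @export
print.summary.cgh_excess_fit <- function(x, ...) {
  cat(sprintf("Features: %d; called in excess: %d at FDR %s\n",
              x$n_features, x$n_called, format(x$alpha)))
  cat(sprintf("Prior: d0 = %s, s0^2 = %.5g; median s2 = %.5g\n",
              format(x$prior$d0, digits = 4), x$prior$s0_sq, x$median_s2))
  cat("coef quantiles:\n")
  print(round(x$coef_quantiles, 3))
  invisible(x)
}

#' @export
coef.cgh_excess_fit <- function(object, ...) {
  stats::setNames(object$results$coef, object$results$feature_id)
}

#' @export
residuals.cgh_excess_fit <- function(object, ...) {
  object$m_matrix - object$results$coef
}

#' MA-style plot of a genomic-excess fit
#'
#' Mean log ratio against mean log intensity, excess calls highlighted.
#'
#' @param x A \code{"cgh_excess_fit"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.cgh_excess_fit <- function(x, ...) {
  r <- x$results
  graphics::plot(r$a_mean, r$coef, pch = 16, cex = 0.3,
                 col = ifelse(r$called_excess, "firebrick", "grey50"),
                 xlab = "mean A (log2 intensity)",
                 ylab = "coef (mean log2 ratio)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' GEL50: true log2 ratio at 50\% detection power
#'
#' Monte-Carlo estimate of the log2-ratio level at which the full detection
#' procedure (moderation, BH adjustment, direction-aware call) reaches 50\%
#' power under the fitted variance prior. For each level on a grid, signal
#' features are embedded in a background of null features, per-array ratios
#' are drawn with variances sampled from the prior, and the detection
#' proportion among signal features is recorded; the crossing of 0.5 is
#' located by linear interpolation.
#'
#' @param prior A \code{"moderation_prior"}.
#' @param n_arrays Number of replicate arrays.
#' @param alpha FDR threshold.
#' @param n_sim Features simulated per grid point (10\% signal, 90\% null).
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @param grid Grid of true log2 levels.
#' @return The interpolated 50\%-power level; \code{Inf} with a warning when
#'   detection never reaches 0.5 on the grid.
#' @export
gel50 <- function(prior, n_arrays = 6, alpha = 0.1, n_sim = 2000, seed = 1,
                  grid = seq(0, 1.5, by = 0.1)) {
  det <- vapply(seq_along(grid), function(k) {
    set.seed(seed + k)
    gel50_detection(grid[k], prior, n_arrays, alpha, n_sim)
  }, numeric(1))
  if (all(det < 0.5)) {
    warning("gel50: detection never reaches 50% on the grid")
    return(Inf)
  }
  k <- which(det >= 0.5)[1L]
  if (k == 1L) return(grid[1L])
  d0 <- det[k - 1L]; d1 <- det[k]
  grid[k - 1L] + (0.5 - d0) / (d1 - d0) * (grid[k] - grid[k - 1L])
}

#' @noRd
gel50_detection <- function(mu, prior, n_arrays, alpha, n_sim) {
  n_sig <- max(100L, round(n_sim * 0.1))
  n_null <- n_sim - n_sig
  n_tot <- n_sig + n_null
  d0 <- prior$d0
  s2_true <- if (is.finite(d0)) {
    prior$s0_sq * d0 / stats::rchisq(n_tot, df = d0)
  } else {
    rep(prior$s0_sq, n_tot)
  }
  mu_vec <- c(rep(mu, n_sig), rep(0, n_null))
  m <- matrix(stats::rnorm(n_tot * n_arrays, mean = mu_vec,
                           sd = sqrt(s2_true)),
              nrow = n_tot)
  coef <- rowMeans(m)
  s2 <- apply(m, 1L, stats::var)
  res <- data.frame(feature_id = as.character(seq_len(n_tot)), coef = coef,
                    s2 = s2, df = n_arrays - 1L, stringsAsFactors = FALSE)
  res <- moderate(res, prior)
  res$q <- bh_adjust(res$p)
  res <- call_excess(res, alpha)
  mean(res$called_excess[seq_len(n_sig)])
}
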