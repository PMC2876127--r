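ma_from_matrix <- function(m) {
  # rows = features, cols = arrays
  data.frame(array_id = rep(sprintf("a%d", seq_len(ncol(m))), each = nrow(m)),
             feature_id = rep(sprintf("f%04d", seq_len(nrow(m))), ncol(m)),
             M = as.vector(m), A = 10, included = TRUE,
             stringsAsFactors = FALSE)
}

test_that("per-feature means, variances and degrees of freedom", {
  ma <- ma_from_matrix(rbind(c(1, 1, 1), c(0.8, 1.2, NA)))
  ma$included[is.na(ma$M)] <- FALSE
  res <- fit_feature_means(ma)
  expect_equal(res$coef, c(1, 1))
  expect_equal(res$s2, c(0, 0.08))
  expect_identical(res$df, c(2L, 1L))

  # permuting array order changes nothing
  m <- matrix(rnorm(60), 10, 6)
  r1 <- fit_feature_means(ma_from_matrix(m))
  r2 <- fit_feature_means(ma_from_matrix(m[, c(4, 2, 6, 1, 5, 3)]))
  expect_equal(r1$coef, r2$coef)
  expect_equal(r1$s2, r2$s2)
})

test_that("the moderation prior is recovered from data simulated at known values", {
  set.seed(2024)
  n <- 5000; d0_true <- 4; s0_true <- 0.02; d <- 5
  s2_feature <- s0_true * d0_true / rchisq(n, d0_true)
  s2 <- s2_feature * rchisq(n, d) / d
  prior <- estimate_moderation_prior(s2, d)
  expect_gt(prior$d0, 2.5)
  expect_lt(prior$d0, 6.5)
  expect_lt(abs(prior$s0_sq - s0_true) / s0_true, 0.25)
})

test_that("the prior estimator agrees with the limma fit on shared data", {
  skip_if_not_installed("limma")
  set.seed(7)
  s2 <- 0.05 * 6 / rchisq(2000, 6) * rchisq(2000, 5) / 5
  ours <- estimate_moderation_prior(s2, 5)
  ref <- limma::fitFDist(s2, df1 = 5)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("prior estimation handles degenerate and scaled inputs", {
  expect_error(estimate_moderation_prior(rep(0, 100), 5),
               "all sample variances are zero")
  expect_error(estimate_moderation_prior(rep(0.1, 10), 5), "at least 50")

  # equal positive variances: no excess spread, d0 infinite
  prior <- estimate_moderation_prior(rep(0.1, 100), 5)
  expect_identical(prior$d0, Inf)

  set.seed(5)
  s2 <- rchisq(500, 5) / 5 * 0.03
  p1 <- estimate_moderation_prior(s2, 5)
  p2 <- estimate_moderation_prior(s2 * 7, 5)
  expect_equal(p2$s0_sq, 7 * p1$s0_sq, tolerance = 1e-10)
  expect_equal(p2$d0, p1$d0, tolerance = 1e-10)

  # trigamma inversion is a true inverse
  y <- trigamma(c(0.1, 1, 5, 50))
  expect_equal(trigamma_inverse(y), c(0.1, 1, 5, 50), tolerance = 1e-6)
})

test_that("moderated variance, t and p follow the posterior formulas", {
  res <- data.frame(feature_id = "f", coef = 0.5, s2 = 0.05, df = 5L)
  out <- moderate(res, structure(list(d0 = 4, s0_sq = 0.01),
                                 class = "moderation_prior"))
  expect_equal(out$s2_moderated, (4 * 0.01 + 5 * 0.05) / 9)
  expect_equal(out$t_moderated, 0.5 / sqrt(out$s2_moderated / 6))
  expect_equal(out$p, 2 * pt(-abs(out$t_moderated), df = 9))

  # d0 = 0 limit: ordinary one-sample t
  res2 <- data.frame(feature_id = sprintf("f%d", 1:3),
                     coef = c(0.3, -0.2, 1), s2 = c(0.02, 0.05, 0.1), df = 4L)
  out0 <- moderate(res2, structure(list(d0 = 0, s0_sq = 1),
                                   class = "moderation_prior"))
  expect_equal(out0$s2_moderated, res2$s2)
  expect_equal(out0$t_moderated, res2$coef / sqrt(res2$s2 / 5))
  expect_equal(out0$p, 2 * pt(-abs(out0$t_moderated), df = 4))

  # d0 = Inf limit: common variance, normal tail
  outI <- moderate(res2, structure(list(d0 = Inf, s0_sq = 0.04),
                                   class = "moderation_prior"))
  expect_equal(outI$s2_moderated, rep(0.04, 3))
  expect_equal(outI$p, 2 * pnorm(-abs(outI$t_moderated)))
})

test_that("moderated t matches the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- matrix(rnorm(800 * 5, mean = rep(c(0, 0.8), c(600, 200)), sd = 0.3),
              800, 5)
  res <- fit_feature_means(ma_from_matrix(m))
  prior <- estimate_moderation_prior(res$s2, res$df)
  res <- moderate(res, prior)

  fit <- limma::lmFit(m, design = matrix(1, 5, 1))
  eb <- limma::eBayes(fit)
  ord <- match(res$feature_id, sprintf("f%04d", seq_len(nrow(m))))
  expect_equal(res$t_moderated, as.vector(eb$t)[ord], tolerance = 1e-8)
  expect_equal(res$p, as.vector(eb$p.value)[ord], tolerance = 1e-8)
})

test_that("moderation shrinks the spread of variance estimates", {
  set.seed(31)
  for (i in 1:5) {
    s2 <- 0.05 * 4 / rchisq(500, 4) * rchisq(500, 5) / 5
    res <- data.frame(feature_id = as.character(1:500), coef = 0, s2 = s2,
                      df = 5L)
    prior <- estimate_moderation_prior(s2, 5)
    out <- moderate(res, prior)
    if (is.finite(prior$d0)) {
      expect_lte(var(log(out$s2_moderated)), var(log(s2)))
    }
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # O(m^2) brute-force step-up: q_i = min over ranks j >= rank(i) of p_(j) m / j
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      ri <- which(o == i)
      cand <- vapply(ri:m, function(j) p[o[j]] * m / j, numeric(1))
      q[i] <- min(1, min(cand))
    }
    q
  }
  set.seed(101)
  for (k in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("excess calls require both FDR significance and positive direction", {
  res <- data.frame(q = c(0.05, 0.05, 0.15), coef = c(0.8, -0.8, 2))
  out <- call_excess(res, alpha = 0.1)
  expect_identical(out$called_excess, c(TRUE, FALSE, FALSE))
})

test_that("the fitted model object carries methods and a coherent surface", {
  set.seed(12)
  m <- matrix(rnorm(600 * 4, mean = rep(c(0, 1), c(450, 150)), sd = 0.3),
              600, 4)
  fit <- fit_genomic_excess(ma_from_matrix(m), alpha = 0.1)
  expect_s3_class(fit, "cgh_excess_fit")
  expect_length(coef(fit), 600)
  expect_equal(dim(residuals(fit)), c(600, 4))
  expect_equal(rowMeans(residuals(fit)), rep(0, 600), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_output(print(fit), "called in excess")
  expect_output(print(summary(fit)), "Prior")
  # most planted shifts are recovered
  planted <- fit$results$feature_id %in% sprintf("f%04d", 451:600)
  expect_gt(mean(fit$results$called_excess[planted]), 0.9)
})

test_that("GEL50 behaves as a power summary", {
  prior <- structure(list(d0 = 4, s0_sq = 0.02), class = "moderation_prior")

  # monotone in the prior scale
  g <- vapply(c(0.005, 0.02, 0.08), function(s0) {
    gel50(structure(list(d0 = 4, s0_sq = s0), class = "moderation_prior"),
          n_arrays = 6, n_sim = 1500, seed = 3)
  }, numeric(1))
  expect_true(all(diff(g) >= 0))

  # vanishing noise: the 50% power level collapses to the grid origin
  tiny <- structure(list(d0 = Inf, s0_sq = 1e-10), class = "moderation_prior")
  expect_lte(gel50(tiny, n_arrays = 4, n_sim = 500, seed = 1), 0.1)

  # Monte-Carlo oracle: an independent re-simulation of the detection curve
  oracle_gel50 <- function(prior, n_arrays, alpha, n_per, seed) {
    set.seed(seed)
    grid <- seq(0, 1.5, by = 0.1)
    det <- numeric(length(grid))
    for (k in seq_along(grid)) {
      n_sig <- n_per; n_null <- 9 * n_per
      s2t <- prior$s0_sq * prior$d0 / rchisq(n_sig + n_null, prior$d0)
      mu <- rep(c(grid[k], 0), c(n_sig, n_null))
      mm <- matrix(rnorm((n_sig + n_null) * n_arrays, mu, sqrt(s2t)),
                   ncol = n_arrays)
      cf <- rowMeans(mm)
      s2 <- apply(mm, 1, var)
      s2m <- (prior$d0 * prior$s0_sq + (n_arrays - 1) * s2) /
        (prior$d0 + n_arrays - 1)
      t <- cf / sqrt(s2m / n_arrays)
      p <- 2 * pt(-abs(t), df = prior$d0 + n_arrays - 1)
      q <- p.adjust(p, "BH")
      det[k] <- mean(q[seq_len(n_sig)] < alpha & cf[seq_len(n_sig)] > 0)
    }
    k <- which(det >= 0.5)[1]
    grid[k - 1] + (0.5 - det[k - 1]) / (det[k] - det[k - 1]) * 0.1
  }
  g_pkg <- gel50(prior, n_arrays = 6, alpha = 0.1, n_sim = 8000, seed = 5)
  g_ind <- oracle_gel50(prior, n_arrays = 6, alpha = 0.1, n_per = 800,
                        seed = 17)
  expect_lt(abs(g_pkg - g_ind), 0.03)
})
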