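test_that("rate identities hold exactly for arbitrary counts", {
  set.seed(8)
  for (i in 1:20) {
    tp <- sample(0:3000, 1); fp <- sample(0:800, 1); fn <- sample(0:2500, 1)
    s <- evaluation_summary(tp, fp, fn)
    expect_identical(s$n_x_analyzed, tp + fn)
    if (tp + fn > 0) expect_equal(s$tp_rate + s$fn_rate, 1)
    expect_equal(s$fp_rate * (tp + fp), fp)
  }
  # degenerate: nothing called
  s0 <- evaluation_summary(0, 0, 120)
  expect_identical(s0$fp_rate, 0)
  expect_identical(s0$fn_pct, 100L)
})

test_that("published-style count tables reproduce their whole-percent rates", {
  # counts as printed for a platform species and two heterologous species
  # under conserved-1000, conserved-100 and all-features normalization
  rows <- list(
    list(c(2940, 569, 206), c(93, 16, 7)),
    list(c(1211, 274, 2021), c(37, 18, 63)),
    list(c(804, 662, 2243), c(26, 45, 74)),
    list(c(2921, 614, 225), c(93, 17, 7)),
    list(c(944, 146, 2288), c(29, 13, 71)),
    list(c(522, 307, 2525), c(17, 37, 83)),
    list(c(2916, 372, 230), c(93, 11, 7)),
    list(c(1685, 1079, 1547), c(52, 39, 48)),
    list(c(1698, 3404, 1349), c(56, 67, 44)))
  for (r in rows) {
    s <- evaluation_summary(r[[1]][1], r[[1]][2], r[[1]][3])
    expect_identical(c(s$tp_pct, s$fp_pct, s$fn_pct), as.integer(r[[2]]))
  }
  # half-up percent rounding
  expect_identical(percent_half_up(c(0.165, 0.1649, 0.005, 0)),
                   c(17L, 16L, 1L, 0L))
})

test_that("summarize_calls counts X and autosomal calls against annotation", {
  ann <- tiny_annotation()
  res <- data.frame(feature_id = ann$feature_id,
                    called_excess = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  s <- summarize_calls(res, ann, species = "sp", normalization = "c1000")
  expect_identical(c(s$tp, s$fp, s$fn), c(1L, 1L, 1L))
  expect_equal(s$fp_rate, 0.5)
  expect_equal(s$fp_rate_autosomal, 0.25)

  missing <- res; missing$feature_id[1] <- "ghost"
  expect_error(summarize_calls(missing, ann), "missing from annotation")
})

test_that("divergence binning counts and excludes as specified", {
  n <- 20
  ann <- data.frame(feature_id = sprintf("f%02d", 1:n),
                    is_x = rep(TRUE, n), stringsAsFactors = FALSE)
  pid <- c(99.5,                              # 0.5% divergence: excluded
           rep(98.5, 6), rep(97.2, 8), rep(95.5, 4), NA)
  called <- c(TRUE, rep(c(TRUE, FALSE), 3), rep(TRUE, 8),
              rep(FALSE, 4), TRUE)
  profile <- data.frame(feature_id = ann$feature_id, top_hit_pid = pid,
                        stringsAsFactors = FALSE)
  res <- data.frame(feature_id = ann$feature_id, called_excess = called,
                    stringsAsFactors = FALSE)
  out <- detection_by_divergence(res, profile, ann)
  expect_identical(out$bin_lo, c(1, 2, 4))
  expect_identical(out$n, c(6L, 8L, 4L))
  expect_equal(out$prop_detected, c(3 / 6, 1, 0))
  expect_identical(out$low_support, c(FALSE, FALSE, TRUE))

  # a feature below the exclusion cut and one without a hit never appear
  expect_identical(sum(out$n), 18L)
})

test_that("confounder classification builds the right category sets", {
  ann <- tiny_annotation()
  profile <- data.frame(
    feature_id = c("fx1", "fx2", "fa1", "fa2"),
    top_hit_pid = c(NA, 95, 94, 96),
    n_hits_het = c(0L, 2L, 3L, 1L),
    n_hits_ref = c(1L, 3L, 1L, 2L),
    hit_ratio = c(0, 2 / 3, 3, 0.5),
    no_hit = c(TRUE, FALSE, FALSE, FALSE),
    autosomal_only = c(FALSE, TRUE, FALSE, FALSE),
    het_x_hit = c(FALSE, FALSE, TRUE, FALSE),
    tel_or_het = c(FALSE, TRUE, FALSE, FALSE),
    ref_not_found = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)

  fn <- classify_error_confounders(c("fx1", "fx2"), "false_negative", ann,
                                   profile)
  expect_identical(sort(fn$sets$no_hit), "fx1")
  expect_identical(sort(fn$sets$autosomal_only), "fx2")
  expect_identical(sort(fn$sets$ref_hits_gt_het), c("fx1", "fx2"))
  # union not double-counted
  expect_identical(fn$union_count, 2L)
  expect_identical(fn$total_errors, 2L)

  fp <- classify_error_confounders(c("fa1", "fa2"), "false_positive", ann,
                                   profile)
  expect_identical(fp$sets$het_x_hit, "fa1")
  expect_identical(fp$sets$het_hits_gt_ref, "fa1")
  expect_identical(fp$union_count, 1L)

  expect_error(classify_error_confounders("fa1", "false_negative", ann,
                                          profile), "must be X features")
  expect_error(classify_error_confounders("fx1", "false_positive", ann,
                                          profile), "must be autosomal")
})

test_that("set unions and explained percentages match hand accounting", {
  b <- confounder_breakdown(list(a = c("x", "y"), b = c("y", "z"),
                                 c = character(0)), total_errors = 10)
  expect_identical(b$union_count, 3L)
  expect_identical(explained_fraction(b), 30L)

  # published-style accounting: explained union over total errors
  expect_identical(explained_fraction(confounder_breakdown(
    total_errors = 2021, union_count = 945)), 47L)
  expect_identical(explained_fraction(confounder_breakdown(
    total_errors = 2243, union_count = 508)), 23L)
  expect_identical(explained_fraction(confounder_breakdown(
    total_errors = 274, union_count = 63)), 23L)
  expect_identical(explained_fraction(confounder_breakdown(
    total_errors = 662, union_count = 198)), 30L)

  expect_identical(explained_fraction(confounder_breakdown(
    total_errors = 50, union_count = 0)), 0L)
  expect_true(is.na(explained_fraction(confounder_breakdown(
    total_errors = 0, union_count = 0))))
  expect_error(confounder_breakdown(total_errors = 5, union_count = 6),
               "exceeds total")
})

test_that("false-negative copy-ratio correlation matches closed forms", {
  # exact linearity
  proxy <- 2^seq(-1, 1, length.out = 15)
  out <- fn_copy_ratio_correlation(log2(proxy) * 0.4 + 1, proxy)
  expect_equal(out$r, 1)

  # constant proxy is not applicable
  expect_true(is.na(fn_copy_ratio_correlation(rnorm(15), rep(2, 15))$r))
  expect_true(is.na(fn_copy_ratio_correlation(rnorm(5), 2^rnorm(5))$r))

  # 12-point fixture against a direct covariance/SD computation
  set.seed(9)
  coef <- rnorm(12)
  proxy <- 2^rnorm(12)
  out <- fn_copy_ratio_correlation(coef, proxy)
  x <- coef; y <- log2(proxy)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-10)
  t_hand <- r_hand * sqrt(10 / (1 - r_hand^2))
  expect_equal(out$p, 2 * pt(-abs(t_hand), df = 10), tolerance = 1e-10)
})

test_that("planted confounders are recovered in the right categories", {
  cfg <- sim_config(n_features = 8000, species = "simulans_like", seed = 33)
  out <- suppressMessages(run_pipeline(run_config(sim = cfg)))
  f <- out$experiment$truth$features
  res <- out$fit$results
  prof <- out$profile
  idx <- match(res$feature_id, f$feature_id)
  one_conf <- (f$paralog_family + f$moved_off_x + f$moved_onto_x +
                 f$deleted + f$heterochromatic)[idx] == 1L

  fn_ids <- out$fn_breakdown$sets
  fp_ids <- out$fp_breakdown$sets
  recovery <- function(planted_ids, set_ids) {
    if (length(planted_ids) == 0L) return(NA_real_)
    mean(planted_ids %in% set_ids)
  }
  err_fn <- res$feature_id[f$is_x[idx] & !res$called_excess & one_conf]
  err_fp <- res$feature_id[!f$is_x[idx] & res$called_excess & one_conf]

  planted_del <- intersect(err_fn, f$feature_id[f$deleted])
  planted_moved <- intersect(err_fn, f$feature_id[f$moved_off_x])
  planted_onto <- intersect(err_fp, f$feature_id[f$moved_onto_x])
  r <- c(recovery(planted_del, fn_ids$no_hit),
         recovery(planted_moved, fn_ids$autosomal_only),
         recovery(planted_onto, fp_ids$het_x_hit))
  expect_true(all(r[!is.na(r)] >= 0.95))
  # there must be something to recover in at least two categories
  expect_gte(sum(!is.na(r)), 2L)
})

test_that("report tables are written deterministically", {
  s <- evaluation_summary(10, 3, 5, species = "sp", normalization = "c1000")
  b_fn <- confounder_breakdown(list(no_hit = c("a", "b")), total_errors = 5,
                               direction = "false_negative")
  curve <- data.frame(bin_lo = 1:2, bin_hi = 2:3, n = c(10L, 5L),
                      prop_detected = c(0.5, 0.2),
                      low_support = c(FALSE, FALSE))
  d1 <- file.path(tempfile(), "r1"); d2 <- file.path(tempfile(), "r2")
  p1 <- build_report(s, b_fn, NULL, curve, d1)
  p2 <- build_report(s, b_fn, NULL, curve, d2)
  expect_true(all(file.exists(p1)))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_identical(basename(p1),
                   c("evaluation_summary.tsv", "confounders_fn.tsv",
                     "divergence_curve.tsv"))
})
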