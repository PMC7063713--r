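test_that("group comparison output is order- and eye-label-invariant", {
  coh <- make_cohort(seed = 5)
  gc1 <- group_compare(coh, "DRCL_TAZ", alpha = 0.01)
  perm <- coh[sample(nrow(coh)), ]
  gc2 <- group_compare(perm, "DRCL_TAZ", alpha = 0.01)
  expect_equal(gc1$p_overall, gc2$p_overall, tolerance = 1e-12)
  expect_equal(gc1$pairwise$p_value, gc2$pairwise$p_value,
               tolerance = 1e-12)
  flip <- coh
  flip$eye <- ifelse(flip$eye == "OD", "OS", "OD")
  gc3 <- group_compare(flip, "DRCL_TAZ", alpha = 0.01)
  expect_equal(gc1$pairwise$p_value, gc3$pairwise$p_value,
               tolerance = 1e-12)
  expect_error(group_compare(coh[coh$group != "DON", ], "DRCL_TAZ"),
               NA)
  tiny <- coh[c(1, 40, 80), ]
  expect_error(group_compare(tiny, "DRCL_TAZ"), ">= 2 eyes")
})

test_that("group comparison separates groups drawn at published parameters", {
  # control vs DON has by far the largest effect; it is flagged at the
  # family alpha in the vast majority of replicates, and rejection rates
  # follow the effect sizes
  set.seed(42)
  R <- 60
  hits <- matrix(0, R, 3)
  for (r in seq_len(R)) {
    d <- clustered_groups(means = c(73.9, 70.2, 66.4),
                          sds = c(4.8, 4.4, 7.7))
    gc <- group_compare(d, "y", alpha = 0.01)
    hits[r, ] <- gc$pairwise$significant
  }
  rates <- colMeans(hits)   # control-nonDON, control-DON, nonDON-DON
  expect_gt(rates[2], 0.8)
  expect_gt(rates[2], rates[1])
  expect_gt(rates[1], rates[3])
})

test_that("identical groups yield uniform-ish p-values", {
  set.seed(11)
  ps <- replicate(60, {
    d <- clustered_groups()
    group_compare(d, "y", alpha = 0.05)$p_overall
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("pearson matches cor.test and handles degenerate input", {
  df <- data.frame(a = 1:10, b = 1:10, c = 10:1, k = rep(1, 10))
  expect_equal(pearson(df, "a", "b")$r, 1)
  expect_equal(pearson(df, "a", "c")$r, -1)
  expect_error(pearson(df, "a", "k"), "zero variance")
  expect_error(pearson(df[1:2, ], "a", "b"), ">= 3")
  set.seed(2)
  df2 <- data.frame(x = rnorm(50))
  df2$y <- 0.5 * df2$x + rnorm(50)
  ct <- cor.test(df2$x, df2$y)
  out <- pearson(df2, "x", "y")
  expect_equal(out$r, unname(ct$estimate))
  expect_equal(out$p_value, ct$p.value)
})

test_that("the generated structure-perfusion correlation is recovered", {
  # pooled TAO eyes carry the configured latent correlation between
  # GCC TAZ thickness and SRCL TAZ density
  sp <- cohort_spec(eyes_per_group = c(control = 4, nonDON = 1500,
                                       DON = 1500))
  coh <- make_cohort(sp, seed = 8)
  tao <- coh$group %in% c("nonDON", "DON")
  out <- pearson(coh, "GCC_TAZ", "SRCL_TAZ", subset = tao)
  expect_lt(abs(out$r - 0.312), 0.06)
  expect_lt(out$p_value, 1e-10)
})

test_that("empirical AUC equals pairwise enumeration", {
  expect_equal(as.numeric(empirical_auc(c(1, 2, 3, 10, 11, 12),
                                        c(0, 0, 0, 1, 1, 1))), 1)
  expect_equal(as.numeric(empirical_auc(rep(5, 8),
                                        rep(c(0, 1), 4))), 0.5)
  expect_equal(as.numeric(empirical_auc(c(1, 2, 3, 2, 3, 4),
                                        c(0, 0, 0, 1, 1, 1))),
               7 / 9, tolerance = 1e-12)
  enumerate_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    acc <- 0
    for (p in pos) for (q in neg) {
      acc <- acc + (p > q) + 0.5 * (p == q)
    }
    max(acc, length(pos) * length(neg) - acc) /
      (length(pos) * length(neg))
  }
  set.seed(6)
  for (i in 1:30) {
    s <- sample(1:8, 20, replace = TRUE)    # heavy ties
    l <- sample(c(0, 1), 20, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(as.numeric(empirical_auc(s, l)), enumerate_auc(s, l),
                 tolerance = 1e-12)
  }
  expect_error(empirical_auc(1:5, rep(1, 5)), "both classes")
})

test_that("binormal AUC matches its closed form", {
  expect_equal(binormal_auc(10, 2, 10, 3), 0.5)
  expect_equal(round(binormal_auc(95.2, 10.3, 84.5, 13.4), 3), 0.737)
  expect_equal(round(binormal_auc(100.8, 12.0, 87.2, 15.0), 2), 0.76)
  expect_equal(binormal_auc(0, 1, 1.414214, 1), pnorm(1), tolerance = 1e-6)
})

test_that("composite index degenerates and dominates correctly", {
  set.seed(13)
  n <- 80
  df <- data.frame(
    a = c(rnorm(n, 0), rnorm(n, 1)),
    b = 5,
    pos = rep(c(FALSE, TRUE), each = n))
  comp <- composite_index(df, "a", "b", df$pos)
  single <- single_roc(df, "a", df$pos)
  expect_equal(comp$auc, single$auc, tolerance = 1e-12)
  # two informative predictors: in-sample AUC never below either margin
  for (i in 1:20) {
    df2 <- data.frame(
      a = c(rnorm(n, 0), rnorm(n, 0.8)),
      b = c(rnorm(n, 0), rnorm(n, 0.5)),
      pos = rep(c(FALSE, TRUE), each = n))
    comp2 <- composite_index(df2, "a", "b", df2$pos)
    m <- max(single_roc(df2, "a", df2$pos)$auc,
             single_roc(df2, "b", df2$pos)$auc)
    expect_gte(comp2$auc + 1e-9, m)
  }
})

test_that("composite index of pure noise approaches chance", {
  set.seed(21)
  n <- 2000
  df <- data.frame(a = rnorm(2 * n), b = rnorm(2 * n),
                   pos = rep(c(FALSE, TRUE), each = n))
  comp <- composite_index(df, "a", "b", df$pos)
  expect_lt(abs(comp$auc - 0.5), 0.05)
})

test_that("separation triggers the penalized fallback", {
  df <- data.frame(a = c(1:10, 21:30), b = rnorm(20),
                   pos = rep(c(FALSE, TRUE), each = 10))
  comp <- composite_index(df, "a", "b", df$pos)
  expect_true(comp$separated)
  expect_equal(comp$auc, 1)
  expect_true(all(is.finite(comp$coefficients)))
})

test_that("roc_report emits the configured single and composite rows", {
  coh <- make_cohort(seed = 4)
  rep <- roc_report(coh)
  expect_equal(sum(rep$kind == "single"), 17)
  expect_equal(sum(rep$kind == "composite"), 10)
  comp <- rep[rep$kind == "composite", ]
  # two cutoffs per composite row: one in GCC um, one in RCD %
  gcc_cut <- as.matrix(comp[, grepl("^cutoff_GCC", names(comp))])
  rcd_cut <- as.matrix(comp[, grepl("^cutoff_(SRCL|DRCL)", names(comp))])
  expect_true(all(rowSums(!is.na(gcc_cut)) == 1))
  expect_true(all(rowSums(!is.na(rcd_cut)) == 1))
  expect_true(all(rep$auc >= 0.5 & rep$auc <= 1))
  expect_true(all(rep$sensitivity >= 0 & rep$sensitivity <= 100))
  expect_true(all(rep$specificity >= 0 & rep$specificity <= 100))
  # missing measure -> that row skipped with a warning
  warns <- capture_warnings(
    rep2 <- roc_report(coh[, names(coh) != "DRCL_C6"]))
  expect_true(any(grepl("missing", warns)))
  expect_equal(sum(rep2$kind == "composite"), 5)
})

test_that("tidy and glance methods return one-row summaries", {
  coh <- make_cohort(seed = 9)
  gc <- group_compare(coh, "GCC_TAZ", alpha = 0.01)
  td <- tidy(gc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_true(all(c("estimate", "p_value", "significant") %in% names(td)))
  gl <- glance(gc)
  expect_equal(nrow(gl), 1)
  rr <- single_roc(coh, "GCC_TAZ", coh$group == "DON")
  expect_equal(nrow(tidy(rr)), 1)
  expect_true(glance(rr)$n_positive > 0)
})
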