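# Cohort-level statistics: eye-clustered three-group comparisons,
# Pearson correlations, empirical and binormal ROC/AUC, and the logistic
# composite index. All functions are data-frame-first and return tibbles
# (or classed objects with tidy()/glance() methods).

group_levels <- c("control", "nonDON", "DON")

#' Three-group comparison with eye-cluster-robust inference
#'
#' Fits the group-mean model `measure ~ group` over eyes, tests the
#' overall group effect and the three pairwise contrasts. Because the two
#' eyes of one patient are correlated, standard errors are cluster-robust
#' (CR1/HC1 sandwich estimator clustered on patient, the working
#' assumption being exchangeable within-patient correlation) and the
#' reference distribution is t with (clusters - groups) degrees of
#' freedom. Cohorts with one eye per patient reduce to ordinary one-way
#' ANOVA inference up to the small-sample factor.
#'
#' @param records Data frame of eye records: columns `patient_id`,
#'   `group` (control / nonDON / DON) and the measure column.
#' @param measure Name of the measure column (string).
#' @param alpha Family significance level (0.01 for the thickness/RCD
#'   families, 0.05 for general comparisons).
#' @return Object of class `group_comparison`; see [tidy.group_comparison()].
#' @export
group_compare <- function(records, measure, alpha = 0.01) {
  stopifnot(all(c("patient_id", "group", measure) %in% names(records)))
  df <- records[stats::complete.cases(records[[measure]]), , drop = FALSE]
  df$group <- factor(df$group, levels = intersect(group_levels,
                                                  unique(df$group)))
  counts <- table(df$group)
  if (any(counts < 2)) {
    stop("each group needs >= 2 eyes; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  g <- levels(df$group)
  y <- df[[measure]]
  fit <- lm(y ~ 0 + group, data = df)          # cell-means coding
  V <- sandwich::vcovCL(fit, cluster = df$patient_id, type = "HC1")
  n_cl <- length(unique(df$patient_id))
  dfree <- n_cl - length(g)
  # overall Wald test of equal means
  k <- length(g)
  L <- cbind(diag(k - 1), 0) - cbind(matrix(0, k - 1, 1), diag(k - 1))
  b <- coef(fit)
  W <- drop(t(L %*% b) %*% solve(L %*% V %*% t(L)) %*% (L %*% b)) / (k - 1)
  p_overall <- stats::pf(W, k - 1, dfree, lower.tail = FALSE)
  pairs <- utils::combn(g, 2, simplify = FALSE)
  pair_tbl <- purrr::map_dfr(pairs, function(pr) {
    cvec <- as.numeric(g == pr[1]) - as.numeric(g == pr[2])
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    tibble::tibble(group_a = pr[1], group_b = pr[2], estimate = est,
                   se = se, statistic = tval,
                   p_value = 2 * pt(-abs(tval), dfree))
  })
  pair_tbl$significant <- pair_tbl$p_value < alpha
  summ <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_eyes = dplyr::n(), mean = mean(.data[[measure]]),
                     sd = stats::sd(.data[[measure]]),
                     .groups = "drop")
  structure(list(measure = measure, alpha = alpha, summary = summ,
                 p_overall = p_overall, pairwise = pair_tbl,
                 df = dfree, n_clusters = n_cl),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: overall p = %.4g (alpha = %g)\n",
              x$measure, x$p_overall, x$alpha))
  print(x$pairwise)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble of the three pairwise contrasts with cluster-robust
#'   p-values and the significance flag at the recorded alpha.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, measure = x$measure, .before = 1)
}

#' @rdname tidy.group_comparison
#' @return For `glance()`: one row with the overall Wald-F p-value,
#'   cluster count and residual degrees of freedom.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(measure = x$measure, p_overall = x$p_overall,
                 n_clusters = x$n_clusters, df = x$df, alpha = x$alpha)
}

#' Pearson correlation between two measures
#'
#' @param records Data frame with the two measure columns.
#' @param x_measure,y_measure Column names (strings).
#' @param subset Optional logical vector or expression result selecting
#'   rows (e.g. pooled TAO eyes).
#' @return One-row tibble: r, p_value, n.
#' @export
pearson <- function(records, x_measure, y_measure, subset = NULL) {
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  x <- records[[x_measure]]; y <- records[[y_measure]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in ", if (stats::var(x) == 0) x_measure else y_measure,
         call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(x = x_measure, y = y_measure,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Empirical (Mann--Whitney) AUC
#'
#' Probability that a positive-class score exceeds a negative-class
#' score, ties counted half: the Mann--Whitney U statistic divided by
#' n1 * n0, computed from midranks. Orientation is chosen so the reported
#' AUC is >= 0.5 and recorded in the `direction` attribute (`1` if higher
#' scores indicate the positive class, `-1` otherwise).
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector (TRUE / 1 = positive class).
#' @return AUC in `[0.5, 1]` with attribute `direction`.
#' @export
empirical_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc >= 0.5) 1 else -1
  structure(max(auc, 1 - auc), direction = direction)
}

#' Binormal (normal-theory) AUC
#'
#' Closed-form AUC for two normal score distributions:
#' `pnorm(|mean1 - mean2| / sqrt(sd1^2 + sd2^2))`. Used as the
#' closed-form cross-check of empirical AUCs computed from group
#' means and SDs.
#'
#' @param mean1,sd1 Parameters of one class.
#' @param mean2,sd2 Parameters of the other class.
#' @return AUC in `[0.5, 1)`.
#' @examples
#' binormal_auc(95.2, 10.3, 84.5, 13.4)  # 0.737
#' @export
binormal_auc <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 > 0, sd2 > 0)
  pnorm(abs(mean1 - mean2) / sqrt(sd1^2 + sd2^2))
}

# Youden-optimal operating point of an ROC over fitted probabilities;
# returns index of the optimal threshold, sensitivity/specificity there
youden_point <- function(scores, labels) {
  th <- sort(unique(scores))
  stats_at <- vapply(th, function(t) {
    pred <- scores >= t
    c(sens = sum(pred & labels) / sum(labels),
      spec = sum(!pred & !labels) / sum(!labels))
  }, numeric(2))
  j <- stats_at["sens", ] + stats_at["spec", ] - 1
  best <- which.max(j)
  list(threshold = th[best], sensitivity = stats_at["sens", best],
       specificity = stats_at["spec", best])
}

#' Composite diagnostic index by two-predictor logistic regression
#'
#' Fits `P(positive) = logit^-1(b0 + b1 a + b2 b)` by maximum likelihood,
#' scores each eye by the fitted probability, and reports the AUC of
#' those probabilities with the Youden-optimal operating point. The
#' per-component cutoffs printed alongside are the component values of
#' the observation sitting at the optimal probability threshold
#' (an interpretation of one-cutoff-per-component reporting; set
#' `cutoff_mode = "probability"` to report the probability threshold
#' instead). Complete separation is flagged and the fit refit with a mild
#' ridge penalty on the slopes.
#'
#' @param records Data frame.
#' @param indicator_a,indicator_b Column names of the two indicators.
#' @param positive Logical vector (or column name) marking the positive
#'   class (e.g. DON).
#' @param cutoff_mode `"component"` (default) or `"probability"`.
#' @return Object of class `roc_result`.
#' @export
composite_index <- function(records, indicator_a, indicator_b, positive,
                            cutoff_mode = c("component", "probability")) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (is.character(positive) && length(positive) == 1) {
    positive <- as.logical(records[[positive]])
  }
  a <- records[[indicator_a]]; b <- records[[indicator_b]]
  ok <- stats::complete.cases(a, b, positive)
  a <- a[ok]; b <- b[ok]; y <- positive[ok]
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  d <- data.frame(y = y, a = a, b = b)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ a + b, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  separated <- sep_warn || !isTRUE(fit$converged) ||
    any(abs(coef(fit)[-1]) > 50, na.rm = TRUE)
  if (separated && !anyNA(coef(fit))) {
    # mild ridge fallback: IRLS with quadratic penalty on the slopes
    fit <- suppressWarnings(
      glm(y ~ a + b, data = d, family = binomial(),
          method = ridge_logit_fit(lambda = 1e-2)))
  }
  prob <- as.numeric(predict(fit, type = "response"))
  auc <- empirical_auc(prob, y)
  yp <- youden_point(prob, y)
  at <- which.min(abs(prob - yp$threshold))
  cutoffs <- if (cutoff_mode == "component") {
    setNames(c(a[at], b[at]), c(indicator_a, indicator_b))
  } else {
    c(probability = yp$threshold)
  }
  # p-value for AUC vs 0.5 via the Mann-Whitney normal approximation
  n1 <- sum(y); n0 <- sum(!y)
  z <- (as.numeric(auc) - 0.5) / sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  structure(list(indicators = c(indicator_a, indicator_b),
                 auc = as.numeric(auc),
                 direction = attr(auc, "direction"),
                 cutoffs = cutoffs,
                 sensitivity = 100 * yp$sensitivity,
                 specificity = 100 * yp$specificity,
                 p_value = 2 * pnorm(-abs(z)),
                 coefficients = coef(fit), separated = separated,
                 n_positive = n1, n_negative = n0),
            class = "roc_result")
}

# glm method factory: IRLS with an L2 penalty on non-intercept slopes,
# used only as the separation fallback of composite_index()
ridge_logit_fit <- function(lambda = 1e-2) {
  function(x, y, weights = NULL, start = NULL, etastart = NULL,
           mustart = NULL, offset = NULL, family = binomial(),
           control = list(), intercept = TRUE, singular.ok = TRUE) {
    x <- as.matrix(x)
    p <- ncol(x)
    if (is.null(weights)) weights <- rep(1, NROW(x))
    if (is.null(offset)) offset <- rep(0, NROW(x))
    pen <- diag(c(0, rep(lambda, p - 1)), p)
    beta <- rep(0, p)
    for (it in 1:100) {
      eta <- drop(x %*% beta) + offset
      mu <- family$linkinv(eta)
      w <- weights * mu * (1 - mu)
      z <- eta - offset + (y - mu) / pmax(mu * (1 - mu), 1e-10)
      XtW <- t(x * w)
      beta_new <- solve(XtW %*% x + pen, XtW %*% z)
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- drop(beta_new); break }
      beta <- drop(beta_new)
    }
    eta <- drop(x %*% beta) + offset
    mu <- family$linkinv(eta)
    list(coefficients = setNames(beta, colnames(x)),
         residuals = (y - mu) / pmax(mu * (1 - mu), 1e-10),
         fitted.values = mu, effects = numeric(0), R = diag(p),
         rank = p, qr = qr(x * sqrt(pmax(w, 1e-10))), family = family,
         linear.predictors = eta,
         deviance = sum(family$dev.resids(y, mu, weights)),
         aic = NA_real_, null.deviance = NA_real_, iter = it,
         weights = w, prior.weights = weights, df.residual = NROW(x) - p,
         df.null = NROW(x) - 1, y = y, converged = TRUE, boundary = FALSE)
  }
}

#' Single-indicator ROC
#'
#' Empirical AUC of one measure for positive vs negative class, with the
#' Youden-optimal cutoff in native units and sensitivity/specificity
#' there. Orientation is chosen so AUC >= 0.5 (direction recorded).
#'
#' @inheritParams composite_index
#' @param indicator Column name of the measure.
#' @return Object of class `roc_result`.
#' @export
single_roc <- function(records, indicator, positive) {
  if (is.character(positive) && length(positive) == 1) {
    positive <- as.logical(records[[positive]])
  }
  s <- records[[indicator]]
  ok <- stats::complete.cases(s, positive)
  s <- s[ok]; y <- positive[ok]
  auc <- empirical_auc(s, y)
  dir <- attr(auc, "direction")
  yp <- youden_point(s * dir, y)
  n1 <- sum(y); n0 <- sum(!y)
  z <- (as.numeric(auc) - 0.5) / sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  structure(list(indicators = indicator, auc = as.numeric(auc),
                 direction = dir,
                 cutoffs = setNames(yp$threshold * dir, indicator),
                 sensitivity = 100 * yp$sensitivity,
                 specificity = 100 * yp$specificity,
                 p_value = 2 * pnorm(-abs(z)),
                 coefficients = NULL, separated = FALSE,
                 n_positive = n1, n_negative = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.3f, sens %.0f%%, spec %.0f%% (p = %.3g)\n",
              paste(x$indicators, collapse = " + "), x$auc,
              x$sensitivity, x$specificity, x$p_value))
  invisible(x)
}

#' Tidy an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return One-row tibble: indicators, auc, cutoffs (one column per
#'   component), sensitivity, specificity, p_value.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  out <- tibble::tibble(
    indicator = paste(x$indicators, collapse = " + "),
    auc = x$auc, sensitivity = x$sensitivity,
    specificity = x$specificity, p_value = x$p_value)
  for (i in seq_along(x$cutoffs)) {
    out[[paste0("cutoff_", names(x$cutoffs)[i])]] <- unname(x$cutoffs[i])
  }
  out
}

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, direction = x$direction,
                 n_positive = x$n_positive, n_negative = x$n_negative,
                 separated = x$separated, p_value = x$p_value)
}

#' Full ROC report: single indicators and composite indices
#'
#' Emits the single-indicator AUCs (GCC thickness: TAZ, S, T, I, N; SRCL
#' and DRCL RCD: TAZ, C6, S, T, I, N) separating DON eyes from controls,
#' and the ten composite rows pairing each GCC region with the C6 RCD of
#' each capillary layer.
#'
#' @param records Wide eye-record data frame (one row per eye) with
#'   measure columns named `<layer>_<region>`, e.g. `GCC_TAZ`,
#'   `SRCL_C6`, and a `group` column.
#' @param positive_group Group treated as positive class (default "DON").
#' @param negative_group Reference class (default "control").
#' @return Tibble with one row per ROC (`kind` = single / composite).
#' @export
roc_report <- function(records, positive_group = "DON",
                       negative_group = "control") {
  sub <- records[records$group %in% c(positive_group, negative_group), ,
                 drop = FALSE]
  if (length(unique(sub$group)) < 2) {
    stop("need both ", positive_group, " and ", negative_group, " eyes",
         call. = FALSE)
  }
  pos <- sub$group == positive_group
  singles <- c(paste0("GCC_", c("TAZ", "S", "T", "I", "N")),
               paste0("SRCL_", c("TAZ", "C6", "S", "T", "I", "N")),
               paste0("DRCL_", c("TAZ", "C6", "S", "T", "I", "N")))
  single_rows <- purrr::map_dfr(singles, function(ind) {
    if (!ind %in% names(sub)) {
      warning("measure ", ind, " missing; row skipped")
      return(tibble::tibble())
    }
    dplyr::mutate(tidy(single_roc(sub, ind, pos)), kind = "single")
  })
  pairs <- tidyr::expand_grid(
    gcc = paste0("GCC_", c("TAZ", "S", "T", "I", "N")),
    rcdl = c("SRCL_C6", "DRCL_C6"))
  comp_rows <- purrr::map2_dfr(pairs$gcc, pairs$rcdl, function(gi, ri) {
    if (!all(c(gi, ri) %in% names(sub))) {
      warning("measures ", gi, "/", ri, " missing; row skipped")
      return(tibble::tibble())
    }
    dplyr::mutate(tidy(composite_index(sub, gi, ri, pos)),
                  kind = "composite")
  })
  dplyr::bind_rows(single_rows, comp_rows) |>
    dplyr::relocate("kind")
}
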