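#' Classify cognitive status from domain z-scores
#'
#' A patient is cognitively impaired (CI) when at least `min_domains`
#' cognitive domains fall at or below `threshold` standard deviations of
#' the healthy-control norms (default: z <= -2 on >= 2 of the domains),
#' and cognitively preserved (CP) otherwise.
#'
#' @param domain_z Numeric vector of per-domain z-scores (no missing
#'   values; no imputation is performed).
#' @param threshold Impairment cutoff on the z-scale (default -2,
#'   inclusive).
#' @param min_domains Minimum number of impaired domains (default 2).
#' @return `"CI"` or `"CP"`.
#' @export
classify_cognitive_status <- function(domain_z, threshold = -2, min_domains = 2) {
  if (length(domain_z) < min_domains) {
    stop(sprintf("Need at least %d domains, got %d.", min_domains, length(domain_z)), call. = FALSE)
  }
  if (anyNA(domain_z)) stop("Missing domain z-scores: classification requires complete domains.", call. = FALSE)
  if (sum(domain_z <= threshold) >= min_domains) "CI" else "CP"
}

#' Correlation with two-sided p-value
#'
#' Pearson or Spearman correlation with the two-sided p-value from the
#' exact t transform on n - 2 degrees of freedom (for Spearman, applied to
#' the rank-transformed data). The Pearson/Spearman choice is an explicit
#' argument — typically Spearman for outcomes judged non-normal.
#'
#' @param x,y Numeric vectors, length >= 3, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `method`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Fewer than 3 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("Constant input: correlation undefined.", call. = FALSE)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  res <- pearson_with_p(x, y)
  tibble::tibble(method = method, r = res$r, p = res$p, n = res$n)
}

#' Bonferroni-adjusted significance level
#'
#' Divides the family-wise alpha by the number of tests: 2 tests at
#' alpha = 0.05 give 0.025, 3 group comparisons give 0.0167.
#'
#' @param base_alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests in the family.
#' @return Adjusted per-test alpha.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1, base_alpha > 0, base_alpha < 1)
  base_alpha / n_tests
}

#' Covariate-adjusted group comparison (general linear model)
#'
#' Least-squares linear model of an outcome on a group factor plus
#' covariates. The omnibus group effect is the partial F test of the group
#' dummies given the covariates; adjusted (marginal) group means and all
#' pairwise contrasts are computed on the same fitted model, with
#' unadjusted contrast p-values to be gated by a Bonferroni alpha
#' downstream.
#'
#' @param data Data frame with the outcome, group and covariate columns.
#' @param outcome Name of the outcome column.
#' @param group Name of the group column (coerced to factor).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param pairwise Compute adjusted means and pairwise contrasts (set
#'   `FALSE` to skip, e.g. in large simulation loops that only need the
#'   omnibus test).
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @export
glm_group_compare <- function(data, outcome, group = "group", covariates = c("age", "sex"),
                              pairwise = TRUE) {
  stopifnot(is.data.frame(data), outcome %in% names(data), group %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    stop(sprintf("Covariate column(s) not found: %s.", paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, c(outcome, group, covariates)]), , drop = FALSE]
  d[[group]] <- factor(d[[group]])
  counts <- table(d[[group]])
  if (any(counts < 2)) {
    stop(sprintf("Every group needs >= 2 subjects; got: %s.",
                 paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")), call. = FALSE)
  }
  degenerate_result <- function(reason) {
    warning(sprintf("Degenerate group comparison for '%s': %s. Flagged, not tested.",
                    outcome, reason), call. = FALSE)
    structure(list(outcome = outcome, F = NA_real_, df1 = NA_integer_,
                   df2 = NA_integer_, p = NA_real_, adjusted_means = NULL,
                   pairwise = NULL, covariates = covariates, n = nrow(d),
                   groups = levels(d[[group]]), model = NULL,
                   degenerate = TRUE, reason = reason),
              class = "group_comparison")
  }
  if (stats::var(d[[outcome]]) == 0) {
    return(degenerate_result("outcome has zero variance"))
  }
  rhs_full <- paste(c(group, covariates), collapse = " + ")
  rhs_red <- if (length(covariates) > 0) paste(covariates, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste(outcome, "~", rhs_full))
  f_red <- stats::as.formula(paste(outcome, "~", rhs_red))
  fit <- stats::lm(f_full, data = d)
  X <- stats::model.matrix(fit)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-seq_len(qrX$rank)]
    stop(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- stats::var(d[[outcome]]) * (nrow(d) - 1)
  if (rss <= 1e-12 * tss) {
    return(degenerate_result("model fits the outcome perfectly (zero residual variance)"))
  }
  fit_red <- stats::lm(f_red, data = d)
  an <- stats::anova(fit_red, fit)
  Fstat <- an$F[2]
  p <- an$`Pr(>F)`[2]
  if (!is.finite(Fstat) || Fstat < 0) {
    # group sum of squares is zero up to round-off (identical group means)
    Fstat <- 0; p <- 1
  }
  df1 <- an$Df[2]
  df2 <- an$Res.Df[2]

  adjusted_means <- NULL
  pairwise_tbl <- NULL
  if (pairwise) {
    emm <- emmeans::emmeans(fit, specs = group)
    adjusted_means <- tibble::as_tibble(as.data.frame(emm)) |>
      dplyr::rename(group = !!rlang::sym(group), adjusted_mean = "emmean")
    ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    pairwise_tbl <- tibble::tibble(
      contrast = as.character(ctr$contrast),
      estimate = ctr$estimate, se = ctr$SE, df = ctr$df,
      t = ctr$t.ratio, p = ctr$p.value
    )
  }
  structure(list(
    outcome = outcome, F = Fstat, df1 = df1, df2 = df2, p = p,
    adjusted_means = adjusted_means, pairwise = pairwise_tbl,
    covariates = covariates, n = nrow(d), groups = levels(d[[group]]), model = fit,
    degenerate = FALSE, reason = NA_character_
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s ~ group%s%s\n", x$outcome,
              if (length(x$covariates)) " + " else "", paste(x$covariates, collapse = " + ")))
  if (isTRUE(x$degenerate)) {
    cat(sprintf("  degenerate: %s (n = %d)\n", x$reason, x$n))
    return(invisible(x))
  }
  cat(sprintf("  omnibus F(%d, %d) = %.4g, p = %.4g (n = %d)\n", x$df1, x$df2, x$F, x$p, x$n))
  if (!is.null(x$pairwise)) {
    for (k in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %s: diff = %.4g, p = %.4g\n",
                  x$pairwise$contrast[k], x$pairwise$estimate[k], x$pairwise$p[k]))
    }
  }
  invisible(x)
}

#' ROC analysis of a candidate biomarker
#'
#' Rank-based (Mann-Whitney) estimate of the area under the ROC curve for
#' separating two classes, with ties counted 0.5. Orientation is fixed:
#' higher scores predict the positive class, and the AUC is reported as-is
#' (values below 0.5 are not flipped). The two-sided p-value against
#' AUC = 0.5 uses the Hanley-McNeil standard error evaluated under the
#' null; an optional permutation p is available. The optimal cutoff
#' maximizes sensitivity + specificity (prediction rule: score >= cutoff
#' is positive), ties broken toward the lower threshold.
#'
#' @param scores Numeric biomarker values.
#' @param labels Class labels, same length as `scores`.
#' @param positive Label of the positive class (default `"CI"`).
#' @param n_permutations If > 0, additionally compute a label-permutation
#'   p-value with this many draws.
#' @return An object of class `roc_result`; see [tidy()]/[glance()].
#' @export
roc_analysis <- function(scores, labels, positive = "CI", n_permutations = 0) {
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.character(labels)[ok]
  is_pos <- labels == positive
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  if (n1 == 0 || n2 == 0) {
    stop(sprintf("Both classes must be non-empty (positive '%s': %d, other: %d).",
                 positive, n1, n2), call. = FALSE)
  }
  auc_of <- function(pos_flag) {
    r <- rank(scores)
    (sum(r[pos_flag]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  }
  auc <- auc_of(is_pos)
  # Hanley-McNeil variance with A, Q1, Q2 evaluated under the null A = 0.5.
  se0 <- sqrt((0.25 + (n1 + n2 - 2) / 12) / (n1 * n2))
  z <- (auc - 0.5) / se0
  p <- 2 * stats::pnorm(-abs(z))
  p_perm <- NA_real_
  if (n_permutations > 0) {
    null_auc <- replicate(n_permutations, auc_of(sample(is_pos)))
    p_perm <- (1 + sum(abs(null_auc - 0.5) >= abs(auc - 0.5))) / (n_permutations + 1)
  }
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(cut) mean(scores[is_pos] >= cut), numeric(1))
  spec <- vapply(cand, function(cut) mean(scores[!is_pos] < cut), numeric(1))
  best <- which.max(sens + spec)   # first index = lowest threshold on ties
  curve <- tibble::tibble(cutoff = cand, sensitivity = sens, specificity = spec)
  structure(list(
    auc = auc, p = p, z = z, p_permutation = p_perm,
    cutoff = cand[best], sensitivity = sens[best], specificity = spec[best],
    n_positive = n1, n_negative = n2, positive = positive, curve = curve
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (p = %.3g vs 0.5), positive = %s (n = %d vs %d)\n",
              x$auc, x$p, x$positive, x$n_positive, x$n_negative))
  cat(sprintf("  optimal cutoff %.4g: sensitivity %.2f, specificity %.2f\n",
              x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}
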