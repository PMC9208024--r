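#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a covariate-adjusted group comparison
#'
#' @param x A `group_comparison` from [glm_group_compare()].
#' @param ... Unused.
#' @return Tibble of pairwise contrasts (estimate, se, t, unadjusted p);
#'   empty when the comparison was fitted with `pairwise = FALSE`.
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble::tibble(contrast = character(0), estimate = numeric(0),
                          se = numeric(0), df = numeric(0), t = numeric(0),
                          p = numeric(0)))
  }
  x$pairwise
}

#' @rdname tidy.group_comparison
#' @return For `glance()`: one row with the omnibus F test and model
#'   metadata.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, F = x$F, df1 = x$df1, df2 = x$df2,
                 p = x$p, n = x$n,
                 covariates = paste(x$covariates, collapse = "+"))
}

#' Tidy a ROC analysis
#'
#' @param x A `roc_result` from [roc_analysis()].
#' @param ... Unused.
#' @return The ROC curve: one row per candidate cutoff with sensitivity
#'   and specificity.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @return For `glance()`: one row with AUC, p, optimal cutoff and its
#'   sensitivity/specificity.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, p = x$p, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

#' Tidy a pipeline results bundle
#'
#' @param x An `sfc_results` from [run_pipeline()].
#' @param ... Unused.
#' @return The combined [results_table()].
#' @export
tidy.sfc_results <- function(x, ...) results_table(x)

#' @rdname tidy.sfc_results
#' @return For `glance()`: one row summarising cohort size, gated bands,
#'   significant coupling measures and seed.
#' @export
glance.sfc_results <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    q1_mm = x$thresholds$q1, q3_mm = x$thresholds$q3,
    gated_bands = paste(x$gated_bands, collapse = "+"),
    significant_coupling = paste(x$coupling_significant, collapse = "+"),
    n_tests = nrow(results_table(x)), seed = x$seed
  )
}
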