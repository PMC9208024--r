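#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a functional connectivity matrix
#'
#' Heatmap of the node x node AECc matrix.
#'
#' @param object An `fc_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = rownames(m) %||% as.character(seq_len(nrow(m))),
                           col = colnames(m) %||% as.character(seq_len(ncol(m))))
  df$value <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (isTRUE(attr(object, "rescaled"))) "AECc (rescaled)" else "AECc") +
    ggplot2::labs(title = sprintf("Functional connectivity (%s band)", attr(object, "band")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity with the
#'   optimal cutoff marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point", x = 1 - object$specificity, y = object$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::labs(title = sprintf("ROC: AUC = %.3f (p = %.3g)", object$auc, object$p),
                  subtitle = sprintf("optimal cutoff %.3g (sens %.2f, spec %.2f)",
                                     object$cutoff, object$sensitivity, object$specificity),
                  x = "1 - specificity", y = "sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot per-subject coupling by group
#'
#' Boxplots of within-subject structure-function coupling per edge class
#' and group, one dot per subject.
#'
#' @param object An `sfc_results` from [run_pipeline()].
#' @param band Band to plot (default: first gated band).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfc_results <- function(object, band = NULL, ...) {
  if (is.null(object$coupling)) stop("No coupling values in this results bundle (no band passed the gate).", call. = FALSE)
  band <- band %||% object$gated_bands[1]
  d <- dplyr::filter(object$coupling, .data$band == !!band, !is.na(.data$r))
  d$group <- factor(d$group, levels = c("HC", "CP", "CI"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$r, colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~ .data$class) +
    ggplot2::labs(title = sprintf("Structure-function coupling (%s band)", band),
                  x = NULL, y = "within-subject coupling (Pearson r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Histogram of tract lengths with quartile cutoffs
#'
#' @param cohort An `sfc_cohort` (healthy-control edges are pooled), or a
#'   list of [structural_connectome()] objects.
#' @param thresholds Optional [range_thresholds()] to mark; default:
#'   pooled quartiles of the supplied connectomes.
#' @return A ggplot.
#' @export
plot_tract_lengths <- function(cohort, thresholds = NULL) {
  scs <- if (inherits(cohort, "sfc_cohort")) {
    cohort$connectomes[cohort$subjects$id[cohort$subjects$group == "HC"]]
  } else cohort
  pooled <- unlist(lapply(scs, function(sc) {
    len <- edge_vector(sc$lengths)
    len[edge_vector(sc$fa) > 0]
  }), use.names = FALSE)
  thresholds <- thresholds %||% quartile_thresholds(scs)
  ggplot2::ggplot(tibble::tibble(length_mm = pooled), ggplot2::aes(x = .data$length_mm)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(thresholds$q1, thresholds$q3), linetype = "dashed") +
    ggplot2::labs(title = "Pooled healthy-control tract lengths",
                  subtitle = sprintf("short < %.1f mm (Q1), long > %.1f mm (Q3)",
                                     thresholds$q1, thresholds$q3),
                  x = "tract length (mm)", y = "edges") +
    ggplot2::theme_minimal()
}
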