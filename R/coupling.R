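# Pearson r with the two-sided p-value from the exact t transform,
# t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
pearson_with_p <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  list(r = r, p = p, n = n)
}

#' Within-subject structure-function coupling
#'
#' Pearson correlation between a subject's structural (FA) and functional
#' (FC) edge-weight vectors over one edge class. The two vectors must come
#' from the same fixed edge ordering (row-major upper triangle restricted
#' to the class, as produced by [mask_fc_by_structure()]).
#'
#' @param sc_vector,fc_vector Equal-length numeric edge-value vectors.
#' @param subject_id,class,band Identifiers carried into the result.
#' @param min_edges Minimum number of edges for a reported value (default
#'   3); below this the coupling is a flagged missing value.
#' @return One-row tibble: `subject_id`, `class`, `band`, `r`, `n_edges`.
#' @export
within_subject_coupling <- function(sc_vector, fc_vector, subject_id = NA_character_,
                                    class = NA_character_, band = NA_character_,
                                    min_edges = 3) {
  if (length(sc_vector) != length(fc_vector)) {
    stop("SC and FC edge vectors differ in length: not the same edge set.", call. = FALSE)
  }
  n <- length(sc_vector)
  if (n < min_edges) {
    warning(sprintf("Only %d edges (< %d): coupling reported as missing for subject %s.",
                    n, min_edges, subject_id), call. = FALSE)
    r <- NA_real_
  } else {
    if (stats::sd(sc_vector) == 0) stop("Constant SC edge vector: coupling undefined (SC side).", call. = FALSE)
    if (stats::sd(fc_vector) == 0) stop("Constant FC edge vector: coupling undefined (FC side).", call. = FALSE)
    r <- stats::cor(sc_vector, fc_vector)
  }
  tibble::tibble(subject_id = as.character(subject_id), class = as.character(class),
                 band = as.character(band), r = r, n_edges = n)
}

#' Per-subject mean SC and FC by edge class
#'
#' For every subject, band and edge class, averages the FA values and the
#' FC values over the subject's structurally present edges of that class.
#' These subject-level means are the inputs to the between-subject
#' correlations.
#'
#' @param subjects Tibble with at least `id` and `group` columns.
#' @param connectomes Named list of [structural_connectome()] per subject.
#' @param fc Named list per subject of named lists per band of
#'   `fc_matrix` objects.
#' @param masks Named list of `edge_class_mask` per subject (subject
#'   presence intersected with group-level length thresholds).
#' @param classes Edge classes to tabulate.
#' @return Tidy tibble: `id`, `group`, `band`, `class`, `mean_sc`,
#'   `mean_fc`, `n_edges`.
#' @export
subject_class_means <- function(subjects, connectomes, fc, masks,
                                classes = c("whole", "short", "long")) {
  stopifnot(all(c("id", "group") %in% names(subjects)))
  purrr::map_dfr(seq_len(nrow(subjects)), function(k) {
    id <- subjects$id[k]
    mask <- masks[[id]]
    sc <- connectomes[[id]]
    purrr::map_dfr(names(fc[[id]]), function(band_name) {
      purrr::map_dfr(classes, function(cl) {
        n_in <- sum(switch(cl, whole = mask$present, short = mask$short, long = mask$long))
        if (n_in == 0) {
          return(tibble::tibble(id = id, group = subjects$group[k], band = band_name,
                                class = cl, mean_sc = NA_real_, mean_fc = NA_real_,
                                n_edges = 0L))
        }
        tibble::tibble(
          id = id, group = subjects$group[k], band = band_name, class = cl,
          mean_sc = mean(mask_fc_by_structure(sc$fa, mask, cl)),
          mean_fc = mean(mask_fc_by_structure(fc[[id]][[band_name]], mask, cl)),
          n_edges = as.integer(n_in)
        )
      })
    })
  })
}

#' Between-subject correlation of average SC and FC
#'
#' Correlates subject-level mean SC against subject-level mean FC across
#' the subjects of one group (Pearson, two-sided p from the t transform):
#' one coefficient per group describing whether individual differences in
#' global structural and functional connectivity move together.
#'
#' @param means Tibble from [subject_class_means()], or any tibble with
#'   `mean_sc` and `mean_fc` columns (plus optional `group`, `band`,
#'   `class` columns used for filtering/labeling).
#' @param class,band,group Optional filters applied before correlating.
#' @param min_subjects Minimum subjects with complete means (default 3).
#' @return One-row tibble: `group`, `class`, `band`, `r`, `p`,
#'   `n_subjects`.
#' @export
between_subject_correlation <- function(means, class = NULL, band = NULL, group = NULL,
                                        min_subjects = 3) {
  d <- means
  if (!is.null(class) && "class" %in% names(d)) d <- dplyr::filter(d, .data$class == !!class)
  if (!is.null(band) && "band" %in% names(d)) d <- dplyr::filter(d, .data$band == !!band)
  if (!is.null(group) && "group" %in% names(d)) d <- dplyr::filter(d, .data$group %in% !!group)
  d <- dplyr::filter(d, is.finite(.data$mean_sc), is.finite(.data$mean_fc))
  if (nrow(d) < min_subjects) {
    stop(sprintf("Only %d subjects with defined means (< %d).", nrow(d), min_subjects), call. = FALSE)
  }
  if (stats::sd(d$mean_sc) == 0) stop("Zero variance in subject-mean SC.", call. = FALSE)
  if (stats::sd(d$mean_fc) == 0) stop("Zero variance in subject-mean FC.", call. = FALSE)
  res <- pearson_with_p(d$mean_sc, d$mean_fc)
  tibble::tibble(
    group = if (!is.null(group)) paste(group, collapse = "+") else "all",
    class = class %||% NA_character_, band = band %||% NA_character_,
    r = res$r, p = res$p, n_subjects = res$n
  )
}

#' Cross-range between-subject correlation
#'
#' Correlates mean SC over one edge class against mean FC over another
#' (e.g. short-range FC vs long-range SC), across subjects of one group —
#' a specificity check on the short/long stratification.
#'
#' @param means Tibble from [subject_class_means()].
#' @param sc_class Edge class supplying the SC averages.
#' @param fc_class Edge class supplying the FC averages.
#' @inheritParams between_subject_correlation
#' @return One-row tibble: `group`, `sc_class`, `fc_class`, `band`, `r`,
#'   `p`, `n_subjects`.
#' @export
cross_range_correlation <- function(means, sc_class, fc_class, band = NULL, group = NULL,
                                    min_subjects = 3) {
  d <- means
  if (!is.null(band)) d <- dplyr::filter(d, .data$band == !!band)
  if (!is.null(group)) d <- dplyr::filter(d, .data$group %in% !!group)
  sc_side <- dplyr::filter(d, .data$class == !!sc_class) |>
    dplyr::select("id", "band", sc = "mean_sc")
  fc_side <- dplyr::filter(d, .data$class == !!fc_class) |>
    dplyr::select("id", "band", fc = "mean_fc")
  dd <- dplyr::inner_join(sc_side, fc_side, by = c("id", "band")) |>
    dplyr::filter(is.finite(.data$sc), is.finite(.data$fc))
  if (nrow(dd) < min_subjects) {
    stop(sprintf("Only %d subjects with defined means (< %d).", nrow(dd), min_subjects), call. = FALSE)
  }
  if (stats::sd(dd$sc) == 0 || stats::sd(dd$fc) == 0) stop("Zero variance in one of the averages.", call. = FALSE)
  res <- pearson_with_p(dd$sc, dd$fc)
  tibble::tibble(
    group = if (!is.null(group)) paste(group, collapse = "+") else "all",
    sc_class = sc_class, fc_class = fc_class, band = band %||% NA_character_,
    r = res$r, p = res$p, n_subjects = res$n
  )
}
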