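#' Run the full structure-function coupling analysis
#'
#' Executes the analysis chain on a cohort, in the study's order:
#' (1) per-subject sparsity and short/long connection-count group checks;
#' (2) between-subject whole-brain SC-FC correlations per band, within
#' healthy controls and patients separately; (3) band gating — only bands
#' with a significant whole-brain relation in either group proceed;
#' (4) short/long between-subject correlations in gated bands (2-test
#' Bonferroni); (5) within-subject coupling compared between HC/CP/CI with
#' a covariate-adjusted GLM (omnibus at the 2-test alpha, pairwise at the
#' 3-comparison alpha); (6) correlations of surviving coupling measures
#' with cognitive domain scores among patients; (7) separate SC and FC
#' group comparisons within surviving classes; (8) ROC analyses of
#' whole/short/long coupling for classifying cognitive impairment among
#' patients; (9) post hoc cross-range and FC-vs-FC correlations (and
#' relative power when time series are available). Skipped gated stages
#' are logged, not silently absent.
#'
#' @param cohort An `sfc_cohort` (from [generate_cohort()] or
#'   [read_cohort()]) or a cohort directory path. If the cohort carries
#'   time series instead of FC matrices, FC is computed via [fc_matrix()]
#'   for every band first.
#' @param quartile_overrides Optional [range_thresholds()] to use instead
#'   of pooled healthy-control quartiles.
#' @param alpha Family-wise significance level (default 0.05).
#' @param gate_alpha Raw alpha for the band gate (default 0.05).
#' @param presence_floor Structural presence threshold on FA (default 0).
#' @param covariates_coupling Covariates for coupling group comparisons
#'   (default age, sex).
#' @param covariates_scfc Covariates for the separate SC/FC group
#'   comparisons (default age, sex, education).
#' @param verbose Print stage progress.
#' @return An object of class `sfc_results`; see [tidy()],
#'   [report_results()] and `autoplot()` methods.
#' @export
run_pipeline <- function(cohort, quartile_overrides = NULL, alpha = 0.05,
                         gate_alpha = 0.05, presence_floor = 0,
                         covariates_coupling = c("age", "sex"),
                         covariates_scfc = c("age", "sex", "education"),
                         verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "sfc_cohort"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  t0 <- proc.time()[["elapsed"]]
  subjects <- cohort$subjects
  subjects$group2 <- ifelse(subjects$group == "HC", "HC", "MS")
  ids <- subjects$id
  bands <- cohort$config$bands
  band_names <- names(bands)

  fc <- cohort$fc
  if (is.null(fc)) {
    if (is.null(cohort$timeseries)) stop("Cohort carries neither FC matrices nor time series.", call. = FALSE)
    say("Computing AECc FC matrices from time series for %d subjects x %d bands ...",
        length(ids), length(bands))
    fc <- stats::setNames(lapply(ids, function(id) {
      stats::setNames(lapply(bands, function(b) fc_matrix(cohort$timeseries[[id]], b)),
                      band_names)
    }), ids)
  }

  # Stage 0: thresholds and per-subject edge-class masks.
  hc_ids <- ids[subjects$group == "HC"]
  thr <- quartile_overrides %||% quartile_thresholds(cohort$connectomes[hc_ids],
                                                     presence_floor = presence_floor)
  say("Stage 0: length thresholds q1 = %.3f mm, q3 = %.3f mm (%s).",
      thr$q1, thr$q3, if (is.null(quartile_overrides)) "pooled HC quartiles" else "override")
  masks <- stats::setNames(lapply(ids, function(id) {
    classify_edges(cohort$connectomes[[id]], thr, presence_floor = presence_floor)
  }), ids)

  # Stage 1: sparsity and connection-count group checks.
  per_subject <- dplyr::mutate(
    subjects,
    sparsity = purrr::map_dbl(ids, ~ sparsity(cohort$connectomes[[.x]], presence_floor)),
    n_short = purrr::map_int(ids, ~ unname(count_range_connections(masks[[.x]])["n_short"])),
    n_long = purrr::map_int(ids, ~ unname(count_range_connections(masks[[.x]])["n_long"]))
  )
  sparsity_test <- glm_group_compare(per_subject, "sparsity", group = "group",
                                     covariates = character(0))
  count_tests <- list(
    n_short = glm_group_compare(per_subject, "n_short", group = "group2", covariates = character(0)),
    n_long = glm_group_compare(per_subject, "n_long", group = "group2", covariates = character(0))
  )
  say("Stage 1: sparsity omnibus F = %.3f (p = %.3f); counts MS-vs-HC p = %.3f (short), %.3f (long).",
      sparsity_test$F, sparsity_test$p, count_tests$n_short$p, count_tests$n_long$p)

  # Stage 2: whole-brain between-subject SC-FC correlations per band.
  means <- subject_class_means(subjects, cohort$connectomes, fc, masks)
  means$group2 <- ifelse(means$group == "HC", "HC", "MS")
  whole_between <- purrr::map_dfr(band_names, function(b) {
    purrr::map_dfr(list("HC", c("CP", "CI")), function(g) {
      out <- between_subject_correlation(means, class = "whole", band = b, group = g)
      out$group <- if (length(g) > 1) "MS" else g
      out
    })
  })

  # Stage 3: band gating.
  gated <- whole_between |>
    dplyr::filter(.data$p < gate_alpha) |>
    dplyr::pull("band") |>
    unique()
  say("Stage 3: band gate (raw p < %.3g in either group) passes: %s.",
      gate_alpha, if (length(gated)) paste(gated, collapse = ", ") else "none")
  for (b in setdiff(band_names, gated)) say("Stage 3: band %s gated out; later stages skipped for it.", b)

  alpha_range <- bonferroni_alpha(alpha, 2)   # short + long analyzed in parallel
  alpha_pair <- bonferroni_alpha(alpha, 3)    # three pairwise group comparisons

  range_between <- NULL
  coupling <- NULL
  coupling_tests <- list()
  coupling_significant <- character(0)
  clinical <- NULL
  sc_fc_tests <- list()
  roc <- list()
  posthoc <- list(cross_range = NULL, fc_vs_fc = NULL, relative_power = NULL)

  if (length(gated) > 0) {
    # Stage 4: short/long between-subject correlations in gated bands.
    range_between <- purrr::map_dfr(gated, function(b) {
      purrr::map_dfr(c("short", "long"), function(cl) {
        purrr::map_dfr(list("HC", c("CP", "CI")), function(g) {
          out <- between_subject_correlation(means, class = cl, band = b, group = g)
          out$group <- if (length(g) > 1) "MS" else g
          out$adjusted_alpha <- alpha_range
          out
        })
      })
    })

    # Stage 5: within-subject coupling and GLM group comparisons.
    coupling <- purrr::map_dfr(ids, function(id) {
      purrr::map_dfr(gated, function(b) {
        purrr::map_dfr(c("whole", "short", "long"), function(cl) {
          sc_v <- mask_fc_by_structure(cohort$connectomes[[id]]$fa, masks[[id]], cl)
          fc_v <- mask_fc_by_structure(fc[[id]][[b]], masks[[id]], cl)
          within_subject_coupling(sc_v, fc_v, subject_id = id, class = cl, band = b)
        })
      })
    })
    coupling <- dplyr::left_join(coupling, subjects, by = c(subject_id = "id"))
    for (b in gated) {
      for (cl in c("short", "long")) {
        d <- dplyr::filter(coupling, .data$band == b, .data$class == cl, !is.na(.data$r))
        key <- paste(b, cl, sep = "_")
        if (length(unique(d$r)) <= 1) {
          say("Stage 5: coupling %s degenerate (no variance across subjects); comparison flagged, not run.", key)
          next
        }
        gc_res <- glm_group_compare(d, "r", group = "group", covariates = covariates_coupling)
        coupling_tests[[key]] <- gc_res
        if (gc_res$p < alpha_range) {
          coupling_significant <- c(coupling_significant, key)
          say("Stage 5: %s coupling omnibus F = %.3f, p = %.4f — significant at alpha = %.3f.",
              key, gc_res$F, gc_res$p, alpha_range)
        } else {
          say("Stage 5: %s coupling omnibus F = %.3f, p = %.4f — not significant; stages 6-7 skipped for it.",
              key, gc_res$F, gc_res$p)
        }
      }
    }

    # Stage 6: clinical correlations for significant coupling measures.
    domain_cols <- c("verbal_memory", "visuospatial_memory", "processing_speed",
                     "working_memory", "verbal_fluency", "executive_function", "attention")
    domain_cols <- intersect(domain_cols, names(subjects))
    if (length(coupling_significant) > 0 && length(domain_cols) > 0) {
      clinical <- purrr::map_dfr(coupling_significant, function(key) {
        b <- sub("_[a-z]+$", "", key); cl <- sub("^.*_", "", key)
        d <- dplyr::filter(coupling, .data$band == b, .data$class == cl,
                           .data$group %in% c("CP", "CI"), !is.na(.data$r))
        purrr::map_dfr(domain_cols, function(dc) {
          res <- correlate(d$r, d[[dc]], method = "pearson")
          tibble::tibble(measure = key, domain = dc, r = res$r, p = res$p, n = res$n)
        })
      })
    }

    # Stage 7: SC and FC group comparisons within surviving classes.
    for (key in coupling_significant) {
      b <- sub("_[a-z]+$", "", key); cl <- sub("^.*_", "", key)
      d <- means |>
        dplyr::filter(.data$band == b, .data$class == cl) |>
        dplyr::left_join(subjects, by = c("id", "group"))
      sc_fc_tests[[paste0(key, "_sc")]] <-
        glm_group_compare(d, "mean_sc", group = "group", covariates = covariates_scfc)
      sc_fc_tests[[paste0(key, "_fc")]] <-
        glm_group_compare(d, "mean_fc", group = "group", covariates = covariates_scfc)
    }

    # Stage 8: ROC analyses of coupling among patients (CI vs CP).
    for (b in gated) {
      for (cl in c("whole", "short", "long")) {
        d <- dplyr::filter(coupling, .data$band == b, .data$class == cl,
                           .data$group %in% c("CP", "CI"), !is.na(.data$r))
        if (length(unique(d$group)) == 2) {
          roc[[paste(b, cl, sep = "_")]] <- roc_analysis(d$r, d$group, positive = "CI")
        } else {
          say("Stage 8: ROC for %s_%s skipped (a class is empty).", b, cl)
        }
      }
    }

    # Stage 9: post hoc specificity checks.
    posthoc$cross_range <- purrr::map_dfr(gated, function(b) {
      purrr::map_dfr(list(c("long", "short"), c("short", "long")), function(pair) {
        purrr::map_dfr(list("HC", c("CP", "CI")), function(g) {
          out <- cross_range_correlation(means, sc_class = pair[1], fc_class = pair[2],
                                         band = b, group = g)
          out$group <- if (length(g) > 1) "MS" else g
          out
        })
      })
    })
    posthoc$fc_vs_fc <- purrr::map_dfr(gated, function(b) {
      ms <- dplyr::filter(means, .data$group2 == "MS", .data$band == b)
      wide <- tidyr::pivot_wider(ms[, c("id", "class", "mean_fc")],
                                 names_from = "class", values_from = "mean_fc")
      purrr::map_dfr(c("short", "long"), function(cl) {
        res <- correlate(wide$whole, wide[[cl]], method = "pearson")
        tibble::tibble(band = b, comparison = paste0("whole_fc_vs_", cl, "_fc"),
                       r = res$r, p = res$p, n = res$n)
      })
    })
    if (!is.null(cohort$timeseries)) {
      posthoc$relative_power <- purrr::map_dfr(gated, function(b) {
        rp <- purrr::map_dbl(ids, ~ relative_power(cohort$timeseries[[.x]], bands[[b]]))
        wb_sc <- purrr::map_dbl(ids, ~ whole_brain_sc(cohort$connectomes[[.x]],
                                                      presence_floor = presence_floor))
        res <- correlate(rp, wb_sc, method = "pearson")
        tibble::tibble(band = b, comparison = "relative_power_vs_sc",
                       r = res$r, p = res$p, n = res$n)
      })
    } else {
      say("Stage 9: relative-power check skipped (cohort has no time series).")
    }
  }

  say("Pipeline finished in %.1f s.", proc.time()[["elapsed"]] - t0)
  structure(list(
    subjects = per_subject, thresholds = thr,
    sparsity_test = sparsity_test, count_tests = count_tests,
    whole_between = whole_between, gated_bands = gated,
    range_between = range_between, coupling = coupling,
    coupling_tests = coupling_tests, coupling_significant = coupling_significant,
    clinical = clinical, sc_fc_tests = sc_fc_tests, roc = roc, posthoc = posthoc,
    alpha = alpha, alpha_range = alpha_range, alpha_pairwise = alpha_pair,
    gate_alpha = gate_alpha, log = log,
    config_hash = rlang::hash(cohort$config), seed = cohort$config$seed
  ), class = "sfc_results")
}

#' @export
print.sfc_results <- function(x, ...) {
  cat("<sfc_results>\n")
  cat(sprintf("  cohort: %d subjects; config hash %s; seed %d\n",
              nrow(x$subjects), substr(x$config_hash, 1, 8), x$seed))
  cat(sprintf("  thresholds: short < %.3f mm, long > %.3f mm\n",
              x$thresholds$q1, x$thresholds$q3))
  cat(sprintf("  gated bands: %s\n",
              if (length(x$gated_bands)) paste(x$gated_bands, collapse = ", ") else "none"))
  for (key in names(x$coupling_tests)) {
    ct <- x$coupling_tests[[key]]
    cat(sprintf("  coupling %s: F = %.3f, p = %.4f%s\n", key, ct$F, ct$p,
                if (key %in% x$coupling_significant) " *" else ""))
  }
  for (key in names(x$roc)) {
    cat(sprintf("  ROC %s: AUC = %.3f (p = %.3f)\n", key, x$roc[[key]]$auc, x$roc[[key]]$p))
  }
  invisible(x)
}

#' Combined results table
#'
#' One row per statistical test in the bundle: statistic, raw p, the
#' alpha it is judged against, and a pass flag — the reporting layout of
#' the analysis.
#'
#' @param results An `sfc_results` object.
#' @return A tibble.
#' @export
results_table <- function(results) {
  stopifnot(inherits(results, "sfc_results"))
  rows <- list()
  add <- function(analysis, statistic, value, p, alpha) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      analysis = analysis, statistic = statistic, value = value, p = p,
      adjusted_alpha = alpha, significant = is.finite(p) & p < alpha)
  }
  add("sparsity_group", "F", results$sparsity_test$F, results$sparsity_test$p, results$alpha)
  for (nm in names(results$count_tests)) {
    add(paste0("count_", nm), "F", results$count_tests[[nm]]$F,
        results$count_tests[[nm]]$p, results$alpha)
  }
  for (k in seq_len(nrow(results$whole_between))) {
    w <- results$whole_between[k, ]
    add(sprintf("between_whole_%s_%s", w$band, w$group), "r", w$r, w$p, results$gate_alpha)
  }
  if (!is.null(results$range_between)) {
    for (k in seq_len(nrow(results$range_between))) {
      w <- results$range_between[k, ]
      add(sprintf("between_%s_%s_%s", w$class, w$band, w$group), "r", w$r, w$p,
          results$alpha_range)
    }
  }
  for (key in names(results$coupling_tests)) {
    ct <- results$coupling_tests[[key]]
    add(paste0("coupling_omnibus_", key), "F", ct$F, ct$p, results$alpha_range)
    if (!is.null(ct$pairwise) && key %in% results$coupling_significant) {
      for (k in seq_len(nrow(ct$pairwise))) {
        add(sprintf("coupling_pairwise_%s_%s", key, gsub(" ", "", ct$pairwise$contrast[k])),
            "diff", ct$pairwise$estimate[k], ct$pairwise$p[k], results$alpha_pairwise)
      }
    }
  }
  if (!is.null(results$clinical)) {
    for (k in seq_len(nrow(results$clinical))) {
      cc <- results$clinical[k, ]
      add(sprintf("clinical_%s_%s", cc$measure, cc$domain), "r", cc$r, cc$p, results$alpha)
    }
  }
  for (key in names(results$sc_fc_tests)) {
    ct <- results$sc_fc_tests[[key]]
    add(paste0("group_", key), "F", ct$F, ct$p, results$alpha)
  }
  for (key in names(results$roc)) {
    add(paste0("roc_", key), "AUC", results$roc[[key]]$auc, results$roc[[key]]$p, results$alpha)
  }
  if (!is.null(results$posthoc$cross_range)) {
    for (k in seq_len(nrow(results$posthoc$cross_range))) {
      w <- results$posthoc$cross_range[k, ]
      add(sprintf("posthoc_sc_%s_fc_%s_%s_%s", w$sc_class, w$fc_class, w$band, w$group),
          "r", w$r, w$p, results$alpha)
    }
  }
  if (!is.null(results$posthoc$fc_vs_fc)) {
    for (k in seq_len(nrow(results$posthoc$fc_vs_fc))) {
      w <- results$posthoc$fc_vs_fc[k, ]
      add(sprintf("posthoc_%s_%s", w$comparison, w$band), "r", w$r, w$p, results$alpha)
    }
  }
  if (!is.null(results$posthoc$relative_power)) {
    for (k in seq_len(nrow(results$posthoc$relative_power))) {
      w <- results$posthoc$relative_power[k, ]
      add(sprintf("posthoc_relative_power_%s", w$band), "r", w$r, w$p, results$alpha)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write the results bundle to a directory
#'
#' Emits `results.tsv` (the combined [results_table()]), `coupling.tsv`
#' (per-subject coupling values), `subjects.tsv` and a human-readable
#' `report.txt` including the stage log, config hash and seed.
#'
#' @param results An `sfc_results`.
#' @param dir Destination directory.
#' @return `dir`, invisibly.
#' @export
report_results <- function(results, dir) {
  stopifnot(inherits(results, "sfc_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(results_table(results), file.path(dir, "results.tsv"), progress = FALSE)
  if (!is.null(results$coupling)) {
    readr::write_tsv(results$coupling, file.path(dir, "coupling.tsv"), progress = FALSE)
  }
  readr::write_tsv(results$subjects, file.path(dir, "subjects.tsv"), progress = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    "Structure-function coupling analysis report",
    sprintf("config hash: %s   seed: %d", results$config_hash, results$seed),
    sprintf("length thresholds: short < %.3f mm, long > %.3f mm",
            results$thresholds$q1, results$thresholds$q3),
    "", "Stage log:", paste0("  ", results$log)
  ), con)
  invisible(dir)
}
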