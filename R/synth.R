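#' Configuration for a synthetic cohort
#'
#' Defines the study conditions a generated cohort emulates: 78 cortical
#' nodes; healthy controls (HC) and multiple sclerosis patients split into
#' cognitively preserved (CP) and impaired (CI) with the cohort sizes
#' 40/46/33; source-level series sampled at 1250 Hz in 13 concatenated
#' epochs of 16,384 samples; symmetric FA connectomes that decline with
#' tract length, with a planted CI-specific FA deficit on long-range
#' edges; and a planted monotone FA-to-envelope-correlation map whose
#' slope differs by group — the structure-function coupling effect the
#' analysis is meant to recover.
#'
#' @param n_hc,n_cp,n_ci Group sizes (default 40 / 46 / 33).
#' @param n_nodes Cortical nodes (default 78).
#' @param sampling_rate Hz (default 1250).
#' @param n_epochs,epoch_samples Epoch structure (default 13 x 16384).
#' @param length_range Tract-length support in mm (default c(10, 250)).
#' @param fa_base Intercept of the FA-vs-length relation (default 0.62).
#' @param fa_length_slope FA decrease per mm (default 8e-4).
#' @param fa_group_deficit_long FA decrement applied to long-range edges
#'   of CI subjects (default 0.03).
#' @param fa_noise_sd Edgewise FA noise SD (default 0.03).
#' @param subject_fa_sd SD of the per-subject global FA offset (default
#'   0.02); creates the between-subject variation in mean SC.
#' @param zero_fraction Per-edge probability of an absent tract (FA set
#'   to exactly zero; default 0.1).
#' @param coupling_slope_by_group Named map group -> slope of the planted
#'   envelope-correlation target vs FA (default HC 0.05, CP 0.15,
#'   CI 0.30: coupling strongest in CI).
#' @param coupled_bands Band names in which the coupling is planted
#'   (default `"theta"`; other bands get slope 0).
#' @param aec_base Baseline raw envelope correlation on edges (default
#'   0.10).
#' @param fa_center FA value at which the planted target equals
#'   `aec_base` (default 0.5; fixed across subjects so subject-level FA
#'   offsets propagate into mean FC).
#' @param noise_sd Observation noise SD: edgewise noise on planted FC
#'   values, and relative additive noise on simulated series (default
#'   0.05).
#' @param env_sigma Log-scale SD of the lognormal latent envelopes
#'   (default 0.5).
#' @param env_bandwidth Low-pass bandwidth of the latent envelope drivers
#'   in Hz (default 2).
#' @param length_jitter_sd Per-subject tract-length jitter SD in mm
#'   (default 2).
#' @param bands Named list of [frequency_band()]s (default
#'   [default_bands()]).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 40, n_cp = 46, n_ci = 33, n_nodes = 78,
                          sampling_rate = 1250, n_epochs = 13, epoch_samples = 16384,
                          length_range = c(10, 250),
                          fa_base = 0.62, fa_length_slope = 8e-4,
                          fa_group_deficit_long = 0.03, fa_noise_sd = 0.03,
                          subject_fa_sd = 0.02, zero_fraction = 0.1,
                          coupling_slope_by_group = c(HC = 0.05, CP = 0.15, CI = 0.30),
                          coupled_bands = "theta", aec_base = 0.10, fa_center = 0.5,
                          noise_sd = 0.05, env_sigma = 0.5, env_bandwidth = 2,
                          length_jitter_sd = 2, bands = default_bands(), seed = 1L) {
  counts <- c(n_hc = n_hc, n_cp = n_cp, n_ci = n_ci, n_nodes = n_nodes,
              n_epochs = n_epochs, epoch_samples = epoch_samples)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("All counts (group sizes, nodes, epochs, samples) must be positive integers.", call. = FALSE)
  }
  if (n_nodes < 2) stop("Need at least 2 nodes.", call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0.", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] >= length_range[2] || length_range[1] <= 0) {
    stop("`length_range` must be an increasing positive (low, high) pair in mm.", call. = FALSE)
  }
  if (!all(c("HC", "CP", "CI") %in% names(coupling_slope_by_group))) {
    stop("`coupling_slope_by_group` must name HC, CP and CI.", call. = FALSE)
  }
  if (zero_fraction < 0 || zero_fraction > 1) stop("`zero_fraction` must be in [0, 1].", call. = FALSE)
  fa_lo <- fa_base - fa_length_slope * length_range[2] - fa_group_deficit_long
  if (fa_base > 1 || fa_lo < -0.2) {
    stop("FA parameters give values far outside [0, 1] before clipping; adjust fa_base / fa_length_slope.", call. = FALSE)
  }
  structure(list(
    n_hc = n_hc, n_cp = n_cp, n_ci = n_ci, n_nodes = n_nodes,
    sampling_rate = sampling_rate, n_epochs = n_epochs, epoch_samples = epoch_samples,
    length_range = as.numeric(length_range),
    fa_base = fa_base, fa_length_slope = fa_length_slope,
    fa_group_deficit_long = fa_group_deficit_long, fa_noise_sd = fa_noise_sd,
    subject_fa_sd = subject_fa_sd, zero_fraction = zero_fraction,
    coupling_slope_by_group = coupling_slope_by_group, coupled_bands = coupled_bands,
    aec_base = aec_base, fa_center = fa_center, noise_sd = noise_sd,
    env_sigma = env_sigma, env_bandwidth = env_bandwidth,
    length_jitter_sd = length_jitter_sd, bands = bands, seed = as.integer(seed)
  ), class = "cohort_config")
}

node_labels_of <- function(config) sprintf("node_%03d", seq_len(config$n_nodes))

# Shared edge-length template: a right-skewed gamma sample shifted to the
# lower range limit and clipped above, emulating the unimodal skewed
# tract-length histogram of healthy controls. The shape/scale are fixed so
# that at the default 10-250 mm range the pooled quartiles fall near the
# published short/long cutoffs (~97 and ~172 mm). Shared across subjects
# so group-level quartile thresholds are meaningful.
length_template <- function(config) {
  n_e <- n_edges_of(config$n_nodes)
  lo <- config$length_range[1]; hi <- config$length_range[2]
  q <- lo + stats::rgamma(n_e, shape = 3.5, scale = (hi - lo) / 6.3)
  pmin(q, hi)
}

#' Generate a tract-length matrix
#'
#' Draws (or jitters) a symmetric matrix of tract lengths in mm. Lengths
#' follow a right-skewed gamma-shaped distribution rescaled onto
#' `length_range`. When a `template` edge vector is supplied, per-subject
#' Gaussian jitter (`length_jitter_sd`) is added and the result clipped to
#' the range, so all subjects share one length template up to small
#' individual variation.
#'
#' @param config A [cohort_config()].
#' @param template Optional edge vector from a previous draw (row-major
#'   upper triangle); if `NULL` a fresh template is drawn.
#' @return Symmetric zero-diagonal matrix of lengths (mm).
#' @export
generate_tract_lengths <- function(config, template = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  v <- template %||% length_template(config)
  if (length(v) != n_edges_of(config$n_nodes)) {
    stop("`template` length does not match the number of edges.", call. = FALSE)
  }
  v <- v + stats::rnorm(length(v), 0, config$length_jitter_sd)
  v <- pmin(pmax(v, config$length_range[1]), config$length_range[2])
  edge_matrix(v, config$n_nodes, node_labels_of(config))
}

#' Generate a structural connectome for one subject
#'
#' Edge FA declines linearly with tract length from `fa_base`, CI subjects
#' lose an additional `fa_group_deficit_long` on long-range edges (above
#' the supplied — or this matrix's own — 75th length percentile), a
#' subject-level offset and edgewise Gaussian noise are added, values are
#' clipped to `[0, 1]`, and a `zero_fraction` of edges is set to exactly
#' zero (absent tracts).
#'
#' @param lengths Symmetric tract-length matrix (mm).
#' @param group `"HC"`, `"CP"` or `"CI"`.
#' @param config A [cohort_config()].
#' @param thresholds Optional [range_thresholds()] defining long-range
#'   edges for the group deficit; default: quartiles of `lengths`.
#' @return A [structural_connectome()].
#' @export
generate_structural_connectome <- function(lengths, group, config, thresholds = NULL) {
  stopifnot(inherits(config, "cohort_config"), group %in% c("HC", "CP", "CI"))
  len <- edge_vector(lengths)
  if (is.null(thresholds)) {
    q <- stats::quantile(len, c(0.25, 0.75), names = FALSE, type = 7)
    thresholds <- range_thresholds(q[1], q[2])
  }
  fa <- config$fa_base - config$fa_length_slope * len
  if (group == "CI") fa <- fa - config$fa_group_deficit_long * (len > thresholds$q3)
  fa <- fa + stats::rnorm(1, 0, config$subject_fa_sd) +
    stats::rnorm(length(fa), 0, config$fa_noise_sd)
  fa <- pmin(pmax(fa, 0), 1)
  if (config$zero_fraction > 0) {
    fa[stats::runif(length(fa)) < config$zero_fraction] <- 0
  }
  structural_connectome(edge_matrix(fa, config$n_nodes, node_labels_of(config)), lengths)
}

# Planted raw-scale envelope-correlation target for one subject and band:
# a linear (hence monotone) function of FA with group-specific slope on
# structurally present edges, constant at aec_base elsewhere.
planted_aec_target <- function(sc, group, config, band_name) {
  fa <- edge_vector(sc$fa)
  slope <- if (band_name %in% config$coupled_bands) {
    unname(config$coupling_slope_by_group[[group]])
  } else 0
  target <- rep(config$aec_base, length(fa))
  present <- fa > 0
  target[present] <- config$aec_base + slope * (fa[present] - config$fa_center)
  target
}

# Planted-FC mode: the AECc estimate is modeled directly as the planted
# target plus edgewise observation noise, clipped to the raw scale and
# rescaled to [0, 1].
generate_fc_planted <- function(sc, group, config, band_name) {
  target <- planted_aec_target(sc, group, config, band_name)
  raw <- target + stats::rnorm(length(target), 0, config$noise_sd)
  raw <- pmin(pmax(raw, -1), 1)
  m <- edge_matrix(raw, config$n_nodes, node_labels_of(config))
  rescale_fc(new_fc_matrix(m, band_name, rescaled = FALSE))
}

#' Generate narrowband series with planted envelope correlations
#'
#' Synthesizes channels x samples source-like signals whose amplitude
#' envelopes carry a prescribed correlation structure: slowly varying
#' latent Gaussian drivers (low-pass at `env_bandwidth` Hz) are mixed
#' through the matrix square root of `target_env_corr`, mapped through a
#' lognormal link (`exp(env_sigma * z)`, positive and monotone in the
#' latent driver), and used to amplitude-modulate independent band-limited
#' noise carriers; broadband Gaussian noise of relative SD `noise_sd` is
#' added. Estimated envelope correlations (and the AECc) are monotone in
#' the planted target; orthogonalization and the lognormal link attenuate
#' them, so recovery is monotone rather than identity.
#'
#' @param target_env_corr Symmetric positive-semidefinite matrix with unit
#'   diagonal: target correlations of the latent envelope drivers.
#' @param band A [frequency_band()] for the carriers.
#' @param config A [cohort_config()] (sampling rate, epoch structure,
#'   envelope and noise parameters).
#' @param keep_latent Attach the latent envelopes (`channels x samples`)
#'   as attribute `"latent_envelopes"` for oracle checks.
#' @return A [source_ts()] with `n_epochs * epoch_samples` samples.
#' @export
generate_envelope_correlated_series <- function(target_env_corr, band, config,
                                                keep_latent = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  check_band(band, config$sampling_rate)
  mat_name <- deparse(substitute(target_env_corr))[1]
  target_env_corr <- check_square_symmetric(target_env_corr, mat_name)
  if (max(abs(diag(target_env_corr) - 1)) > 1e-8) {
    stop(sprintf("`%s` must have unit diagonal.", mat_name), call. = FALSE)
  }
  ev <- eigen(target_env_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("`%s` is not positive semidefinite (min eigenvalue %.3g).",
                 mat_name, min(ev)), call. = FALSE)
  }
  k <- nrow(target_env_corr)
  n <- config$n_epochs * config$epoch_samples
  fs <- config$sampling_rate
  # latent drivers: low-pass filtered white noise, standardized, mixed
  z <- fft_bandpass_matrix(matrix(stats::rnorm(n * k), n, k), fs, 0, config$env_bandwidth)
  z <- scale(z)
  z <- z %*% t(sqrtm_psd(target_env_corr))
  env <- exp(config$env_sigma * z)
  carrier <- fft_bandpass_matrix(matrix(stats::rnorm(n * k), n, k), fs, band$low, band$high)
  carrier <- scale(carrier)
  x <- env * carrier + config$noise_sd * matrix(stats::rnorm(n * k), n, k)
  labels <- rownames(target_env_corr) %||% paste0("node_", seq_len(k))
  out <- source_ts(t(x), fs, labels)
  if (keep_latent) attr(out, "latent_envelopes") <- t(env)
  out
}

# Domain z-scores consistent with the CI/CP rule: CI gets at least two
# domains forced to z <= -2; HC and CP are redrawn away from the rule.
draw_domain_z <- function(group, n_domains = 7, threshold = -2, min_domains = 2) {
  mu <- switch(group, HC = 0, CP = -0.4, CI = -1.2)
  z <- stats::rnorm(n_domains, mu, 1)
  low <- which(z <= threshold)
  if (group == "CI") {
    if (length(low) < min_domains) {
      fix <- sample(setdiff(seq_len(n_domains), low), min_domains - length(low))
      z[fix] <- threshold - abs(stats::rnorm(length(fix), 0.5, 0.3))
    }
  } else if (length(low) >= min_domains) {
    keep_one <- low[1]
    z[setdiff(low, keep_one)] <- stats::runif(length(low) - 1, threshold + 0.1, -0.5)
  }
  z
}

#' Generate a full synthetic cohort
#'
#' Draws subjects (demographics and cognitive z-scores consistent with
#' their group label), a shared tract-length template with per-subject
#' jitter, per-subject FA connectomes, and per-subject functional
#' connectivity. Two signal modes are available: `"planted_fc"` (default)
#' emits per-band FC matrices directly from the planted
#' envelope-correlation target plus observation noise — the fast path used
#' for cohort-level statistics; `"timeseries"` synthesizes narrowband
#' amplitude-modulated series via
#' [generate_envelope_correlated_series()], leaving FC estimation to
#' [fc_matrix()] (memory-heavy at full scale: reduce nodes/epochs);
#' `"none"` generates structure and subjects only. The cohort is a
#' deterministic function of the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @param signals `"planted_fc"`, `"timeseries"` or `"none"`.
#' @return An object of class `sfc_cohort`: `$subjects` (tibble),
#'   `$connectomes`, `$fc` or `$timeseries` (named by subject id),
#'   `$template_lengths`, `$thresholds` (template quartiles used for
#'   planting), `$config`.
#' @export
generate_cohort <- function(config, signals = c("planted_fc", "timeseries", "none")) {
  stopifnot(inherits(config, "cohort_config"))
  signals <- match.arg(signals)
  set.seed(config$seed)
  groups <- rep(c("HC", "CP", "CI"), times = c(config$n_hc, config$n_cp, config$n_ci))
  if (config$n_hc == 0 || (config$n_cp + config$n_ci) == 0) {
    warning("A downstream group contrast has no subjects on one side.", call. = FALSE)
  }
  n <- length(groups)
  ids <- sprintf("sub_%03d", seq_len(n))
  zmat <- t(vapply(groups, draw_domain_z, numeric(7)))
  colnames(zmat) <- c("verbal_memory", "visuospatial_memory", "processing_speed",
                      "working_memory", "verbal_fluency", "executive_function",
                      "attention")
  subjects <- tibble::tibble(
    id = ids, group = groups,
    age = round(pmin(pmax(stats::rnorm(n, 48, 11), 18), 75), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.7, 0.3)),
    education = sample(c("low", "high"), n, replace = TRUE, prob = c(0.45, 0.55))
  )
  subjects <- dplyr::bind_cols(subjects, tibble::as_tibble(zmat))

  template <- length_template(config)
  tq <- stats::quantile(template, c(0.25, 0.75), names = FALSE, type = 7)
  thresholds <- range_thresholds(tq[1], tq[2])

  connectomes <- vector("list", n); names(connectomes) <- ids
  fc <- if (signals == "planted_fc") stats::setNames(vector("list", n), ids) else NULL
  ts <- if (signals == "timeseries") stats::setNames(vector("list", n), ids) else NULL
  band_names <- names(config$bands)
  for (k in seq_len(n)) {
    lengths <- generate_tract_lengths(config, template = template)
    sc <- generate_structural_connectome(lengths, groups[k], config, thresholds)
    connectomes[[k]] <- sc
    if (signals == "planted_fc") {
      fc[[k]] <- stats::setNames(
        lapply(band_names, function(b) generate_fc_planted(sc, groups[k], config, b)),
        band_names)
    } else if (signals == "timeseries") {
      # One carrier band per generated series is unidentified ex post, so
      # the planted target of the first coupled (or first listed) band
      # drives the envelopes; FC in every band is then estimated downstream.
      b0 <- if (length(config$coupled_bands)) config$coupled_bands[1] else band_names[1]
      target <- edge_matrix(planted_aec_target(sc, groups[k], config, b0),
                            config$n_nodes, node_labels_of(config))
      diag(target) <- 1
      target <- project_correlation(target)
      ts[[k]] <- generate_envelope_correlated_series(target, config$bands[[b0]], config)
    }
  }
  structure(list(subjects = subjects, connectomes = connectomes, fc = fc,
                 timeseries = ts, template_lengths = template,
                 thresholds = thresholds, config = config),
            class = "sfc_cohort")
}

#' @export
print.sfc_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<sfc_cohort> %d subjects (%s), %d nodes, signals: %s\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$config$n_nodes,
              if (!is.null(x$fc)) "planted FC" else if (!is.null(x$timeseries)) "time series" else "none"))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Layout: `subjects.tsv` (id, group, demographics, 7 z-score columns);
#' per subject `sc_fa_<id>.tsv` and `tract_len_<id>.tsv` (square
#' tab-delimited, node-label header); `fc_<id>_<band>.tsv` per band when
#' FC is present, or `timeseries_<id>.tsv` (channels x samples, node-label
#' header column-wise) when time series are present; `cohort.yaml` config
#' snapshot for provenance.
#'
#' @param cohort An `sfc_cohort`.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sfc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"), progress = FALSE)
  for (id in cohort$subjects$id) {
    sc <- cohort$connectomes[[id]]
    write_connectome(sc, file.path(dir, paste0("sc_fa_", id, ".tsv")),
                     file.path(dir, paste0("tract_len_", id, ".tsv")))
    if (!is.null(cohort$fc)) {
      for (b in names(cohort$fc[[id]])) {
        utils::write.table(unclass(cohort$fc[[id]][[b]]),
                           file.path(dir, sprintf("fc_%s_%s.tsv", id, b)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(cohort$timeseries)) {
      utils::write.table(t(cohort$timeseries[[id]]$data),
                         file.path(dir, paste0("timeseries_", id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  cfg <- cohort$config
  scalar <- setdiff(names(cfg), c("bands", "coupling_slope_by_group"))
  snapshot <- c(cfg[scalar],
                list(bands = lapply(cfg$bands, function(b) list(low = b$low, high = b$high)),
                     coupling_slope_by_group = as.list(cfg$coupling_slope_by_group)))
  yaml::write_yaml(snapshot, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `sfc_cohort` (FC matrices are restored when present; time
#'   series files are restored when present).
#' @export
read_cohort <- function(dir) {
  cfg_snap <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  bands <- lapply(names(cfg_snap$bands), function(nm) {
    frequency_band(nm, cfg_snap$bands[[nm]]$low, cfg_snap$bands[[nm]]$high)
  })
  names(bands) <- names(cfg_snap$bands)
  config <- cohort_config(
    n_hc = cfg_snap$n_hc, n_cp = cfg_snap$n_cp, n_ci = cfg_snap$n_ci,
    n_nodes = cfg_snap$n_nodes, sampling_rate = cfg_snap$sampling_rate,
    n_epochs = cfg_snap$n_epochs, epoch_samples = cfg_snap$epoch_samples,
    length_range = unlist(cfg_snap$length_range),
    fa_base = cfg_snap$fa_base, fa_length_slope = cfg_snap$fa_length_slope,
    fa_group_deficit_long = cfg_snap$fa_group_deficit_long,
    fa_noise_sd = cfg_snap$fa_noise_sd, subject_fa_sd = cfg_snap$subject_fa_sd,
    zero_fraction = cfg_snap$zero_fraction,
    coupling_slope_by_group = unlist(cfg_snap$coupling_slope_by_group),
    coupled_bands = cfg_snap$coupled_bands, aec_base = cfg_snap$aec_base,
    fa_center = cfg_snap$fa_center, noise_sd = cfg_snap$noise_sd,
    env_sigma = cfg_snap$env_sigma, env_bandwidth = cfg_snap$env_bandwidth,
    length_jitter_sd = cfg_snap$length_jitter_sd, bands = bands, seed = cfg_snap$seed
  )
  subjects <- readr::read_tsv(file.path(dir, "subjects.tsv"), show_col_types = FALSE,
                              progress = FALSE)
  ids <- subjects$id
  connectomes <- stats::setNames(lapply(ids, function(id) {
    read_connectome(file.path(dir, paste0("sc_fa_", id, ".tsv")),
                    file.path(dir, paste0("tract_len_", id, ".tsv")))
  }), ids)
  fc <- NULL
  if (file.exists(file.path(dir, sprintf("fc_%s_%s.tsv", ids[1], names(bands)[1])))) {
    fc <- stats::setNames(lapply(ids, function(id) {
      stats::setNames(lapply(names(bands), function(b) {
        m <- as.matrix(utils::read.table(file.path(dir, sprintf("fc_%s_%s.tsv", id, b)),
                                         header = TRUE, sep = "\t", check.names = FALSE))
        rownames(m) <- colnames(m)
        as_fc_matrix(m, b, rescaled = TRUE)
      }), names(bands))
    }), ids)
  }
  ts <- NULL
  if (file.exists(file.path(dir, paste0("timeseries_", ids[1], ".tsv")))) {
    ts <- stats::setNames(lapply(ids, function(id) {
      m <- as.matrix(utils::read.table(file.path(dir, paste0("timeseries_", id, ".tsv")),
                                       header = TRUE, sep = "\t", check.names = FALSE))
      source_ts(t(m), config$sampling_rate, colnames(m))
    }), ids)
  }
  structure(list(subjects = subjects, connectomes = connectomes, fc = fc,
                 timeseries = ts, template_lengths = NULL, thresholds = NULL,
                 config = config),
            class = "sfc_cohort")
}
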