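test_that("tract lengths are symmetric, ranged, deterministic under a fixed seed", {
  cfg <- small_config(n_nodes = 30)
  set.seed(60)
  len <- generate_tract_lengths(cfg)
  expect_identical(len, t(len))
  expect_true(all(diag(len) == 0))
  off <- len[upper.tri(len)]
  expect_true(all(off >= 10 & off <= 250))
  set.seed(61); l1 <- generate_tract_lengths(cfg)
  set.seed(61); l2 <- generate_tract_lengths(cfg)
  expect_identical(l1, l2)
  expect_error(cohort_config(length_range = c(250, 10)), "increasing")
})

test_that("pooled generated lengths match the quantile oracle and skew right", {
  cfg <- cohort_config(n_hc = 2, n_cp = 2, n_ci = 2, n_nodes = 40, seed = 62)
  set.seed(62)
  template <- NULL
  mats <- replicate(6, generate_tract_lengths(cfg), simplify = FALSE)
  pooled <- unlist(lapply(mats, function(m) m[upper.tri(m)]))
  q <- quantile(pooled, c(0.25, 0.75), names = FALSE, type = 7)
  expect_equal(q[1], oracle_quantile(pooled, 0.25), tolerance = 1e-10)
  expect_equal(q[2], oracle_quantile(pooled, 0.75), tolerance = 1e-10)
  expect_gt(mean(pooled), median(pooled))   # right skew
})

test_that("FA declines with length by construction and CI lose FA on long edges", {
  cfg <- small_config(fa_noise_sd = 0, subject_fa_sd = 0, zero_fraction = 0,
                      length_jitter_sd = 0, n_nodes = 20)
  set.seed(63)
  len <- generate_tract_lengths(cfg)
  sc <- generate_structural_connectome(len, "HC", cfg)
  v_len <- len[upper.tri(len)]
  v_fa <- sc$fa[upper.tri(sc$fa)]
  ord <- order(v_len)
  unclipped <- v_fa[ord] > 0 & v_fa[ord] < 1
  expect_true(all(diff(v_fa[ord][unclipped]) <= 1e-12))
  # group deficit: mean long-range FA of CI below HC by about the deficit
  cfg2 <- small_config(fa_group_deficit_long = 0.03, subject_fa_sd = 0,
                       zero_fraction = 0, n_nodes = 20)
  set.seed(64)
  template <- generate_tract_lengths(cfg2)
  thr <- {
    v <- template[upper.tri(template)]
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    range_thresholds(q[1], q[2])
  }
  long_mean <- function(group) {
    mean(replicate(100, {
      sc <- generate_structural_connectome(template, group, cfg2, thr)
      mean(mask_fc_by_structure(sc$fa, classify_edges(sc, thr), "long"))
    }))
  }
  expect_lt(abs(long_mean("HC") - long_mean("CI") - 0.03), 0.005)
  # fully absent connectome
  cfg3 <- small_config(zero_fraction = 1, n_nodes = 12)
  set.seed(65)
  sc_empty <- generate_structural_connectome(generate_tract_lengths(cfg3), "HC", cfg3)
  expect_equal(sparsity(sc_empty), 1)
})

test_that("envelope-correlated series validate the target and are seed-deterministic", {
  cfg <- cohort_config(n_nodes = 3, sampling_rate = 250, n_epochs = 1,
                       epoch_samples = 4096, seed = 1)
  band <- frequency_band("theta", 4, 8)
  bad_target <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  expect_error(generate_envelope_correlated_series(bad_target, band, cfg),
               "bad_target.*not positive semidefinite")
  tg <- diag(3)
  set.seed(66); s1 <- generate_envelope_correlated_series(tg, band, cfg)
  set.seed(66); s2 <- generate_envelope_correlated_series(tg, band, cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(dim(s1$data), c(3L, 4096L))
  no_diag <- diag(3) * 2
  expect_error(generate_envelope_correlated_series(no_diag, band, cfg), "unit diagonal")
})

test_that("latent envelopes carry the planted ordering", {
  cfg <- cohort_config(n_nodes = 4, sampling_rate = 250, n_epochs = 1,
                       epoch_samples = 32768, seed = 1)
  band <- frequency_band("theta", 4, 8)
  tg <- diag(4)
  tg[1, 2] <- tg[2, 1] <- 0.9
  tg[3, 4] <- tg[4, 3] <- 0.3
  set.seed(67)
  ts <- generate_envelope_correlated_series(tg, band, cfg, keep_latent = TRUE)
  env <- attr(ts, "latent_envelopes")
  r_strong <- cor(env[1, ], env[2, ])
  r_weak <- cor(env[3, ], env[4, ])
  expect_gt(r_strong, r_weak)
  # estimated AECc preserves the ordering of the latent correlations
  a_strong <- aecc_pair(ts$data[1, ], ts$data[2, ], band, 250)
  a_weak <- aecc_pair(ts$data[3, ], ts$data[4, ], band, 250)
  expect_gt(a_strong, a_weak)
})

test_that("cohorts carry the study's group sizes and rule-consistent labels", {
  cfg <- cohort_config(n_nodes = 12, seed = 68)   # default 40/46/33 subjects
  coh <- generate_cohort(cfg, signals = "none")
  expect_identical(as.integer(table(coh$subjects$group)[c("HC", "CP", "CI")]),
                   c(40L, 46L, 33L))
  expect_identical(nrow(coh$subjects), 119L)
  zcols <- c("verbal_memory", "visuospatial_memory", "processing_speed",
             "working_memory", "verbal_fluency", "executive_function", "attention")
  status <- apply(as.matrix(coh$subjects[, zcols]), 1, classify_cognitive_status)
  expect_true(all(status[coh$subjects$group == "CI"] == "CI"))
  expect_true(all(status[coh$subjects$group != "CI"] == "CP"))
})

test_that("cohorts are byte-identical under identical config and differ across seeds", {
  cfg <- small_config(seed = 69, n_nodes = 10)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$connectomes, c2$connectomes)
  expect_identical(c1$fc, c2$fc)
  c3 <- generate_cohort(small_config(seed = 70, n_nodes = 10))
  expect_false(identical(c1$connectomes, c3$connectomes))
})

test_that("noise-free planted linear coupling gives exactly unit within-subject r", {
  cfg <- small_config(noise_sd = 0, n_nodes = 14, seed = 71,
                      coupling_slope_by_group = c(HC = 0.1, CP = 0.2, CI = 0.3))
  coh <- generate_cohort(cfg)
  thr <- quartile_thresholds(coh$connectomes[coh$subjects$group == "HC"])
  for (id in coh$subjects$id[1:6]) {
    mask <- classify_edges(coh$connectomes[[id]], thr)
    sc_v <- mask_fc_by_structure(coh$connectomes[[id]]$fa, mask, "whole")
    fc_v <- mask_fc_by_structure(coh$fc[[id]]$theta, mask, "whole")
    expect_equal(within_subject_coupling(sc_v, fc_v)$r, 1, tolerance = 1e-12)
  }
})

test_that("the planted group ordering of long-range coupling is recovered", {
  hits <- vapply(1:10, function(s) {
    cfg <- cohort_config(n_hc = 50, n_cp = 2, n_ci = 50, n_nodes = 16, seed = 100 + s)
    coh <- generate_cohort(cfg)
    thr <- quartile_thresholds(coh$connectomes[coh$subjects$group == "HC"])
    r <- vapply(coh$subjects$id, function(id) {
      mask <- classify_edges(coh$connectomes[[id]], thr)
      cor(mask_fc_by_structure(coh$connectomes[[id]]$fa, mask, "long"),
          mask_fc_by_structure(coh$fc[[id]]$theta, mask, "long"))
    }, numeric(1))
    mean(r[coh$subjects$group == "CI"]) > mean(r[coh$subjects$group == "HC"])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("cohorts round-trip through the directory layout", {
  cfg <- small_config(n_hc = 3, n_cp = 3, n_ci = 3, n_nodes = 8, seed = 72)
  coh <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "subjects.tsv")))
  expect_true(file.exists(file.path(d, "cohort.yaml")))
  back <- read_cohort(d)
  expect_equal(back$subjects$group, coh$subjects$group)
  id <- coh$subjects$id[1]
  expect_equal(back$connectomes[[id]]$fa, coh$connectomes[[id]]$fa, tolerance = 1e-10)
  expect_equal(unclass(back$fc[[id]]$theta), unclass(coh$fc[[id]]$theta), tolerance = 1e-10)
  expect_identical(back$config$seed, cfg$seed)
})
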