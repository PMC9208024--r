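make_sc <- function(fa_v, len_v, n) {
  fa <- matrix(0, n, n); len <- matrix(0, n, n)
  k <- 1
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    fa[i, j] <- fa[j, i] <- fa_v[k]
    len[i, j] <- len[j, i] <- len_v[k]
    k <- k + 1
  }
  structural_connectome(fa, len)
}

test_that("connectome validation catches out-of-range FA, asymmetry and label mismatch", {
  fa <- matrix(c(0, 0.5, 0.5, 0), 2)
  len <- matrix(c(0, 100, 100, 0), 2)
  expect_s3_class(structural_connectome(fa, len), "structural_connectome")
  bad <- fa; bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(structural_connectome(bad, len), "outside \\[0, 1\\] at cell")
  asym <- fa; asym[1, 2] <- 0.6
  expect_warning(structural_connectome(asym, len), "symmetrized")
  # tract present but no length
  expect_error(structural_connectome(fa, matrix(0, 2, 2)), "non-positive length")
})

test_that("connectomes round-trip through delimited text", {
  set.seed(30)
  sc <- random_connectome(10)
  d <- withr::local_tempdir()
  write_connectome(sc, file.path(d, "fa.tsv"), file.path(d, "len.tsv"))
  back <- read_connectome(file.path(d, "fa.tsv"), file.path(d, "len.tsv"))
  expect_equal(back$fa, sc$fa, tolerance = 1e-12)
  expect_equal(back$lengths, sc$lengths, tolerance = 1e-12)
  # label mismatch between the two files is an error
  sc2 <- sc; rownames(sc2$fa) <- colnames(sc2$fa) <- paste0("x", 1:10)
  utils::write.table(sc2$fa, file.path(d, "fa2.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_connectome(file.path(d, "fa2.tsv"), file.path(d, "len.tsv")),
               "labels differ")
})

test_that("sparsity equals the brute-force absent-edge fraction", {
  n <- 8
  n_e <- n * (n - 1) / 2
  fa_v <- rep(0.5, n_e)
  len_v <- runif(n_e, 20, 200)
  expect_equal(sparsity(make_sc(fa_v, len_v, n)), 0)
  fa_half <- fa_v; fa_half[seq_len(n_e / 2)] <- 0
  expect_equal(sparsity(make_sc(fa_half, len_v, n)), 0.5)
  set.seed(31)
  for (rep in 1:10) {
    sc <- random_connectome(9, p_present = runif(1, 0.2, 0.9))
    cnt <- 0; tot <- 0
    for (i in 1:8) for (j in (i + 1):9) { tot <- tot + 1; if (sc$fa[i, j] == 0) cnt <- cnt + 1 }
    expect_equal(sparsity(sc), cnt / tot)
  }
})

test_that("pooled quartile thresholds match the interpolation oracle", {
  # hand case: pooled lengths 1..8 -> q1 = 2.75, q3 = 6.25
  sc <- make_sc(rep(0.5, 6), c(1, 2, 3, 4, 5, 6), 4)
  sc2 <- make_sc(c(0.5, 0.5, 0, 0, 0, 0), c(7, 8, 1, 1, 1, 1), 4)
  thr <- quartile_thresholds(list(sc, sc2))
  expect_equal(thr$q1, 2.75)
  expect_equal(thr$q3, 6.25)
  set.seed(32)
  scs <- replicate(4, random_connectome(12), simplify = FALSE)
  pooled <- unlist(lapply(scs, function(s) {
    v <- s$lengths[upper.tri(s$lengths)][s$fa[upper.tri(s$fa)] > 0]
    v
  }))
  thr2 <- quartile_thresholds(scs)
  expect_equal(thr2$q1, oracle_quantile(pooled, 0.25), tolerance = 1e-12)
  expect_equal(thr2$q3, oracle_quantile(pooled, 0.75), tolerance = 1e-12)
  expect_error(quartile_thresholds(list(make_sc(rep(0, 6), rep(1, 6), 4))), "present edges")
})

test_that("edge classification uses strict inequalities at the published cutoffs", {
  thr <- range_thresholds(96.765, 172.056)
  sc <- make_sc(rep(0.5, 6), c(90, 96.765, 130, 172.056, 200, 96.766), 4)
  mask <- classify_edges(sc, thr)
  expect_identical(mask$short, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(mask$long, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # degenerate: all lengths equal -> both classes empty
  thr_c <- range_thresholds(50, 50)
  mask_c <- classify_edges(make_sc(rep(0.5, 6), rep(50, 6), 4), thr_c)
  expect_identical(sum(mask_c$short) + sum(mask_c$long), 0L)
})

test_that("class counts match enumeration on random connectomes", {
  set.seed(33)
  for (rep in 1:20) {
    sc <- random_connectome(10, p_present = runif(1, 0.3, 1))
    thr <- quartile_thresholds(list(sc))
    mask <- classify_edges(sc, thr)
    n_s <- 0L; n_l <- 0L
    for (i in 1:9) for (j in (i + 1):10) {
      if (sc$fa[i, j] > 0 && sc$lengths[i, j] < thr$q1) n_s <- n_s + 1L
      if (sc$fa[i, j] > 0 && sc$lengths[i, j] > thr$q3) n_l <- n_l + 1L
    }
    expect_identical(count_range_connections(mask), c(n_short = n_s, n_long = n_l))
    expect_false(any(mask$short & mask$long))
    expect_true(all(mask$short | mask$long | TRUE))
    expect_true(all(which(mask$short) %in% which(mask$present)))
  }
})

test_that("classification is invariant to consistent node relabeling", {
  set.seed(34)
  sc <- random_connectome(9)
  thr <- quartile_thresholds(list(sc))
  perm <- sample(9)
  sc_p <- structural_connectome(sc$fa[perm, perm], sc$lengths[perm, perm])
  expect_identical(count_range_connections(classify_edges(sc, thr)),
                   count_range_connections(classify_edges(sc_p, thr)))
})

test_that("masking extracts the requested class values in fixed order", {
  set.seed(35)
  sc <- random_connectome(8)
  thr <- quartile_thresholds(list(sc))
  mask <- classify_edges(sc, thr)
  fc_vals <- matrix(runif(64), 8); fc_vals <- (fc_vals + t(fc_vals)) / 2; diag(fc_vals) <- 0
  fc <- as_fc_matrix(fc_vals, rescaled = TRUE)
  v <- mask_fc_by_structure(fc, mask, "whole")
  # per-edge lookup oracle, row-major upper triangle
  expected <- c()
  for (i in 1:7) for (j in (i + 1):8) if (sc$fa[i, j] > 0) expected <- c(expected, fc_vals[i, j])
  expect_equal(v, expected)
  expect_equal(mean(v), mean(expected))
  # no long edges -> error
  thr_hi <- range_thresholds(5, 1e6)
  expect_error(mask_fc_by_structure(fc, classify_edges(sc, thr_hi), "long"), "No edges")
  # whole-class mean equals the FC mean restricted to present edges
  all_present <- make_sc(rep(0.4, 28), runif(28, 20, 200), 8)
  mask_all <- classify_edges(all_present, thr)
  expect_length(mask_fc_by_structure(fc, mask_all, "whole"), 28)
  expect_equal(mean(mask_fc_by_structure(fc, mask_all, "whole")), whole_brain_fc(fc))
})
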