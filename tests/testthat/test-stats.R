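test_that("cognitive status follows the two-impaired-domains rule with inclusive boundary", {
  expect_identical(classify_cognitive_status(c(-2.1, -2.0, 0, 0, 0, 0, 0)), "CI")
  expect_identical(classify_cognitive_status(c(-3, 0, 0, 0, 0, 0, 0)), "CP")
  expect_identical(classify_cognitive_status(rep(0, 7)), "CP")
  expect_identical(classify_cognitive_status(c(-1.99, -1.99, -1.99, 0, 0, 0, 0)), "CP")
  expect_error(classify_cognitive_status(c(-3, NA, 0, 0, 0, 0, 0)), "Missing")
  expect_error(classify_cognitive_status(-3), "at least 2")
})

test_that("Bonferroni alphas reproduce the two- and three-test corrections", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(bonferroni_alpha(0.05, 3), 3), 0.017)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
})

test_that("correlate matches direct formulas and distinguishes monotone nonlinearity", {
  set.seed(50)
  x <- rnorm(10); y <- rnorm(10)
  pe <- correlate(x, y, "pearson")
  expect_equal(pe$r, oracle_pearson(x, y), tolerance = 1e-10)
  expect_equal(pe$p, oracle_pearson_p(pe$r, 10), tolerance = 1e-10)
  sp <- correlate(x, y, "spearman")
  expect_equal(sp$r, oracle_pearson(rank(x), rank(y)), tolerance = 1e-10)
  # cross-check the Pearson branch against the standard implementation
  ct <- cor.test(x, y)
  expect_equal(pe$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pe$p, ct$p.value, tolerance = 1e-10)
  xx <- seq(0.1, 2, length.out = 12)
  expect_equal(correlate(xx, xx, "pearson")$r, 1, tolerance = 1e-12)
  expect_equal(correlate(xx, exp(xx), "spearman")$r, 1, tolerance = 1e-12)
  expect_lt(correlate(xx, exp(xx), "pearson")$r, 1)
  expect_error(correlate(xx, rep(1, 12)), "Constant")
})

test_that("GLM omnibus F matches the normal-equations oracle", {
  set.seed(51)
  n <- 60
  d <- tibble::tibble(
    group = factor(rep(c("HC", "CP", "CI"), each = 20)),
    age = rnorm(n, 50, 10),
    sex = sample(c("F", "M"), n, replace = TRUE),
    y = rnorm(n) + 0.6 * (rep(c(0, 0.5, 1), each = 20))
  )
  fit <- glm_group_compare(d, "y", covariates = c("age", "sex"))
  X_full <- model.matrix(~ group + age + sex, d)
  X_red <- model.matrix(~ age + sex, d)
  orc <- oracle_glm_F(d$y, X_full, X_red)
  expect_equal(fit$F, orc$F, tolerance = 1e-8)
  expect_equal(fit$p, orc$p, tolerance = 1e-8)
  expect_identical(fit$df1, 2)
  # adjusted means present for every group, pairwise has 3 contrasts
  expect_identical(nrow(fit$adjusted_means), 3L)
  expect_identical(nrow(fit$pairwise), 3L)
})

test_that("two groups without covariates reduce to the pooled t test (F = t^2)", {
  set.seed(52)
  d <- tibble::tibble(group = rep(c("A", "B"), each = 15), y = rnorm(30) + rep(c(0, 1), each = 15))
  fit <- glm_group_compare(d, "y", covariates = character(0))
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
})

test_that("identical groups give F = 0 and a fully mediated effect vanishes after adjustment", {
  d0 <- tibble::tibble(group = rep(c("A", "B", "C"), each = 5), y = rep(c(1, 2, 3, 4, 5), 3))
  fit0 <- glm_group_compare(d0, "y", covariates = character(0))
  expect_equal(fit0$F, 0, tolerance = 1e-10)
  expect_equal(fit0$p, 1, tolerance = 1e-10)
  # group difference carried entirely by age
  set.seed(53)
  age <- c(rnorm(25, 40, 3), rnorm(25, 60, 3))
  d1 <- tibble::tibble(group = rep(c("young", "old"), each = 25), age = age,
                       y = 0.5 * age + rnorm(50, 0, 0.5))
  unadj <- glm_group_compare(d1, "y", covariates = character(0))
  adj <- glm_group_compare(d1, "y", covariates = "age")
  expect_lt(unadj$p, 1e-6)
  expect_gt(adj$p, 0.05)
})

test_that("degenerate and rank-deficient designs are flagged, not mis-tested", {
  d <- tibble::tibble(group = rep(c("A", "B"), each = 5), y = rep(0.5, 10),
                      age2 = rep(1:5, 2))
  expect_warning(fit <- glm_group_compare(d, "y", covariates = character(0)), "zero variance")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$F))
  d2 <- tibble::tibble(group = rep(c("A", "B"), each = 5), y = rnorm(10),
                       age = 1:10, age_copy = 1:10)
  expect_error(glm_group_compare(d2, "y", covariates = c("age", "age_copy")),
               "rank deficient")
})

test_that("ROC equals exhaustive pair and threshold enumeration, including ties", {
  # perfectly separated
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c("CP", "CI"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 3); expect_lte(r$cutoff, 10)
  # all tied
  expect_equal(roc_analysis(rep(2, 10), rep(c("CP", "CI"), 5))$auc, 0.5)
  set.seed(54)
  for (rep in 1:15) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n2)), 1)   # rounding induces ties
    labels <- rep(c("CI", "CP"), c(n1, n2))
    rr <- roc_analysis(scores, labels)
    expect_equal(rr$auc, oracle_auc(scores[labels == "CI"], scores[labels == "CP"]),
                 tolerance = 1e-12)
    expect_equal(rr$cutoff, oracle_cutoff(scores[labels == "CI"], scores[labels == "CP"]))
  }
  expect_error(roc_analysis(1:5, rep("CI", 5)), "non-empty")
})

test_that("AUC is invariant under strictly increasing transforms and cross-checks with pROC", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- rnorm(30)
  labels <- rep(c("CI", "CP"), 15)
  a1 <- roc_analysis(scores, labels)$auc
  expect_equal(roc_analysis(exp(scores), labels)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_analysis(scores * 100 - 3, labels)$auc, a1, tolerance = 1e-12)
  pr <- pROC::roc(response = labels, predictor = scores, levels = c("CP", "CI"),
                  direction = "<", quiet = TRUE)
  expect_equal(a1, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("the permutation p-value agrees in order of magnitude with the analytic one", {
  set.seed(56)
  scores <- c(rnorm(12, 1.2), rnorm(12))
  labels <- rep(c("CI", "CP"), each = 12)
  r <- roc_analysis(scores, labels, n_permutations = 400)
  expect_false(is.na(r$p_permutation))
  expect_lt(abs(log10(r$p_permutation) - log10(max(r$p, 1 / 401))), 1.5)
})
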