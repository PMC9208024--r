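# Independent oracles: deliberately naive implementations used to check
# the package's code paths. They must never call the functions they check.

# Linear-interpolation quantile at position (n - 1) * p + 1 on the sorted
# sample.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Pearson correlation from the raw definition.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
}

# AUC by exhaustive pair enumeration with ties counted one half.
oracle_auc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Optimal cutoff by exhaustive sweep over unique scores (rule: score >=
# cutoff predicts positive), ties broken toward the lower threshold.
oracle_cutoff <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  best <- -Inf; best_cut <- NA_real_
  for (cut in cand) {
    j <- mean(pos >= cut) + mean(neg < cut)
    if (j > best + 1e-12) { best <- j; best_cut <- cut }
  }
  best_cut
}

# Omnibus partial F for a group factor given covariates, from the normal
# equations and the F distribution directly.
oracle_glm_F <- function(y, X_full, X_red) {
  beta_f <- solve(crossprod(X_full), crossprod(X_full, y))
  beta_r <- solve(crossprod(X_red), crossprod(X_red, y))
  rss_f <- sum((y - X_full %*% beta_f)^2)
  rss_r <- sum((y - X_red %*% beta_r)^2)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- length(y) - ncol(X_full)
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# A small random structural connectome for enumeration checks.
random_connectome <- function(n_nodes, p_present = 0.7) {
  n_e <- n_nodes * (n_nodes - 1) / 2
  fa_v <- ifelse(stats::runif(n_e) < p_present, stats::runif(n_e, 0.2, 0.8), 0)
  len_v <- stats::runif(n_e, 10, 250)
  fa <- matrix(0, n_nodes, n_nodes); len <- matrix(0, n_nodes, n_nodes)
  k <- 1
  for (i in seq_len(n_nodes - 1)) for (j in seq.int(i + 1, n_nodes)) {
    fa[i, j] <- fa[j, i] <- fa_v[k]
    len[i, j] <- len[j, i] <- len_v[k]
    k <- k + 1
  }
  structural_connectome(fa, len)
}

# Compact cohort configuration for fast cohort-level tests.
small_config <- function(..., n_hc = 10, n_cp = 10, n_ci = 8, n_nodes = 16, seed = 1) {
  cohort_config(n_hc = n_hc, n_cp = n_cp, n_ci = n_ci, n_nodes = n_nodes,
                seed = seed, ...)
}
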