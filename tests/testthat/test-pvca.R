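test_that("sample PCA reproduces a dense eigendecomposition", {
  set.seed(61)
  A <- matrix(rnorm(120 * 8, 10, 2), 120, 8)
  t <- tiny_table(A, scale_tag = "log2_quantile")
  p <- sample_pca(t)
  Z <- (A - rowMeans(A)) / apply(A, 1, sd)
  e <- eigen(cor(Z), symmetric = TRUE)
  expect_equal(p$eigenvalues, pmax(e$values, 0), tolerance = 1e-10)
  expect_equal(abs(p$scores), abs(e$vectors %*% diag(sqrt(pmax(e$values, 0)))),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # constant rows are dropped with a warning
  A2 <- rbind(A, 5)
  expect_warning(sample_pca(tiny_table(A2, scale_tag = "log2_quantile")),
                 "constant")
})

test_that("i.i.d. noise gives an approximately flat spectrum", {
  set.seed(62)
  A <- matrix(rnorm(4000 * 10), 4000, 10)
  p <- sample_pca(tiny_table(A, scale_tag = "log2_quantile"))
  ev <- p$eigenvalues[1:9]           # last one is ~0 by centering
  expect_lt(max(ev) / min(ev), 3)
})

test_that("REML random-intercept fit matches the balanced ANOVA closed form", {
  set.seed(63)
  for (rep in 1:100) {
    g <- sample(3:6, 1); n <- sample(4:8, 1)
    grp <- rep(paste0("g", seq_len(g)), each = n)
    y <- rnorm(g, sd = 3)[factor(grp)] + rnorm(g * n)
    want <- oracle_anova_vc(y, grp)
    if (want["factor"] == 0) next      # boundary handled below
    fit <- fit_random_intercepts(y, data.frame(grp = grp), "grp")
    expect_equal(fit$variance_components[["grp"]], want[["factor"]],
                 tolerance = 1e-6)
    expect_equal(fit$residual_variance, want[["residual"]],
                 tolerance = 1e-6)
  }
})

test_that("degenerate responses give zero components", {
  d <- data.frame(grp = rep(c("a", "b", "c"), each = 4))
  fit <- fit_random_intercepts(rep(2, 12), d, "grp")
  expect_equal(unname(fit$variance_components), 0)
  expect_equal(fit$residual_variance, 0)
  # equal group means: factor variance hits the zero boundary
  y <- rep(c(-1, 1), 6)
  fit2 <- fit_random_intercepts(y, d, "grp")
  expect_equal(unname(fit2$variance_components["grp"]), 0, tolerance = 1e-8)
  expect_error(fit_random_intercepts(1:3, data.frame(grp = c("a", "b", "c")),
                                     "grp"))
})

test_that("pc_n is the smallest k reaching the variance threshold", {
  set.seed(64)
  A <- matrix(rnorm(200 * 12, 10), 200, 12)
  t <- tiny_table(A, months = rep(c("May", "June", "July", "August"),
                                  each = 3),
                  sites = rep(c("A", "B", "C"), 4),
                  batches = rep(1:4, 3), scale_tag = "log2_quantile")
  p <- sample_pca(t)
  v <- pvca(t, factors = c("month", "site"), pca = p)
  frac <- cumsum(p$eigenvalues) / sum(p$eigenvalues)
  expect_equal(v$pc_n, which(frac >= 0.6)[1])
  expect_equal(sum(v$proportions), 1, tolerance = 1e-9)
  expect_true(all(v$proportions >= 0))
})

test_that("planted structure is attributed to the right factor", {
  # batch-only structure: batch dominates, month/site negligible
  sim <- simulate_table(sim_config(n_features = 600, seed = 65,
                                   month_effect_frac = 0,
                                   site_effect_frac = 0))
  t <- quantile_normalize(log2_transform(
    restrict_samples(sim$table, "wastewater")))
  v <- suppressWarnings(pvca(t))
  expect_gt(v$proportions[["batch"]], v$proportions[["month"]])
  expect_gt(v$proportions[["batch"]], v$proportions[["site"]])
  expect_lt(v$proportions[["month"]], 0.1)
  expect_lt(v$proportions[["site"]], 0.1)

  # pure noise: residual dominates
  set.seed(66)
  A <- matrix(rnorm(800 * 56, 12), 800, 56)
  tn <- tiny_table(A, months = rep(sim_config()$months, each = 8),
                   sites = rep(c("A", "B", "C", "D", "E", "G", "influent",
                                 "effluent"), 7),
                   batches = rep(c(1, 2, 3, 3, 3, 4, 4), each = 8),
                   scale_tag = "log2_quantile")
  vn <- suppressWarnings(pvca(tn))
  expect_gt(vn$proportions[["residual"]], 0.9)
})

test_that("proportions are invariant to sample order and feature scaling", {
  sim <- simulate_table(sim_config(n_features = 200, seed = 67))
  t <- quantile_normalize(log2_transform(
    restrict_samples(sim$table, "wastewater")))
  v1 <- suppressWarnings(pvca(t))
  perm <- sample(n_samples(t))
  t2 <- t
  t2$samples <- t$samples[perm, ]
  t2$abundance <- t$abundance[, perm]
  v2 <- suppressWarnings(pvca(t2))
  expect_equal(v2$proportions, v1$proportions, tolerance = 1e-6)
  t3 <- t
  t3$abundance <- t$abundance * runif(n_features(t), 0.5, 2)
  v3 <- suppressWarnings(pvca(t3))
  expect_equal(v3$proportions, v1$proportions, tolerance = 1e-6)
})

test_that("perfect nesting of month in batch triggers a warning, not a failure", {
  sim <- simulate_table(sim_config(n_features = 150, seed = 68))
  t <- quantile_normalize(log2_transform(
    restrict_samples(sim$table, "wastewater")))
  expect_warning(pvca(t), "nested")
})
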