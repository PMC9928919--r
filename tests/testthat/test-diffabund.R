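test_that("group model computes group means and residual df", {
  A <- rbind(c(10, 10, 12, 12), c(1, 2, 3, 4))
  t <- tiny_table(A, months = c("May", "May", "June", "June"),
                  sites = c("A", "B", "A", "B"),
                  scale_tag = "log2_quantile")
  fit <- fit_group_model(t, grouping = "month")
  expect_equal(unname(fit$fit$coefficients[1, ]), c(10, 12))
  expect_equal(unname(fit$fit$sigma[1]), 0)
  expect_equal(fit$df_residual, 2)
  # brute-force recomputation on a random table
  set.seed(81)
  sim <- simulate_table(sim_config(n_features = 20, seed = 81))
  tq <- quantile_normalize(log2_transform(
    restrict_samples(sim$table, "wastewater")))
  f <- fit_group_model(tq, grouping = "month")
  expect_equal(f$df_residual, 56 - 7)
  mo <- sample_design(tq)$month
  for (g in c(1, 5, 12)) {
    expect_equal(unname(f$fit$coefficients[g, levels(mo)]),
                 as.vector(tapply(tq$abundance[g, ], mo, mean)),
                 tolerance = 1e-10)
    s2 <- sum((tq$abundance[g, ] -
                 tapply(tq$abundance[g, ], mo, mean)[mo])^2) / (56 - 7)
    expect_equal(unname(f$fit$sigma[g]^2), s2, tolerance = 1e-10)
  }
})

test_that("all-pairs enumeration gives g(g-1)/2 contrasts", {
  expect_equal(nrow(make_all_pairs(sim_config()$months)), 21)
  expect_equal(nrow(make_all_pairs(paste0("s", 1:8))), 28)
  p <- make_all_pairs(c("influent", "effluent"))
  expect_equal(nrow(p), 1)
  expect_equal(p$name, "influent-effluent")
  expect_error(make_all_pairs("one"))
})

test_that("moderated t matches the independent moment-matching oracle", {
  set.seed(82)
  Y <- matrix(rnorm(5 * 6, 10), 5, 6)
  g <- rep(c("a", "b"), each = 3)
  t <- tiny_table(Y, months = rep(c("May", "June"), each = 3),
                  sites = paste0("s", 1:6), scale_tag = "log2_quantile")
  fit <- fit_group_model(t, grouping = rep(c("a", "b"), each = 3))
  ct <- ebayes_moderate(fit, make_all_pairs(c("a", "b")))
  want <- oracle_moderated_t(Y, g, "a", "b")
  expect_equal(attr(ct, "d0"), want$d0, tolerance = 1e-8)
  expect_equal(attr(ct, "s02"), want$s02, tolerance = 1e-8)
  expect_equal(ct$t, unname(want$t), tolerance = 1e-8)
  expect_equal(ct$p_value, unname(want$p), tolerance = 1e-8)
  expect_equal(ct$logfc,
               unname(rowMeans(Y[, 1:3]) - rowMeans(Y[, 4:6])),
               tolerance = 1e-10)
})

test_that("equal residual variances give the ordinary-t limit", {
  # residuals identical across features => d0 = Inf, s2.post = s02
  Y <- rbind(c(0, 1, 10, 11), c(5, 6, 2, 3), c(-3, -2, 7, 8),
             c(1, 2, 1, 2), c(0, 1, 5, 6), c(2, 3, 9, 10),
             c(4, 5, 0, 1), c(8, 9, 3, 4), c(1, 2, 8, 9), c(0, 1, 2, 3))
  g <- rep(c("a", "b"), each = 2)
  t <- tiny_table(Y, months = c("May", "May", "June", "June"),
                  sites = c("A", "B", "A", "B"),
                  scale_tag = "log2_quantile")
  fit <- fit_group_model(t, grouping = g)
  ct <- ebayes_moderate(fit, make_all_pairs(c("a", "b")))
  expect_true(is.infinite(attr(ct, "d0")))
  s2 <- 4 * 0.5^2 / 2          # every feature: residuals +-0.5, df 2
  ordinary_t <- (rowMeans(Y[, 1:2]) - rowMeans(Y[, 3:4])) / sqrt(s2 * (1))
  expect_equal(ct$t, unname(ordinary_t), tolerance = 1e-10)
})

test_that("zero-variance features still get finite moderated t", {
  set.seed(83)
  Y <- matrix(rnorm(30 * 6, 10), 30, 6)
  Y[1, ] <- c(5, 5, 5, 9, 9, 9)          # zero residual, real effect
  t <- tiny_table(Y, months = rep(c("May", "June"), each = 3),
                  sites = paste0("s", 1:6), scale_tag = "log2_quantile")
  fit <- fit_group_model(t, grouping = rep(c("a", "b"), each = 3))
  ct <- suppressWarnings(ebayes_moderate(fit, make_all_pairs(c("a", "b"))))
  expect_true(is.finite(ct$t[1]))
  expect_lt(ct$p_value[1], 0.05)
})

test_that("BH adjustment equals brute-force step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)))
  set.seed(84)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("planted month effects are recovered with controlled errors", {
  # batch effects off; alignment dropout off so that power is driven by
  # the planted effect size, not by missingness leverage (a missed
  # detection enters the log2 model as 0 and inflates that feature's
  # residual variance — see the vignette on detection-limit artifacts)
  # per-sample efficiency is also off: with censoring active it shifts
  # whole samples across the detection limit, a real month-level signal
  # in the realized data that would count against the planted-truth FDR
  cfg <- sim_config(n_features = 500, seed = 85,
                    batch_effect = list(common = c(0, 0, 0, 0),
                                        sensitivity_sd = 0, idio_sd = 0,
                                        scale_log_sd = 0),
                    efficiency_sd = 0, noise_df = Inf,
                    sparsity = list(frac_sporadic = 0.35,
                                    sporadic_log2_range = c(8.5, 12.5),
                                    detection_threshold = 500,
                                    dropout = 0),
                    month_effect_frac = 0.1, site_effect_frac = 0,
                    split_frac_duplicate = 0, split_frac_alternating = 0)
  sim <- simulate_table(cfg)
  filt <- filter_frequency(suppressMessages(
    filter_features(sim$table)$table))
  tt <- restrict_samples(filt, "wastewater")
  t <- quantile_normalize(log2_transform(tt))
  fit <- fit_group_model(t, grouping = "month")
  ct <- ebayes_moderate(fit, make_all_pairs(levels(sample_design(t)$month)))
  sig <- significant_features(ct)
  hits <- unique(unlist(sig$sets))
  # planted features detected in every sample must be recovered
  full <- tt$features$feature_id[rowMeans(tt$abundance > 0) == 1]
  planted <- intersect(sim$truth$month_effects$feature, full)
  expect_gt(length(planted), 20)
  expect_gt(mean(planted %in% hits), 0.9)
  # false discoveries among nulls stay near the FDR target; BH controls
  # the rate over (feature, contrast) discoveries within each contrast
  null_feats <- setdiff(t$features$feature_id,
                        sim$truth$month_effects$feature)
  disc <- ct[ct$significant, ]
  fdp <- sum(disc$feature_id %in% null_feats) / max(1, nrow(disc))
  expect_lt(fdp, 0.1)
})

test_that("null data yields almost no significant features", {
  set.seed(86)
  A <- matrix(rnorm(300 * 56, 12), 300, 56)
  months <- rep(sim_config()$months, each = 8)
  t <- tiny_table(A, months = months,
                  sites = rep(c("A", "B", "C", "D", "E", "G", "influent",
                                "effluent"), 7),
                  scale_tag = "log2_quantile")
  fit <- fit_group_model(t, grouping = "month")
  ct <- ebayes_moderate(fit, make_all_pairs(unique(months)))
  expect_lt(sum(significant_features(ct)$counts), 5)
})

test_that("significance bookkeeping: alpha monotonicity and overlaps", {
  set.seed(87)
  sim <- simulate_table(sim_config(n_features = 150, seed = 87))
  t <- quantile_normalize(log2_transform(
    restrict_samples(sim$table, "wastewater")))
  fit <- fit_group_model(t, grouping = "month")
  ct <- ebayes_moderate(fit, make_all_pairs(levels(sample_design(t)$month)))
  s05 <- significant_features(ct, 0.05)
  s01 <- significant_features(ct, 0.01)
  expect_true(all(s01$counts <= s05$counts))
  ov <- contrast_overlap(ct, ct)
  expect_identical(ov$counts, s05$counts)
  expect_true(all(ct$p_adj >= ct$p_value - 1e-12))
})
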