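test_that("S/N filter: inclusive boundary, absent values kept", {
  A <- matrix(1e5, 4, 2)
  t <- tiny_table(A, snr = c(10, 9.99, NA, 200))
  out <- suppressMessages(filter_snr(t))
  expect_equal(out$features$feature_id, c(1L, 3L, 4L))
  expect_error(filter_snr(t, threshold = 0))
})

test_that("S/N filter matches a brute-force recount on random data", {
  set.seed(21)
  snr <- runif(100, 0, 20)
  t <- tiny_table(matrix(1e5, 100, 2), snr = snr)
  expect_equal(n_features(filter_snr(t)), sum(snr >= 10))
})

test_that("blank filter: strictly greater than fold x blank mean", {
  A <- cbind(c(1000, 500), c(0, 0), c(50, 50), c(50, 50))
  t <- tiny_table(A, roles = c("wastewater", "wastewater",
                               "method_blank", "method_blank"))
  out <- filter_blank(t)
  expect_equal(out$features$feature_id, 1L)   # 1000 > 500; 500 > 500 fails
  # no blanks: skip with warning
  t2 <- tiny_table(matrix(1, 2, 2))
  expect_warning(out2 <- filter_blank(t2), "skip")
  expect_equal(n_features(out2), 2)
})

test_that("blank filter removes planted contaminants, keeps clean features", {
  sim <- simulate_table(sim_config(n_features = 400, seed = 4,
                                   contaminant_frac = 0.1))
  out <- filter_blank(sim$table)
  expect_true(!any(sim$truth$contaminant_ids %in% out$features$feature_id))
  # non-contaminant analytes with any wastewater detection survive
  ww <- which(sim$table$samples$role == "wastewater")
  detected <- which(apply(sim$table$abundance[, ww], 1, max) > 0)
  clean <- setdiff(intersect(seq_len(400), detected),
                   sim$truth$contaminant_ids)
  expect_gt(mean(clean %in% out$features$feature_id), 0.95)
})

test_that("RT filter keeps rt >= 4.5 (Table 2 features at 5.7-6.1 survive)", {
  t <- read_alignment(table2_path(), table2_ann_path())
  expect_equal(n_features(filter_rt(t)), 4)
  t2 <- tiny_table(matrix(1, 3, 2), rt = c(4.5, 4.49, 0))
  expect_equal(filter_rt(t2)$features$feature_id, 1L)
})

test_that("min-height filter: >= 3000 in at least one wastewater sample", {
  A <- cbind(c(3000, 2999, 0), c(10, 10, 0), c(0, 0, 1e6))
  t <- tiny_table(A, roles = c("wastewater", "wastewater",
                               "calibration_standard"))
  out <- filter_min_height(t)
  expect_equal(out$features$feature_id, 1L)   # feature 3 lives only in QC
  set.seed(31)
  A2 <- matrix(round(runif(200 * 5, 0, 6000)), 200, 5)
  t2 <- tiny_table(A2)
  expect_equal(n_features(filter_min_height(t2)),
               sum(apply(A2, 1, max) >= 3000))
})

test_that("frequency filter: 60% of some month or some site", {
  sim <- simulate_table(sim_config(n_features = 150, seed = 6))
  t <- sim$table
  d <- sample_design(t)
  out <- filter_frequency(t, d)
  # brute force over month and site groups on wastewater columns
  ww <- which(t$samples$role == "wastewater")
  det <- t$abundance[, ww] > 0
  mo <- t$samples$month[ww]; si <- t$samples$site[ww]
  keep <- sapply(seq_len(n_features(t)), function(g) {
    any(tapply(det[g, ], mo, mean) >= 0.6) ||
      any(tapply(det[g, ], si, mean) >= 0.6)
  })
  expect_equal(out$features$feature_id, t$features$feature_id[keep])
})

test_that("frequency filter boundary: one full site keeps, spread-out detections drop", {
  # 56-sample grid; feature A detected in all 7 samples of one site,
  # feature B detected once per month (never 60% anywhere)
  sim <- simulate_table(sim_config(n_features = 2, seed = 2))
  t <- sim$table
  ww <- which(t$samples$role == "wastewater")
  t$abundance[, ] <- 0
  siteE <- ww[t$samples$site[ww] %in% "E"]
  t$abundance[1, siteE] <- 5000
  # one detection per month, each at a different site: no month or site
  # group ever reaches 60%
  mo <- unique(t$samples$month[ww])
  si <- unique(t$samples$site[ww])
  diag_cells <- vapply(seq_along(mo), function(i)
    ww[which(t$samples$month[ww] == mo[i] &
               t$samples$site[ww] == si[i])], integer(1))
  t$abundance[2, diag_cells] <- 5000
  out <- filter_frequency(t)
  expect_equal(out$features$feature_id, 1L)
})

test_that("restrict_samples keeps rows, drops columns, errors when empty", {
  sim <- simulate_table(sim_config(n_features = 20, seed = 2))
  out <- restrict_samples(sim$table, "wastewater")
  expect_equal(n_samples(out), 56)
  expect_equal(n_features(out), n_features(sim$table))
  expect_equal(n_samples(restrict_samples(sim$table, unique(sim$table$samples$role))),
               n_samples(sim$table))
  t <- tiny_table(matrix(1, 1, 2))
  expect_error(restrict_samples(t, "method_blank"), "no samples")
})

test_that("filters are order-insensitive subsets and the report adds up", {
  sim <- simulate_table(sim_config(n_features = 300, seed = 10))
  t <- sim$table
  a <- suppressMessages(
    filter_min_height(filter_rt(filter_blank(filter_snr(t)))))
  b <- suppressMessages(
    filter_snr(filter_blank(filter_rt(filter_min_height(t)))))
  expect_identical(a$features$feature_id, b$features$feature_id)
  expect_identical(a$abundance, b$abundance)
  # surviving rows unchanged
  keep <- match(a$features$feature_id, t$features$feature_id)
  expect_identical(a$abundance, t$abundance[keep, , drop = FALSE])
  fl <- suppressMessages(filter_features(t))
  rep <- fl$report
  expect_equal(attr(rep, "n_in") - sum(rep$n_removed), attr(rep, "n_out"))
  expect_equal(attr(rep, "n_out"), n_features(fl$table))
  expect_identical(fl$table$features$feature_id, a$features$feature_id)
})
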