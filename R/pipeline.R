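#' Configuration for a processing recipe
#'
#' The four recipes differ only in their designated stages:
#' \describe{
#'   \item{`SB`}{single batch: filter, join, log2, quantile; PVCA without
#'     the batch factor (add it back via `factors` to study a simulated
#'     batch assignment).}
#'   \item{`MB-unC`}{multi batch, uncorrected: filter, join, log2,
#'     quantile.}
#'   \item{`MB-IS`}{multi batch, ISTD scaled: filter, join, median-ISTD
#'     scaling, log2 — PVCA and clustering run on the log2 scale without
#'     quantile normalization. Quantile normalization is deliberately
#'     omitted for this recipe: ISTD scaling is a rank-preserving
#'     per-sample rescaling, so quantile-normalizing afterwards would
#'     erase it and reproduce the uncorrected dataset exactly, making
#'     the comparison vacuous. Differential abundance is not run on this
#'     scale.}
#'   \item{`MB-C`}{multi batch, ComBat corrected: filter, join, log2,
#'     quantile, empirical-Bayes batch correction.}
#' }
#'
#' @param recipe one of `"SB"`, `"MB-unC"`, `"MB-IS"`, `"MB-C"`
#' @param snr_threshold,blank_fold,min_rt,min_height,freq filter
#'   parameters (see [filtering])
#' @param join a [join_criteria()] list
#' @param combat_method `"nonparametric"` or `"parametric"`
#' @param factors PVCA factors; `NULL` selects
#'   `c("month", "site", "batch")` for multi-batch recipes and
#'   `c("month", "site")` for SB
#' @param var_threshold cumulative-variance threshold for `pc_n`
#' @param k cluster count for HCA
#' @param groupings grouping schemes for differential abundance
#' @param alpha adjusted-p significance threshold
#' @param gap_B,seed reference-set size and seed for the gap statistic
#'   (the only stochastic stage)
#' @return a `RecipeConfig` list
#' @export
recipe_config <- function(recipe = c("MB-C", "MB-unC", "MB-IS", "SB"),
                          snr_threshold = 10, blank_fold = 10,
                          min_rt = 4.5, min_height = 3000, freq = 0.60,
                          join = join_criteria(),
                          combat_method = "nonparametric",
                          factors = NULL, var_threshold = 0.60,
                          k = 7, groupings = c("month", "site", "cluster"),
                          alpha = 0.05, gap_B = 50, seed = 1L) {
  recipe <- match.arg(recipe)
  if (is.null(factors))
    factors <- if (recipe == "SB") c("month", "site")
               else c("month", "site", "batch")
  cfg <- as.list(environment())
  class(cfg) <- c("RecipeConfig", "list")
  cfg
}

#' Run a full processing recipe
#'
#' Executes the stages designated by the recipe in canonical order —
#' filtering, split-feature joining, normalization, optional batch
#' correction, restriction to wastewater samples, PVCA, hierarchical
#' clustering with silhouette and gap diagnostics, and (for
#' quantile-normalized recipes) differential abundance over all pairwise
#' contrasts of each grouping scheme. Every stage's report plus feature
#' and sample counts are recorded in a provenance log.
#'
#' @param config a [recipe_config()]
#' @param table a raw-scale `FeatureTable`
#' @param istd_ids integer ISTD feature ids (required for `MB-IS`; the
#'   scaling divisors are computed from this unfiltered input table so
#'   that ISTD rows need not survive filtering)
#' @return a `RecipeRun` list: `config`, `table` (final scale),
#'   `filter_report`, `join_report`, `pvca`, `cluster` (with
#'   `silhouette` and `gap` curves), `diffabund` (per grouping: the fit
#'   and `ContrastTable`), `provenance`
#' @export
run_recipe <- function(config, table, istd_ids = NULL) {
  stopifnot(inherits(config, "RecipeConfig"),
            inherits(table, "FeatureTable"), table$scale_tag == "raw")
  prov <- list()
  note <- function(stage, tab, extra = NULL) {
    prov[[stage]] <<- c(list(n_features = n_features(tab),
                             n_samples = n_samples(tab)), extra)
  }
  note("input", table, list(recipe = config$recipe, seed = config$seed))

  divisors <- NULL
  if (config$recipe == "MB-IS") {
    if (is.null(istd_ids))
      stop("recipe MB-IS requires istd_ids")
    rows <- match(istd_ids, table$features$feature_id)
    if (anyNA(rows)) stop("istd_ids absent from the input table")
    divisors <- apply(table$abundance[rows, , drop = FALSE], 2,
                      stats::median)
    names(divisors) <- table$samples$sample_id
  }

  fl <- filter_features(table, config$snr_threshold, config$blank_fold,
                        config$min_rt, config$min_height)
  table <- fl$table
  note("filter", table, list(report = fl$report))

  jn <- join_features(table, config$join)
  table <- jn$table
  note("join", table, list(report = jn$report))

  design_all <- sample_design(table)
  table <- filter_frequency(table, design_all, config$freq)
  note("frequency_filter", table)

  table <- restrict_samples(table, "wastewater")
  note("restrict", table)

  if (config$recipe == "MB-IS") {
    ## drop any surviving ISTD rows, then scale by the precomputed divisors
    table <- subset_features(table,
                             !table$features$feature_id %in% istd_ids)
    table <- log2_transform(istd_scale(table, divisors = divisors)$table)
    note("istd_scale_log2", table)
  } else {
    table <- quantile_normalize(log2_transform(table))
    note("log2_quantile", table)
  }

  adjustment <- NULL
  if (config$recipe == "MB-C") {
    cb <- combat_correct(table, method = config$combat_method)
    table <- cb$table
    adjustment <- cb$adjustment
    note("combat", table, list(method = config$combat_method))
  }

  design <- sample_design(table)
  p <- sample_pca(table)
  decomposition <- pvca(table, design, factors = config$factors,
                        var_threshold = config$var_threshold, pca = p)
  note("pvca", table, list(pc_n = decomposition$pc_n))

  cl <- hca(p$scores, decomposition$pc_n, config$k)
  k_max <- min(10L, n_samples(table) - 1L)
  cl$silhouette <- silhouette_curve(p$scores, decomposition$pc_n,
                                    2:k_max)
  cl$gap <- gap_curve(p$scores, decomposition$pc_n, 1:k_max,
                      B = config$gap_B, seed = config$seed)
  note("cluster", table, list(k = config$k))

  diffab <- NULL
  if (config$recipe != "MB-IS" && length(config$groupings)) {
    diffab <- list()
    for (gr in config$groupings) {
      g <- if (gr == "cluster") {
        factor(paste0("c", cl$assignment))
      } else gr
      fit <- withCallingHandlers(
        fit_group_model(table, design, g),
        warning = function(w) invokeRestart("muffleWarning"))
      contrasts <- make_all_pairs(fit$levels)
      diffab[[gr]] <- list(fit = fit, contrasts = contrasts,
                           table = ebayes_moderate(fit, contrasts))
    }
    note("diffabund", table,
         list(groupings = config$groupings, alpha = config$alpha))
  }

  out <- list(config = config, table = table,
              filter_report = fl$report, join_report = jn$report,
              adjustment = adjustment, pca = p, pvca = decomposition,
              cluster = cl, diffabund = diffab, provenance = prov)
  class(out) <- c("RecipeRun", "list")
  out
}

#' @export
print.RecipeRun <- function(x, ...) {
  cat("Recipe", x$config$recipe, "run:\n")
  for (nm in names(x$provenance))
    cat(sprintf("  %-16s %5d features x %3d samples\n", nm,
                x$provenance[[nm]]$n_features,
                x$provenance[[nm]]$n_samples))
  cat("PVCA proportions:\n")
  print(round(x$pvca$proportions, 4))
  if (!is.null(x$diffabund)) {
    for (gr in names(x$diffabund)) {
      cnt <- significant_features(x$diffabund[[gr]]$table,
                                  x$config$alpha)$counts
      cat("significant features (", gr, "): ",
          sum(cnt > 0), "/", length(cnt),
          " contrasts non-empty, total ", sum(cnt), "\n", sep = "")
    }
  }
  invisible(x)
}
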