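#' Per-feature group-means linear model
#'
#' Fits, for every feature, the one-way least-squares model whose
#' coefficients are the group means of the normalized log2 abundances,
#' one model per grouping scheme (sampling month, sampling location, or
#' HCA cluster). Interactions are not modelled: with one sample per
#' month-site combination they are not estimable. Fitting is delegated
#' to `limma::lmFit`.
#'
#' @param table a `FeatureTable` on the quantile-normalized (optionally
#'   batch-corrected) scale, wastewater samples only
#' @param design a [sample_design()] covering the samples, or any
#'   data.frame with a `sample_id` column and the grouping column
#' @param grouping name of the design column to group by, or a factor /
#'   character vector with one entry per sample
#' @return a `GroupFit`: list with the `limma` fit (`fit`), the group
#'   factor (`group`), its `levels`, `feature_id`, and the residual
#'   degrees of freedom `df_residual`
#' @export
fit_group_model <- function(table, design = sample_design(table),
                            grouping = "month") {
  if (length(grouping) == 1 && is.character(grouping)) {
    d <- design_for(table, design)
    g <- d[[grouping]]
    if (is.null(g)) stop("design has no column ", dQuote(grouping))
    label <- grouping
  } else {
    if (length(grouping) != n_samples(table))
      stop("grouping vector must have one entry per sample")
    g <- grouping
    label <- "group"
  }
  g <- droplevels(factor(g))
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("group(s) with a single sample excluded: ",
            paste(small, collapse = ", "))
    keep <- !g %in% small
    table <- subset_samples(table, keep)
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2)
    stop("need at least 2 groups with 2+ samples")
  dm <- stats::model.matrix(~ 0 + g)
  colnames(dm) <- levels(g)
  fit <- limma::lmFit(table$abundance, dm)
  out <- list(fit = fit, group = g, levels = levels(g),
              grouping = label,
              feature_id = table$features$feature_id,
              df_residual = length(g) - nlevels(g))
  class(out) <- c("GroupFit", "list")
  out
}

#' All pairwise contrasts between group levels
#'
#' @param levels character vector of g group levels (g >= 2)
#' @return a `ContrastSpec` data.frame with `level_a`, `level_b` and
#'   `name` (`"a-b"`, meaning mean(a) - mean(b)); g(g-1)/2 rows in
#'   deterministic order
#' @export
make_all_pairs <- function(levels) {
  levels <- as.character(levels)
  if (length(levels) < 2) stop("need at least 2 levels")
  idx <- utils::combn(length(levels), 2)
  out <- data.frame(level_a = levels[idx[1, ]], level_b = levels[idx[2, ]])
  out$name <- paste(out$level_a, out$level_b, sep = "-")
  class(out) <- c("ContrastSpec", "data.frame")
  out
}

#' Moderated-t statistics for a set of contrasts
#'
#' Applies empirical-Bayes variance moderation (`limma::eBayes`): the
#' per-feature residual variances are shrunk toward a pooled prior
#' variance `s0^2` with prior degrees of freedom `d0`, both estimated
#' from the ensemble of features by moment matching on the log
#' variances. Moderated t-statistics use the posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` with `d0 + d` degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted within each contrast across
#' features (set `adjust_across = TRUE` for one global adjustment over
#' all contrasts instead).
#'
#' @param fits a [fit_group_model()] result
#' @param contrasts a [make_all_pairs()] spec (or compatible data.frame)
#' @param adjust_across adjust p-values across all contrasts at once
#'   instead of within each contrast
#' @return a `ContrastTable` data.frame: `feature_id`, `contrast`,
#'   `logfc` (difference of group means on the normalized log2 scale),
#'   `t` (moderated), `p_value`, `p_adj`, `significant` (`p_adj` < 0.05);
#'   attributes `d0` (prior df) and `s02` (prior variance)
#' @export
ebayes_moderate <- function(fits, contrasts, adjust_across = FALSE) {
  stopifnot(inherits(fits, "GroupFit"))
  bad <- setdiff(c(contrasts$level_a, contrasts$level_b), fits$levels)
  if (length(bad))
    stop("contrast level(s) not in the fit: ", paste(bad, collapse = ", "))
  cm <- matrix(0, length(fits$levels), nrow(contrasts),
               dimnames = list(fits$levels, contrasts$name))
  for (r in seq_len(nrow(contrasts))) {
    cm[contrasts$level_a[r], r] <- 1
    cm[contrasts$level_b[r], r] <- -1
  }
  eb <- limma::eBayes(limma::contrasts.fit(fits$fit, cm))
  p <- eb$p.value
  padj <- if (adjust_across) {
    matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  } else {
    apply(p, 2, bh_adjust)
  }
  out <- data.frame(
    feature_id = rep(fits$feature_id, ncol(cm)),
    contrast = rep(colnames(cm), each = nrow(p)),
    logfc = as.vector(eb$coefficients),
    t = as.vector(eb$t),
    p_value = as.vector(p),
    p_adj = as.vector(padj))
  out$significant <- out$p_adj < 0.05
  attr(out, "d0") <- eb$df.prior
  attr(out, "s02") <- eb$s2.prior
  class(out) <- c("ContrastTable", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment controlling the false discovery rate,
#' with running-minimum enforcement (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significant feature sets per contrast
#'
#' @param ct a `ContrastTable` from [ebayes_moderate()]
#' @param alpha adjusted-p threshold
#' @return list with `sets` (named list of feature-id vectors, one per
#'   contrast) and `counts`
#' @export
significant_features <- function(ct, alpha = 0.05) {
  sets <- lapply(split(ct, ct$contrast),
                 function(d) d$feature_id[d$p_adj < alpha])
  sets <- sets[unique(ct$contrast)]       # deterministic contrast order
  list(sets = sets, counts = vapply(sets, length, integer(1)))
}

#' Overlap of significant features between two analyses
#'
#' For each contrast present in both tables (e.g. the same month pair
#' before and after batch correction), the features significant in both.
#'
#' @param ct1,ct2 `ContrastTable`s sharing contrast names
#' @param alpha adjusted-p threshold
#' @return list with `sets` (intersection per shared contrast) and
#'   `counts`
#' @export
contrast_overlap <- function(ct1, ct2, alpha = 0.05) {
  s1 <- significant_features(ct1, alpha)$sets
  s2 <- significant_features(ct2, alpha)$sets
  shared <- intersect(names(s1), names(s2))
  sets <- stats::setNames(
    lapply(shared, function(nm) intersect(s1[[nm]], s2[[nm]])), shared)
  list(sets = sets, counts = vapply(sets, length, integer(1)))
}
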