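#' PCA on the sample-sample correlation matrix
#'
#' Standardizes each feature (row) and eigendecomposes the correlation
#' matrix between samples, the basis used both for variance-component
#' analysis and for clustering. Constant feature rows carry no
#' correlation information and are dropped with a warning.
#'
#' @param table a `FeatureTable` on any scale (feature standardization
#'   makes the mathematics scale-free, but the scale changes the
#'   effective weighting of features: log2-derived scales weight
#'   features evenly, the raw scale emphasizes high-abundance behaviour)
#' @return list with `scores` (samples x PCs, eigenvector columns scaled
#'   by the square root of their eigenvalue, signs fixed so the largest
#'   loading is positive), `eigenvalues` (non-negative, decreasing) and
#'   `var_fraction` (eigenvalues / total)
#' @export
sample_pca <- function(table) {
  if (n_samples(table) < 3) stop("PCA needs at least 3 samples")
  X <- table$abundance
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped before PCA")
    X <- X[sds > 0, , drop = FALSE]
  }
  if (!nrow(X)) stop("no non-constant features")
  Z <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  C <- stats::cor(Z)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {             # deterministic sign convention
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  scores <- V %*% diag(sqrt(ev), nrow = length(ev))
  rownames(scores) <- colnames(X)
  list(scores = scores, eigenvalues = ev, var_fraction = ev / sum(ev))
}

#' Fit a crossed random-intercept model by REML
#'
#' Fits `y ~ 1 + (1|f)` for every factor `f` in `factors` simultaneously
#' (all intercepts random, centered at zero with unknown variance) and
#' returns the REML variance components. Fitting is by `lme4::lmer`;
#' singular fits (a component estimated at the zero boundary) are
#' accepted silently, which keeps the fit stable when two factors are
#' collinear, e.g. sampling month perfectly nested in analytical batch.
#'
#' @param y numeric response, one value per sample (typically one PC)
#' @param design data.frame of factor columns covering the samples
#' @param factors names of `design` columns to include
#' @return a `MixedModelFit`: list with `variance_components` (named, one
#'   per factor), `residual_variance` and `reml_loglik`
#' @export
fit_random_intercepts <- function(y, design, factors) {
  stopifnot(length(factors) >= 1, all(factors %in% names(design)),
            length(y) == nrow(design))
  d <- data.frame(.y = y)
  for (f in factors) {
    fac <- droplevels(factor(design[[f]]))
    if (nlevels(fac) < 2)
      stop("factor ", f, " has fewer than 2 levels")
    d[[f]] <- fac
  }
  max_lev <- max(vapply(factors, function(f) nlevels(d[[f]]), integer(1)))
  if (length(y) < max_lev + 2)
    stop("need at least ", max_lev + 2, " observations, got ", length(y))

  if (stats::var(y) == 0) {
    vc <- stats::setNames(rep(0, length(factors)), factors)
    out <- list(variance_components = vc, residual_variance = 0,
                reml_loglik = NA_real_)
    class(out) <- c("MixedModelFit", "list")
    return(out)
  }

  form <- stats::as.formula(paste(
    ".y ~ 1 +", paste0("(1 | ", factors, ")", collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore",
                 optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-12)))))
  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  vc <- stats::setNames(vc_tab$vcov[match(factors, vc_tab$grp)], factors)
  out <- list(variance_components = vc,
              residual_variance = vc_tab$vcov[vc_tab$grp == "Residual"],
              reml_loglik = as.numeric(stats::logLik(fit)))
  class(out) <- c("MixedModelFit", "list")
  out
}

#' Principal variance component analysis
#'
#' Quantifies the share of overall variance attributable to each
#' experimental factor (sampling month, sampling location, analytical
#' batch). The leading principal components of the sample-correlation
#' matrix — the smallest number accounting for at least `var_threshold`
#' of total variance — are each decomposed by a crossed random-intercept
#' model, the per-PC variance fractions are normalized to sum to one, and
#' the per-factor fractions are averaged across the retained PCs with the
#' (renormalized) eigenvalues as weights.
#'
#' A warning is issued when one factor is perfectly nested in another
#' (e.g. every sampling month analysed wholly within one batch): the
#' model stays estimable, but variance attribution between the two is
#' then driven by pooling, not by the data.
#'
#' @param table a `FeatureTable` (wastewater samples only; see
#'   [sample_pca()] on scales)
#' @param design a [sample_design()] covering the samples
#' @param factors subset of `c("month", "site", "batch")`; omit `batch`
#'   for single-batch data
#' @param var_threshold cumulative-variance threshold selecting `pc_n`
#' @param pca optionally, a precomputed [sample_pca()] result
#' @return a `VarianceDecomposition`: `factors` (including "residual"),
#'   `proportions` (weighted-average fractions, summing to 1), `pc_n`,
#'   `eigenvalues` (retained), `per_pc` (PC x factor matrix of per-PC
#'   fractions)
#' @export
pvca <- function(table, design = sample_design(table),
                 factors = c("month", "site", "batch"),
                 var_threshold = 0.60, pca = NULL) {
  stopifnot(all(factors %in% c("month", "site", "batch")))
  if (is.null(pca)) pca <- sample_pca(table)
  d <- design_for(table, design)

  ## warn on perfectly nested factor pairs
  for (f1 in factors) for (f2 in setdiff(factors, f1)) {
    tab <- table(d[[f1]], d[[f2]])
    if (all(rowSums(tab > 0) == 1) && nlevels(factor(d[[f1]])) >
        nlevels(factor(d[[f2]])))
      warning("factor ", f1, " is perfectly nested in ", f2,
              "; their variance shares are not separately identifiable")
  }

  frac <- cumsum(pca$var_fraction)
  pc_n <- which(frac >= var_threshold)[1]
  if (is.na(pc_n)) pc_n <- length(frac)

  per_pc <- matrix(NA_real_, pc_n, length(factors) + 1,
                   dimnames = list(paste0("PC", seq_len(pc_n)),
                                   c(factors, "residual")))
  for (i in seq_len(pc_n)) {
    fit <- fit_random_intercepts(pca$scores[, i], d, factors)
    v <- c(fit$variance_components, residual = fit$residual_variance)
    per_pc[i, ] <- v / sum(v)
  }
  w <- pca$eigenvalues[seq_len(pc_n)]
  w <- w / sum(w)
  props <- as.vector(t(per_pc) %*% w)
  names(props) <- colnames(per_pc)

  out <- list(factors = colnames(per_pc), proportions = props,
              pc_n = pc_n, eigenvalues = pca$eigenvalues[seq_len(pc_n)],
              per_pc = per_pc, var_threshold = var_threshold)
  class(out) <- c("VarianceDecomposition", "list")
  out
}

#' @export
print.VarianceDecomposition <- function(x, ...) {
  cat("PVCA over", x$pc_n, "PCs (>=",
      sprintf("%.0f%%", 100 * x$var_threshold), "of variance)\n")
  print(round(x$proportions, 4))
  invisible(x)
}
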