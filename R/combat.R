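#' Empirical-Bayes location/scale batch correction
#'
#' @description
#' Removes per-feature additive and multiplicative analytical-batch
#' effects from a normalized feature table by the empirical-Bayes
#' location/scale model (ComBat). The assumption is that the batch
#' effects acting on individual features are themselves draws from a
#' batch-wide distribution, so information can be pooled across features
#' to stabilize the per-feature estimates. No covariates are used: the
#' design is batch-only, as appropriate when sampling date and run date
#' are inseparable.
#'
#' The procedure is:
#' \enumerate{
#'   \item standardize each feature: `z = (y - alpha_hat) / sigma_hat`,
#'     with `alpha_hat` the batch-size-weighted grand mean and
#'     `sigma_hat^2` the pooled within-batch variance;
#'   \item estimate per-feature, per-batch location `gamma_hat` (batch
#'     mean of z) and scale `delta2_hat` (batch variance of z);
#'   \item shrink. Parametric: normal prior on gamma, inverse-gamma prior
#'     on delta2, hyperparameters by method of moments, with the coupled
#'     posterior means iterated to convergence (tolerance 1e-4, at most
#'     100 iterations). Nonparametric (default): the prior is the
#'     empirical distribution of all other features' `(gamma_hat,
#'     delta2_hat)` in the batch; the shrunk estimates are weighted
#'     averages with weights equal to the Gaussian likelihood of the
#'     feature's standardized batch data under each other feature's
#'     estimates. This path is deterministic: the integral over the
#'     empirical prior is an exact finite sum.
#'   \item adjust: `y* = sigma_hat * (z - gamma_star) / sqrt(delta2_star)
#'     + alpha_hat`.
#' }
#'
#' The nonparametric prior is the default because estimated batch effects
#' of environmental features often fail the parametric normality /
#' inverse-gamma assumptions.
#'
#' @param table a `FeatureTable` with `scale_tag = "log2_quantile"` (the
#'   standard pipeline position) or `"log2"`; at least 2 batches, each
#'   with at least 2 samples
#' @param method `"nonparametric"` (default) or `"parametric"`
#' @return list with `table` (corrected, `scale_tag =
#'   "log2_quantile_combat"`) and `adjustment`, a `BatchAdjustment` with
#'   `gamma_hat`, `delta2_hat`, `gamma_star`, `delta2_star` (features x
#'   batches), `alpha_hat`, `sigma2_hat`, `batches`, `method`
#' @export
combat_correct <- function(table, method = c("nonparametric", "parametric")) {
  method <- match.arg(method)
  stopifnot(table$scale_tag %in% c("log2", "log2_quantile"))
  batch <- table$samples$batch
  if (anyNA(batch)) stop("all samples must carry a batch label")
  batches <- sort(unique(batch))
  if (length(batches) < 2) stop("single batch: nothing to correct")
  cols <- lapply(batches, function(b) which(batch == b))
  n_i <- lengths(cols)
  if (any(n_i < 2))
    stop("batch(es) with < 2 samples (variance undefined): ",
         paste(batches[n_i < 2], collapse = ", "))

  X <- table$abundance
  G <- nrow(X); N <- ncol(X); B <- length(batches)

  ## constant features cannot be standardized; pass through unadjusted
  batch_means <- vapply(cols, function(j) rowMeans(X[, j, drop = FALSE]),
                        numeric(G))
  if (is.null(dim(batch_means))) batch_means <- matrix(batch_means, 1, B)
  alpha_hat <- as.vector(batch_means %*% (n_i / N))
  resid <- X - batch_means[, rep(seq_len(B), n_i)[order(unlist(cols))],
                           drop = FALSE]
  sigma2_hat <- rowSums(resid^2) / N
  flat <- sigma2_hat <= .Machine$double.eps
  if (any(flat))
    message(sum(flat), " feature(s) with zero pooled variance passed",
            " through unadjusted")

  Xa <- X[!flat, , drop = FALSE]
  Ga <- nrow(Xa)
  a_hat <- alpha_hat[!flat]
  s_hat <- sqrt(sigma2_hat[!flat])
  Z <- (Xa - a_hat) / s_hat

  gamma_hat <- vapply(cols, function(j) rowMeans(Z[, j, drop = FALSE]),
                      numeric(Ga))
  delta2_hat <- vapply(seq_len(B), function(i) {
    j <- cols[[i]]
    rowSums((Z[, j, drop = FALSE] - gamma_hat[, i])^2) / (n_i[i] - 1)
  }, numeric(Ga))
  if (is.null(dim(gamma_hat))) {
    gamma_hat <- matrix(gamma_hat, 1, B)
    delta2_hat <- matrix(delta2_hat, 1, B)
  }
  ## a feature constant within one batch (e.g. undetected there) has a
  ## zero scale estimate; floor it so likelihoods and divisions stay
  ## finite — shrinkage then pulls its scale toward the ensemble anyway
  delta2_hat <- pmax(delta2_hat, 1e-8)

  if (method == "nonparametric") {
    est <- lapply(seq_len(B), function(i)
      np_shrink(Z[, cols[[i]], drop = FALSE],
                gamma_hat[, i], delta2_hat[, i]))
  } else {
    est <- lapply(seq_len(B), function(i)
      param_shrink(Z[, cols[[i]], drop = FALSE],
                   gamma_hat[, i], delta2_hat[, i]))
  }
  gamma_star <- vapply(est, `[[`, numeric(Ga), "gamma")
  delta2_star <- vapply(est, `[[`, numeric(Ga), "delta2")
  if (is.null(dim(gamma_star))) {
    gamma_star <- matrix(gamma_star, 1, B)
    delta2_star <- matrix(delta2_star, 1, B)
  }

  Zadj <- Z
  for (i in seq_len(B))
    Zadj[, cols[[i]]] <- (Z[, cols[[i]], drop = FALSE] - gamma_star[, i]) /
      sqrt(delta2_star[, i])
  Xout <- X
  Xout[!flat, ] <- Zadj * s_hat + a_hat
  table$abundance <- Xout
  table$scale_tag <- paste0(table$scale_tag, "_combat")

  expand <- function(M) {
    out <- matrix(NA_real_, G, B,
                  dimnames = list(rownames(X), paste0("batch", batches)))
    out[!flat, ] <- M
    out
  }
  adjustment <- structure(list(
    gamma_hat = expand(gamma_hat), delta2_hat = expand(delta2_hat),
    gamma_star = expand(gamma_star), delta2_star = expand(delta2_star),
    alpha_hat = alpha_hat, sigma2_hat = sigma2_hat,
    batches = batches, n_per_batch = n_i, method = method,
    unadjusted = which(flat)), class = c("BatchAdjustment", "list"))
  list(table = table, adjustment = adjustment)
}

# Nonparametric shrinkage for one batch: for each feature g, the shrunk
# (gamma, delta2) are likelihood-weighted averages of all OTHER features'
# raw estimates, the weight of donor g' being the Gaussian likelihood of
# z_g under N(gamma_hat[g'], delta2_hat[g']). All likelihoods close in
# the exponent via sufficient statistics, so the whole batch is three
# rank-one matrix operations.
np_shrink <- function(Zb, g_hat, d_hat) {
  n <- ncol(Zb)
  G <- nrow(Zb)
  S <- rowSums(Zb^2)
  T1 <- rowSums(Zb)
  ## log L[g, g'] = C[g'] - S[g] * a[g'] + T1[g] * b[g']
  a <- 1 / (2 * d_hat)
  b <- g_hat / d_hat
  C <- -(n / 2) * log(2 * pi * d_hat) - n * g_hat^2 / (2 * d_hat)
  logL <- matrix(C, G, G, byrow = TRUE) - outer(S, a) + outer(T1, b)
  diag(logL) <- -Inf                       # donors exclude the feature itself
  m <- apply(logL, 1, max)
  W <- exp(logL - m)
  wsum <- rowSums(W)
  list(gamma = as.vector(W %*% g_hat) / wsum,
       delta2 = as.vector(W %*% d_hat) / wsum)
}

# Parametric shrinkage for one batch: normal prior on gamma, inverse-
# gamma prior on delta2, hyperparameters by method of moments, with the
# coupled posterior means iterated to a fixed point.
param_shrink <- function(Zb, g_hat, d_hat, tol = 1e-4, maxit = 100) {
  n <- ncol(Zb)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  m <- mean(d_hat); v <- stats::var(d_hat)
  if (!is.finite(v) || v <= 0 || t2 <= 0)   # degenerate prior: no shrinkage
    return(list(gamma = g_hat, delta2 = d_hat))
  a_prior <- (2 * v + m^2) / v
  b_prior <- (m * v + m^3) / v
  g_star <- g_hat; d_star <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
    ss <- rowSums((Zb - g_new)^2)
    d_new <- (b_prior + ss / 2) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_star), abs(d_new - d_star))
    g_star <- g_new; d_star <- d_new
    if (change < tol) break
  }
  list(gamma = g_star, delta2 = d_star)
}

#' @export
print.BatchAdjustment <- function(x, ...) {
  cat("BatchAdjustment (", x$method, " prior): ",
      nrow(x$gamma_hat), " features x ", length(x$batches), " batches\n",
      sep = "")
  cat("  batch sizes:", paste(x$n_per_batch, collapse = ", "), "\n")
  if (length(x$unadjusted))
    cat("  ", length(x$unadjusted), "constant feature(s) passed through\n")
  invisible(x)
}
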