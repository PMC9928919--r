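#' Hierarchical clustering on retained principal components
#'
#' Agglomerative clustering of samples with Euclidean distance and Ward's
#' variance-minimizing linkage (the squared-Euclidean "ward.D2" update,
#' heights reported on the distance scale), on the first `pc_n` score
#' dimensions — the same components used for the variance decomposition.
#'
#' @param scores sample x PC score matrix (see [sample_pca()])
#' @param pc_n number of leading PCs to use
#' @param k number of clusters to cut the tree into
#' @return a `ClusterResult`: `linkage` (an `hclust` tree), `k`,
#'   `assignment` (named cluster id per sample), `pc_n`
#' @export
hca <- function(scores, pc_n, k) {
  stopifnot(pc_n >= 1, pc_n <= ncol(scores))
  n <- nrow(scores)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  d <- stats::dist(scores[, seq_len(pc_n), drop = FALSE])
  hc <- stats::hclust(d, method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  out <- list(linkage = hc, k = k, assignment = assignment, pc_n = pc_n)
  class(out) <- c("ClusterResult", "list")
  out
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("Ward HCA on", x$pc_n, "PCs, k =", x$k, "clusters; sizes:",
      paste(table(x$assignment), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette width per cluster count
#'
#' @param scores,pc_n as in [hca()]
#' @param k_range candidate cluster counts (within `[2, n - 1]`)
#' @return data.frame with `k` and `mean_silhouette` (NaN when the
#'   configuration is degenerate, e.g. all points identical)
#' @export
silhouette_curve <- function(scores, pc_n, k_range = 2:10) {
  stopifnot(all(k_range >= 2), all(k_range <= nrow(scores) - 1))
  Y <- scores[, seq_len(pc_n), drop = FALSE]
  d <- stats::dist(Y)
  if (max(d) == 0) {          # all points identical: width undefined
    warning("all points identical; silhouette undefined")
    return(data.frame(k = k_range, mean_silhouette = NaN))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  ms <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(cl, d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = ms)
}

# Within-cluster dispersion W_k of Tibshirani's gap statistic:
# sum over clusters of (sum of pairwise squared distances) / (2 n_r).
gap_wk <- function(Y, cl) {
  sum(vapply(split(seq_len(nrow(Y)), cl), function(idx) {
    if (length(idx) < 2) return(0)
    sum(stats::dist(Y[idx, , drop = FALSE])^2) / (2 * length(idx))
  }, numeric(1)))
}

#' Gap-statistic curve
#'
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)` with B reference datasets
#' drawn uniformly over each retained PC dimension's observed range, each
#' clustered by the same Ward procedure as the data. The usual selection
#' rule is the smallest k with `Gap(k) >= Gap(k+1) - se(k+1)` (see
#' [gap_select_k()]).
#'
#' @param scores,pc_n as in [hca()]
#' @param k_range candidate cluster counts (may include 1)
#' @param B number of reference datasets
#' @param seed optional seed making the curve reproducible
#' @return data.frame with `k`, `log_w`, `e_log_w`, `gap`, `se`
#'   (the standard error inflated by `sqrt(1 + 1/B)`)
#' @export
gap_curve <- function(scores, pc_n, k_range = 1:10, B = 50, seed = NULL) {
  stopifnot(all(k_range >= 1), all(k_range <= nrow(scores)))
  if (!is.null(seed)) set.seed(seed)
  Y <- scores[, seq_len(pc_n), drop = FALSE]
  hc <- stats::hclust(stats::dist(Y), method = "ward.D2")
  log_w <- vapply(k_range, function(k)
    log(gap_wk(Y, stats::cutree(hc, k = k))), numeric(1))

  lo <- apply(Y, 2, min); hi <- apply(Y, 2, max)
  log_wstar <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    Yb <- vapply(seq_len(ncol(Y)),
                 function(j) stats::runif(nrow(Y), lo[j], hi[j]),
                 numeric(nrow(Y)))
    hcb <- stats::hclust(stats::dist(Yb), method = "ward.D2")
    log_wstar[b, ] <- vapply(k_range, function(k)
      log(gap_wk(Yb, stats::cutree(hcb, k = k))), numeric(1))
  }
  e_log_w <- colMeans(log_wstar)
  se <- apply(log_wstar, 2, stats::sd) * sqrt(1 + 1 / B)
  data.frame(k = k_range, log_w = log_w, e_log_w = e_log_w,
             gap = e_log_w - log_w, se = se)
}

#' Select a cluster count from a gap curve
#'
#' @param gap data.frame from [gap_curve()]
#' @return the smallest k with `Gap(k) >= Gap(k+1) - se(k+1)`, or the
#'   largest k examined if the criterion never fires
#' @export
gap_select_k <- function(gap) {
  for (r in seq_len(nrow(gap) - 1))
    if (gap$gap[r] >= gap$gap[r + 1] - gap$se[r + 1]) return(gap$k[r])
  gap$k[nrow(gap)]
}
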