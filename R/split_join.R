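#' Criteria for joining split features
#'
#' Alignment can report one true analyte as two features ("split
#' features"), either as duplicates (identical heights, scattered
#' dropouts) or as alternating features (complementary nonzero patterns).
#' Two features are considered members of one split feature when all
#' three criteria hold: retention times within `rt_tol` seconds, m/z
#' within `mz_tol` ppm (computed against the pair's mean m/z), and MS1
#' isotope-abundance ratios with coefficient of variation of at most
#' `iso_cv_max`.
#'
#' @param rt_tol retention-time tolerance in seconds
#' @param mz_tol m/z tolerance in ppm
#' @param iso_cv_max maximum CV (sd/mean, n-1 standard deviation) of the
#'   two isotope ratios; for a pair this equals `|a-b| / (sqrt(2) * mean)`
#' @return a `JoinCriteria` list
#' @export
join_criteria <- function(rt_tol = 15, mz_tol = 10, iso_cv_max = 0.20) {
  if (rt_tol <= 0 || mz_tol <= 0 || iso_cv_max <= 0)
    stop("all joining tolerances must be strictly positive")
  structure(list(rt_tol = rt_tol, mz_tol = mz_tol, iso_cv_max = iso_cv_max),
            class = c("JoinCriteria", "list"))
}

# CV of a pair using the sample (n-1) standard deviation; NA when either
# value is missing or the mean is zero.
pair_cv <- function(a, b) {
  m <- (a + b) / 2
  out <- abs(a - b) / (sqrt(2) * m)
  out[!is.finite(out) & !is.na(a) & !is.na(b) & a == 0 & b == 0] <- NA
  out[m == 0] <- NA
  out
}

# All pairs (i < j) meeting the three criteria, via an m/z sort + sliding
# window so only near-mass pairs are compared. rt tolerances in minutes.
candidate_pairs_core <- function(mz, rt_min, iso, rt_tol_min = 0.25,
                                 mz_tol_ppm = 10, iso_cv_max = 0.20) {
  n <- length(mz)
  empty <- data.frame(i = integer(), j = integer())
  if (n < 2) return(empty)
  ord <- order(mz)
  mzo <- mz[ord]
  res_i <- res_j <- list()
  lo <- 1L
  for (hi in 2:n) {
    # widest admissible mass gap at this m/z
    while (mzo[hi] - mzo[lo] > mz_tol_ppm * 1e-6 * (mzo[hi] + mzo[lo]) / 2 &&
           lo < hi)
      lo <- lo + 1L
    if (lo < hi) {
      cand <- lo:(hi - 1L)
      a <- ord[cand]; b <- ord[hi]
      ok <- meets_all_criteria(mz[a], rep(mz[b], length(a)),
                               rt_min[a], rep(rt_min[b], length(a)),
                               iso[a], rep(iso[b], length(a)),
                               rt_tol_min, mz_tol_ppm, iso_cv_max)
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        res_i[[length(res_i) + 1L]] <- pmin(a[ok], b)
        res_j[[length(res_j) + 1L]] <- pmax(a[ok], b)
      }
    }
  }
  if (!length(res_i)) return(empty)
  out <- data.frame(i = unlist(res_i), j = unlist(res_j))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Enumerate candidate split-feature pairs
#'
#' @param table a raw-scale `FeatureTable`
#' @param criteria a [join_criteria()] list
#' @return data.frame with columns `id_a`, `id_b` (feature ids, id_a <
#'   id_b), `rt_diff_s`, `mz_diff_ppm`, `iso_cv` for every pair meeting
#'   all three criteria. Pairs where either isotope ratio is absent are
#'   excluded (the ratio criterion cannot be evaluated).
#' @export
candidate_pairs <- function(table, criteria = join_criteria()) {
  stopifnot(table$scale_tag == "raw")
  f <- table$features
  prs <- candidate_pairs_core(f$mz, f$rt_min, f$isotope_ratio,
                              rt_tol_min = criteria$rt_tol / 60,
                              mz_tol_ppm = criteria$mz_tol,
                              iso_cv_max = criteria$iso_cv_max)
  data.frame(
    id_a = f$feature_id[prs$i],
    id_b = f$feature_id[prs$j],
    rt_diff_s = abs(f$rt_min[prs$i] - f$rt_min[prs$j]) * 60,
    mz_diff_ppm = abs(f$mz[prs$i] - f$mz[prs$j]) /
      ((f$mz[prs$i] + f$mz[prs$j]) / 2) * 1e6,
    iso_cv = pair_cv(f$isotope_ratio[prs$i], f$isotope_ratio[prs$j]))
}

# Union-find with path compression.
uf_find <- function(parent, x) {
  while (parent[x] != x) {
    parent[x] <- parent[parent[x]]
    x <- parent[x]
  }
  x
}

#' Join split features
#'
#' Candidate pairs (see [candidate_pairs()]) are closed transitively:
#' connected components of the pair graph are merged into single
#' features. The merged abundance is the element-wise maximum over
#' members — duplicates carry identical values where both are present,
#' and alternating members carry the true magnitude in exactly one member
#' per sample, so the maximum recovers both without double counting.
#' Merged m/z and retention time are total-abundance-weighted means; the
#' merged feature keeps the id (and S/N / isotope ratio) of the member
#' with the greatest summed abundance (ties: smallest id). The operation
#' is idempotent on tables whose remaining features are pairwise
#' separated.
#'
#' @param table a raw-scale `FeatureTable`
#' @param criteria a [join_criteria()] list
#' @return list with `table` (merged) and `report`: `n_pairs_merged`
#'   (candidate pairs absorbed), `n_features_removed`, `fraction_joined`
#'   (removed / features in), `clusters` (list of merged id groups) and
#'   `chained_clusters` (ids of components held together only through
#'   intermediates, i.e. containing a member pair that fails a criterion
#'   — flagged for audit)
#' @export
join_features <- function(table, criteria = join_criteria()) {
  stopifnot(table$scale_tag == "raw")
  n_in <- n_features(table)
  prs <- candidate_pairs(table, criteria)
  f <- table$features
  idx_a <- match(prs$id_a, f$feature_id)
  idx_b <- match(prs$id_b, f$feature_id)

  parent <- seq_len(n_in)
  for (k in seq_len(nrow(prs))) {
    ra <- uf_find(parent, idx_a[k])
    rb <- uf_find(parent, idx_b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n_in), function(x) uf_find(parent, x), integer(1))
  comp <- split(seq_len(n_in), root)
  multi <- comp[lengths(comp) > 1]

  keep_row <- rep(TRUE, n_in)
  clusters <- list()
  chained <- list()
  for (members in multi) {
    A <- table$abundance[members, , drop = FALSE]
    merged <- apply(A, 2, max)
    tot <- rowSums(A)
    w <- if (sum(tot) > 0) tot / sum(tot) else rep(1 / length(members),
                                                   length(members))
    lead_local <- members[order(-tot, f$feature_id[members])][1]
    table$abundance[lead_local, ] <- merged
    table$features$mz[lead_local] <- sum(w * f$mz[members])
    table$features$rt_min[lead_local] <- sum(w * f$rt_min[members])
    keep_row[setdiff(members, lead_local)] <- FALSE
    ids <- f$feature_id[members]
    clusters[[length(clusters) + 1L]] <- ids
    ## chained if some member pair violates a criterion on its own
    pw <- utils::combn(members, 2)
    all_ok <- all(meets_all_criteria(
      f$mz[pw[1, ]], f$mz[pw[2, ]], f$rt_min[pw[1, ]], f$rt_min[pw[2, ]],
      f$isotope_ratio[pw[1, ]], f$isotope_ratio[pw[2, ]],
      criteria$rt_tol / 60, criteria$mz_tol, criteria$iso_cv_max),
      na.rm = FALSE)
    if (is.na(all_ok) || !all_ok)
      chained[[length(chained) + 1L]] <- ids
  }
  out <- subset_features(table, keep_row)
  n_removed <- n_in - n_features(out)
  report <- list(n_pairs_merged = nrow(prs),
                 n_features_removed = n_removed,
                 fraction_joined = if (n_in) n_removed / n_in else 0,
                 clusters = clusters,
                 chained_clusters = chained)
  class(report) <- c("JoinReport", "list")
  list(table = out, report = report)
}

#' @export
print.JoinReport <- function(x, ...) {
  cat("Split-feature join:", length(x$clusters), "clusters merged,",
      x$n_features_removed, "features removed (",
      sprintf("%.1f%%", 100 * x$fraction_joined), ")\n")
  if (length(x$chained_clusters))
    cat("  ", length(x$chained_clusters),
        "cluster(s) joined only through intermediates\n")
  invisible(x)
}
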