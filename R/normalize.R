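#' log2(y + 1) transform
#'
#' Raw peak heights span more than six orders of magnitude; the +1 offset
#' keeps non-detects at 0. The transform is strictly monotone and
#' invertible (`2^y - 1`).
#'
#' @param table a `FeatureTable` on the raw or ISTD-scaled scale
#' @return the transformed `FeatureTable` (`scale_tag = "log2"`)
#' @export
log2_transform <- function(table) {
  stopifnot(table$scale_tag %in% c("raw", "istd_scaled"))
  if (length(table$abundance) && any(table$abundance < 0))
    stop("negative abundance: log2(y + 1) undefined")
  table$abundance <- log2(table$abundance + 1)
  table$scale_tag <- "log2"
  table
}

#' Quantile normalization
#'
#' Classic sorted-mean algorithm: the reference distribution is the mean
#' across samples of the sorted columns; every entry is replaced by the
#' reference value at its within-column rank, tied entries receiving the
#' mean of the reference values over the tied rank span. Afterwards every
#' column follows the reference distribution (identical multisets when
#' the columns are tie-free). Zeros (non-detects on the log2 scale)
#' participate like any other value and form one tie group per column.
#'
#' @param table a `FeatureTable` with `scale_tag = "log2"`
#' @return the normalized `FeatureTable` (`scale_tag = "log2_quantile"`)
#' @export
quantile_normalize <- function(table) {
  stopifnot(table$scale_tag == "log2")
  X <- table$abundance
  if (ncol(X) < 2) {
    message("single-sample table: quantile normalization is the identity")
    table$scale_tag <- "log2_quantile"
    return(table)
  }
  if (nrow(X) >= 1) {
    ref <- rowMeans(apply(X, 2, sort))
    for (j in seq_len(ncol(X))) {
      pos <- rank(X[, j], ties.method = "first")
      v <- ref[pos]
      X[, j] <- stats::ave(v, X[, j], FUN = mean)
    }
    table$abundance <- X
  }
  table$scale_tag <- "log2_quantile"
  table
}

#' Scale peak heights by the per-sample median internal standard
#'
#' Every height in a sample is divided by the median peak height of the
#' designated isotopically labelled internal standards (ISTDs) in that
#' sample, removing shared per-sample response differences (injection and
#' ionization efficiency, batch-wide drift the ISTDs experience). ISTD
#' rows themselves are scaled too and are typically excluded downstream.
#'
#' @param table a raw-scale `FeatureTable`
#' @param istds integer vector of ISTD feature ids (all present in the
#'   table), used to compute the divisors
#' @param divisors optional named numeric vector (by sample id) of
#'   precomputed divisors, e.g. from the unfiltered table when ISTD rows
#'   have been filtered out; overrides `istds`
#' @param normalize rescale the divisors to geometric mean 1 (default).
#'   This keeps the scaled heights in their original counts range —
#'   only the per-sample ratios matter for the correction — so a later
#'   log2(y + 1) transform treats detected peaks as a per-sample shift
#'   instead of crushing them toward the +1 offset. Set `FALSE` to
#'   divide by the literal median ISTD heights.
#' @return list with `table` (`scale_tag = "istd_scaled"`) and `divisors`
#'   (as applied)
#' @export
istd_scale <- function(table, istds = NULL, divisors = NULL,
                       normalize = TRUE) {
  stopifnot(table$scale_tag == "raw")
  if (is.null(divisors)) {
    if (is.null(istds) || !length(istds))
      stop("istds must be a non-empty set of feature ids")
    rows <- match(istds, table$features$feature_id)
    if (anyNA(rows))
      stop("ISTD feature id(s) not in table: ",
           paste(istds[is.na(rows)], collapse = ", "))
    divisors <- apply(table$abundance[rows, , drop = FALSE], 2,
                      stats::median)
    names(divisors) <- table$samples$sample_id
  } else {
    divisors <- divisors[table$samples$sample_id]
  }
  bad <- which(is.na(divisors) | divisors <= 0)
  if (length(bad))
    stop("median ISTD height is zero/undefined for sample(s): ",
         paste(table$samples$sample_id[bad], collapse = ", "))
  if (normalize) divisors <- divisors / exp(mean(log(divisors)))
  table$abundance <- sweep(table$abundance, 2, divisors, `/`)
  table$scale_tag <- "istd_scaled"
  list(table = table, divisors = divisors)
}
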