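#' Feature filtering rules
#'
#' @description
#' Five sequential rules remove low-quality and background features from a
#' raw alignment:
#' \itemize{
#'   \item [filter_snr()]: signal-to-noise at least 10 (features with no
#'     reported S/N are kept — missingness is an export artifact, not
#'     evidence of noise).
#'   \item [filter_blank()]: maximum wastewater signal strictly greater
#'     than 10 times the mean method-blank signal (mean includes zeros).
#'   \item [filter_rt()]: retention time at least 4.5 min (early eluters
#'     align unreliably).
#'   \item [filter_min_height()]: at least 3000 counts in at least one
#'     wastewater sample (drops features only present in blanks, spikes
#'     or standards).
#'   \item [filter_frequency()]: detected (height > 0) in at least 60% of
#'     the samples of at least one month or one site.
#' }
#' All filters are row subsets: surviving abundances are unchanged. The
#' boundary semantics are inclusive for "cut-off of ten" and "at least
#' 3000", strict for "greater than ten times", and "below 4.5 min
#' excluded" keeps rt >= 4.5.
#'
#' @name filtering
NULL

#' @rdname filtering
#' @param table a raw-scale `FeatureTable`
#' @param threshold S/N cut-off (kept when `snr >= threshold`)
#' @return the filtered `FeatureTable`
#' @export
filter_snr <- function(table, threshold = 10) {
  stopifnot(table$scale_tag == "raw")
  if (threshold <= 0) stop("threshold must be > 0")
  snr <- table$features$snr
  if (anyNA(snr))
    message(sum(is.na(snr)), " feature(s) with absent S/N kept")
  subset_features(table, is.na(snr) | snr >= threshold)
}

#' @rdname filtering
#' @param fold blank-filter multiplier (kept when
#'   `max(wastewater) > fold * mean(blanks)`)
#' @export
filter_blank <- function(table, fold = 10) {
  stopifnot(table$scale_tag == "raw")
  ww <- ww_cols(table)
  if (!length(ww)) stop("table has no wastewater samples")
  bl <- blank_cols(table)
  if (!length(bl)) {
    warning("no method blanks present; blank filter skipped")
    return(table)
  }
  max_ww <- apply(table$abundance[, ww, drop = FALSE], 1, max)
  mean_bl <- rowMeans(table$abundance[, bl, drop = FALSE])
  subset_features(table, max_ww > fold * mean_bl)
}

#' @rdname filtering
#' @param min_rt minimum retention time in minutes (kept when
#'   `rt_min >= min_rt`)
#' @export
filter_rt <- function(table, min_rt = 4.5) {
  stopifnot(table$scale_tag == "raw")
  subset_features(table, table$features$rt_min >= min_rt)
}

#' @rdname filtering
#' @param floor minimum peak height in counts; a feature is kept when its
#'   maximum over wastewater samples is `>= floor`
#' @export
filter_min_height <- function(table, floor = 3000) {
  stopifnot(table$scale_tag == "raw")
  ww <- ww_cols(table)
  if (!length(ww)) stop("table has no wastewater samples")
  max_ww <- apply(table$abundance[, ww, drop = FALSE], 1, max)
  subset_features(table, max_ww >= floor)
}

#' @rdname filtering
#' @param design a [sample_design()] covering all wastewater samples
#' @param frac occurrence fraction; a feature is kept when detected
#'   (abundance > 0) in at least `frac` of the samples of some month or
#'   some site
#' @export
filter_frequency <- function(table, design = sample_design(table),
                             frac = 0.60) {
  stopifnot(table$scale_tag == "raw")
  ww <- ww_cols(table)
  if (!length(ww)) stop("table has no wastewater samples")
  d <- design[match(table$samples$sample_id[ww], design$sample_id), ]
  if (anyNA(d$sample_id))
    stop("design does not cover all wastewater samples")
  det <- table$abundance[, ww, drop = FALSE] > 0
  keep <- rep(FALSE, n_features(table))
  for (grouping in c("month", "site")) {
    g <- as.character(d[[grouping]])
    for (lev in unique(stats::na.omit(g))) {
      j <- which(g == lev)
      if (!length(j)) next                       # empty group ignored
      keep <- keep | rowMeans(det[, j, drop = FALSE]) >= frac
    }
  }
  subset_features(table, keep)
}

#' Restrict a FeatureTable to samples of given roles
#'
#' @param table a `FeatureTable`
#' @param roles character vector of roles to keep (default: the final
#'   wastewater-only analysis set)
#' @return the `FeatureTable` with only the requested sample columns;
#'   feature rows are unchanged
#' @export
restrict_samples <- function(table, roles = "wastewater") {
  keep <- table$samples$role %in% roles
  if (!any(keep)) stop("restriction to roles {",
                       paste(roles, collapse = ", "),
                       "} leaves no samples")
  subset_samples(table, keep)
}

#' Apply the standard filter cascade with an accounting report
#'
#' Runs S/N, blank, retention-time and minimum-height filters in the
#' canonical order and records how many features each rule removed.
#' Split-feature joining and the frequency filter sit between/after these
#' in the full pipeline (see [run_recipe()]) and report separately.
#'
#' @param table raw `FeatureTable`
#' @param snr_threshold,blank_fold,min_rt,min_height rule parameters, see
#'   [filtering]
#' @return list with `table` (filtered) and `report` (data.frame of
#'   per-rule removals; attributes `n_in`, `n_out`)
#' @export
filter_features <- function(table, snr_threshold = 10, blank_fold = 10,
                            min_rt = 4.5, min_height = 3000) {
  n_in <- n_features(table)
  steps <- list(
    snr = function(t) filter_snr(t, snr_threshold),
    blank = function(t) filter_blank(t, blank_fold),
    rt = function(t) filter_rt(t, min_rt),
    min_height = function(t) filter_min_height(t, min_height))
  removed <- integer(length(steps))
  names(removed) <- names(steps)
  for (s in names(steps)) {
    before <- n_features(table)
    table <- steps[[s]](table)
    removed[s] <- before - n_features(table)
  }
  report <- data.frame(rule = names(removed), n_removed = unname(removed))
  attr(report, "n_in") <- n_in
  attr(report, "n_out") <- n_features(table)
  list(table = table, report = report)
}
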