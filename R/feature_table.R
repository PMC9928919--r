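#' @title Feature tables for nontarget LC-HRMS data
#'
#' @description
#' A `FeatureTable` couples a feature-by-sample matrix of peak heights with
#' feature metadata (m/z, retention time, S/N, MS1 isotope-abundance ratio)
#' and sample metadata (role, site, month, analytical batch). It is the
#' single container passed between every processing stage; the `scale_tag`
#' field records which transformations have been applied so that stages can
#' refuse input on the wrong scale.
#'
#' @name FeatureTable
NULL

.scale_tags <- c("raw", "istd_scaled", "log2", "log2_quantile",
                 "log2_combat", "log2_quantile_combat")

.sample_roles <- c("wastewater", "method_blank", "matrix_spike",
                   "calibration_standard")

#' Construct a FeatureTable
#'
#' @param features data.frame with columns `feature_id` (unique integers),
#'   `mz` (Th, > 0), `rt_min` (minutes, >= 0), `snr` (signal-to-noise,
#'   `NA` allowed for "not reported"), `isotope_ratio` (MS1 M+1/M or M+2/M
#'   abundance ratio, `NA` allowed).
#' @param samples data.frame with columns `sample_id` (unique),
#'   `role` (one of wastewater, method_blank, matrix_spike,
#'   calibration_standard), `site`, `month`, `batch` (`NA` where not
#'   applicable; wastewater samples must carry site and month).
#' @param abundance numeric matrix, rows = features, columns = samples.
#'   Entries must be non-negative when `scale_tag = "raw"`.
#' @param scale_tag processing state, one of `"raw"`, `"istd_scaled"`,
#'   `"log2"`, `"log2_quantile"`, `"log2_quantile_combat"`.
#'
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(features, samples, abundance, scale_tag = "raw") {
  stopifnot(is.data.frame(features), is.data.frame(samples),
            is.matrix(abundance))
  scale_tag <- match.arg(scale_tag, .scale_tags)

  req_f <- c("feature_id", "mz", "rt_min", "snr", "isotope_ratio")
  miss <- setdiff(req_f, names(features))
  if (length(miss))
    stop("features is missing column(s): ", paste(miss, collapse = ", "))
  req_s <- c("sample_id", "role", "site", "month", "batch")
  miss <- setdiff(req_s, names(samples))
  if (length(miss))
    stop("samples is missing column(s): ", paste(miss, collapse = ", "))

  if (nrow(abundance) != nrow(features) || ncol(abundance) != nrow(samples))
    stop("abundance must be ", nrow(features), " x ", nrow(samples),
         ", got ", nrow(abundance), " x ", ncol(abundance))
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id")
  bad_role <- setdiff(unique(samples$role), .sample_roles)
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))

  if (nrow(features)) {
    if (any(!is.finite(features$mz)) || any(features$mz <= 0))
      stop("feature mz must be finite and > 0")
    if (any(!is.finite(features$rt_min)) || any(features$rt_min < 0))
      stop("feature rt_min must be finite and >= 0")
    if (any(features$snr < 0, na.rm = TRUE))
      stop("feature snr must be >= 0 when present")
    if (any(features$isotope_ratio < 0, na.rm = TRUE))
      stop("feature isotope_ratio must be >= 0 when present")
  }
  if (anyNA(abundance) || any(!is.finite(abundance)))
    stop("abundance entries must be finite and non-missing ",
         "(absent detections are encoded as 0)")
  if (scale_tag == "raw" && nrow(abundance) && any(abundance < 0))
    stop("raw abundance entries must be >= 0")

  ww <- samples$role == "wastewater"
  if (any(ww & (is.na(samples$site) | is.na(samples$month))))
    stop("wastewater samples must have site and month")
  key <- paste(samples$month[ww], samples$site[ww])
  if (anyDuplicated(key))
    stop("duplicate (month, site) wastewater sample: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  rownames(abundance) <- as.character(features$feature_id)
  colnames(abundance) <- as.character(samples$sample_id)
  rownames(features) <- NULL
  rownames(samples) <- NULL

  structure(list(features = features, samples = samples,
                 abundance = abundance, scale_tag = scale_tag),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat("FeatureTable:", nrow(x$features), "features x",
      nrow(x$samples), "samples [scale:", x$scale_tag, "]\n")
  tab <- table(x$samples$role)
  cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!all(is.na(x$samples$batch)))
    cat("  batches:", paste(sort(unique(stats::na.omit(x$samples$batch))),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Number of features / samples in a FeatureTable
#' @param table a `FeatureTable`
#' @return integer count
#' @export
n_features <- function(table) nrow(table$features)

#' @rdname n_features
#' @export
n_samples <- function(table) nrow(table$samples)

#' @export
dim.FeatureTable <- function(x) c(nrow(x$features), nrow(x$samples))

# Row subset preserving metadata/matrix correspondence.
subset_features <- function(table, keep) {
  table$features <- table$features[keep, , drop = FALSE]
  rownames(table$features) <- NULL
  table$abundance <- table$abundance[keep, , drop = FALSE]
  table
}

# Column subset preserving metadata/matrix correspondence.
subset_samples <- function(table, keep) {
  table$samples <- table$samples[keep, , drop = FALSE]
  rownames(table$samples) <- NULL
  table$abundance <- table$abundance[, keep, drop = FALSE]
  table
}

ww_cols <- function(table) which(table$samples$role == "wastewater")
blank_cols <- function(table) which(table$samples$role == "method_blank")

# Chronological order of the default sampling campaign; levels actually
# present are kept in this order, anything else is appended alphabetically.
.month_order <- c("May", "June", "July", "August", "September",
                  "November", "January")

month_factor <- function(x) {
  lev <- c(intersect(.month_order, unique(x)),
           sort(setdiff(unique(stats::na.omit(x)), .month_order)))
  factor(x, levels = lev)
}

#' Extract the experimental design of a FeatureTable
#'
#' Returns the factor assignments (sampling month, sampling location,
#' analytical batch) used by the mixed models, contrasts, and the
#' frequency filter. Months are ordered chronologically.
#'
#' @param table a `FeatureTable`
#' @param roles sample roles to include (default wastewater only)
#' @return data.frame with columns `sample_id`, `month`, `site`, `batch`
#'   (factors; class `SampleDesign`)
#' @export
sample_design <- function(table, roles = "wastewater") {
  s <- table$samples[table$samples$role %in% roles, , drop = FALSE]
  d <- data.frame(sample_id = s$sample_id,
                  month = month_factor(s$month),
                  site = factor(s$site),
                  batch = factor(s$batch),
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  class(d) <- c("SampleDesign", "data.frame")
  d
}

# Align a design to the columns of a table (wastewater subset), erroring on
# wastewater samples with no design row.
design_for <- function(table, design) {
  idx <- match(table$samples$sample_id, design$sample_id)
  ww <- table$samples$role == "wastewater"
  if (any(ww & is.na(idx)))
    stop("design does not cover sample(s): ",
         paste(table$samples$sample_id[ww & is.na(idx)], collapse = ", "))
  design[idx, , drop = FALSE]
}
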