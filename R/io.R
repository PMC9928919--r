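#' Default feature-metadata column names of an MS-DIAL style export
#'
#' Export column headers vary between MS-DIAL versions, so the reader takes
#' a configurable map from internal field names to file column names; this
#' is the default.
#'
#' @return named character vector mapping internal names to column headers
#' @export
default_column_map <- function() {
  c(feature_id = "Alignment ID",
    mz = "Average Mz",
    rt_min = "Average Rt(min)",
    snr = "S/N",
    isotope_ratio = "MS1 isotopic ratio")
}

# Parse a character vector of numbers that may carry thousands separators
# ("165,052"). Blank/NA cells become NA. Unparseable cells are reported
# with their file row and column.
parse_numeric_cells <- function(x, column, data_row_offset = 1L) {
  x <- trimws(x)
  x[x %in% c("", "NA", "NaN", "null")] <- NA_character_
  y <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  bad <- which(!is.na(x) & is.na(y))
  if (length(bad))
    stop("unparseable numeric value ", dQuote(x[bad[1]]),
         " in column ", dQuote(column),
         ", data row ", bad[1] + data_row_offset - 1L)
  y
}

# Sniff tab vs comma separation from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Read a sample annotation file
#'
#' Tab- or comma-separated, with columns `sample_id`, `role`, and
#' optionally `site`, `month`, `batch` (blank where not applicable).
#'
#' @param path annotation file
#' @return data.frame of sample metadata
#' @export
read_sample_annotation <- function(path) {
  ann <- read_delim_auto(path)
  need <- c("sample_id", "role")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("sample annotation is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("site", "month", "batch"))
    if (is.null(ann[[col]])) ann[[col]] <- NA_character_
  blank <- function(x) { x[trimws(x) == ""] <- NA_character_; x }
  data.frame(sample_id = ann$sample_id,
             role = ann$role,
             site = blank(ann$site),
             month = blank(ann$month),
             batch = as.integer(parse_numeric_cells(ann$batch, "batch")),
             stringsAsFactors = FALSE)
}

#' Read an MS-DIAL style alignment export
#'
#' Parses a tab-delimited alignment table (one header row; feature
#' metadata columns plus one peak-height column per sample) into a
#' [feature_table()]. Thousands separators in numeric cells are accepted.
#' Missing heights are read as 0 (absence of detection); missing S/N or
#' isotope ratio stay `NA` so downstream rules can distinguish "no value"
#' from 0.
#'
#' @param path alignment export (tab-separated)
#' @param sample_annotation annotation file path (see
#'   [read_sample_annotation()]) or an equivalent data.frame
#' @param column_map named character vector as in [default_column_map()];
#'   entries for `snr` / `isotope_ratio` whose column is absent from the
#'   file yield all-`NA` metadata rather than an error
#' @return a `FeatureTable` with `scale_tag = "raw"`
#' @export
read_alignment <- function(path, sample_annotation,
                           column_map = default_column_map()) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE)
  ann <- if (is.data.frame(sample_annotation)) sample_annotation
         else read_sample_annotation(sample_annotation)

  need <- c("feature_id", "mz", "rt_min")
  miss <- setdiff(need, names(column_map))
  if (length(miss))
    stop("column_map is missing entries for: ", paste(miss, collapse = ", "))
  absent_required <- setdiff(column_map[need], names(raw))
  if (length(absent_required))
    stop("alignment file lacks required column(s): ",
         paste(absent_required, collapse = ", "))

  grab <- function(field) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw))
      return(rep(NA_real_, nrow(raw)))
    parse_numeric_cells(raw[[col]], col)
  }
  features <- data.frame(
    feature_id = as.integer(grab("feature_id")),
    mz = grab("mz"),
    rt_min = grab("rt_min"),
    snr = grab("snr"),
    isotope_ratio = grab("isotope_ratio"))

  sample_cols <- setdiff(names(raw), column_map[column_map %in% names(raw)])
  unknown <- setdiff(sample_cols, ann$sample_id)
  if (length(unknown))
    stop("sample column(s) without annotation: ",
         paste(unknown, collapse = ", "))
  samples <- ann[match(sample_cols, ann$sample_id), , drop = FALSE]

  abundance <- matrix(0, nrow(raw), length(sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- parse_numeric_cells(raw[[sample_cols[j]]], sample_cols[j])
    v[is.na(v)] <- 0
    abundance[, j] <- v
  }
  feature_table(features, samples, abundance, scale_tag = "raw")
}

#' Write a FeatureTable as an alignment-style export
#'
#' Tab-separated, "." decimal separator, no thousands separators, full
#' double precision, so that `read_alignment()` of the written file
#' reproduces the matrix exactly.
#'
#' @param table a `FeatureTable`
#' @param path output file
#' @param annotation_path optional path to also write the sample
#'   annotation needed to re-read the file
#' @param column_map as in [read_alignment()]
#' @return invisibly, `path`
#' @export
write_alignment <- function(table, path, annotation_path = NULL,
                            column_map = default_column_map()) {
  fmt <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    out
  }
  f <- table$features
  df <- data.frame(fmt(f$feature_id), fmt(f$mz), fmt(f$rt_min),
                   fmt(f$snr), fmt(f$isotope_ratio),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- column_map[c("feature_id", "mz", "rt_min",
                            "snr", "isotope_ratio")]
  for (j in seq_len(n_samples(table)))
    df[[table$samples$sample_id[j]]] <- fmt(table$abundance[, j])
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write alignment to ", path, ": ",
         conditionMessage(ok))
  if (!is.null(annotation_path)) {
    s <- table$samples
    utils::write.table(s, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
  }
  invisible(path)
}
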