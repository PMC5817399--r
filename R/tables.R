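INFRACLASSES <- c("Chondrostei", "Holostei", "Teleostei", "Incertae sedis")
ENVIRONMENTS <- c("marine", "freshwater")

#' Read a specimen metadata table
#'
#' CSV with columns `specimen_id, species, genus, family, infraclass,
#' environment, stage, lagerstatten_only`. `infraclass` must be one of
#' Chondrostei, Holostei, Teleostei or Incertae sedis; `environment` one of
#' marine or freshwater; `lagerstatten_only` logical (TRUE/FALSE or 0/1).
#' Unknown categorical values are a hard error naming the offending row:
#' silently dropping specimens would corrupt time-bin sample sizes.
#'
#' @param path path to the metadata CSV.
#' @return A data.frame of specimen records, file order preserved.
#' @export
readMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "species", "genus", "family", "infraclass",
                "environment", "stage", "lagerstatten_only")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$infraclass %in% INFRACLASSES)
  if (length(bad))
    stop("row ", bad[1], ": unknown infraclass '", df$infraclass[bad[1]],
         "' (expected one of ", paste(INFRACLASSES, collapse = ", "), ")")
  bad <- which(!df$environment %in% ENVIRONMENTS)
  if (length(bad))
    stop("row ", bad[1], ": unknown environment '", df$environment[bad[1]],
         "' (expected one of ", paste(ENVIRONMENTS, collapse = ", "), ")")
  if (anyDuplicated(df$specimen_id))
    stop("duplicated specimen_id in metadata: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
               collapse = ", "))
  df$lagerstatten_only <- as.logical(df$lagerstatten_only)
  if (anyNA(df$lagerstatten_only))
    stop("lagerstatten_only must be TRUE/FALSE (or 0/1) in every row")
  df[required]
}

#' Read a functional trait table
#'
#' CSV with columns `specimen_id, char1..char5`; empty cells are missing
#' values. Present values must be strictly positive (all five characters are
#' ratios of positive measurements).
#'
#' @param path path to the trait CSV.
#' @return A data.frame with `specimen_id` and numeric `char1..char5`.
#' @export
readTraitTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", paste0("char", 1:5))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[required]
  for (ch in paste0("char", 1:5)) {
    df[[ch]] <- as.numeric(df[[ch]])
    bad <- which(!is.na(df[[ch]]) & df[[ch]] <= 0)
    if (length(bad))
      stop("row ", bad[1], ": non-positive value in ", ch)
  }
  df
}

#' Write trait table to CSV (empty cell = missing)
#' @param traits data.frame as returned by [readTraitTable()].
#' @param path output path.
#' @export
writeTraitTable <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write disparity series to CSV
#'
#' One row per time bin and metric with columns
#' `bin, metric, value, ci_low, ci_high, n`.
#'
#' @param path output path.
#' @param ... one or more `disparity_series` objects (see [disparitySeries()]).
#' @export
writeSeries <- function(path, ...) {
  series <- list(...)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(bin = s$bin, metric = s$metric, value = s$value,
               ci_low = s$ci_low, ci_high = s$ci_high, n = s$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a disparity series CSV written by [writeSeries()]
#' @param path path to the CSV.
#' @return A data.frame with bin, metric, value, ci_low, ci_high, n.
#' @export
readSeries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("bin", "metric", "value", "ci_low", "ci_high", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("series file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read a raw jaw-measurement table
#'
#' CSV with columns `specimen_id, inlever, outlever_anterior,
#' outlever_posterior, max_depth, jaw_length, jaw_area, tooth_row`; empty
#' cells are missing. Lengths in any single consistent unit; `jaw_area` in
#' that unit squared. Present values must be strictly positive. A jaw deeper
#' than it is long is anatomically surprising but not impossible, so
#' `max_depth > jaw_length` only warns.
#'
#' @param path path to the measurement CSV.
#' @return A data.frame of measurements.
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "inlever", "outlever_anterior",
                "outlever_posterior", "max_depth", "jaw_length", "jaw_area",
                "tooth_row")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[required]
  for (m in required[-1]) {
    df[[m]] <- as.numeric(df[[m]])
    bad <- which(!is.na(df[[m]]) & df[[m]] <= 0)
    if (length(bad))
      stop("row ", bad[1], ": non-positive value in ", m)
  }
  odd <- which(!is.na(df$max_depth) & !is.na(df$jaw_length) &
                 df$max_depth > df$jaw_length)
  if (length(odd))
    warning("max_depth exceeds jaw_length in ", length(odd), " row(s)")
  df
}

# Join-key check used by the pipeline: every id in `ids` must be present in
# the metadata; unmatched ids are a hard error listing them.
checkIdsMatch <- function(ids, metadata, what = "input") {
  unmatched <- setdiff(ids, metadata$specimen_id)
  if (length(unmatched))
    stop(what, " specimen_id(s) absent from metadata: ",
         paste(utils::head(unmatched, 10), collapse = ", "),
         if (length(unmatched) > 10) ", ..." else "")
  invisible(TRUE)
}
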