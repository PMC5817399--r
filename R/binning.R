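#' Construct a time-bin scheme
#'
#' An ordered (oldest to youngest) set of named time bins, each a disjoint,
#' non-empty set of stratigraphic stages with a midpoint age in Ma.
#'
#' @param df data.frame with columns `bin`, `stage`, `midpoint_ma` (one row
#'   per member stage; bins ordered by first appearance), or the path of such
#'   a CSV.
#' @return An object of class `time_bin_scheme`: `bins` (ordered names),
#'   `stages` (named list of stage vectors), `midpoints` (named numeric,
#'   Ma), `stage_to_bin` (named lookup).
#' @export
timeBinScheme <- function(df) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  required <- c("bin", "stage", "midpoint_ma")
  if (length(setdiff(required, names(df))))
    stop("bin scheme needs columns: ", paste(required, collapse = ", "))
  bins <- unique(df$bin)
  if (anyDuplicated(df$stage))
    stop("stage assigned to more than one bin: ",
         paste(unique(df$stage[duplicated(df$stage)]), collapse = ", "))
  stages <- split(df$stage, factor(df$bin, levels = bins))
  if (any(lengths(stages) == 0)) stop("empty bin in scheme")
  midpoints <- vapply(bins, function(b)
    unique(df$midpoint_ma[df$bin == b])[1], numeric(1))
  if (is.unsorted(rev(midpoints)))
    stop("bins must be ordered oldest to youngest (decreasing midpoint age)")
  stage_to_bin <- stats::setNames(df$bin, df$stage)
  structure(list(bins = bins, stages = stages,
                 midpoints = stats::setNames(midpoints, bins),
                 stage_to_bin = stage_to_bin),
            class = "time_bin_scheme")
}

#' @export
print.time_bin_scheme <- function(x, ...) {
  cat("Time bin scheme: ", length(x$bins), " bins, ",
      length(x$stage_to_bin), " stages (",
      max(x$midpoints), "-", min(x$midpoints), " Ma)\n", sep = "")
  invisible(x)
}

#' The default Permian-Jurassic 17-bin scheme
#'
#' Seventeen time bins spanning the Asselian (298.9 Ma) to the Tithonian
#' (145 Ma): twelve single-stage bins and five combined bins (early, middle
#' and late Permian, Early Triassic, Middle Jurassic) built from 27 ICS
#' stages, combining short and under-sampled stages. Combined-bin membership
#' follows ICS series boundaries; midpoints are stage/series midpoints on
#' the ICS 2016 timescale. The scheme ships as an editable CSV
#' (`system.file("extdata", "bins_permian_jurassic.csv", package =
#' "morphodisp")`), so alternative schemes (e.g. series-level bins across
#' the Permo-Triassic boundary) are a config swap, not a code change.
#'
#' @return A `time_bin_scheme` with 17 bins.
#' @export
permianJurassicBins <- function() {
  timeBinScheme(system.file("extdata", "bins_permian_jurassic.csv",
                            package = "morphodisp", mustWork = TRUE))
}

#' Assign specimens to time bins
#'
#' Maps each specimen's stage to its bin. Unknown stages are a hard error
#' listing the offending specimens; input order is preserved within bins.
#'
#' @param records metadata data.frame from [readMetadata()].
#' @param scheme a `time_bin_scheme`.
#' @return An object of class `binned_dataset`: `bins` (named list of
#'   specimen-id vectors in scheme order), `n` (named counts), `scheme`,
#'   `records`.
#' @export
assignBins <- function(records, scheme) {
  stopifnot(inherits(scheme, "time_bin_scheme"))
  bin_of <- scheme$stage_to_bin[records$stage]
  if (anyNA(bin_of)) {
    bad <- records$specimen_id[is.na(bin_of)]
    stop("stage(s) not in the bin scheme for specimen(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "")
  }
  members <- lapply(scheme$bins, function(b)
    records$specimen_id[bin_of == b])
  names(members) <- scheme$bins
  structure(list(bins = members, n = lengths(members), scheme = scheme,
                 records = records),
            class = "binned_dataset")
}

#' @export
print.binned_dataset <- function(x, ...) {
  cat("Binned dataset: ", sum(x$n), " specimens in ", length(x$bins),
      " bins\n", sep = "")
  print(x$n)
  invisible(x)
}

#' Per-bin sample sizes (within-study diversity series)
#'
#' @param binned a `binned_dataset`.
#' @return Named integer vector of counts in scheme order (empty bins report
#'   zero).
#' @export
binSizes <- function(binned) {
  stopifnot(inherits(binned, "binned_dataset"))
  binned$n
}

#' Smallest occupied bin
#'
#' @param binned a `binned_dataset`.
#' @param ignore_empty skip bins with zero specimens (default TRUE).
#' @return List with `bin` and `n`.
#' @export
minBinSize <- function(binned, ignore_empty = TRUE) {
  n <- binned$n
  if (ignore_empty) n <- n[n > 0]
  if (!length(n)) stop("no occupied bins")
  i <- which.min(n)
  list(bin = names(n)[i], n = unname(n[i]))
}

#' Subset specimen records by subgroup
#'
#' Composable filters over the metadata: by infraclass, environment, and/or
#' removal of specimens known only from Lagerstaetten deposits (the
#' preservation-bias sensitivity analysis).
#'
#' @param records metadata data.frame.
#' @param infraclass optional infraclass value(s) to keep.
#' @param environment optional environment value(s) to keep.
#' @param drop_lagerstatten drop rows with `lagerstatten_only = TRUE`.
#' @return The filtered data.frame.
#' @export
subsetRecords <- function(records, infraclass = NULL, environment = NULL,
                          drop_lagerstatten = FALSE) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(infraclass)) keep <- keep & records$infraclass %in% infraclass
  if (!is.null(environment)) keep <- keep & records$environment %in% environment
  if (drop_lagerstatten) keep <- keep & !records$lagerstatten_only
  records[keep, , drop = FALSE]
}
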