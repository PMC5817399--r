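#' Read a TPS landmark file
#'
#' Parses the plain-text TPS format produced by the tpsDig lineage of
#' digitizing tools. Each record starts with `LM=<k>` followed by `k`
#' whitespace-separated `x y` lines; optional `ID=`, `IMAGE=`, `SCALE=` and
#' `COMMENT=` lines follow. `CURVES=`/`POINTS=` blocks are ignored: the
#' sliding topology comes from the sliders file so that semilandmark identity
#' has one source of truth. When `SCALE=` is present, coordinates are
#' multiplied by it; the specimen id is taken from `ID=`, falling back to
#' the `IMAGE=` basename, falling back to `record_<i>`.
#'
#' @param path path to a TPS file.
#' @return A list of landmark configurations, each a list with `specimen_id`,
#'   `coords` (k x 2 matrix) and `scale`; records in file order.
#' @export
readTPS <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lm_at <- grep("^LM=", lines, ignore.case = TRUE)
  if (!length(lm_at)) stop("no LM= records found in ", path)
  ends <- c(lm_at[-1] - 1L, length(lines))
  out <- vector("list", length(lm_at))
  for (r in seq_along(lm_at)) {
    block <- lines[lm_at[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM=", "", block[1], ignore.case = TRUE)))
    if (is.na(k) || k < 0)
      stop("record ", r, ": malformed LM= line")
    coord_lines <- block[-1]
    is_kv <- grepl("^[A-Za-z]+=", coord_lines)
    numeric_lines <- coord_lines[!is_kv & nzchar(coord_lines)]
    if (length(numeric_lines) < k)
      stop("record ", r, ": LM=", k, " but only ", length(numeric_lines),
           " coordinate lines")
    numeric_lines <- numeric_lines[seq_len(k)]
    coords <- matrix(NA_real_, k, 2)
    for (i in seq_len(k)) {
      xy <- suppressWarnings(as.numeric(strsplit(numeric_lines[i], "[ \t]+")[[1]]))
      if (length(xy) != 2 || anyNA(xy))
        stop("record ", r, ", coordinate line ", i,
             ": expected two numbers, got '", numeric_lines[i], "'")
      coords[i, ] <- xy
    }
    kv <- coord_lines[is_kv]
    getval <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, ignore.case = TRUE, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1], ignore.case = TRUE)
      else NA_character_
    }
    id <- getval("ID")
    if (is.na(id)) {
      img <- getval("IMAGE")
      if (!is.na(img))
        id <- sub("\\.[^.]*$", "", basename(gsub("\\\\", "/", img)))
    }
    if (is.na(id) || !nzchar(id)) id <- paste0("record_", r)
    scale <- suppressWarnings(as.numeric(getval("SCALE")))
    if (!is.na(scale)) {
      if (scale <= 0) stop("record ", r, ": SCALE= must be positive")
      coords <- coords * scale
    } else scale <- NA_real_
    if (any(!is.finite(coords)))
      stop("record ", r, ": non-finite coordinate")
    out[[r]] <- list(specimen_id = id, coords = coords, scale = scale)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [readTPS()]: coordinates are written as stored (any scale
#' already applied), with an `ID=` line per record. Full-precision output so
#' a write/read round trip reproduces coordinates exactly.
#'
#' @param configurations list of configurations as returned by [readTPS()].
#' @param path output path.
#' @export
writeTPS <- function(configurations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configurations) {
    k <- nrow(cfg$coords)
    writeLines(paste0("LM=", k), con)
    writeLines(apply(cfg$coords, 1, function(p)
      paste(format(p[1], digits = 17), format(p[2], digits = 17))), con)
    writeLines(paste0("ID=", cfg$specimen_id), con)
  }
  invisible(path)
}

#' Read a semilandmark sliders file
#'
#' Each non-empty line holds `before,slider,after` as 1-based landmark
#' indices. A landmark may serve as the tangent neighbour of several sliders
#' (and a slider may be another slider's neighbour), but each slider may be
#' defined only once. An empty file yields a zero-row matrix (all-fixed
#' scheme). Range validation against a particular scheme happens at scheme
#' assembly, not here.
#'
#' @param path path to the sliders CSV.
#' @return Integer matrix with columns `before`, `slider`, `after`.
#' @export
readSliders <- function(path) {
  if (!file.exists(path)) stop("sliders file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) && grepl("^before", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines))
    return(matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("before", "slider", "after"))))
  triples <- t(vapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.integer(strsplit(lines[i], ",")[[1]]))
    if (length(v) != 3 || anyNA(v))
      stop("sliders line ", i, ": expected 'before,slider,after', got '",
           lines[i], "'")
    v
  }, integer(3)))
  colnames(triples) <- c("before", "slider", "after")
  sl <- triples[, "slider"]
  if (anyDuplicated(sl))
    stop("duplicate slider index in sliders file: ",
         paste(unique(sl[duplicated(sl)]), collapse = ", "))
  if (any(triples[, "before"] == sl) || any(triples[, "after"] == sl))
    stop("slider listed as its own tangent neighbour")
  triples
}

#' Write a sliders definition file
#' @param triples integer matrix with columns `before`, `slider`, `after`.
#' @param path output path.
#' @export
writeSliders <- function(triples, path) {
  writeLines(c("before,slider,after",
               apply(triples, 1, paste, collapse = ",")), path)
  invisible(path)
}
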