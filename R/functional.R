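#' Compute the five jaw functional characters from raw measurements
#'
#' Lower-jaw lever and proportion characters, each a dimensionless ratio
#' known to relate to feeding mechanics:
#' \describe{
#'   \item{char1}{anterior mechanical advantage: inlever (jaw joint to
#'     adductor attachment) / outlever to the anterior-most teeth.}
#'   \item{char2}{posterior mechanical advantage: inlever / outlever to the
#'     posterior-most teeth.}
#'   \item{char3}{maximum jaw depth / jaw length.}
#'   \item{char4}{average jaw depth: jaw area (without teeth) / jaw length
#'     squared.}
#'   \item{char5}{relative tooth-row length: tooth-row length / jaw length.}
#' }
#' A character is missing iff any of its input measurements is missing, so
#' preservational gaps propagate explicitly rather than silently.
#'
#' @param measurements data.frame as returned by [readMeasurements()] (or a
#'   single-row list with the same fields).
#' @return A data.frame with `specimen_id` and `char1..char5`.
#' @export
computeCharacters <- function(measurements) {
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  for (f in c("inlever", "outlever_anterior", "outlever_posterior",
              "max_depth", "jaw_length", "jaw_area", "tooth_row")) {
    if (is.null(m[[f]])) m[[f]] <- NA_real_
    bad <- which(!is.na(m[[f]]) & m[[f]] <= 0)
    if (length(bad))
      stop("row ", bad[1], ": non-positive measurement in ", f)
  }
  data.frame(specimen_id = m$specimen_id,
             char1 = m$inlever / m$outlever_anterior,
             char2 = m$inlever / m$outlever_posterior,
             char3 = m$max_depth / m$jaw_length,
             char4 = m$jaw_area / m$jaw_length^2,
             char5 = m$tooth_row / m$jaw_length,
             stringsAsFactors = FALSE)
}

#' Average functional characters within species
#'
#' Species represented by several measured specimens get, per character, the
#' arithmetic mean over the specimens in which that character is present
#' (pairwise-available averaging — an incomplete specimen still contributes
#' its recorded characters). A species' character is missing only when it is
#' missing in every specimen of that species.
#'
#' @param traits trait data.frame (`specimen_id`, `char1..char5`).
#' @param species_map named character vector or data.frame
#'   (`specimen_id`, `species`) mapping specimens to species.
#' @return A trait data.frame with one row per species (in first-appearance
#'   order), `specimen_id` holding the species name.
#' @export
averageBySpecies <- function(traits, species_map) {
  if (is.data.frame(species_map)) {
    sp <- species_map$species[match(traits$specimen_id,
                                    species_map$specimen_id)]
  } else {
    sp <- unname(species_map[traits$specimen_id])
  }
  if (anyNA(sp))
    stop("specimens without a species mapping: ",
         paste(utils::head(traits$specimen_id[is.na(sp)], 5), collapse = ", "))
  species <- unique(sp)
  out <- do.call(rbind, lapply(species, function(s) {
    rows <- traits[sp == s, paste0("char", 1:5), drop = FALSE]
    means <- vapply(rows, function(col) {
      v <- col[!is.na(col)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    cbind(data.frame(specimen_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of missing cells in a trait table
#'
#' Missing cells over `rows x 5` character cells.
#'
#' @param traits trait data.frame (`specimen_id`, `char1..char5`).
#' @return Fraction in `[0, 1]`.
#' @export
missingnessRate <- function(traits) {
  if (!nrow(traits)) stop("empty trait table")
  cells <- as.matrix(traits[paste0("char", 1:5)])
  mean(is.na(cells))
}

#' Keep only specimens with all five characters recorded
#'
#' The primary analysis path: missing-data imputation is deliberately not
#' offered, because regularized-PCA imputation of preservational gaps
#' produces artefactual linear structure in morphospace; analyses run on the
#' complete cases instead.
#'
#' @param traits trait data.frame (`specimen_id`, `char1..char5`).
#' @return A list with `traits` (the complete-case subset, order preserved)
#'   and `n_complete`.
#' @export
completeCaseFilter <- function(traits) {
  keep <- stats::complete.cases(traits[paste0("char", 1:5)])
  list(traits = traits[keep, , drop = FALSE], n_complete = sum(keep))
}
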