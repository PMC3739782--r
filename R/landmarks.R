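#' Single-specimen landmark configuration
#'
#' Holds one specimen's named 3D landmark coordinates together with the set of
#' landmark ids that could not be digitized (missing, e.g. broken before
#' burial) and specimen-level metadata.
#'
#' @param specimen_id character scalar.
#' @param points numeric matrix with 3 columns (x, y, z) and rownames giving
#'   integer landmark ids. Rows for missing landmarks are omitted.
#' @param missing integer vector of landmark ids absent from `points`.
#' @param metadata list as returned by [specimen_metadata()].
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, points, missing = integer(),
                            metadata = specimen_metadata()) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have three coordinate columns")
  if (is.null(rownames(points))) stop("points must have landmark-id rownames")
  storage.mode(points) <- "double"
  if (nrow(points) && !all(is.finite(points)))
    stop("non-missing landmarks must have three finite coordinates")
  missing <- sort(as.integer(missing))
  present <- as.integer(rownames(points))
  if (any(missing %in% present))
    stop("a landmark id cannot be both present and missing")
  colnames(points) <- c("x", "y", "z")
  structure(
    list(specimen_id = as.character(specimen_id), points = points,
         missing = missing, metadata = metadata),
    class = "landmark_config")
}

#' Specimen metadata
#'
#' @param nominal_taxon taxon label as originally assigned (may be revised by
#'   analysis; nominal species of crushed skulls are often taphomorphotypes).
#' @param age_class `"adult"` or `"juvenile"`.
#' @param skull_length optional total skull length (mm).
#' @param source free-text provenance.
#' @return A list with class `specimen_metadata`.
#' @export
specimen_metadata <- function(nominal_taxon = NA_character_,
                              age_class = c("adult", "juvenile"),
                              skull_length = NA_real_,
                              source = NA_character_) {
  age_class <- match.arg(age_class)
  structure(list(nominal_taxon = nominal_taxon, age_class = age_class,
                 skull_length = skull_length, source = source),
            class = "specimen_metadata")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d landmarks (%d missing), age %s\n",
              x$specimen_id, nrow(x$points), length(x$missing),
              x$metadata$age_class))
  invisible(x)
}

landmark_ids <- function(config) as.integer(rownames(config$points))

#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all landmarks to their centroid. Invariant to
#' translation and rotation; scales linearly under isotropic scaling.
#'
#' @param config a `landmark_config` with no missing landmarks, or a bare
#'   K x 3 coordinate matrix.
#' @return Non-negative scalar, in the length units of the coordinates.
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_config")) {
    if (length(config$missing))
      stop("centroid size is undefined with missing landmarks: ",
           paste(config$missing, collapse = ", "))
    x <- config$points
  } else {
    x <- as.matrix(config)
  }
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

## flatten K x 3 coordinates to a 3K vector (x1,y1,z1,x2,...) and back
flatten_config <- function(x) as.vector(t(x))
unflatten_config <- function(v, ids = NULL) {
  m <- matrix(v, ncol = 3, byrow = TRUE,
              dimnames = list(ids, c("x", "y", "z")))
  m
}
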