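#' Default skull wireframe connectivity
#'
#' Edge list connecting the retained landmarks of the bundled psittacosaurid
#' scheme into an interpretable wireframe (rostrum chain, naris / orbit /
#' temporal-fenestra rings, jugal horns, skull roof). Edges touching an
#' excluded or absent landmark are dropped automatically.
#'
#' @param ids optional integer vector of landmark ids actually present; edges
#'   with an endpoint outside `ids` are removed.
#' @return data frame with integer columns `from`, `to`.
#' @export
default_wireframe <- function(ids = NULL) {
  edges <- utils::read.csv(system.file("extdata", "wireframe_edges.csv",
                                       package = "taphomorph",
                                       mustWork = TRUE))
  if (!is.null(ids))
    edges <- edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write a landmark configuration as a wireframe OBJ file
#'
#' Exports the landmarks as OBJ vertices and the wireframe edges as OBJ line
#' elements, viewable in any standard mesh viewer.
#'
#' @param coords K x 3 coordinate matrix with landmark-id rownames (e.g. from
#'   [reconstruct_shape()]).
#' @param edges data frame with columns `from`, `to` holding landmark ids;
#'   defaults to [default_wireframe()] restricted to the present ids.
#' @param path output `.obj` path.
#' @param comment optional comment line written into the file header.
#' @return `path`, invisibly.
#' @export
write_wireframe_obj <- function(coords, path, edges = NULL, comment = NULL) {
  coords <- as.matrix(coords)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  if (is.null(edges)) edges <- default_wireframe(as.integer(ids))
  vi <- match(as.character(edges$from), ids)
  vj <- match(as.character(edges$to), ids)
  if (anyNA(vi) || anyNA(vj))
    stop("wireframe edges reference landmarks absent from the configuration")
  lines <- c(
    if (!is.null(comment)) paste("#", comment),
    sprintf("v %.10g %.10g %.10g", coords[, 1], coords[, 2], coords[, 3]),
    sprintf("l %d %d", vi, vj))
  writeLines(lines, path)
  invisible(path)
}
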