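#' Landmark scheme
#'
#' A landmark scheme names the homologous 3D points digitized on every
#' specimen, records which ids form bilateral (left/right) pairs across the
#' sagittal plane, which ids lie on the midline, and which ids are excluded
#' from multivariate analyses (typically because they are missing in too many
#' specimens to be worth keeping at the cost of sample size).
#'
#' @param ids integer vector of unique, sorted landmark ids.
#' @param descriptions character vector of anatomical labels, same length as
#'   `ids`.
#' @param bilateral_pairs named integer vector mapping an id to its homologue
#'   on the other side of the skull (names are ids as character). Must be
#'   symmetric (`pair[pair[i]] == i`) and irreflexive.
#' @param excluded_ids integer vector of ids excluded from analyses; subset of
#'   `ids`.
#' @param midline_ids integer vector of ids lying on the sagittal plane;
#'   disjoint from all pair members.
#' @return An object of class `landmark_scheme`.
#' @seealso [read_scheme()], [psittacosaur_scheme()], [apply_exclusions()]
#' @export
landmark_scheme <- function(ids, descriptions, bilateral_pairs = integer(),
                            excluded_ids = integer(), midline_ids = integer()) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("landmark ids must be unique")
  if (is.unsorted(ids)) stop("landmark ids must be ordered")
  if (length(descriptions) != length(ids))
    stop("one description per landmark id is required")
  excluded_ids <- as.integer(excluded_ids)
  midline_ids <- as.integer(midline_ids)
  if (!all(excluded_ids %in% ids)) stop("excluded_ids must be a subset of ids")
  if (!all(midline_ids %in% ids)) stop("midline_ids must be a subset of ids")
  bp <- as.integer(bilateral_pairs)
  names(bp) <- names(bilateral_pairs)
  if (length(bp)) {
    from <- as.integer(names(bp))
    if (!all(from %in% ids) || !all(bp %in% ids))
      stop("bilateral pair members must be landmark ids")
    if (any(from == bp)) stop("bilateral pairs must be irreflexive")
    back <- bp[as.character(bp)]
    if (!identical(unname(back), from))
      stop("bilateral pairs must be symmetric")
    if (any(midline_ids %in% c(from, bp)))
      stop("midline ids cannot belong to a bilateral pair")
  }
  structure(
    list(ids = ids, descriptions = as.character(descriptions),
         bilateral_pairs = bp, excluded_ids = sort(excluded_ids),
         midline_ids = sort(midline_ids)),
    class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("Landmark scheme: %d landmarks (%d excluded, %d midline, %d paired)\n",
              length(x$ids), length(x$excluded_ids), length(x$midline_ids),
              length(x$bilateral_pairs)))
  invisible(x)
}

#' Ids retained by a scheme (all ids minus the exclusion list)
#' @param scheme a `landmark_scheme`.
#' @return integer vector of retained landmark ids, in scheme order.
#' @export
retained_ids <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  setdiff(scheme$ids, scheme$excluded_ids)
}

#' Read / write a landmark scheme file
#'
#' The scheme file is a plain CSV with columns `id`, `description`, `pair`
#' (id of the bilateral homologue or NA), `midline` (logical) and `excluded`
#' (logical).
#'
#' @param path file path.
#' @return `read_scheme` returns a `landmark_scheme`; `write_scheme` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "description", "pair", "midline", "excluded")
  if (!all(need %in% names(df)))
    stop("scheme file must have columns: ", paste(need, collapse = ", "))
  pairs <- df$pair[!is.na(df$pair)]
  names(pairs) <- df$id[!is.na(df$pair)]
  landmark_scheme(
    ids = df$id,
    descriptions = df$description,
    bilateral_pairs = pairs,
    excluded_ids = df$id[as.logical(df$excluded)],
    midline_ids = df$id[as.logical(df$midline)])
}

#' @rdname read_scheme
#' @param scheme a `landmark_scheme` to write.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  pair <- rep(NA_integer_, length(scheme$ids))
  if (length(scheme$bilateral_pairs))
    pair[match(as.integer(names(scheme$bilateral_pairs)), scheme$ids)] <-
      scheme$bilateral_pairs
  df <- data.frame(id = scheme$ids, description = scheme$descriptions,
                   pair = pair,
                   midline = scheme$ids %in% scheme$midline_ids,
                   excluded = scheme$ids %in% scheme$excluded_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The bundled 56-landmark psittacosaurid skull scheme
#'
#' Fifty-six named cranial landmarks covering the rostrum, nares, orbits,
#' temporal fenestrae, quadrates, jugal horns and skull roof of a
#' psittacosaurid skull, digitized on both sides because taphonomic crushing
#' differs between the left and right sides. Twelve ids (17, 18, 21, 36, 39,
#' 43, 44, 45, 46, 48, 49, 50) are flagged excluded because they were missing
#' in several specimens of the study cohort, leaving 44 landmarks for
#' analysis.
#'
#' @return A `landmark_scheme` with 56 ids, 26 bilateral pairs, 4 midline ids
#'   and 12 excluded ids.
#' @export
psittacosaur_scheme <- function() {
  read_scheme(system.file("extdata", "psittacosaur_scheme.csv",
                          package = "taphomorph", mustWork = TRUE))
}
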