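#' Read landmark datasets
#'
#' Reads a multi-specimen 3D landmark file in one of three dialects into a
#' list of [landmark_config()] objects:
#'
#' * `"morphologika"` — section-based text: `[individuals]`, `[landmarks]`,
#'   `[dimensions]`, `[names]`, `[rawpoints]`, with per-specimen blocks
#'   introduced by a quoted name line (`'name`).
#' * `"tps"` — `LM3=K` records followed by K coordinate lines and an
#'   `ID=name` line.
#' * `"csv"` — long format with columns `specimen`, `landmark_id`, `x`, `y`,
#'   `z` (the canonical output dialect).
#'
#' Missing landmarks are encoded as `NA` coordinates (any dialect) or, in the
#' CSV dialect, by omitting the row entirely when a scheme supplies the full
#' id set.
#'
#' @param path input file path.
#' @param dialect one of `"morphologika"`, `"tps"`, `"csv"`.
#' @param scheme optional `landmark_scheme`; when given, landmark ids are
#'   taken from the scheme (in order) for the positional dialects, and per-
#'   specimen landmark counts are checked against it.
#' @return List of `landmark_config` objects, one per specimen.
#' @export
read_landmarks <- function(path, dialect = c("csv", "morphologika", "tps"),
                           scheme = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("landmark file not found: ", path)
  configs <- switch(dialect,
                    csv = .read_landmarks_csv(path, scheme),
                    morphologika = .read_landmarks_morphologika(path, scheme),
                    tps = .read_landmarks_tps(path, scheme))
  if (!is.null(scheme)) {
    for (cf in configs) {
      all_ids <- sort(c(landmark_ids(cf), cf$missing))
      if (!identical(all_ids, scheme$ids))
        stop("specimen ", cf$specimen_id,
             " does not cover the scheme's landmark ids")
    }
  }
  counts <- vapply(configs, function(cf) nrow(cf$points) + length(cf$missing),
                   integer(1))
  if (length(unique(counts)) > 1)
    stop("inconsistent landmark counts across specimens: ",
         paste(unique(counts), collapse = ", "))
  configs
}

.parse_num <- function(tok, line) {
  v <- suppressWarnings(as.numeric(tok))
  bad <- is.na(v) & !(toupper(tok) %in% c("NA", "NAN"))
  if (any(bad))
    stop("non-numeric coordinate '", tok[bad][1], "' at line ", line)
  v
}

.make_config <- function(specimen_id, coords, ids, metadata = NULL) {
  ## coords: K x 3 with NAs marking missing landmarks
  miss <- ids[!stats::complete.cases(coords)]
  keep <- stats::complete.cases(coords)
  m <- coords[keep, , drop = FALSE]
  rownames(m) <- ids[keep]
  landmark_config(specimen_id, m, missing = miss,
                  metadata = if (is.null(metadata)) specimen_metadata()
                             else metadata)
}

.read_landmarks_csv <- function(path, scheme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("specimen", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("malformed header: CSV dialect needs columns ",
         paste(need, collapse = ", "), " (line 1)")
  for (col in c("x", "y", "z"))
    if (!is.numeric(df[[col]]))
      df[[col]] <- .parse_num(df[[col]], line = NA)
  split_idx <- split(seq_len(nrow(df)), factor(df$specimen,
                                               levels = unique(df$specimen)))
  lapply(names(split_idx), function(sp) {
    rows <- df[split_idx[[sp]], ]
    ids <- if (is.null(scheme)) sort(unique(rows$landmark_id)) else scheme$ids
    coords <- matrix(NA_real_, length(ids), 3)
    mi <- match(rows$landmark_id, ids)
    if (anyNA(mi))
      stop("specimen ", sp, " has landmark ids outside the scheme")
    coords[mi, ] <- as.matrix(rows[, c("x", "y", "z")])
    .make_config(sp, coords, ids)
  })
}

.read_landmarks_morphologika <- function(path, scheme) {
  lines <- readLines(path)
  strip <- trimws(lines)
  sec <- function(name) {
    i <- which(tolower(strip) == paste0("[", name, "]"))
    if (length(i) != 1)
      stop("malformed header: expected one [", name, "] section")
    i
  }
  n_ind <- as.integer(strip[sec("individuals") + 1])
  n_lm <- as.integer(strip[sec("landmarks") + 1])
  n_dim <- as.integer(strip[sec("dimensions") + 1])
  if (is.na(n_ind) || is.na(n_lm) || is.na(n_dim))
    stop("malformed header: non-numeric count at line ",
         sec("individuals") + 1)
  if (n_dim != 3) stop("only 3-dimensional data are supported")
  i_names <- sec("names")
  nm <- strip[(i_names + 1):(i_names + n_ind)]
  i_raw <- sec("rawpoints")
  ids <- if (is.null(scheme)) seq_len(n_lm) else scheme$ids
  if (length(ids) != n_lm)
    stop("file has ", n_lm, " landmarks but the scheme defines ", length(ids))
  cursor <- i_raw + 1
  configs <- vector("list", n_ind)
  for (k in seq_len(n_ind)) {
    while (cursor <= length(strip) && !startsWith(strip[cursor], "'"))
      cursor <- cursor + 1
    if (cursor > length(strip))
      stop("inconsistent landmark counts: specimen block ", k, " not found")
    name <- sub("^'", "", strip[cursor])
    if (name != nm[k])
      stop("specimen name mismatch at line ", cursor, ": '", name, "'")
    coords <- matrix(NA_real_, n_lm, 3)
    for (j in seq_len(n_lm)) {
      ln <- cursor + j
      tok <- strsplit(strip[ln], "[ \t]+")[[1]]
      if (length(tok) != 3)
        stop("inconsistent landmark counts at line ", ln,
             ": expected 3 coordinates")
      coords[j, ] <- .parse_num(tok, ln)
    }
    cursor <- cursor + n_lm + 1
    configs[[k]] <- .make_config(name, coords, ids)
  }
  configs
}

.read_landmarks_tps <- function(path, scheme) {
  lines <- trimws(readLines(path))
  configs <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1; next }
    if (!grepl("^LM3=", lines[i]))
      stop("malformed header at line ", i, ": expected LM3=")
    k <- as.integer(sub("^LM3=", "", lines[i]))
    if (is.na(k)) stop("non-numeric landmark count at line ", i)
    ids <- if (is.null(scheme)) seq_len(k) else scheme$ids
    if (length(ids) != k)
      stop("record at line ", i, " has ", k,
           " landmarks but the scheme defines ", length(ids))
    coords <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      ln <- i + j
      if (ln > length(lines))
        stop("inconsistent landmark counts: truncated record at line ", i)
      tok <- strsplit(lines[ln], "[ \t]+")[[1]]
      if (length(tok) != 3)
        stop("inconsistent landmark counts at line ", ln)
      coords[j, ] <- .parse_num(tok, ln)
    }
    i <- i + k + 1
    if (i > length(lines) || !grepl("^ID=", lines[i]))
      stop("malformed record: missing ID= line at line ", i)
    name <- sub("^ID=", "", lines[i])
    i <- i + 1
    configs[[length(configs) + 1]] <- .make_config(name, coords, ids)
  }
  configs
}

.fmt <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, function(v) sprintf("%.17g", v),
                                character(1)))
}

.full_coords <- function(config, ids) {
  coords <- matrix(NA_real_, length(ids), 3)
  coords[match(landmark_ids(config), ids), ] <- config$points
  coords
}

#' Write landmark datasets
#'
#' Inverse of [read_landmarks()]. Coordinates are written with 17 significant
#' digits so that a write/read round trip reproduces every double exactly.
#'
#' @param configs list of `landmark_config` objects.
#' @param path output file path.
#' @param dialect output dialect (see [read_landmarks()]).
#' @param scheme optional `landmark_scheme` fixing the id order; defaults to
#'   the ids present in the first configuration (plus its missing ids).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(configs, path,
                            dialect = c("csv", "morphologika", "tps"),
                            scheme = NULL) {
  dialect <- match.arg(dialect)
  ids <- if (is.null(scheme))
    sort(c(landmark_ids(configs[[1]]), configs[[1]]$missing))
  else scheme$ids
  out <- switch(dialect,
    csv = {
      rows <- lapply(configs, function(cf) {
        coords <- .full_coords(cf, ids)
        paste(cf$specimen_id, ids, .fmt(coords[, 1]), .fmt(coords[, 2]),
              .fmt(coords[, 3]), sep = ",")
      })
      c("specimen,landmark_id,x,y,z", unlist(rows))
    },
    morphologika = {
      body <- unlist(lapply(configs, function(cf) {
        coords <- .full_coords(cf, ids)
        c(paste0("'", cf$specimen_id),
          paste(.fmt(coords[, 1]), .fmt(coords[, 2]), .fmt(coords[, 3])))
      }))
      c("[individuals]", length(configs),
        "[landmarks]", length(ids),
        "[dimensions]", 3,
        "[names]", vapply(configs, `[[`, character(1), "specimen_id"),
        "[rawpoints]", body)
    },
    tps = {
      unlist(lapply(configs, function(cf) {
        coords <- .full_coords(cf, ids)
        c(paste0("LM3=", length(ids)),
          paste(.fmt(coords[, 1]), .fmt(coords[, 2]), .fmt(coords[, 3])),
          paste0("ID=", cf$specimen_id))
      }))
    })
  writeLines(out, path)
  invisible(path)
}

#' Apply a scheme's exclusion rules to a set of configurations
#'
#' First removes the scheme's excluded landmark ids from every configuration
#' (trading landmarks for specimens: a landmark missing in several specimens
#' is cheaper to drop than the specimens would be). Then drops any specimen
#' that is still missing one of the retained landmarks, and reports it.
#'
#' @param configs list of `landmark_config` objects conforming to `scheme`.
#' @param scheme a `landmark_scheme`.
#' @return A list with elements `configs` (retained configurations, excluded
#'   landmarks removed, landmark order preserved) and `report` (list with
#'   `n_landmarks_retained`, `retained_ids`, `retained_specimens`, `dropped`
#'   — a named list mapping dropped specimen ids to their missing retained
#'   landmark ids).
#' @export
apply_exclusions <- function(configs, scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  keep_ids <- retained_ids(scheme)
  if (!length(keep_ids)) stop("exclusion list leaves no landmarks")
  trimmed <- lapply(configs, function(cf) {
    pres <- landmark_ids(cf)
    m <- cf$points[pres %in% keep_ids, , drop = FALSE]
    landmark_config(cf$specimen_id, m,
                    missing = intersect(cf$missing, keep_ids),
                    metadata = cf$metadata)
  })
  has_all <- vapply(trimmed, function(cf) length(cf$missing) == 0, logical(1))
  dropped <- trimmed[!has_all]
  report <- list(
    n_landmarks_retained = length(keep_ids),
    retained_ids = keep_ids,
    retained_specimens = vapply(trimmed[has_all], `[[`, character(1),
                                "specimen_id"),
    dropped = stats::setNames(
      lapply(dropped, `[[`, "missing"),
      vapply(dropped, `[[`, character(1), "specimen_id")))
  if (!any(has_all)) stop("all specimens were dropped by the exclusion rules")
  list(configs = trimmed[has_all], report = report)
}

#' Write an exclusion report as JSON
#' @param report report component of [apply_exclusions()] output.
#' @param path output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
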