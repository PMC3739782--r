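#' Pipeline configuration
#'
#' Collects every setting of the full analysis into one validated object so a
#' run is reproducible from its configuration alone. All file outputs carry
#' the configuration hash in a header comment.
#'
#' @param input path to the landmark file (or a list of `landmark_config`
#'   objects supplied directly via `configs`).
#' @param dialect landmark dialect of `input` (see [read_landmarks()]).
#' @param scheme_path path to a scheme CSV; `NULL` uses the bundled
#'   psittacosaurid scheme.
#' @param configs optional list of `landmark_config` objects overriding
#'   `input`.
#' @param apply_scheme_exclusions apply the scheme's exclusion rules
#'   (default TRUE).
#' @param gpa_tol,gpa_max_iter GPA convergence settings.
#' @param tangent tangent-space projection before PCA (default TRUE).
#' @param component_rule `"fixed_k"` (default, with `fixed_k = 4`) or
#'   `"broken_stick"`.
#' @param fixed_k retained components under `"fixed_k"`.
#' @param band_multiplier confidence-band half-width multiplier
#'   (default 1.96, the normal 95% band).
#' @param error_replicates optional path to a landmark file of replicate
#'   digitizations of one specimen (same dialect), or a list of
#'   `landmark_config`s; enables the error protocol.
#' @param error_specimen_id id of the replicated specimen, excluded from the
#'   "other specimens" side of the error comparison if present in the main
#'   sample.
#' @param allometry_pcs PC indices for the Spearman allometry tests.
#' @param drop_subsets named list of character vectors: each entry triggers a
#'   sensitivity re-run with those specimen ids removed.
#' @param wireframe_pcs PCs to export as wireframe OBJ reconstructions at the
#'   band extremes (default 1:4).
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic; the seed matters when `input` is simulated upstream).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, dialect = "csv",
                            scheme_path = NULL, configs = NULL,
                            apply_scheme_exclusions = TRUE,
                            gpa_tol = 1e-10, gpa_max_iter = 200,
                            tangent = TRUE,
                            component_rule = c("fixed_k", "broken_stick"),
                            fixed_k = 4, band_multiplier = 1.96,
                            error_replicates = NULL,
                            error_specimen_id = NULL,
                            allometry_pcs = 1:4,
                            drop_subsets = list(),
                            wireframe_pcs = 1:4,
                            out_dir = "taphomorph_out", seed = 1) {
  component_rule <- match.arg(component_rule)
  if (is.null(input) && is.null(configs))
    stop("either an input path or a list of configurations is required")
  if (!is.null(input) && !file.exists(input))
    stop("input landmark file not found: ", input)
  if (!is.null(scheme_path) && !file.exists(scheme_path))
    stop("scheme file not found: ", scheme_path)
  if (band_multiplier <= 0) stop("band multiplier must be positive")
  if (is.character(error_replicates) && !file.exists(error_replicates))
    stop("error-replicate file not found: ", error_replicates)
  structure(list(input = input, dialect = dialect, scheme_path = scheme_path,
                 configs = configs,
                 apply_scheme_exclusions = apply_scheme_exclusions,
                 gpa_tol = gpa_tol, gpa_max_iter = gpa_max_iter,
                 tangent = tangent, component_rule = component_rule,
                 fixed_k = fixed_k, band_multiplier = band_multiplier,
                 error_replicates = error_replicates,
                 error_specimen_id = error_specimen_id,
                 allometry_pcs = allometry_pcs, drop_subsets = drop_subsets,
                 wireframe_pcs = wireframe_pcs, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## deterministic short hash of the settings (FNV-1a over the canonical JSON,
## excluding in-memory objects)
config_hash <- function(config) {
  ## the hash identifies the analysis settings: in-memory objects and the
  ## output location do not contribute
  keep <- config[!(names(config) %in% c("configs", "error_replicates",
                                        "out_dir")) |
                   vapply(config, is.character, logical(1))]
  keep$out_dir <- NULL
  js <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); keep h as a double mod 2^32
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    h <- (h * 16777619) %% 4294967296
  }
  ## render the 32-bit value as hex from its two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.write_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# taphomorph config ", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  close(con)
}

#' Run the full analysis pipeline
#'
#' Reads (or accepts) the landmark configurations, applies the scheme's
#' exclusion rules, superimposes with GPA, fits the shape PCA, computes
#' variance accounting, broken-stick selection, confidence bands and outlier
#' flags, the replicate-error protocol when replicates are supplied,
#' Spearman allometry tests on the full sample and every configured drop
#' subset, and wireframe OBJ reconstructions along the leading PCs. All
#' tables, reports and a plain-text run log are written under
#' `config$out_dir`; every file names the configuration hash. Output is
#' byte-identical across runs of the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) a list with `ensemble`, `model`, `variance`, `bands`,
#'   `outliers`, `selected_k`, `error` (or NULL), `allometry` (data frame,
#'   all subsets), `report` (the exclusion report), `hash`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  scheme <- if (is.null(config$scheme_path)) psittacosaur_scheme()
            else read_scheme(config$scheme_path)
  log <- c(paste("taphomorph", as.character(utils::packageVersion("taphomorph"))),
           paste("config hash:", hash),
           paste("seed:", config$seed))
  configs <- if (!is.null(config$configs)) config$configs
             else read_landmarks(config$input, config$dialect, scheme = scheme)
  log <- c(log, sprintf("input specimens: %d", length(configs)))

  report <- NULL
  if (config$apply_scheme_exclusions) {
    ex <- apply_exclusions(configs, scheme)
    configs <- ex$configs
    report <- ex$report
    log <- c(log, sprintf("landmarks retained: %d of %d",
                          report$n_landmarks_retained, length(scheme$ids)),
             sprintf("specimens retained: %d (dropped: %s)",
                     length(configs),
                     if (length(report$dropped))
                       paste(names(report$dropped), collapse = ", ")
                     else "none"))
  }

  ensemble <- gpa(configs, tol = config$gpa_tol,
                  max_iter = config$gpa_max_iter)
  log <- c(log, sprintf("GPA: %d iterations, converged=%s, tangent=%s",
                        ensemble$iterations, ensemble$converged,
                        config$tangent))
  model <- shape_pca(ensemble, tangent = config$tangent)
  vt <- variance_table(model)
  k <- select_components(model, rule = config$component_rule,
                         k = config$fixed_k)
  log <- c(log, sprintf("PCs retained (%s): %d", config$component_rule, k),
           sprintf("broken-stick would retain: %d",
                   select_components(model, rule = "broken_stick")))
  pcs <- seq_len(max(k, max(config$allometry_pcs)))
  pcs <- pcs[pcs <= length(model$eigenvalues)]
  bands <- confidence_bands(model, pcs = pcs,
                            multiplier = config$band_multiplier)
  outliers <- flag_outliers(model, bands)
  log <- c(log, vapply(names(outliers$per_pc), function(pc)
    sprintf("outliers %s: %s", pc,
            if (length(outliers$per_pc[[pc]]))
              paste(outliers$per_pc[[pc]], collapse = ", ") else "none"),
    character(1)))

  err <- NULL
  if (!is.null(config$error_replicates)) {
    reps <- if (is.character(config$error_replicates))
      read_landmarks(config$error_replicates, config$dialect, scheme = NULL)
    else config$error_replicates
    rep_scores <- project_scores(model, reps)
    other <- model$scores
    if (!is.null(config$error_specimen_id))
      other <- other[rownames(other) != config$error_specimen_id, ,
                     drop = FALSE]
    err <- error_distances(other, rep_scores,
                           pcs = seq_len(min(4, length(model$eigenvalues))))
    log <- c(log, sprintf("error protocol: %s",
                          if (err$overlap) "OVERLAP" else "no overlap"))
  }

  allom <- spearman_allometry(model$scores, model$centroid_sizes,
                              pcs = config$allometry_pcs,
                              subset_label = paste0("all-", length(configs)))
  subset_results <- list()
  for (nm in names(config$drop_subsets)) {
    sr <- sensitivity_rerun(configs, drop = config$drop_subsets[[nm]],
                            pcs = config$allometry_pcs,
                            tangent = config$tangent,
                            gpa_tol = config$gpa_tol,
                            max_iter = config$gpa_max_iter,
                            subset_label = nm)
    subset_results[[nm]] <- sr
    allom <- rbind(allom, sr$allometry)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  .write_table(aligned_to_df(ensemble), p("aligned.csv"), hash)
  .write_table(vt, p("variance_table.csv"), hash)
  .write_table(data.frame(specimen = rownames(model$scores),
                          model$scores, row.names = NULL),
               p("scores.csv"), hash)
  .write_table(as.data.frame(bands), p("confidence_bands.csv"), hash)
  .write_table(allom, p("allometry.csv"), hash)
  jsonlite::write_json(list(config_hash = hash, per_pc = outliers$per_pc),
                       p("outliers.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(report))
    jsonlite::write_json(list(config_hash = hash, report = report),
                         p("exclusion_report.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(err)) {
    .write_table(data.frame(
      specimen = c(paste0("replicate", seq_along(err$replicate_distances)),
                   names(err$other_distances)),
      kind = rep(c("replicate", "specimen"),
                 c(length(err$replicate_distances),
                   length(err$other_distances))),
      distance = c(err$replicate_distances, err$other_distances)),
      p("error_distances.csv"), hash)
  }
  for (j in config$wireframe_pcs) {
    if (j > length(model$eigenvalues)) next
    hw <- bands$half_width[match(j, bands$pc)]
    if (is.na(hw)) next
    for (sgn in c(-1, 1)) {
      shp <- reconstruct_shape(model, j, sgn * hw)
      write_wireframe_obj(shp, p(sprintf("wireframe_PC%d_%s.obj", j,
                                         if (sgn > 0) "pos" else "neg")),
                          comment = paste("taphomorph config", hash))
    }
  }
  writeLines(log, p("run_log.txt"))
  invisible(list(ensemble = ensemble, model = model, variance = vt,
                 bands = bands, outliers = outliers, selected_k = k,
                 error = err, allometry = allom, report = report,
                 subsets = subset_results, hash = hash,
                 out_dir = config$out_dir))
}
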