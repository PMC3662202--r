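#' Build and validate a pipeline run configuration
#'
#' Every tunable of the pipeline with its standard default: significance
#' level `alpha = 0.05`, PCA `variance_target = 0.95`, PSO swarm of 30
#' particles over 200 iterations with `c1 = c2 = 2`, `w = 0.8`, and the
#' two-stage SOM schedule. Unknown fields raise a configuration error
#' naming the field, as does a missing required field.
#'
#' @param config named list (e.g. from [load_config]) overriding defaults.
#' @return Validated list of class `vm_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    out_dir = "ventmorph_out",
    n_per_group = c(NC = 17, MCI = 18, AD = 17),
    seed = 1L,
    noise_sd = 8,
    route = "II",
    feature_sets = c("volume", "shape2d"),
    classifier = "pso_svm",
    alpha = 0.05,
    variance_target = 0.95,
    classifier_args = list(),
    grid_shape = c(64L, 72L, 40L),
    voxel_size = c(2.5, 2.5, 2.5))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    vm_stop("config", "unknown config field: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (f in c("alpha", "variance_target", "seed", "route", "classifier"))
    if (is.null(cfg[[f]])) vm_stop("config", "config field missing: %s", f)
  if (!cfg$route %in% c("I", "II"))
    vm_stop("config", "route must be I or II")
  if (!cfg$classifier %in% c("som", "svm", "pso_svm"))
    vm_stop("config", "classifier must be som, svm or pso_svm")
  check_number(cfg$alpha, "alpha", min = 0)
  check_number(cfg$variance_target, "variance_target", min = 0)
  structure(cfg, class = "vm_config")
}

#' Load a configuration file
#'
#' @param path a YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return A validated [run_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) vm_stop("config", "config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  run_config(as.list(raw))
}

# short polynomial fingerprint of the canonical (name-sorted) config JSON
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  h <- 7
  for (b in utf8ToInt(as.character(js))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a feature table as CSV
#'
#' @param table data frame from [cohort_features].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) vm_stop("io", "feature CSV not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(d))
    vm_stop("io", "feature CSV is missing the group column")
  d
}

#' Run the full phantom-to-classification pipeline
#'
#' Generates (or loads) a cohort, segments every subject, assembles the
#' feature table and group statistics, runs the configured leave-one-out
#' evaluation and writes every artifact plus a JSON manifest carrying the
#' configuration and its hash.
#'
#' @param config a [run_config] (or list coerced through it).
#' @return A list of class `vm_run`: the feature table, the
#'   [feature_stats] table, the [loocv] result and the manifest, invisibly
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "vm_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_per_group = config$n_per_group,
                            seed = config$seed,
                            grid_shape = config$grid_shape,
                            voxel_size = config$voxel_size,
                            noise_sd = config$noise_sd)
  feats <- cohort_features(cohort)
  paths <- list(features = file.path(config$out_dir, "features.csv"),
                stats = file.path(config$out_dir, "feature_stats.csv"),
                results = file.path(config$out_dir, "results.csv"),
                confusion = file.path(config$out_dir, "confusion.csv"),
                masks_dir = file.path(config$out_dir, "masks"),
                manifest = file.path(config$out_dir, "manifest.json"))
  write_features(feats$table, paths$features)
  stats <- feature_stats(feats$table)
  write.csv(stats, paths$stats, row.names = FALSE)
  dir.create(paths$masks_dir, showWarnings = FALSE)
  for (i in seq_along(feats$masks))
    write_mask(feats$masks[[i]],
               file.path(paths$masks_dir,
                         paste0(cohort$manifest$subject_id[i], "_mask.nii.gz")))
  res <- loocv(feats$table, classifier = config$classifier,
               route = config$route, feature_sets = config$feature_sets,
               alpha = config$alpha,
               variance_target = config$variance_target,
               classifier_args = config$classifier_args,
               masks = feats$masks, seed = config$seed)
  per_class <- vapply(rownames(res$confusion),
                      function(cl) class_accuracy(res$confusion, cl),
                      numeric(1))
  write.csv(data.frame(metric = c("overall_accuracy",
                                  paste0("accuracy_", names(per_class))),
                       value = round_half_up(100 * c(res$accuracy, per_class), 2)),
            paths$results, row.names = FALSE)
  write.csv(as.data.frame(unclass(res$confusion)), paths$confusion)
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(unclass(config)),
                   artifacts = unlist(paths[c("features", "stats", "results",
                                              "confusion")]),
                   n_subjects = nrow(feats$table))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(structure(list(features = feats$table, stats = stats,
                           loocv = res, manifest = manifest),
                      class = "vm_run"))
}
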