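# End-to-end pipeline: synthetic generation (or user CSVs) -> features ->
# classification -> group firing statistics -> behavior scoring, with a
# manifest auditing record counts at every stage.

#' Pipeline run configuration
#'
#' Exactly one of `input` (paths to user CSVs) or `synthetic` (a
#' [cohort_spec()]) must be given.
#'
#' @param synthetic a [cohort_spec()] for a synthetic run, or `NULL`.
#' @param input list with paths `spikes`, `metadata` and optionally
#'   `waveforms`, `behavior`, or `NULL`.
#' @param classifier a [classifier_config()].
#' @param behavior_n_per_group animals per group for the synthetic
#'   behavior table (default 12; ignored when `input$behavior` is given).
#' @param alpha significance level for the statistics stage.
#' @param out_dir output directory.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(synthetic = cohort_spec(),
                       input = NULL,
                       classifier = classifier_config(),
                       behavior_n_per_group = 12,
                       alpha = 0.05,
                       out_dir = "dgephys_run",
                       seed = 1L) {
  if (is.null(synthetic) == is.null(input)) {
    dg_stop("exactly one of `synthetic` or `input` must be given",
            "dg_config_error")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_spec")) {
    dg_stop("`synthetic` must be a cohort_spec", "dg_config_error")
  }
  if (!is.null(input) &&
      !all(c("spikes", "metadata") %in% names(input))) {
    dg_stop("`input` must name at least `spikes` and `metadata` paths",
            "dg_config_error")
  }
  stopifnot(inherits(classifier, "classifier_config"))
  assert_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE,
                strict_upper = TRUE)
  structure(list(synthetic = synthetic, input = input,
                 classifier = classifier,
                 behavior_n_per_group = behavior_n_per_group,
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Serialize a config to a plain list for JSON.
.config_as_list <- function(config) {
  syn <- config$synthetic
  if (!is.null(syn)) {
    syn <- unclass(syn)
    syn$class_params <- lapply(syn$class_params, unclass)
    syn$group_rate_multipliers <-
      as.data.frame(syn$group_rate_multipliers)
  }
  list(synthetic = syn, input = config$input,
       classifier = unclass(config$classifier),
       behavior_n_per_group = config$behavior_n_per_group,
       alpha = config$alpha, seed = config$seed)
}

#' Load a run configuration from JSON or YAML
#'
#' The file mirrors the [run_config()] fields; `synthetic` fields mirror
#' [cohort_spec()] and `classifier` fields mirror [classifier_config()].
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param seed,out_dir optional overrides.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    sargs <- raw$synthetic
    if (!is.null(sargs$class_params)) {
      sargs$class_params <- lapply(sargs$class_params, as.list)
    }
    if (!is.null(sargs$group_rate_multipliers)) {
      sargs$group_rate_multipliers <-
        as.matrix(as.data.frame(sargs$group_rate_multipliers))
    }
    syn <- do.call(cohort_spec, sargs)
  }
  cls <- if (is.null(raw$classifier)) classifier_config() else
    do.call(classifier_config, raw$classifier)
  run_config(
    synthetic = syn,
    input = raw$input,
    classifier = cls,
    behavior_n_per_group = raw$behavior_n_per_group %||% 12,
    alpha = raw$alpha %||% 0.05,
    out_dir = out_dir %||% raw$out_dir %||% "dgephys_run",
    seed = seed %||% raw$seed %||% 1L
  )
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    dg_stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            "dg_stage_error")
  })
}

#' Run the full pipeline
#'
#' Chains data loading (or synthetic generation), feature extraction,
#' classification, per-class group firing statistics and behavior scoring,
#' writing `features.tsv`, `labels.tsv`, `stats.tsv`, `behavior.csv`,
#' `config.json` and `manifest.json` into the output directory.  Given the
#' same configuration and seed the outputs are byte-identical across runs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of class `dg_run` with the in-memory results
#'   (`units`, `features`, `classification`, `stats`, `behavior`,
#'   `manifest`, `out_dir`).
#' @examples
#' \donttest{
#' cfg <- run_config(synthetic = cohort_spec(animals_per_group = 2, seed = 42),
#'                   out_dir = tempfile())
#' run <- run_pipeline(cfg)
#' run$manifest$counts
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  input_checksums <- NULL

  units <- .stage("load", wh({
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- config$seed
      generate_cohort(spec)
    } else {
      paths <- unlist(config$input[c("spikes", "waveforms", "metadata",
                                     "behavior")])
      input_checksums <- as.list(tools::md5sum(paths[file.exists(paths)]))
      read_units(config$input$spikes, config$input$waveforms,
                 config$input$metadata)
    }
  }))

  features <- .stage("features", wh(compute_unit_features(units)))
  classification <- .stage("classify",
                           wh(classify_cohort(features, config$classifier)))

  labeled <- merge(classification$units, units$metadata, by = "unit_id",
                   sort = TRUE)
  stats_tab <- .stage("stats", wh(
    compare_firing_by_group(labeled, alpha = config$alpha)))

  behavior <- .stage("behavior", wh({
    raw <- if (!is.null(config$input) && !is.null(config$input$behavior)) {
      .read_csv_checked(config$input$behavior,
                        c("animal_id", "group", "defeated",
                          "phase1_s", "phase2_s"))
    } else {
      generate_behavior(config$behavior_n_per_group,
                        seed = config$seed + 1L)
    }
    score_behavior(raw)
  }))

  excluded <- sum(behavior$phenotype == "excluded")
  manifest <- list(
    tool = "dgephys",
    version = as.character(utils::packageVersion("dgephys")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(
      files = {
        tmp <- file.path(config$out_dir, "config.json")
        jsonlite::write_json(.config_as_list(config), tmp,
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        tmp
      })),
    input_checksums = input_checksums,
    counts = list(
      units_in = nrow(units$metadata),
      features = nrow(features),
      labeled = sum(classification$units$class != "unclassifiable"),
      unclassifiable = sum(classification$units$class == "unclassifiable"),
      by_class = as.list(classification$counts),
      behavior_animals = nrow(behavior),
      behavior_excluded = excluded),
    ahp_threshold_used = classification$threshold_used,
    warnings = warnings_seen)

  .write_tsv(features, file.path(config$out_dir, "features.tsv"))
  .write_tsv(labeled, file.path(config$out_dir, "labels.tsv"))
  .write_tsv(as.data.frame(stats_tab),
             file.path(config$out_dir, "stats.tsv"))
  beh_out <- behavior
  num <- vapply(beh_out, is.numeric, TRUE)
  beh_out[num] <- lapply(beh_out[num],
                         function(x) formatC(x, digits = 12, format = "g"))
  utils::write.csv(beh_out, file.path(config$out_dir, "behavior.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(
    list(units = units, features = features,
         classification = classification, stats = stats_tab,
         behavior = behavior, manifest = manifest,
         out_dir = config$out_dir),
    class = "dg_run"))
}

#' @export
print.dg_run <- function(x, ...) {
  cat(sprintf("<dg_run> %d units -> %d labeled (+%d unclassifiable), %d behavior animals\n",
              x$manifest$counts$units_in, x$manifest$counts$labeled,
              x$manifest$counts$unclassifiable,
              x$manifest$counts$behavior_animals))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
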