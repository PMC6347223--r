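# End-to-end orchestration: simulate -> metrics -> score/classify ->
# summarise, with CSV/JSON artefacts and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param generator A [cohort_config()] for the simulate stage.
#' @param extraction An [extraction_config()] (used when images are the
#'   input; the default synthetic pipeline works from filament tables).
#' @param class_thresholds Damage-class boundaries in percent
#'   (default `c(10, 20)`).
#' @param annexin_threshold Apoptosis gate, a.u. (default 6000).
#' @param control Reference condition label for the rank tests.
#' @param comparisons Passed to [summarize_cohort()].
#' @param alpha Significance level (default 0.05).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            extraction = extraction_config(),
                            class_thresholds = c(10, 20),
                            annexin_threshold = 6000,
                            control = "control",
                            comparisons = "control_vs_each",
                            alpha = 0.05) {
  if (annexin_threshold <= 0) abort("`annexin_threshold` must be positive.")
  structure(list(
    generator = generator, extraction = extraction,
    class_thresholds = class_thresholds,
    annexin_threshold = annexin_threshold,
    control = control, comparisons = comparisons, alpha = alpha
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> per-cell metrics -> paired alteration scoring and
#' classification -> cohort statistics, writing every intermediate table as
#' CSV plus a JSON summary and a reproducibility manifest into `out_dir`.
#' Identical `(config, seed)` reproduce byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output.
#' @param stages Character subset of
#'   `c("simulate", "metrics", "classify", "stats")`; later stages require
#'   the earlier ones.
#' @return List of class `cryo_run`: `cohort`, `metrics`, `records`,
#'   `summary`, `manifest` (the run manifest, or `NULL` without `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL,
                         stages = c("simulate", "metrics", "classify",
                                    "stats")) {
  stages <- match.arg(stages, several.ok = TRUE)
  t0 <- Sys.time()
  paths <- character()
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(out_dir, name)
      readr::write_csv(df, p)
      paths[[name]] <<- p
    }
  }
  res <- list()

  res$cohort <- tryCatch(
    simulate_cohort(config$generator, seed = seed),
    error = function(e) abort(paste0("[simulate] ", conditionMessage(e)))
  )
  emit(res$cohort$filaments, "filaments.csv")
  emit(res$cohort$manifest, "manifest.csv")
  if (!"metrics" %in% stages) {
    return(finish_run(res, config, seed, out_dir, paths, t0))
  }

  res$metrics <- tryCatch(
    filament_metrics(res$cohort$filaments),
    error = function(e) abort(paste0("[metrics] ", conditionMessage(e)))
  )
  emit(res$metrics, "metrics.csv")
  if (!"classify" %in% stages) {
    return(finish_run(res, config, seed, out_dir, paths, t0))
  }

  res$records <- tryCatch(
    score_alterations(res$metrics, res$cohort$manifest,
                      thresholds = config$class_thresholds,
                      annexin_threshold = config$annexin_threshold),
    error = function(e) abort(paste0("[classify] ", conditionMessage(e)))
  )
  emit(res$records, "alterations.csv")
  if (!"stats" %in% stages) {
    return(finish_run(res, config, seed, out_dir, paths, t0))
  }

  res$summary <- tryCatch(
    summarize_cohort(res$records, control = config$control,
                     comparisons = config$comparisons,
                     alpha = config$alpha),
    error = function(e) abort(paste0("[stats] ", conditionMessage(e)))
  )
  emit(res$summary$class_fractions, "class_fractions.csv")
  emit(res$summary$delta_summaries, "delta_summaries.csv")
  emit(res$summary$direction_splits, "direction_splits.csv")
  emit(res$summary$tests, "rank_tests.csv")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(
        class_fractions = res$summary$class_fractions,
        delta_summaries = res$summary$delta_summaries,
        tests = res$summary$tests,
        glance = glance(res$summary)
      ),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
    paths[["summary.json"]] <- file.path(out_dir, "summary.json")
  }
  finish_run(res, config, seed, out_dir, paths, t0)
}

finish_run <- function(res, config, seed, out_dir, paths, t0) {
  if (!is.null(out_dir)) {
    checksums <- tools::md5sum(unlist(paths))
    names(checksums) <- names(paths)
    manifest <- list(
      package_version = as.character(utils::packageVersion("cryofil")),
      seed = seed,
      config_hash = rlang::hash(unclass(config)),
      outputs = as.list(checksums),
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE)
    res$manifest <- manifest
  }
  structure(res, class = "cryo_run")
}

#' @export
print.cryo_run <- function(x, ...) {
  cat("<cryo_run>\n")
  if (!is.null(x$cohort)) {
    cat(sprintf("  cohort:  %d cells\n", nrow(x$cohort$manifest)))
  }
  if (!is.null(x$records)) {
    cat(sprintf("  scored:  %d records\n", nrow(x$records)))
  }
  if (!is.null(x$summary)) {
    g <- glance(x$summary)
    cat(sprintf("  tests:   %d (%d significant)\n", g$n_tests,
                g$n_significant))
  }
  invisible(x)
}
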