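# CSV and YAML interchange. All tabular interchange is plain CSV with the
# documented column schemas, so intermediate artefacts are reusable outside R.

filament_schema <- c("cell_id", "stage", "length_um", "width_um",
                     "theta_deg", "x_um", "y_um")
manifest_schema <- c("cell_id", "replicate", "condition", "recovery_min",
                     "detached", "annexin_sd", "planted_class")

#' Write a simulated cohort to CSV files
#'
#' Writes `filaments.csv` (one row per filament) and `manifest.csv` (one row
#' per cell) into `dir`.
#'
#' @param cohort A `cryo_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    filaments = file.path(dir, "filaments.csv"),
    manifest = file.path(dir, "manifest.csv")
  )
  readr::write_csv(cohort$filaments, paths[["filaments"]])
  readr::write_csv(cohort$manifest, paths[["manifest"]])
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' @param dir Directory containing `filaments.csv` and `manifest.csv`.
#' @return List with tibbles `filaments` and `manifest`.
#' @export
read_cohort <- function(dir) {
  list(
    filaments = readr::read_csv(file.path(dir, "filaments.csv"),
                                show_col_types = FALSE),
    manifest = readr::read_csv(file.path(dir, "manifest.csv"),
                               show_col_types = FALSE)
  )
}

#' Validate filament and manifest tables against the interchange schemas
#'
#' Checks required columns and value ranges (`theta_deg` in `[0, 180)`,
#' `length_um > 0`, `width_um > 0`, probabilities and flags well-formed).
#' Violations are reported with row and field coordinates and a
#' fatal/warning severity; fatal rows would corrupt downstream metrics,
#' warnings are recoverable.
#'
#' @param filaments Filament table (or `NULL` to skip).
#' @param manifest Manifest table (or `NULL` to skip).
#' @return Tibble of violations: `table`, `row`, `field`, `severity`,
#'   `message`. Zero rows means the inputs are well-formed.
#' @export
validate_inputs <- function(filaments = NULL, manifest = NULL) {
  out <- list()
  add <- function(table, row, field, severity, message) {
    out[[length(out) + 1]] <<- tibble(
      table = table, row = row, field = field, severity = severity,
      message = message
    )
  }
  if (!is.null(filaments)) {
    miss <- setdiff(setdiff(filament_schema, c("x_um", "y_um")),
                    names(filaments))
    for (col in miss) {
      add("filaments", NA_integer_, col, "fatal", "required column missing")
    }
    if (length(miss) == 0L) {
      bad <- which(!is.finite(filaments$length_um) | filaments$length_um <= 0)
      for (r in bad) add("filaments", r, "length_um", "fatal",
                        "length must be finite and > 0")
      bad <- which(!is.finite(filaments$width_um) | filaments$width_um <= 0)
      for (r in bad) add("filaments", r, "width_um", "fatal",
                        "width must be finite and > 0")
      bad <- which(!is.finite(filaments$theta_deg) |
                     filaments$theta_deg < 0 | filaments$theta_deg >= 180)
      for (r in bad) add("filaments", r, "theta_deg", "fatal",
                        "orientation must lie in [0, 180)")
      bad <- which(!filaments$stage %in% c("pre", "post"))
      for (r in bad) add("filaments", r, "stage", "fatal",
                        "stage must be 'pre' or 'post'")
    }
  }
  if (!is.null(manifest)) {
    miss <- setdiff(c("cell_id", "detached"), names(manifest))
    for (col in miss) {
      add("manifest", NA_integer_, col, "fatal", "required column missing")
    }
    if (length(miss) == 0L) {
      dup <- which(duplicated(manifest$cell_id))
      for (r in dup) add("manifest", r, "cell_id", "fatal",
                        "duplicate cell identifier")
      if ("annexin_sd" %in% names(manifest)) {
        bad <- which(!is.na(manifest$annexin_sd) & manifest$annexin_sd < 0)
        for (r in bad) add("manifest", r, "annexin_sd", "fatal",
                          "intensity SD must be >= 0")
        bad <- which(is.na(manifest$annexin_sd) & !manifest$detached)
        for (r in bad) add("manifest", r, "annexin_sd", "warning",
                          "attached cell without an apoptosis readout")
      }
    }
  }
  if (length(out) == 0L) {
    tibble(table = character(), row = integer(), field = character(),
           severity = character(), message = character())
  } else {
    bind_rows(out)
  }
}

#' Write / read a generator configuration as YAML
#'
#' @param cfg A [cohort_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `cohort_config` (read).
#' @export
write_cohort_config <- function(cfg, path) {
  raw <- unclass(cfg)
  # serialise each class-probability matrix as a list of per-time columns
  raw$class_probs <- lapply(raw$class_probs, function(p) {
    lapply(seq_len(ncol(p)), function(j) unname(p[, j]))
  })
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$class_probs <- lapply(raw$class_probs, function(p) {
    if (is.matrix(p)) p else do.call(cbind, lapply(p, unlist))
  })
  do.call(cohort_config, raw)
}
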