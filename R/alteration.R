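# Paired pre/post alteration scoring and apoptosis-gated damage classes.

#' Percentage alteration of a parameter between two stages
#'
#' \deqn{\Delta = 100\,(x_a / x_b - 1)} where `b` indexes the value before
#' and `a` the value after cryopreservation.
#'
#' @param before Value before (must be strictly positive and finite).
#' @param after Value after.
#' @return Signed percentage alteration; `NA` (with no error) when either
#'   input is non-finite or `before <= 0` — such cells are excluded upstream
#'   with an explicit reason.
#' @examples
#' percent_alteration(100, 80) # -20
#' percent_alteration(50, 75) # +50
#' @export
percent_alteration <- function(before, after) {
  out <- 100 * (after / before - 1)
  bad <- !is.finite(before) | !is.finite(after) | before <= 0
  out[bad] <- NA_real_
  out
}

#' Total alteration of the actin cytoskeleton
#'
#' The mean absolute percentage alteration over the three descriptors:
#' \deqn{\Delta_T = \tfrac{1}{3}(|\Delta_F| + |\Delta_L| + |\Delta_\nu|)}
#'
#' @param delta_F,delta_L,delta_nu Signed percentage alterations.
#' @return `Delta_T >= 0`, or `NA` if any component is non-finite.
#' @examples
#' total_alteration(-20, 10, -30) # 20
#' @export
total_alteration <- function(delta_F, delta_L, delta_nu) {
  out <- (abs(delta_F) + abs(delta_L) + abs(delta_nu)) / 3
  bad <- !is.finite(delta_F) | !is.finite(delta_L) | !is.finite(delta_nu)
  out[bad] <- NA_real_
  out
}

#' Standard deviation of Annexin-V fluorescence intensity
#'
#' The apoptosis readout: the population standard deviation of pixel
#' intensities, optionally restricted to a cell mask.
#'
#' @param pixels Numeric vector, matrix or array of intensities (a.u.).
#' @param mask Optional logical vector/matrix of the same length selecting
#'   the cell region; `NULL` uses every pixel.
#' @return Population standard deviation (divisor `n`), in a.u.
#' @examples
#' annexin_sd(c(0, 12400)) # 6200
#' @export
annexin_sd <- function(pixels, mask = NULL) {
  x <- as.numeric(pixels)
  if (!is.null(mask)) {
    if (length(mask) != length(x)) {
      abort("`mask` must have the same number of elements as `pixels`.")
    }
    x <- x[as.logical(mask)]
  }
  if (length(x) < 2L) {
    abort("Need at least 2 pixels to compute an intensity standard deviation.")
  }
  sqrt(mean((x - mean(x))^2))
}

#' Apoptosis gate on the Annexin intensity standard deviation
#'
#' A cell is apoptosis-positive when the standard deviation of its Annexin-V
#' fluorescence exceeds the threshold (strictly greater than; the
#' boundary value itself is negative).
#'
#' @param sd_au Intensity standard deviation(s), a.u.
#' @param threshold Gate threshold, default 6000 a.u.
#' @return Logical: apoptosis-positive?
#' @examples
#' apoptosis_gate(c(6500, 6000, 100))
#' @export
apoptosis_gate <- function(sd_au, threshold = 6000) {
  check_scalar_number(threshold, "threshold", lower = 0)
  sd_au > threshold
}

#' Assign a damage class to a single cell
#'
#' Classification rules, applied in order:
#' * a detached cell (lost surface contact during cryopreservation) is
#'   classed `"detached"` regardless of everything else;
#' * an apoptosis-negative cell is classed `"I"` regardless of `delta_T`;
#' * otherwise `delta_T <= t1` gives class `"I"`, `t1 < delta_T <= t2` class
#'   `"II"`, `delta_T > t2` class `"III"`.
#'
#' Boundary values (`delta_T` exactly at a threshold) fall to the lower
#' class: the underlying inequalities are strict on both sides, leaving the
#' boundary unassigned, and the conservative call is the milder class.
#'
#' @param delta_T Total alteration in percent (may be `NA` for detached
#'   cells).
#' @param apoptotic Logical apoptosis flag.
#' @param detached Logical detachment flag.
#' @param thresholds Class boundaries `c(t1, t2)` in percent, default
#'   `c(10, 20)`.
#' @return Factor with levels `I`, `II`, `III`, `detached` (vectorised).
#' @examples
#' classify_cell(35, apoptotic = FALSE, detached = FALSE) # I
#' classify_cell(15, apoptotic = TRUE, detached = FALSE) # II
#' @export
classify_cell <- function(delta_T, apoptotic, detached = FALSE,
                          thresholds = c(10, 20)) {
  if (length(thresholds) != 2L || any(!is.finite(thresholds)) ||
      thresholds[1] <= 0 || thresholds[2] <= thresholds[1]) {
    abort("`thresholds` must be two increasing positive numbers.")
  }
  k <- max(length(delta_T), length(apoptotic), length(detached))
  delta_T <- rep_len(delta_T, k)
  apoptotic <- rep_len(apoptotic, k)
  detached <- rep_len(detached, k)
  out <- character(k)
  for (i in seq_len(k)) {
    out[i] <- if (isTRUE(detached[i])) {
      "detached"
    } else if (!isTRUE(apoptotic[i])) {
      "I"
    } else if (is.na(delta_T[i])) {
      NA_character_
    } else if (delta_T[i] <= thresholds[1]) {
      "I"
    } else if (delta_T[i] <= thresholds[2]) {
      "II"
    } else {
      "III"
    }
  }
  factor(out, levels = class_levels())
}

class_levels <- function() c("I", "II", "III", "detached")

#' Score paired pre/post observations of a cohort
#'
#' Joins per-cell metrics for both stages with the cohort manifest and
#' computes, for every cell: the three signed percentage alterations
#' (`delta_nu`, `delta_F`, `delta_L`), the total alteration `delta_T`, the
#' apoptosis flag (from `annexin_sd` in the manifest), and the assigned
#' class.
#'
#' Edge cases:
#' * detached cells short-circuit to class `"detached"`; their deltas are
#'   `NA`;
#' * a non-detached cell whose post observation has zero filaments cannot
#'   produce finite deltas; total F-actin loss being the most severe outcome,
#'   it is classed `"III"` with `excluded_reason = "post_undefined"` and `NA`
#'   deltas (it still counts in class fractions but not in delta summaries);
#' * a cell with undefined pre metrics, a non-positive pre parameter, or a
#'   non-finite `nu` (isotropic sample) is excluded: class `NA` with a
#'   reason, reported via a warning.
#'
#' @param metrics Per-cell metrics as returned by [filament_metrics()], with
#'   rows for stages `"pre"` and `"post"`.
#' @param manifest Cohort manifest: `cell_id`, `replicate`, `condition`,
#'   `recovery_min`, `detached`, `annexin_sd` (post-thaw; `NA` allowed for
#'   detached cells).
#' @param thresholds Class boundaries passed to [classify_cell()].
#' @param annexin_threshold Apoptosis gate in a.u., default 6000.
#' @return Tibble with one row per cell: manifest labels, `delta_F`,
#'   `delta_L`, `delta_nu`, `delta_T`, `apoptotic`, `assigned_class`,
#'   `excluded_reason`.
#' @export
score_alterations <- function(metrics, manifest, thresholds = c(10, 20),
                              annexin_threshold = 6000) {
  required <- c("cell_id", "detached")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    abort(sprintf("`manifest` is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (col in c("replicate", "condition", "recovery_min", "annexin_sd")) {
    if (!col %in% names(manifest)) manifest[[col]] <- NA
  }

  pre <- metrics |>
    filter(.data$stage == "pre") |>
    select("cell_id", n_pre = "n", nu_pre = "nu_rad",
           F_pre = "F_um2", L_pre = "L_um", defined_pre = "defined")
  post <- metrics |>
    filter(.data$stage == "post") |>
    select("cell_id", n_post = "n", nu_post = "nu_rad",
           F_post = "F_um2", L_post = "L_um", defined_post = "defined")

  rec <- manifest |>
    as_tibble() |>
    select("cell_id", "replicate", "condition", "recovery_min",
           "detached", "annexin_sd") |>
    left_join(pre, by = "cell_id") |>
    left_join(post, by = "cell_id") |>
    mutate(
      defined_pre = !is.na(.data$defined_pre) & .data$defined_pre,
      defined_post = !is.na(.data$defined_post) & .data$defined_post,
      apoptotic = !is.na(.data$annexin_sd) &
        apoptosis_gate(.data$annexin_sd, annexin_threshold)
    )

  scored <- rec |>
    mutate(
      excluded_reason = dplyr::case_when(
        .data$detached ~ NA_character_,
        !.data$defined_pre ~ "pre_undefined",
        !.data$defined_post ~ "post_undefined",
        !is.finite(.data$nu_pre) ~ "nu_pre_nonfinite",
        .data$nu_pre <= 0 ~ "nu_pre_nonpositive",
        !is.finite(.data$nu_post) ~ "nu_post_nonfinite",
        TRUE ~ NA_character_
      ),
      delta_F = ifelse(.data$detached | !is.na(.data$excluded_reason),
                       NA_real_,
                       percent_alteration(.data$F_pre, .data$F_post)),
      delta_L = ifelse(.data$detached | !is.na(.data$excluded_reason),
                       NA_real_,
                       percent_alteration(.data$L_pre, .data$L_post)),
      delta_nu = ifelse(.data$detached | !is.na(.data$excluded_reason),
                        NA_real_,
                        percent_alteration(.data$nu_pre, .data$nu_post)),
      delta_T = total_alteration(.data$delta_F, .data$delta_L, .data$delta_nu),
      assigned_class = dplyr::case_when(
        .data$detached ~ factor("detached", levels = class_levels()),
        .data$excluded_reason %in% "post_undefined" ~
          factor("III", levels = class_levels()),
        is.na(.data$excluded_reason) ~
          classify_cell(.data$delta_T, .data$apoptotic, FALSE, thresholds),
        TRUE ~ factor(NA_character_, levels = class_levels())
      )
    )

  n_excluded <- sum(!is.na(scored$excluded_reason) &
                      is.na(scored$assigned_class))
  if (n_excluded > 0) {
    warn(sprintf("%d cell(s) excluded from classification (see `excluded_reason`).",
                 n_excluded))
  }
  scored |>
    select("cell_id", "replicate", "condition", "recovery_min", "detached",
           "annexin_sd", "apoptotic", "delta_F", "delta_L", "delta_nu",
           "delta_T", "assigned_class", "excluded_reason")
}
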