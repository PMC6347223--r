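# Per-cell descriptors of a filament network: circular standard deviation
# (nu), F-actin content (F) and mean filament length (L).

#' Mean resultant length of a set of orientation angles
#'
#' Each angle is interpreted as a unit vector; `R` is the length of the
#' vector sum divided by the number of angles:
#' \deqn{R = \frac{1}{n}\sqrt{(\sum_i \sin\alpha_i)^2 + (\sum_i \cos\alpha_i)^2}}
#' `R = 1` means perfectly parallel orientations, `R` near 0 an isotropic
#' network. Angles are taken literally (no axial doubling by default): the
#' filament-orientation convention stores angles in `[0, 180)` degrees and
#' applies sine/cosine directly to them. With `doubled_angles = TRUE` the
#' standard axial-statistics transform (angles doubled before summation) is
#' used instead.
#'
#' @param theta_deg Numeric vector of orientation angles in degrees.
#' @param doubled_angles Double the angles before computing the resultant
#'   (axial-data convention). Default `FALSE`.
#' @return `R` in `[0, 1]`, or `NA` for an empty input.
#' @seealso [circular_std()]
#' @examples
#' resultant_length(c(0, 90)) # sqrt(2)/2
#' resultant_length(c(0, 60, 120)) # 2/3
#' @export
resultant_length <- function(theta_deg, doubled_angles = FALSE) {
  if (length(theta_deg) == 0L) {
    return(NA_real_)
  }
  if (anyNA(theta_deg)) {
    abort("`theta_deg` contains missing values.")
  }
  a <- deg2rad(theta_deg)
  if (doubled_angles) a <- 2 * a
  r <- sqrt(sum(sin(a))^2 + sum(cos(a))^2) / length(a)
  min(r, 1) # guard against rounding just above 1
}

#' Circular standard deviation of orientation angles
#'
#' The conventional circular standard deviation
#' \deqn{\nu = \sqrt{-2\ln R}}
#' where `R` is the mean resultant length ([resultant_length()]).
#' `nu = 0` indicates perfectly parallel filaments; large values a branched,
#' isotropic network. When `R` falls below `r_floor` (a fully isotropic
#' sample), `nu` is reported as `Inf` rather than an error so that cohort
#' processing can continue; such cells are excluded from downstream
#' alteration statistics with a warning.
#'
#' @inheritParams resultant_length
#' @param r_floor Values of `R` below this are treated as 0 and yield
#'   `nu = Inf`. Default `1e-12`.
#' @return `nu` in radians (`>= 0`, possibly `Inf`), or `NA` for empty input.
#' @examples
#' circular_std(c(10, 10, 10)) # 0
#' circular_std(c(0, 90)) # sqrt(log(2))
#' @export
circular_std <- function(theta_deg, doubled_angles = FALSE, r_floor = 1e-12) {
  r <- resultant_length(theta_deg, doubled_angles = doubled_angles)
  nu_from_r(r, doubled_angles = doubled_angles, r_floor = r_floor)
}

nu_from_r <- function(r, doubled_angles = FALSE, r_floor = 1e-12) {
  if (is.na(r)) {
    return(NA_real_)
  }
  if (r < r_floor) {
    return(Inf)
  }
  nu <- sqrt(-2 * log(r))
  if (doubled_angles) nu <- nu / 2
  nu
}

#' F-actin content of a filament set
#'
#' The area proxy \eqn{F = \sum_i l_i w_i} (length times width, summed over
#' filaments), in square micrometres. An empty set has `F = 0`.
#'
#' @param filaments Data frame with columns `length_um` and `width_um`.
#' @return `F` in um^2.
#' @examples
#' f_actin_content(tibble::tibble(length_um = c(10, 5), width_um = c(2, 1)))
#' @export
f_actin_content <- function(filaments) {
  if (nrow(filaments) == 0L) {
    return(0)
  }
  check_filament_df(filaments)
  sum(filaments$length_um * filaments$width_um)
}

#' Mean filament length
#'
#' \eqn{L = \frac{1}{n}\sum_i l_i} in micrometres. Undefined (`NA`) for an
#' empty set.
#'
#' @param filaments Data frame with a `length_um` column.
#' @return `L` in um.
#' @export
mean_filament_length <- function(filaments) {
  if (nrow(filaments) == 0L) {
    return(NA_real_)
  }
  mean(filaments$length_um)
}

#' Per-cell filament-network metrics
#'
#' Computes the three per-cell descriptors — circular standard deviation
#' `nu_rad`, F-actin content `F_um2`, mean filament length `L_um` — plus the
#' filament count `n` and mean resultant length `R`, for every
#' `cell_id` x `stage` group of a filament table. A group with zero filaments
#' yields `defined = FALSE` with `F_um2 = 0` and the other metrics `NA`.
#'
#' @param filaments Filament table: one row per detected filament with
#'   columns `length_um`, `width_um`, `theta_deg` and (optionally) `cell_id`,
#'   `stage`. Missing grouping columns are filled with a single dummy group.
#' @param doubled_angles Passed to [resultant_length()].
#' @return A tibble with one row per `cell_id` x `stage`:
#'   `n`, `R`, `nu_rad`, `F_um2`, `L_um`, `defined`.
#' @examples
#' fil <- tibble::tibble(
#'   cell_id = "c1", stage = "pre",
#'   length_um = c(3, 5, 10), width_um = 1, theta_deg = c(0, 60, 120)
#' )
#' filament_metrics(fil)
#' @export
filament_metrics <- function(filaments, doubled_angles = FALSE) {
  check_filament_df(filaments)
  if (any(filaments$length_um <= 0, na.rm = TRUE)) {
    abort("`length_um` must be strictly positive.")
  }
  if (any(filaments$width_um <= 0, na.rm = TRUE)) {
    abort("`width_um` must be strictly positive.")
  }
  if (any(filaments$theta_deg < 0 | filaments$theta_deg >= 180, na.rm = TRUE)) {
    abort("`theta_deg` must lie in [0, 180).")
  }
  df <- as_tibble(filaments)
  if (!"cell_id" %in% names(df)) df$cell_id <- "cell"
  if (!"stage" %in% names(df)) df$stage <- "pre"
  df |>
    group_by(.data$cell_id, .data$stage) |>
    summarise(
      n = dplyr::n(),
      R = resultant_length(.data$theta_deg, doubled_angles = doubled_angles),
      F_um2 = sum(.data$length_um * .data$width_um),
      L_um = mean(.data$length_um),
      .groups = "drop"
    ) |>
    mutate(
      nu_rad = purrr::map_dbl(.data$R, nu_from_r,
                              doubled_angles = doubled_angles),
      defined = .data$n > 0
    ) |>
    select("cell_id", "stage", "n", "R", "nu_rad", "F_um2", "L_um", "defined")
}
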