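# Ground-truth filament-network generation: orientation sampling, per-cell
# filament sets, Annexin pixel synthesis.

#' Sample filament orientations from a wrapped normal distribution
#'
#' Draws `n` angles from a normal distribution with mean `mean_deg` (degrees)
#' and standard deviation `sigma_rad` (radians), wrapped onto the circle. The
#' wrapped normal is used (rather than a von Mises) because its mean
#' resultant length has the exact closed form `R = exp(-sigma^2/2)`, so the
#' circular standard deviation of the draws equals `sigma_rad` analytically —
#' which makes the orientation model verifiable against the metrics module
#' without simulation error.
#'
#' With `fold = TRUE` (default) angles are reduced to the orientation
#' half-circle `[0, 180)` at generation time, matching the
#' "angle to the horizontal" convention. Note that folding is a lossy axial
#' reduction: when an appreciable fraction of the distribution crosses the
#' 0/180 boundary (roughly `sigma_rad > 0.6` for a mean at 90 degrees), the
#' literal circular standard deviation of the *folded* angles is biased low
#' relative to `sigma_rad`; the closed form holds exactly for the unfolded
#' draws (`fold = FALSE`, angles in `[0, 360)`).
#'
#' @param n Number of angles (`>= 0`).
#' @param mean_deg Mean orientation, degrees.
#' @param sigma_rad Dispersion, radians (`>= 0`; 0 gives `n` copies of
#'   `mean_deg`).
#' @param seed Optional integer seed (local RNG scope).
#' @param fold Fold into `[0, 180)` (default) or return wrapped angles in
#'   `[0, 360)`.
#' @return Numeric vector of angles in degrees.
#' @examples
#' sample_orientations(5, 37, 0) # five copies of 37
#' @export
sample_orientations <- function(n, mean_deg, sigma_rad, seed = NULL,
                                fold = TRUE) {
  check_scalar_number(n, "n", lower = 0)
  check_scalar_number(sigma_rad, "sigma_rad", lower = 0)
  draw <- function() mean_deg + rad2deg(rnorm(n, 0, sigma_rad))
  theta <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (fold) theta %% 180 else theta %% 360
}

#' Configuration of the synthetic-cohort generator
#'
#' Bundles the experimental design (conditions, recovery times, replicates,
#' cells per replicate) with the distributions of the ground-truth filament
#' networks and the per-stratum damage presets. Defaults reproduce the design
#' of a paired pre/post single-cell cryopreservation study: 4 conditions x
#' 3 recovery times x 3 replicates x 15 cells.
#'
#' @param n_cells_per_replicate Cells measured per replicate (default 15).
#' @param n_replicates Independent experimental replicates (default 3).
#' @param conditions Condition labels. The shipped damage presets cover
#'   `control`, `slow_1C`, `slow_10C` (slow freezing at 1 and 10 degC/min)
#'   and `vitrified`.
#' @param recovery_times_min Post-thaw recovery times in minutes.
#' @param filament_count_range Integer interval for per-cell filament counts.
#' @param length_meanlog,length_sdlog Log-normal parameters of filament
#'   length in um (defaults give a median of 8 um).
#' @param width_mean,width_sd,width_min Truncated-normal parameters of
#'   filament width in um.
#' @param orientation_sigma_rad Wrapped-normal dispersion of orientations
#'   about a per-cell random mean direction.
#' @param cell_semi_axes Ellipse semi-axes (um) bounding filament centroids.
#' @param class_probs Named list `condition -> 4 x n_times matrix` of planted
#'   class probabilities (rows `I`, `II`, `III`, `detached`; columns in the
#'   order of `recovery_times_min`). `NULL` uses shipped presets that
#'   qualitatively mimic published cryo-damage patterns (slow freezing at
#'   1 degC/min mostly intact at 0 min then degrading; 10 degC/min heavily
#'   damaged; vitrification largely preserved). The presets are illustrative,
#'   not reproductions of measured fractions. The `detached` row is the
#'   per-stratum detachment probability.
#' @param apoptotic_class1_prob Probability that a planted class-I cell is
#'   apoptosis-positive (with total alteration kept below the first class
#'   boundary). Default 0.1.
#' @param class_margin Guaranteed distance (percentage points) between every
#'   planted cell's total alteration and the class boundaries (default 2).
#' @param annexin_positive_range,annexin_negative_range Target ranges (a.u.)
#'   for the Annexin intensity SD of apoptosis-positive / -negative cells;
#'   kept clear of the 6000 a.u. gate.
#' @param annexin_n_pixels Pixels per synthetic Annexin readout.
#' @param delta_T_max Upper bound (percent) for planted class-III total
#'   alterations.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cells_per_replicate = 15,
                          n_replicates = 3,
                          conditions = c("control", "slow_1C", "slow_10C",
                                         "vitrified"),
                          recovery_times_min = c(0, 15, 120),
                          filament_count_range = c(30, 80),
                          length_meanlog = log(8), length_sdlog = 0.4,
                          width_mean = 0.4, width_sd = 0.08, width_min = 0.1,
                          orientation_sigma_rad = 0.5,
                          cell_semi_axes = c(30, 18),
                          class_probs = NULL,
                          apoptotic_class1_prob = 0.1,
                          class_margin = 2,
                          annexin_positive_range = c(7000, 12000),
                          annexin_negative_range = c(500, 4000),
                          annexin_n_pixels = 1024,
                          delta_T_max = 60) {
  cfg <- list(
    n_cells_per_replicate = as.integer(n_cells_per_replicate),
    n_replicates = as.integer(n_replicates),
    conditions = conditions,
    recovery_times_min = recovery_times_min,
    filament_count_range = as.integer(filament_count_range),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    width_mean = width_mean, width_sd = width_sd, width_min = width_min,
    orientation_sigma_rad = orientation_sigma_rad,
    cell_semi_axes = cell_semi_axes,
    class_probs = class_probs %||% default_class_probs(conditions,
                                                       recovery_times_min),
    apoptotic_class1_prob = apoptotic_class1_prob,
    class_margin = class_margin,
    annexin_positive_range = annexin_positive_range,
    annexin_negative_range = annexin_negative_range,
    annexin_n_pixels = as.integer(annexin_n_pixels),
    delta_T_max = delta_T_max
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  check_scalar_number(cfg$n_cells_per_replicate, "n_cells_per_replicate", 1)
  check_scalar_number(cfg$n_replicates, "n_replicates", 1)
  check_scalar_number(cfg$length_sdlog, "length_sdlog", 0)
  check_scalar_number(cfg$width_mean, "width_mean", 1e-9)
  check_scalar_number(cfg$width_sd, "width_sd", 0)
  check_scalar_number(cfg$width_min, "width_min", 1e-9)
  check_scalar_number(cfg$orientation_sigma_rad, "orientation_sigma_rad", 0)
  check_scalar_number(cfg$apoptotic_class1_prob, "apoptotic_class1_prob", 0, 1)
  check_scalar_number(cfg$class_margin, "class_margin", 0, 4)
  if (length(cfg$filament_count_range) != 2L ||
      cfg$filament_count_range[1] < 0 ||
      cfg$filament_count_range[2] < cfg$filament_count_range[1]) {
    abort("`filament_count_range` must be a non-decreasing pair of counts.")
  }
  for (cond in cfg$conditions) {
    p <- cfg$class_probs[[cond]]
    if (is.null(p) || nrow(p) != 4L ||
        ncol(p) != length(cfg$recovery_times_min)) {
      abort(sprintf("`class_probs` for condition '%s' must be a 4 x %d matrix.",
                    cond, length(cfg$recovery_times_min)))
    }
    if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-9)) {
      abort(sprintf("`class_probs` columns for '%s' must be probability vectors.",
                    cond))
    }
  }
  invisible(cfg)
}

# Shipped planted-class probability presets, one 4 x n_times matrix per
# condition (rows I, II, III, detached). Qualitative shapes only: control
# intact; slow 1C/min intact at 0 min then degrading; slow 10C/min heavily
# damaged with high detachment; vitrified largely preserved.
default_class_probs <- function(conditions, recovery_times_min) {
  n_t <- length(recovery_times_min)
  mk <- function(...) {
    m <- matrix(c(...), nrow = 4)
    m <- m[, seq_len(min(ncol(m), n_t)), drop = FALSE]
    if (ncol(m) < n_t) m <- m[, rep(ncol(m), n_t), drop = FALSE]
    sweep(m, 2, colSums(m), "/")
  }
  presets <- list(
    control = mk(c(0.96, 0.03, 0.01, 0.00),
                 c(0.96, 0.03, 0.01, 0.00),
                 c(0.96, 0.03, 0.01, 0.00)),
    slow_1C = mk(c(0.89, 0.09, 0.00, 0.02),
                 c(0.51, 0.17, 0.12, 0.20),
                 c(0.47, 0.15, 0.16, 0.22)),
    slow_10C = mk(c(0.645, 0.20, 0.11, 0.045),
                  c(0.356, 0.12, 0.124, 0.40),
                  c(0.25, 0.11, 0.33, 0.31)),
    vitrified = mk(c(0.733, 0.14, 0.08, 0.047),
                   c(0.756, 0.09, 0.08, 0.074),
                   c(0.60, 0.07, 0.086, 0.244))
  )
  out <- lapply(conditions, function(cond) {
    presets[[cond]] %||% presets$control
  })
  names(out) <- conditions
  out
}

#' Generate the ground-truth filament set of one cell
#'
#' Draws a filament count uniformly from `filament_count_range`, lengths from
#' the configured log-normal, widths from a truncated normal (lower bound
#' `width_min`), orientations from a wrapped normal about a per-cell random
#' mean direction, and centroids uniformly inside the cell ellipse.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed (local RNG scope).
#' @param cell_id Identifier stamped on the rows.
#' @param stage Stage label, default `"pre"`.
#' @return Filament tibble: `cell_id`, `stage`, `length_um`, `width_um`,
#'   `theta_deg`, `x_um`, `y_um`.
#' @export
generate_cell_filaments <- function(cfg = cohort_config(), seed = 1,
                                    cell_id = "cell", stage = "pre") {
  validate_cohort_config(cfg)
  with_seed(seed, {
    n <- if (cfg$filament_count_range[1] == cfg$filament_count_range[2]) {
      cfg$filament_count_range[1]
    } else {
      sample(cfg$filament_count_range[1]:cfg$filament_count_range[2], 1L)
    }
    mean_dir <- runif(1, 0, 180)
    lengths <- rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)
    widths <- pmax(rnorm(n, cfg$width_mean, cfg$width_sd), cfg$width_min)
    theta <- (mean_dir + rad2deg(rnorm(n, 0, cfg$orientation_sigma_rad))) %% 180
    # uniform in the ellipse by rejection-free polar sampling
    r <- sqrt(runif(n))
    phi <- runif(n, 0, 2 * pi)
    tibble(
      cell_id = cell_id, stage = stage,
      length_um = lengths, width_um = widths, theta_deg = theta,
      x_um = cfg$cell_semi_axes[1] * r * cos(phi),
      y_um = cfg$cell_semi_axes[2] * r * sin(phi)
    )
  })
}

#' Synthesise an Annexin-V pixel intensity readout
#'
#' Generates `n_pixels` intensities whose population standard deviation
#' equals `target_sd` exactly (Gaussian draws standardised and rescaled), on
#' a positive baseline. Used to plant apoptosis-positive
#' (`target_sd > 6000 a.u.`) and -negative cells.
#'
#' @param positive Logical; used only for validation against the 6000 a.u.
#'   gate — a positive cell must be given `target_sd > 6000`, a negative one
#'   `target_sd < 6000`.
#' @param target_sd Target intensity standard deviation, a.u. (`>= 0`).
#' @param n_pixels Number of pixels (`>= 2`).
#' @param seed Integer seed (local RNG scope).
#' @return Numeric intensity vector, a.u.
#' @export
generate_annexin_pixels <- function(positive, target_sd, n_pixels = 1024,
                                    seed = 1) {
  check_scalar_number(target_sd, "target_sd", lower = 0)
  if (n_pixels < 2) abort("`n_pixels` must be at least 2.")
  if (isTRUE(positive) && target_sd <= 6000) {
    abort("A positive cell requires `target_sd` above the 6000 a.u. gate.")
  }
  if (!isTRUE(positive) && target_sd >= 6000) {
    abort("A negative cell requires `target_sd` below the 6000 a.u. gate.")
  }
  baseline <- 5 * target_sd + 100
  if (target_sd == 0) {
    return(rep(baseline, n_pixels))
  }
  with_seed(seed, {
    z <- rnorm(n_pixels)
    z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
    baseline + z * target_sd
  })
}
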