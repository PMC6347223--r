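# Internal helpers shared across modules.

#' Fold angles onto the orientation half-circle
#'
#' Orientations of undirected line segments are axial: an angle and the same
#' angle plus 180 degrees describe the same filament. All angles in the
#' package are stored folded into `[0, 180)` degrees, matching the
#' "angle to the horizontal" convention of filament-measurement tools.
#'
#' @param theta_deg Numeric vector of angles in degrees.
#' @return Angles folded into `[0, 180)` degrees.
#' @examples
#' fold_angle(c(-10, 45, 180, 190, 359))
#' @export
fold_angle <- function(theta_deg) {
  theta_deg %% 180
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Deterministic seed fan-out: one global seed expands to per-stage and
# per-unit child seeds through a counter scheme (a fixed-multiplier LCG step
# on 31-bit state), so any subset of cells can be regenerated independently
# of cohort iteration order. Keeps every derived seed strictly below 2^31.
child_seed <- function(seed, ...) {
  idx <- c(...)
  state <- as.double(seed %% 2147483647)
  for (k in idx) {
    state <- (state * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(state)
}

# run code under a local RNG state (restores the caller's .Random.seed)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_filament_df <- function(df, name = "filaments") {
  required <- c("length_um", "width_um", "theta_deg")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

empty_filaments <- function() {
  tibble(
    cell_id = character(), stage = character(),
    length_um = double(), width_um = double(), theta_deg = double(),
    x_um = double(), y_um = double()
  )
}
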