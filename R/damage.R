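# Phenomenological cryo-damage operators acting on filament tables. Each
# emulates a measurement signature of freeze-thaw injury rather than a
# biophysical mechanism: buckling (one bent filament detected as several
# short, disoriented segments), depolymerization (filament loss, including
# localized holes), and cracking (straight fractures through the network).

#' Buckle a fraction of filaments
#'
#' Each selected filament (independent Bernoulli draws with probability
#' `fraction`) is replaced by `k_segments` collinear sub-segments whose
#' lengths sum to the parent length (uniform Dirichlet partition), whose
#' widths equal the parent width, and whose orientations are the parent angle
#' plus independent normal jitter of SD `jitter_sd_deg`, folded to
#' `[0, 180)`. Sub-segment centroids are spread along the parent axis. With
#' zero jitter, F-actin content is conserved exactly while the mean filament
#' length drops by the factor `k_segments`.
#'
#' @param filaments Filament tibble.
#' @param fraction Probability a filament buckles, in `[0, 1]`.
#' @param k_segments Number of fragments per buckled filament (`>= 2`).
#' @param jitter_sd_deg Orientation jitter SD of the fragments, degrees.
#' @param seed Integer seed (local RNG scope).
#' @return Filament tibble.
#' @export
apply_buckling <- function(filaments, fraction, k_segments = 3,
                           jitter_sd_deg = 15, seed = 1) {
  check_scalar_number(fraction, "fraction", 0, 1)
  check_scalar_number(jitter_sd_deg, "jitter_sd_deg", lower = 0)
  if (k_segments < 2) abort("`k_segments` must be at least 2.")
  if (nrow(filaments) == 0L || fraction == 0) {
    return(as_tibble(filaments))
  }
  with_seed(seed, {
    hit <- runif(nrow(filaments)) < fraction
    keep <- as_tibble(filaments)[!hit, , drop = FALSE]
    broken <- as_tibble(filaments)[hit, , drop = FALSE]
    if (nrow(broken) == 0L) {
      return(keep)
    }
    pieces <- purrr::map(seq_len(nrow(broken)), function(i) {
      f <- broken[i, ]
      # uniform partition of the parent length into k positive parts
      cuts <- sort(runif(k_segments - 1))
      parts <- diff(c(0, cuts, 1)) * f$length_um
      jitter <- rnorm(k_segments, 0, jitter_sd_deg)
      # fragment centres along the parent axis
      ends <- cumsum(parts)
      centers <- ends - parts / 2 - f$length_um / 2
      ux <- cos(deg2rad(f$theta_deg))
      uy <- sin(deg2rad(f$theta_deg))
      tibble(
        cell_id = f$cell_id, stage = f$stage,
        length_um = parts, width_um = f$width_um,
        theta_deg = (f$theta_deg + jitter) %% 180,
        x_um = f$x_um + centers * ux,
        y_um = f$y_um + centers * uy
      )
    })
    bind_rows(keep, bind_rows(pieces))
  })
}

#' Depolymerize: remove filaments globally and inside holes
#'
#' Deletes an independent Bernoulli(`removal_fraction`) subset of filaments,
#' then deletes every remaining filament whose centroid lies within
#' `hole_radius_um` of a hole centre — emulating both diffuse F-actin loss
#' and localized holes in the network.
#'
#' @param filaments Filament tibble.
#' @param removal_fraction Probability each filament is removed, `[0, 1]`.
#' @param hole_centers Optional list of `c(x, y)` hole centres (um) or a
#'   two-column matrix/data frame.
#' @param hole_radius_um Hole disc radius (um, `>= 0`).
#' @param seed Integer seed (local RNG scope).
#' @return Filament tibble (possibly empty).
#' @export
apply_depolymerization <- function(filaments, removal_fraction,
                                   hole_centers = NULL, hole_radius_um = 0,
                                   seed = 1) {
  check_scalar_number(removal_fraction, "removal_fraction", 0, 1)
  check_scalar_number(hole_radius_um, "hole_radius_um", lower = 0)
  df <- as_tibble(filaments)
  if (nrow(df) == 0L) {
    return(df)
  }
  if (removal_fraction > 0) {
    keep <- with_seed(seed, runif(nrow(df)) >= removal_fraction)
    df <- df[keep, , drop = FALSE]
  }
  if (!is.null(hole_centers) && nrow(df) > 0L) {
    centers <- if (is.list(hole_centers) && !is.data.frame(hole_centers)) {
      do.call(rbind, hole_centers)
    } else {
      as.matrix(hole_centers)
    }
    for (i in seq_len(nrow(centers))) {
      d2 <- (df$x_um - centers[i, 1])^2 + (df$y_um - centers[i, 2])^2
      df <- df[d2 > hole_radius_um^2, , drop = FALSE]
    }
  }
  df
}

#' Crack the network along line fractures
#'
#' Every filament whose axis segment crosses a crack line is split into two
#' collinear filaments with a gap of `gap_um` removed symmetrically around
#' the intersection point. Pieces shorter than `min_length_um` are dropped.
#' Cracking never increases the mean filament length and never increases
#' F-actin content.
#'
#' @param filaments Filament tibble.
#' @param crack_lines List of crack line segments, each
#'   `c(x0, y0, x1, y1)` in um.
#' @param gap_um Total gap removed at each crossing (um, `>= 0`).
#' @param min_length_um Minimum surviving piece length (um).
#' @return Filament tibble.
#' @export
apply_cracking <- function(filaments, crack_lines, gap_um,
                           min_length_um = 0.5) {
  check_scalar_number(gap_um, "gap_um", lower = 0)
  df <- as_tibble(filaments)
  if (nrow(df) == 0L || length(crack_lines) == 0L) {
    return(df)
  }
  out <- purrr::map(seq_len(nrow(df)), function(i) {
    f <- df[i, ]
    ux <- cos(deg2rad(f$theta_deg))
    uy <- sin(deg2rad(f$theta_deg))
    # the filament as a parametrized segment over t in [-l/2, l/2]
    pieces <- list(c(-f$length_um / 2, f$length_um / 2))
    for (cl in crack_lines) {
      new_pieces <- list()
      for (p in pieces) {
        hit <- segment_crack_param(f$x_um, f$y_um, ux, uy, p, cl)
        if (is.na(hit)) {
          new_pieces <- c(new_pieces, list(p))
        } else {
          lo <- c(p[1], hit - gap_um / 2)
          hi <- c(hit + gap_um / 2, p[2])
          if (diff(lo) > 0) new_pieces <- c(new_pieces, list(lo))
          if (diff(hi) > 0) new_pieces <- c(new_pieces, list(hi))
        }
      }
      pieces <- new_pieces
    }
    lens <- vapply(pieces, diff, numeric(1))
    keep <- lens >= min_length_um
    if (!any(keep)) {
      return(NULL)
    }
    mids <- vapply(pieces, mean, numeric(1))[keep]
    tibble(
      cell_id = f$cell_id, stage = f$stage,
      length_um = lens[keep], width_um = f$width_um,
      theta_deg = f$theta_deg,
      x_um = f$x_um + mids * ux,
      y_um = f$y_um + mids * uy
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty_filaments() else res
}

# Parameter t (along the filament axis) of the crossing between the filament
# sub-segment [p1, p2] and a crack segment c(x0, y0, x1, y1); NA if they do
# not cross.
segment_crack_param <- function(cx, cy, ux, uy, p, cl) {
  # filament point: (cx, cy) + t (ux, uy); crack point: (x0, y0) + s * d
  dx <- cl[3] - cl[1]
  dy <- cl[4] - cl[2]
  det <- ux * (-dy) - uy * (-dx)
  if (abs(det) < 1e-12) {
    return(NA_real_) # parallel
  }
  rx <- cl[1] - cx
  ry <- cl[2] - cy
  t <- (rx * (-dy) - ry * (-dx)) / det
  s <- (ux * ry - uy * rx) / det
  if (t <= p[1] || t >= p[2] || s < 0 || s > 1) {
    return(NA_real_)
  }
  t
}
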