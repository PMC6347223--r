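# Paired pre/post cohort simulation with planted ground-truth classes.
#
# Construction per cell: a pre network is drawn; a planted class is sampled
# from the stratum's class-probability preset; damage operators with
# condition-flavoured severities produce the post network; a final uniform
# length rescaling pins the cell's total alteration to a target value at
# least `class_margin` percentage points away from the 10/20 class
# boundaries. The planted class is then *recomputed* from the achieved
# alteration, the apoptosis flag and the detachment flag through the same
# rules the classifier applies, so planted labels are consistent by
# construction even when a severe orientation change makes a milder target
# unreachable.

#' Simulate a paired pre/post cryopreservation cohort
#'
#' Generates, for every condition x recovery time x replicate,
#' `n_cells_per_replicate` cells observed before ("pre") and after ("post")
#' cryopreservation. Post networks are derived from their pre twins via the
#' damage operators ([apply_buckling()], [apply_depolymerization()],
#' [apply_cracking()]); detached cells carry no post filaments. Apoptosis is
#' coupled deterministically to damage by default: damaged (class II/III)
#' cells are Annexin-positive, intact cells negative, with a configurable
#' fraction of apoptosis-positive class-I cells whose total alteration stays
#' below the first boundary.
#'
#' Every cell's planted class is guaranteed: the achieved total alteration
#' lies at least `class_margin` percentage points from the 10/20 boundaries,
#' so the classification pipeline recovers the planted labels exactly.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer master seed; fans out to per-cell child seeds so any
#'   subset is reproducible independently.
#' @return A list of class `cryo_cohort`:
#'   * `filaments` — filament table for all cells and stages;
#'   * `manifest` — one row per cell: `cell_id`, `replicate`, `condition`,
#'     `recovery_min`, `detached`, `annexin_sd`, `planted_class`,
#'     `planted_delta_T`;
#'   * `config`, `seed`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_cells_per_replicate = 3,
#'                                      n_replicates = 1), seed = 7)
#' dplyr::count(coh$manifest, condition, planted_class)
#' }
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1) {
  validate_cohort_config(cfg)
  strata <- tidyr::expand_grid(
    condition = cfg$conditions,
    recovery_min = cfg$recovery_times_min,
    replicate = seq_len(cfg$n_replicates)
  )
  cells <- purrr::pmap(strata, function(condition, recovery_min, replicate) {
    ci <- match(condition, cfg$conditions)
    ti <- match(recovery_min, cfg$recovery_times_min)
    purrr::map(seq_len(cfg$n_cells_per_replicate), function(k) {
      cell_seed <- child_seed(seed, ci, ti, replicate, k)
      simulate_cell(cfg, condition, recovery_min, replicate, k, ci, ti,
                    cell_seed)
    })
  })
  cells <- purrr::flatten(cells)
  structure(list(
    filaments = bind_rows(purrr::map(cells, "filaments")),
    manifest = bind_rows(purrr::map(cells, "manifest")),
    config = cfg,
    seed = seed
  ), class = "cryo_cohort")
}

#' @export
print.cryo_cohort <- function(x, ...) {
  cat(sprintf(
    "<cryo_cohort> %d cells (%d conditions x %d times x %d replicates), seed %d\n",
    nrow(x$manifest), length(x$config$conditions),
    length(x$config$recovery_times_min), x$config$n_replicates, x$seed))
  print(dplyr::count(x$manifest, .data$condition, .data$planted_class))
  invisible(x)
}

simulate_cell <- function(cfg, condition, recovery_min, replicate, k,
                          ci, ti, cell_seed) {
  cell_id <- sprintf("%s_t%03d_r%d_c%02d", condition, recovery_min,
                     replicate, k)
  pre <- generate_cell_filaments(cfg, seed = child_seed(cell_seed, 1),
                                 cell_id = cell_id, stage = "pre")
  draws <- with_seed(child_seed(cell_seed, 2), {
    list(
      class = sample(class_levels(), 1,
                     prob = cfg$class_probs[[condition]][, ti]),
      u_apop1 = runif(1),
      sd_pos = runif(1, cfg$annexin_positive_range[1],
                     cfg$annexin_positive_range[2]),
      sd_neg = runif(1, cfg$annexin_negative_range[1],
                     cfg$annexin_negative_range[2]),
      target_II = runif(1, 10 + cfg$class_margin, 20 - cfg$class_margin),
      target_III = runif(1, 20 + cfg$class_margin, cfg$delta_T_max),
      target_I = runif(1, 1, 10 - cfg$class_margin)
    )
  })

  if (draws$class == "detached") {
    return(list(
      filaments = pre,
      manifest = tibble(
        cell_id = cell_id, replicate = replicate, condition = condition,
        recovery_min = recovery_min, detached = TRUE,
        annexin_sd = NA_real_,
        planted_class = factor("detached", class_levels()),
        planted_delta_T = NA_real_
      )
    ))
  }

  apoptotic <- switch(draws$class,
    I = draws$u_apop1 < cfg$apoptotic_class1_prob,
    II = TRUE, III = TRUE
  )

  post <- damage_cell(pre, condition, draws$class, cfg,
                      seed = child_seed(cell_seed, 3))
  pre_m <- summarise_set(pre)

  if (apoptotic) {
    target <- switch(draws$class, I = draws$target_I, II = draws$target_II,
                     III = draws$target_III)
    fit <- pin_total_alteration(pre_m, post, target, cfg)
    post <- fit$post
    achieved <- fit$delta_T
  } else {
    achieved <- achieved_delta_T(pre_m, post)
  }

  post$cell_id <- cell_id
  post$stage <- "post"
  ann_sd <- if (apoptotic) draws$sd_pos else draws$sd_neg
  planted <- classify_cell(achieved, apoptotic, FALSE)

  list(
    filaments = bind_rows(pre, post),
    manifest = tibble(
      cell_id = cell_id, replicate = replicate, condition = condition,
      recovery_min = recovery_min, detached = FALSE,
      annexin_sd = ann_sd,
      planted_class = planted,
      planted_delta_T = achieved
    )
  )
}

summarise_set <- function(fs) {
  list(
    nu = circular_std(fs$theta_deg),
    F = f_actin_content(fs),
    L = mean_filament_length(fs)
  )
}

achieved_delta_T <- function(pre_m, post) {
  post_m <- summarise_set(post)
  total_alteration(
    percent_alteration(pre_m$F, post_m$F),
    percent_alteration(pre_m$L, post_m$L),
    percent_alteration(pre_m$nu, post_m$nu)
  )
}

# Condition-flavoured damage recipes. Slow freezing: buckling (intracellular
# ice distorts filaments) plus diffuse depolymerization; vitrification:
# cracking (glass fractures) plus mild loss. Severities scale with the
# planted class; class-I cells only get mild remeasurement noise.
damage_cell <- function(pre, condition, class, cfg, seed) {
  sev <- switch(class, I = 0.08, II = 0.35, III = 0.7)
  post <- pre
  post$stage <- "post"
  with_seed(seed, {
    # remeasurement noise on all cells
    post$length_um <- post$length_um * rlnorm(nrow(post), 0, 0.015)
    post$width_um <- pmax(post$width_um * rlnorm(nrow(post), 0, 0.015),
                          cfg$width_min)
    post$theta_deg <- (post$theta_deg + rnorm(nrow(post), 0, 0.75)) %% 180
  })
  if (class == "I") {
    return(post)
  }
  if (condition == "vitrified") {
    cracks <- with_seed(child_seed(seed, 11), {
      n_cr <- if (class == "III") 3 else 1
      purrr::map(seq_len(n_cr), function(i) {
        ang <- runif(1, 0, pi)
        off <- runif(1, -0.4, 0.4) * cfg$cell_semi_axes[2]
        span <- 2.2 * cfg$cell_semi_axes[1]
        c(-span * cos(ang) / 2 - off * sin(ang),
          -span * sin(ang) / 2 + off * cos(ang),
          span * cos(ang) / 2 - off * sin(ang),
          span * sin(ang) / 2 + off * cos(ang))
      })
    })
    post <- apply_cracking(post, cracks, gap_um = 1.5 + 2 * sev)
    post <- apply_depolymerization(post, removal_fraction = 0.3 * sev,
                                   seed = child_seed(seed, 12))
  } else {
    post <- apply_buckling(post, fraction = sev, k_segments = 3,
                           jitter_sd_deg = 8 + 17 * sev,
                           seed = child_seed(seed, 13))
    hole <- if (class == "III") list(c(0, 0)) else NULL
    post <- apply_depolymerization(post, removal_fraction = 0.35 * sev,
                                   hole_centers = hole,
                                   hole_radius_um = 0.25 * cfg$cell_semi_axes[2],
                                   seed = child_seed(seed, 14))
  }
  if (nrow(post) < 3) {
    # keep a remnant so post metrics stay defined; planted classes target
    # finite alterations, never total loss
    post <- pre[seq_len(min(3, nrow(pre))), , drop = FALSE]
    post$stage <- "post"
    post$length_um <- post$length_um * 0.5
  }
  post
}

# Pin the total alteration of a damaged post set to `target` by scaling all
# post lengths by a common factor s (widths and orientations untouched, so
# delta_nu is fixed and delta_F, delta_L scale together). g(s) is strictly
# decreasing on (0, s0] where s0 = min(F_b/F_a, L_b/L_a), from ~ +Inf-ish
# down to the reachable minimum; the root is found there. Targets below the
# reachable minimum are lifted to the nearest boundary-safe value above it.
pin_total_alteration <- function(pre_m, post, target, cfg) {
  post_m <- summarise_set(post)
  a <- post_m$F / pre_m$F
  b <- post_m$L / pre_m$L
  dnu <- abs(percent_alteration(pre_m$nu, post_m$nu))
  if (!is.finite(dnu)) {
    abort("Cannot pin alteration: non-finite orientation change.")
  }
  g <- function(s) {
    (abs(100 * (s * a - 1)) + abs(100 * (s * b - 1)) + dnu) / 3
  }
  s0 <- min(1 / a, 1 / b)
  m <- g(s0)
  margin <- cfg$class_margin
  if (target < m) {
    # lift into the nearest class band (by total alteration) that is
    # reachable and margin-safe
    target <- if (m <= 10 - margin) {
      max(m, 1)
    } else if (m <= 20 - margin) {
      max(m, 10 + margin)
    } else {
      max(m, 20 + margin)
    }
  }
  if (target <= m + 1e-9) {
    s <- s0
  } else {
    s <- stats::uniroot(function(s) g(s) - target,
                        lower = 1e-4, upper = s0, tol = 1e-12)$root
  }
  post$length_um <- post$length_um * s
  post_m2 <- summarise_set(post)
  list(post = post, delta_T = achieved_delta_T(pre_m, post))
}
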