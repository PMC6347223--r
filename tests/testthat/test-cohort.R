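small_cfg <- function(...) {
  cohort_config(n_cells_per_replicate = 4, n_replicates = 2, ...)
}

test_that("cohort size follows the experimental design arithmetic", {
  cfg <- small_cfg()
  coh <- simulate_cohort(cfg, seed = 2)
  expect_equal(nrow(coh$manifest),
               length(cfg$conditions) * length(cfg$recovery_times_min) *
                 cfg$n_replicates * cfg$n_cells_per_replicate)
  expect_equal(anyDuplicated(coh$manifest$cell_id), 0)
  # every attached cell has pre and post filaments, detached only pre
  fil <- coh$filaments
  for (i in seq_len(nrow(coh$manifest))) {
    cid <- coh$manifest$cell_id[i]
    stages <- unique(fil$stage[fil$cell_id == cid])
    if (coh$manifest$detached[i]) {
      expect_identical(stages, "pre")
    } else {
      expect_setequal(stages, c("pre", "post"))
    }
  }
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- small_cfg()
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a$filaments, b$filaments)
  expect_identical(a$manifest, b$manifest)
  c2 <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$filaments, c2$filaments))
})

test_that("forcing detachment in one stratum detaches all its cells", {
  cfg <- small_cfg()
  cfg$class_probs$slow_10C[, 2] <- c(0, 0, 0, 1)
  coh <- simulate_cohort(cfg, seed = 5)
  stratum <- coh$manifest$condition == "slow_10C" &
    coh$manifest$recovery_min == cfg$recovery_times_min[2]
  expect_true(all(coh$manifest$detached[stratum]))
  expect_false(any(coh$filaments$stage[coh$filaments$cell_id %in%
    coh$manifest$cell_id[stratum]] == "post"))
})

test_that("planted total alterations respect the class-boundary margin", {
  coh <- simulate_cohort(small_cfg(), seed = 77)
  dt <- coh$manifest$planted_delta_T
  gated <- !is.na(dt) &
    apoptosis_gate(ifelse(is.na(coh$manifest$annexin_sd), 0,
                          coh$manifest$annexin_sd))
  margin <- coh$config$class_margin
  expect_true(all(abs(dt[gated] - 10) >= margin - 1e-9))
  expect_true(all(abs(dt[gated] - 20) >= margin - 1e-9))
})

test_that("apoptosis is coupled to damage: class II/III positive, detached unmeasured", {
  coh <- simulate_cohort(small_cfg(), seed = 21)
  m <- coh$manifest
  damaged <- m$planted_class %in% c("II", "III")
  expect_true(all(m$annexin_sd[damaged] > 6000))
  expect_true(all(is.na(m$annexin_sd[m$planted_class == "detached"])))
})

test_that("pipeline classification recovers every planted label", {
  coh <- simulate_cohort(small_cfg(), seed = 13)
  rec <- score_alterations(filament_metrics(coh$filaments), coh$manifest)
  joined <- dplyr::inner_join(
    rec, coh$manifest[, c("cell_id", "planted_class")], by = "cell_id")
  expect_equal(as.character(joined$assigned_class),
               as.character(joined$planted_class))
})

test_that("cohort round-trips through CSV unchanged (numeric tolerance)", {
  coh <- simulate_cohort(small_cfg(), seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$filaments)[, 3:7],
               as.data.frame(coh$filaments)[, 3:7], tolerance = 1e-12)
  expect_equal(back$manifest$cell_id, coh$manifest$cell_id)
  expect_equal(back$manifest$planted_class,
               as.character(coh$manifest$planted_class))
})

test_that("generator config survives a YAML round trip", {
  cfg <- small_cfg(orientation_sigma_rad = 0.37)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_equal(cfg2$orientation_sigma_rad, 0.37)
  expect_equal(cfg2$class_probs$slow_1C, cfg$class_probs$slow_1C,
               tolerance = 1e-12)
  m1 <- simulate_cohort(cfg, seed = 9)$manifest
  m2 <- simulate_cohort(cfg2, seed = 9)$manifest
  expect_identical(m2$planted_class, m1$planted_class)
  expect_equal(m2$planted_delta_T, m1$planted_delta_T, tolerance = 1e-6)
})
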