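test_that("buckling partitions length, preserves F, and is identity at fraction 0", {
  fs <- random_filaments(25, seed = 8)
  expect_identical(apply_buckling(fs, fraction = 0, seed = 1), fs)
  b <- apply_buckling(fs, fraction = 1, k_segments = 3, jitter_sd_deg = 0,
                      seed = 2)
  expect_equal(nrow(b), 3 * nrow(fs))
  expect_equal(f_actin_content(b), f_actin_content(fs), tolerance = 1e-12)
  expect_equal(mean_filament_length(b), mean_filament_length(fs) / 3,
               tolerance = 1e-12)
  expect_error(apply_buckling(fs, 0.5, k_segments = 1), "at least 2")
})

test_that("buckling with jitter raises measured anisotropy dispersion", {
  # 200-cell Monte-Carlo with the network mean away from the 0/180 fold
  # (the literal, non-axial circular SD is unstable right at the fold):
  # buckled networks show higher nu in nearly all cells
  hits <- 0L
  drops <- 0L
  for (i in 1:200) {
    fs <- make_filaments(
      length_um = stats::rlnorm(50, log(8), 0.4),
      width_um = 0.4,
      theta_deg = sample_orientations(50, 90, 0.5, seed = 4000 + i)
    )
    b <- apply_buckling(fs, fraction = 1, k_segments = 3, jitter_sd_deg = 20,
                        seed = 700 + i)
    if (circular_std(b$theta_deg) > circular_std(fs$theta_deg)) hits <- hits + 1L
    if (mean_filament_length(b) < mean_filament_length(fs)) drops <- drops + 1L
  }
  expect_gte(hits / 200, 0.95)
  expect_equal(drops, 200L) # partition always shortens the mean length
  # median directionality also holds for uncontrolled per-cell mean angles
  d_nu <- vapply(1:100, function(i) {
    fs <- generate_cell_filaments(cohort_config(), seed = 4300 + i)
    b <- apply_buckling(fs, 1, 3, 20, seed = 750 + i)
    circular_std(b$theta_deg) - circular_std(fs$theta_deg)
  }, numeric(1))
  expect_gt(median(d_nu), 0)
})

test_that("depolymerization thins the network and carves holes", {
  fs <- random_filaments(40, seed = 9)
  expect_identical(apply_depolymerization(fs, 0), fs)
  gone <- apply_depolymerization(fs, 1, seed = 1)
  expect_equal(nrow(gone), 0)
  expect_equal(f_actin_content(gone), 0)
  # hole deletion removes exactly the filaments whose centroid is in a disc
  holed <- apply_depolymerization(fs, 0, hole_centers = list(c(0, 0)),
                                  hole_radius_um = 10, seed = 1)
  inside <- fs$x_um^2 + fs$y_um^2 <= 100
  expect_equal(nrow(holed), sum(!inside))
  expect_error(apply_depolymerization(fs, 0.5, hole_radius_um = -1), "must be")
})

test_that("depolymerization at 30% removal loses ~30% of F on average", {
  dF <- vapply(1:200, function(i) {
    fs <- generate_cell_filaments(cohort_config(), seed = 5000 + i)
    d <- apply_depolymerization(fs, 0.3, seed = 900 + i)
    percent_alteration(f_actin_content(fs), f_actin_content(d))
  }, numeric(1))
  se <- stats::sd(dF) / sqrt(length(dF))
  expect_lt(abs(mean(dF) + 30), 3 * se + 0.5)
})

test_that("cracking splits crossing filaments with the gap removed", {
  f1 <- make_filaments(10, width_um = 1, theta_deg = 0)
  cr <- apply_cracking(f1, list(c(0, -5, 0, 5)), gap_um = 2)
  expect_equal(nrow(cr), 2)
  expect_equal(sort(cr$length_um), c(4, 4))
  expect_equal(unique(cr$theta_deg), 0)
  expect_equal(sort(cr$x_um), c(-3, 3))
  # no crack lines -> identity
  expect_identical(apply_cracking(f1, list(), gap_um = 2), f1)
  # a crack that misses leaves the filament intact
  miss <- apply_cracking(f1, list(c(20, -5, 20, 5)), gap_um = 2)
  expect_equal(nrow(miss), 1)
})

test_that("cracking never increases mean length or F-actin content", {
  for (i in 1:50) {
    fs <- random_filaments(20, seed = 300 + i)
    set.seed(i)
    cracks <- lapply(1:2, function(k) runif(4, -20, 20))
    cr <- apply_cracking(fs, cracks, gap_um = runif(1, 0, 3))
    if (nrow(cr) > 0) {
      expect_lte(mean_filament_length(cr),
                 mean_filament_length(fs) + 1e-9)
    }
    expect_lte(f_actin_content(cr), f_actin_content(fs) + 1e-9)
  }
})

test_that("cracking lowers the mean length on damaged cells (directionality)", {
  dL <- vapply(1:200, function(i) {
    fs <- generate_cell_filaments(cohort_config(), seed = 6000 + i)
    cr <- apply_cracking(fs, list(c(-60, -2, 60, 2), c(0, -40, 2, 40)),
                         gap_um = 2)
    percent_alteration(mean_filament_length(fs), mean_filament_length(cr))
  }, numeric(1))
  expect_lt(median(dL), 0)
})
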