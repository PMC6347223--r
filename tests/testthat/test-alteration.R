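test_that("percentage alteration follows 100 (after/before - 1)", {
  expect_equal(percent_alteration(100, 80), -20)
  expect_equal(percent_alteration(50, 75), 50)
  expect_equal(percent_alteration(3.7, 3.7), 0)
  expect_true(is.na(percent_alteration(0, 5)))
  expect_true(is.na(percent_alteration(10, Inf)))
})

test_that("total alteration is the mean of absolute component alterations", {
  expect_equal(total_alteration(0, 0, 0), 0)
  expect_equal(total_alteration(-20, 10, -30), 20)
  expect_equal(total_alteration(-5, 5, 5), 5)
  expect_true(is.na(total_alteration(NA, 5, 5)))
})

test_that("annexin SD is the population SD, optionally masked", {
  expect_equal(annexin_sd(rep(500, 10)), 0)
  expect_equal(annexin_sd(c(0, 12400)), 6200)
  img <- c(rep(0, 50), rep(10000, 50))
  mask <- c(rep(FALSE, 50), rep(TRUE, 50))
  expect_equal(annexin_sd(img, mask), 0)
  expect_gt(annexin_sd(img), 0)
  expect_error(annexin_sd(5), "2 pixels")
})

test_that("apoptosis gate is strict at the 6000 a.u. threshold", {
  expect_true(apoptosis_gate(6500))
  expect_false(apoptosis_gate(6000))
  expect_false(apoptosis_gate(0))
  expect_true(apoptosis_gate(5000, threshold = 4000))
})

test_that("class assignment applies detachment, gate and thresholds in order", {
  expect_equal(as.character(classify_cell(35, FALSE, FALSE)), "I")
  expect_equal(as.character(classify_cell(15, TRUE, FALSE)), "II")
  expect_equal(as.character(classify_cell(25, TRUE, FALSE)), "III")
  expect_equal(as.character(classify_cell(NA, TRUE, TRUE)), "detached")
  # boundary ties fall to the milder class
  expect_equal(as.character(classify_cell(10, TRUE, FALSE)), "I")
  expect_equal(as.character(classify_cell(20, TRUE, FALSE)), "II")
})

test_that("class assignment is monotone in delta_T for gated, attached cells", {
  dts <- sort(runif(50, 0, 40))
  cls <- as.integer(classify_cell(dts, TRUE, FALSE))
  expect_true(all(diff(cls) >= 0))
})

test_that("pairing computes the full alteration chain through the formulas", {
  # pre F=100/L=10/nu=.5; post F=80/L=9/nu=.6 -> deltas (-20,-10,+20), dT=50/3
  metrics <- tibble::tibble(
    cell_id = "z", stage = c("pre", "post"),
    n = c(10, 10), R = NA_real_,
    nu_rad = c(0.5, 0.6), F_um2 = c(100, 80), L_um = c(10, 9),
    defined = TRUE
  )
  manifest <- tibble::tibble(cell_id = "z", replicate = 1,
                             condition = "slow_1C", recovery_min = 0,
                             detached = FALSE, annexin_sd = 9000)
  rec <- score_alterations(metrics, manifest)
  expect_equal(rec$delta_F, -20)
  expect_equal(rec$delta_L, -10)
  expect_equal(rec$delta_nu, 20, tolerance = 1e-12)
  expect_equal(rec$delta_T, 50 / 3, tolerance = 1e-12)
  expect_true(rec$apoptotic)
  expect_equal(as.character(rec$assigned_class), "II")
})

test_that("scoring handles identity, detachment and undefined-post cases", {
  toy <- toy_cohort()
  m <- filament_metrics(toy$filaments)
  rec <- score_alterations(m, toy$manifest)
  rec_a <- rec[rec$cell_id == "a", ]
  expect_equal(rec_a$delta_nu, 0)
  expect_equal(rec_a$delta_F, -20)
  expect_equal(as.character(rec_a$assigned_class), "II")
  rec_b <- rec[rec$cell_id == "b", ]
  expect_equal(as.character(rec_b$assigned_class), "detached")
  expect_true(is.na(rec_b$delta_T))

  # identical pre/post, apoptosis-negative -> delta_T 0, class I
  fil <- dplyr::bind_rows(
    make_filaments(c(5, 7), theta_deg = c(10, 30), cell_id = "w",
                   stage = "pre"),
    make_filaments(c(5, 7), theta_deg = c(10, 30), cell_id = "w",
                   stage = "post")
  )
  man <- tibble::tibble(cell_id = "w", replicate = 1, condition = "control",
                        recovery_min = 0, detached = FALSE, annexin_sd = 500)
  r <- score_alterations(filament_metrics(fil), man)
  expect_equal(r$delta_T, 0)
  expect_equal(as.character(r$assigned_class), "I")

  # attached cell with no post filaments -> class III with a flag
  man2 <- tibble::tibble(cell_id = "q", replicate = 1, condition = "slow_10C",
                         recovery_min = 15, detached = FALSE,
                         annexin_sd = 9000)
  fil2 <- make_filaments(c(5, 7), cell_id = "q", stage = "pre")
  r2 <- score_alterations(filament_metrics(fil2), man2)
  expect_equal(as.character(r2$assigned_class), "III")
  expect_equal(r2$excluded_reason, "post_undefined")
  expect_true(is.na(r2$delta_T))
})

test_that("stored delta_T always equals recomputation from its components", {
  coh <- simulate_cohort(cohort_config(n_cells_per_replicate = 4,
                                       n_replicates = 2), seed = 33)
  rec <- score_alterations(filament_metrics(coh$filaments), coh$manifest)
  fin <- rec[is.finite(rec$delta_T), ]
  expect_gt(nrow(fin), 0)
  expect_equal(fin$delta_T,
               total_alteration(fin$delta_F, fin$delta_L, fin$delta_nu),
               tolerance = 1e-12)
})
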