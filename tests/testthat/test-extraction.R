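# Renderer + extractor round trips on synthetic ground truth.

render_one <- function(theta_deg, length_um = 20, width_um = 0.4,
                       rc = render_config()) {
  make_filaments(length_um, width_um = width_um, theta_deg = theta_deg)
}

disjoint_scene <- function(n = 30, seed = 9, mean_deg = 70, sigma = 0.4) {
  grid <- expand.grid(gx = seq(-2.5, 2.5, 1), gy = seq(-2, 2, 1))
  grid <- grid[seq_len(n), ]
  set.seed(seed)
  make_filaments(
    length_um = runif(n, 5, 9),
    width_um = pmax(rnorm(n, 0.4, 0.06), 0.2),
    theta_deg = sample_orientations(n, mean_deg, sigma, seed = seed + 1),
    x_um = grid$gx * 12, y_um = grid$gy * 12
  )
}

test_that("maximum intensity projection is a per-pixel max over planes", {
  s1 <- matrix(0, 6, 6); s1[2, 3] <- 7
  s2 <- matrix(1, 6, 6); s2[5, 5] <- 4
  mp <- max_intensity_projection(list(s1, s2))
  expect_equal(mp[2, 3], 7)
  expect_equal(mp[5, 5], 4)
  expect_equal(mp[1, 1], 1)
  # single plane is the identity; plane order is irrelevant
  expect_identical(max_intensity_projection(list(s1)), s1)
  expect_identical(max_intensity_projection(list(s2, s1)), mp)
  expect_error(max_intensity_projection(list()), "Empty")
})

test_that("rendering is deterministic and clips out-of-frame filaments", {
  rc <- render_config(gain = 2, read_noise_sd = 3)
  fs <- disjoint_scene(10)
  expect_identical(render_cell(fs, rc, seed = 5), render_cell(fs, rc, seed = 5))
  far <- make_filaments(30, theta_deg = 0, x_um = 32, y_um = 0)
  expect_warning(render_cell(far, render_config(image_px = c(100, 100))),
                 "clipped")
  # empty set renders pure background
  bg <- render_cell(empty_filaments()[0, ], render_config())
  expect_true(all(bg == render_config()$background))
})

test_that("a blank image yields an empty filament table", {
  expect_equal(nrow(extract_filaments(matrix(5, 64, 64))), 0)
  expect_error(extract_filaments(array(0, c(4, 4, 2))), "2D")
})

test_that("a noise-free single filament is recovered within stated tolerances", {
  rc <- render_config()
  ec <- extraction_config()
  fs <- render_one(30)
  ex <- extract_filaments(render_cell(fs, rc), ec)
  expect_equal(nrow(ex), 1)
  expect_lt(abs(ex$theta_deg - 30), 2)
  expect_lt(abs(ex$length_um - 20) / 20, 0.10)
  expect_lt(abs(ex$width_um - 0.4) / 0.4, 0.25)
  # centroid lands on the true position
  expect_lt(abs(ex$x_um), 1)
  expect_lt(abs(ex$y_um), 1)
})

test_that("recovered orientation tracks the rendered angle across the half-circle", {
  rc <- render_config()
  ec <- extraction_config()
  for (th in seq(5, 175, by = 17)) {
    ex <- extract_filaments(render_cell(render_one(th), rc), ec)
    expect_equal(nrow(ex), 1)
    d <- abs(ex$theta_deg - th)
    expect_lt(min(d, 180 - d), 2)
  }
})

test_that("a 30-filament scene is recovered within the end-to-end tolerances", {
  rc <- render_config(image_px = c(520, 520))
  fs <- disjoint_scene(30)
  ex <- extract_filaments(render_cell(fs, rc), extraction_config())
  expect_lte(abs(nrow(ex) - 30) / 30, 0.10)
  expect_lt(abs(circular_std(ex$theta_deg) - circular_std(fs$theta_deg)),
            0.05)
  expect_lt(abs(mean_filament_length(ex) / mean_filament_length(fs) - 1),
            0.10)
  expect_lt(abs(f_actin_content(ex) / f_actin_content(fs) - 1), 0.15)
})

test_that("raising the intensity filter never increases the segment count", {
  rc <- render_config(image_px = c(520, 520))
  img <- render_cell(disjoint_scene(20), rc)
  counts <- vapply(c(0, 5, 40, 80, 200), function(mi) {
    nrow(extract_filaments(img, extraction_config(min_mean_intensity = mi)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a bent polyline is split into multiple straight segments", {
  # two touching 10-um halves at 20 and 60 degrees: the measurement artifact
  # of buckling is one filament detected as several
  ux <- c(cos(20 * pi / 180), cos(60 * pi / 180))
  uy <- c(sin(20 * pi / 180), sin(60 * pi / 180))
  fs <- make_filaments(c(10, 10), width_um = 0.4, theta_deg = c(20, 60),
                       x_um = c(0, 5 * ux[1] + 5 * ux[2]),
                       y_um = c(0, 5 * uy[1] + 5 * uy[2]))
  ex <- extract_filaments(render_cell(fs, render_config()),
                          extraction_config())
  expect_gte(nrow(ex), 2)
  # recovered angles bracket the two true directions
  expect_true(any(abs(ex$theta_deg - 20) < 6))
  expect_true(any(abs(ex$theta_deg - 60) < 6))
})

test_that("images round-trip through TIFF with stack support", {
  rc <- render_config(image_px = c(64, 64))
  img <- render_cell(make_filaments(6, width_um = 0.4, theta_deg = 10), rc)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path, rc)
  back <- read_image_stack(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1) # quantisation only
  # multi-page
  write_image(list(img, img * 0.5), path, rc)
  stack <- read_image_stack(path)
  expect_equal(dim(stack)[3], 2)
  proj <- max_intensity_projection(stack)
  expect_equal(dim(proj), dim(img))
})
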