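test_that("Mann-Whitney U matches symmetry and hand-enumerated cases", {
  r <- mann_whitney_u(c(5, 1, 3), c(5, 1, 3))
  expect_equal(r$statistic, 3 * 3 / 2) # identical multisets -> U = n1 n2 / 2
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p.value, 0.1, tolerance = 1e-12)
  expect_true(r2$exact)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact path equals full enumeration; approximation is close (n <= 7)", {
  set.seed(202)
  for (rep in 1:40) {
    n1 <- sample(3:7, 1)
    n2 <- sample(3:7, 1)
    x <- sample(seq_len(60), n1 + n2) # tie-free by construction
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    p_enum <- oracle_mw_exact(a, b)
    exact <- mann_whitney_u(a, b)
    expect_true(exact$exact)
    expect_equal(exact$p.value, p_enum, tolerance = 1e-9)
    approx <- mann_whitney_u(a, b, exact_max_n = 0)
    expect_false(approx$exact)
    # worst-case deviation of the corrected normal approximation from the
    # exact two-sided p over all configurations with 3 <= n <= 7 is 0.0375
    expect_lt(abs(approx$p.value - p_enum), 0.04)
  }
})

test_that("ties switch to the corrected normal approximation", {
  r <- mann_whitney_u(c(1, 2, 2, 3), c(2, 4, 5))
  expect_false(r$exact)
  expect_true(r$p.value > 0 && r$p.value <= 1)
})

test_that("class fractions average per-replicate partitions", {
  rec <- tibble::tibble(
    condition = "slow_1C", recovery_min = 0,
    replicate = rep(1:3, each = 10),
    assigned_class = factor(
      c(rep("I", 8), "II", "detached",
        rep("I", 9), "II",
        rep("I", 10)),
      levels = c("I", "II", "III", "detached"))
  )
  cf <- class_fractions(rec)
  ci <- cf[cf$class == "I", ]
  expect_equal(ci$mean_fraction, 0.9)
  expect_equal(ci$sd_fraction, 0.1, tolerance = 1e-12)
  # fractions sum to 1 within each stratum
  sums <- tapply(cf$mean_fraction, paste(cf$condition, cf$recovery_min), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("delta summaries use type-7 interpolated quartiles and drop non-finite", {
  rec <- tibble::tibble(
    condition = "v", recovery_min = 0,
    delta_nu = c(1, 2, 3, 4), delta_F = c(-10, 0, 10, NA),
    delta_L = c(5, 5, 5, 5)
  )
  ds <- delta_summaries(rec)
  dn <- ds[ds$parameter == "delta_nu", ]
  expect_equal(dn$median, 2.5)
  expect_equal(dn$q25, quantile(1:4, 0.25, names = FALSE))
  expect_equal(dn$q75, quantile(1:4, 0.75, names = FALSE))
  df_ <- ds[ds$parameter == "delta_F", ]
  expect_equal(df_$n, 3)
  expect_equal(df_$n_dropped, 1)
  expect_equal(df_$median, 0)
})

test_that("direction splits cover only damaged classes and split on sign", {
  rec <- tibble::tibble(
    condition = "s", recovery_min = 15,
    assigned_class = factor(c("II", "III", "II", "III", "I"),
                            levels = c("I", "II", "III", "detached")),
    delta_nu = c(5, -3, -7, 1, 100),
    delta_F = 1, delta_L = 1
  )
  sp <- direction_split(rec, "delta_nu")
  expect_equal(sp$n, 4) # the class-I cell never contributes
  expect_equal(sp$frac_increased, 0.5)
  expect_equal(sp$frac_decreased, 0.5)
})

test_that("a planted location shift is detected with high power", {
  # control deltas centred at 0, treated at +15, n = 15/group
  hits <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    ctrl <- rnorm(15, 0, 10)
    trt <- rnorm(15, 15, 10)
    mann_whitney_u(trt, ctrl)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("summarize_cohort assembles fractions, quartiles, splits and tests", {
  coh <- simulate_cohort(cohort_config(n_cells_per_replicate = 5,
                                       n_replicates = 2), seed = 44)
  rec <- score_alterations(filament_metrics(coh$filaments), coh$manifest)
  s <- summarize_cohort(rec)
  expect_s3_class(s, "cryo_summary")
  # 3 non-control conditions x 3 times x 3 parameters
  expect_equal(nrow(s$tests), 27)
  expect_true(all(s$tests$reference == "control"))
  td <- tidy(s)
  expect_true(all(c("class_fraction", "delta_median", "rank_test") %in%
                    td$component))
  g <- glance(s)
  expect_equal(g$n_cells, nrow(rec))
  # summaries are permutation-invariant
  s2 <- summarize_cohort(rec[sample(nrow(rec)), ])
  expect_equal(s2$class_fractions, s$class_fractions)
  expect_equal(s2$tests$p.value, s$tests$p.value)
})

test_that("plot builders return ggplot objects", {
  coh <- simulate_cohort(cohort_config(n_cells_per_replicate = 5,
                                       n_replicates = 2), seed = 44)
  rec <- score_alterations(filament_metrics(coh$filaments), coh$manifest)
  s <- summarize_cohort(rec)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(plot_delta_summaries(s), "ggplot")
  expect_s3_class(plot_direction_split(s, "delta_F"), "ggplot")
})
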