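# Small in-code fixtures shared across test files.

make_filaments <- function(length_um, width_um = 1, theta_deg = 0,
                           x_um = 0, y_um = 0, cell_id = "c1",
                           stage = "pre") {
  tibble::tibble(
    cell_id = cell_id, stage = stage,
    length_um = length_um,
    width_um = rep_len(width_um, length(length_um)),
    theta_deg = rep_len(theta_deg, length(length_um)),
    x_um = rep_len(x_um, length(length_um)),
    y_um = rep_len(y_um, length(length_um))
  )
}

random_filaments <- function(n, seed) {
  set.seed(seed)
  make_filaments(
    length_um = stats::runif(n, 1, 20),
    width_um = stats::runif(n, 0.1, 1),
    theta_deg = stats::runif(n, 0, 180),
    x_um = stats::runif(n, -20, 20),
    y_um = stats::runif(n, -12, 12)
  )
}

# independent oracle: resultant length by explicit unit-vector summation
# (complex arithmetic), no shared code with the implementation
oracle_resultant <- function(theta_deg) {
  v <- sum(exp(1i * theta_deg * pi / 180))
  Mod(v) / length(theta_deg)
}

# independent oracle: exact two-sided Mann-Whitney p by full enumeration of
# group assignments
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# a tiny paired metrics + manifest pair for classification tests
toy_cohort <- function() {
  fil <- dplyr::bind_rows(
    make_filaments(c(10, 10), width_um = 1, theta_deg = c(0, 40),
                   cell_id = "a", stage = "pre"),
    make_filaments(c(8, 8), width_um = 1, theta_deg = c(0, 40),
                   cell_id = "a", stage = "post"),
    make_filaments(c(10, 10), width_um = 1, theta_deg = c(0, 40),
                   cell_id = "b", stage = "pre")
  )
  manifest <- tibble::tibble(
    cell_id = c("a", "b"),
    replicate = 1L, condition = "slow_1C", recovery_min = 0,
    detached = c(FALSE, TRUE),
    annexin_sd = c(8000, NA),
    planted_class = factor(c("II", "detached"),
                           levels = c("I", "II", "III", "detached"))
  )
  list(filaments = fil, manifest = manifest)
}
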