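# Cohort-level summaries: class fractions over replicates, alteration
# medians/quartiles, direction splits among damaged cells, and rank tests
# against the non-cryopreserved control.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples under the null of equal
#' medians. The p-value is computed from the exact U distribution when
#' `min(n1, n2) <= exact_max_n` and neither sample contains ties, and from
#' the tie-corrected normal approximation (with continuity correction)
#' otherwise. Backed by [stats::wilcox.test()]; `U` counts pairs in which the
#' first sample exceeds the second.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max_n Largest `min(n1, n2)` for which the exact distribution
#'   is used (default 8).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return One-row tibble: `statistic` (U), `p.value`, `n1`, `n2`, `exact`,
#'   `significant`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_max_n = 8, alpha = 0.05) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must be non-empty.")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && min(length(a), length(b)) <= exact_max_n
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE,
                alternative = "two.sided")
  )
  tibble(
    statistic = unname(ht$statistic),
    p.value = min(ht$p.value, 1),
    n1 = length(a), n2 = length(b),
    exact = use_exact,
    significant = ht$p.value < alpha,
    method = if (use_exact) "exact" else "normal approximation (tie-corrected)"
  )
}

#' Class fractions per stratum, averaged over replicates
#'
#' Within each `condition` x `recovery_min` x `replicate`, computes the
#' fraction of cells in each class (`I`, `II`, `III`, `detached`; fractions
#' sum to 1), then reports the unweighted mean and sample standard deviation
#' across replicates. Cells without an assigned class (excluded) are dropped
#' from the denominators.
#'
#' @param records Alteration records from [score_alterations()] (needs
#'   `condition`, `recovery_min`, `replicate`, `assigned_class`).
#' @return Tibble: `condition`, `recovery_min`, `class`, `mean_fraction`,
#'   `sd_fraction`, `n_replicates`.
#' @export
class_fractions <- function(records) {
  rec <- records |> filter(!is.na(.data$assigned_class))
  if (nrow(rec) == 0L) abort("No classified cells in `records`.")
  per_rep <- rec |>
    mutate(assigned_class = factor(.data$assigned_class, class_levels())) |>
    count(.data$condition, .data$recovery_min, .data$replicate,
          .data$assigned_class, .drop = FALSE, name = "n_cells") |>
    group_by(.data$condition, .data$recovery_min, .data$replicate) |>
    mutate(total = sum(.data$n_cells)) |>
    ungroup() |>
    filter(.data$total > 0) |>
    mutate(fraction = .data$n_cells / .data$total)
  per_rep |>
    group_by(.data$condition, .data$recovery_min,
             class = .data$assigned_class) |>
    summarise(
      mean_fraction = mean(.data$fraction),
      sd_fraction = if (dplyr::n() > 1) sd(.data$fraction) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Median and quartiles of the alterations per stratum
#'
#' Summarises one or all alteration parameters per
#' `condition` x `recovery_min`, pooling replicates (the replicate is a
#' repetition of the same condition, not a blocking factor in the summary).
#' Detached and excluded cells carry no finite deltas and are dropped; the
#' number dropped is reported per stratum. Quartiles use R's default type-7
#' linear interpolation between order statistics.
#'
#' @param records Alteration records.
#' @param parameter One of `"delta_nu"`, `"delta_F"`, `"delta_L"` or
#'   `"all"` (default).
#' @return Tibble: `condition`, `recovery_min`, `parameter`, `n`,
#'   `n_dropped`, `q25`, `median`, `q75`.
#' @export
delta_summaries <- function(records,
                            parameter = c("all", "delta_nu", "delta_F",
                                          "delta_L")) {
  parameter <- match.arg(parameter)
  params <- if (parameter == "all") {
    c("delta_nu", "delta_F", "delta_L")
  } else {
    parameter
  }
  long <- records |>
    select("condition", "recovery_min", dplyr::all_of(params)) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "delta")
  q_or_na <- function(x, p) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) NA_real_ else quantile(x, p, names = FALSE, type = 7)
  }
  long |>
    group_by(.data$condition, .data$recovery_min, .data$parameter) |>
    summarise(
      n = sum(is.finite(.data$delta)),
      n_dropped = sum(!is.finite(.data$delta)),
      q25 = q_or_na(.data$delta, 0.25),
      median = q_or_na(.data$delta, 0.5),
      q75 = q_or_na(.data$delta, 0.75),
      .groups = "drop"
    )
}

#' Increase/decrease split among damaged cells
#'
#' Restricted to cells of classes II and III (the damaged classes), reports
#' per stratum the fraction of cells whose alteration increased
#' (`delta > 0`) versus decreased. Cells with `delta == 0` (measure-zero
#' under the continuous pipeline) count as "not increased".
#'
#' @param records Alteration records.
#' @param parameter `"delta_nu"`, `"delta_F"` or `"delta_L"`.
#' @return Tibble: `condition`, `recovery_min`, `parameter`, `n`,
#'   `frac_increased`, `frac_decreased`.
#' @export
direction_split <- function(records,
                            parameter = c("delta_nu", "delta_F", "delta_L")) {
  parameter <- match.arg(parameter)
  rec <- records |>
    filter(.data$assigned_class %in% c("II", "III"),
           is.finite(.data[[parameter]]))
  rec |>
    group_by(.data$condition, .data$recovery_min) |>
    summarise(
      parameter = parameter,
      n = dplyr::n(),
      frac_increased = mean(.data[[parameter]] > 0),
      frac_decreased = mean(.data[[parameter]] <= 0),
      .groups = "drop"
    )
}

#' Summarise a scored cohort
#'
#' The cohort-level analysis: class fractions (mean +/- SD over replicates),
#' alteration medians and quartiles, increase/decrease splits among damaged
#' cells, and two-sided Mann-Whitney U tests of each cryopreserved condition
#' against the control at matching recovery time, for each of the three
#' alteration parameters. No multiple-testing correction is applied by
#' default (per-comparison reporting at `alpha`); set `p_adjust_method` to
#' any [stats::p.adjust()] method to add one.
#'
#' @param records Alteration records from [score_alterations()].
#' @param control Label of the reference condition (default `"control"`).
#' @param comparisons `"control_vs_each"` (default) tests every other
#'   condition against `control`; `"all_pairs"` tests all condition pairs.
#' @param alpha Per-comparison significance level (default 0.05).
#' @param p_adjust_method Optional multiple-testing correction method;
#'   `"none"` (default) matches per-comparison reporting.
#' @return Object of class `cryo_summary`: list with `class_fractions`,
#'   `delta_summaries`, `direction_splits`, `tests`, `n_cells`,
#'   `n_excluded`, `alpha`.
#' @export
summarize_cohort <- function(records, control = "control",
                             comparisons = c("control_vs_each", "all_pairs"),
                             alpha = 0.05, p_adjust_method = "none") {
  comparisons <- match.arg(comparisons)
  conds <- sort(unique(records$condition))
  pairs <- if (comparisons == "control_vs_each") {
    if (!control %in% conds) {
      abort(sprintf("Control condition '%s' not present in `records`.", control))
    }
    tibble(cond_a = setdiff(conds, control), cond_b = control)
  } else {
    cmb <- utils::combn(conds, 2)
    tibble(cond_a = cmb[1, ], cond_b = cmb[2, ])
  }
  grid <- tidyr::expand_grid(
    pairs,
    recovery_min = sort(unique(records$recovery_min)),
    parameter = c("delta_nu", "delta_F", "delta_L")
  )
  tests <- purrr::pmap(grid, function(cond_a, cond_b, recovery_min,
                                      parameter) {
    xa <- records[[parameter]][records$condition == cond_a &
                                 records$recovery_min == recovery_min]
    xb <- records[[parameter]][records$condition == cond_b &
                                 records$recovery_min == recovery_min]
    xa <- xa[is.finite(xa)]
    xb <- xb[is.finite(xb)]
    if (length(xa) == 0L || length(xb) == 0L) {
      return(tibble(condition = cond_a, reference = cond_b,
                    recovery_min = recovery_min, parameter = parameter,
                    statistic = NA_real_, p.value = NA_real_,
                    n1 = length(xa), n2 = length(xb), exact = NA,
                    significant = NA, method = "not run (empty sample)"))
    }
    mann_whitney_u(xa, xb, alpha = alpha) |>
      mutate(condition = cond_a, reference = cond_b,
             recovery_min = recovery_min, parameter = parameter,
             .before = 1)
  }) |> bind_rows()
  if (p_adjust_method != "none") {
    tests <- tests |>
      mutate(p.adjusted = stats::p.adjust(.data$p.value, p_adjust_method),
             significant = .data$p.adjusted < alpha)
  }
  structure(list(
    class_fractions = class_fractions(records),
    delta_summaries = delta_summaries(records),
    direction_splits = bind_rows(
      direction_split(records, "delta_nu"),
      direction_split(records, "delta_F"),
      direction_split(records, "delta_L")
    ),
    tests = tests,
    n_cells = nrow(records),
    n_excluded = sum(!is.na(records$excluded_reason)),
    alpha = alpha
  ), class = "cryo_summary")
}

#' @export
print.cryo_summary <- function(x, ...) {
  cat(sprintf("<cryo_summary> %d cells (%d flagged), %d rank tests (%d significant at %.2g)\n",
              x$n_cells, x$n_excluded, nrow(x$tests),
              sum(x$tests$significant, na.rm = TRUE), x$alpha))
  cat("Class fractions (mean over replicates):\n")
  wide <- x$class_fractions |>
    select("condition", "recovery_min", "class", "mean_fraction") |>
    tidyr::pivot_wider(names_from = "class", values_from = "mean_fraction")
  print(wide, n = 12)
  invisible(x)
}

#' Tidy a cohort summary into one long tibble
#'
#' Stacks class fractions, delta quartiles, direction splits and test
#' results with a `component` discriminator column, ready for filtering and
#' plotting.
#'
#' @param x A `cryo_summary`.
#' @param ... Unused.
#' @return A long tibble with columns `component`, `condition`,
#'   `recovery_min`, `term`, `estimate` plus component-specific columns.
#' @export
tidy.cryo_summary <- function(x, ...) {
  bind_rows(
    x$class_fractions |>
      mutate(component = "class_fraction", term = as.character(.data$class),
             estimate = .data$mean_fraction, sd = .data$sd_fraction) |>
      select("component", "condition", "recovery_min", "term", "estimate",
             "sd"),
    x$delta_summaries |>
      mutate(component = "delta_median", term = .data$parameter,
             estimate = .data$median) |>
      select("component", "condition", "recovery_min", "term", "estimate",
             "q25", "q75", "n"),
    x$direction_splits |>
      mutate(component = "direction_split", term = .data$parameter,
             estimate = .data$frac_increased) |>
      select("component", "condition", "recovery_min", "term", "estimate",
             "n"),
    x$tests |>
      mutate(component = "rank_test",
             term = paste(.data$parameter, "vs", .data$reference),
             estimate = .data$statistic) |>
      select("component", "condition", "recovery_min", "term", "estimate",
             "p.value", "significant")
  )
}

#' One-row overview of a cohort summary
#'
#' @param x A `cryo_summary`.
#' @param ... Unused.
#' @return One-row tibble: cell counts, exclusions, number of strata, test
#'   counts and significant calls.
#' @export
glance.cryo_summary <- function(x, ...) {
  tibble(
    n_cells = x$n_cells,
    n_excluded = x$n_excluded,
    n_strata = nrow(dplyr::distinct(x$class_fractions,
                                    .data$condition, .data$recovery_min)),
    n_tests = sum(!is.na(x$tests$p.value)),
    n_significant = sum(x$tests$significant, na.rm = TRUE),
    alpha = x$alpha
  )
}
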