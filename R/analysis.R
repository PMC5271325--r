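# Statistical analyses on trial tables (synthetic or imported): pooling,
# baseline subtraction, uncorrected-fraction slopes, variability and score
# summaries, counterfactual rescoring, the ideal-observer benchmark, bias
# curves and data-vs-model slope agreement. All group summaries are
# mean +/- SE between subjects (subject-level statistics first, never
# trials pooled across subjects).

#' Pool left and right high-uncertainty trials by mirroring
#'
#' Adds a pooled `uncertainty` column (`"low"` / `"high"`) and mirrored,
#' sign-symmetric copies of the signed quantities: high-left trials are
#' reflected (sign flip of `s_true_cm`, `b_cm`, `perturbation_level`,
#' `r_cm`, `delta_s_cm`) onto high-right before any class summary, which
#' is valid because the task is left/right symmetric by construction.
#' Mirrored columns carry the suffix `_p`.
#'
#' @param records A response tibble (see [simulate_responses()]).
#' @return The tibble with `uncertainty`, `b_p`, `level_p`, `delta_p`
#'   columns added.
#' @export
pool_sides <- function(records) {
  flip <- ifelse(records$uncertainty_class == "high-left", -1, 1)
  dplyr::mutate(records,
                uncertainty = ifelse(.data$uncertainty_class == "low",
                                     "low", "high"),
                b_p = flip * .data$b_cm,
                level_p = flip * .data$perturbation_level,
                delta_p = flip * .data$delta_s_cm)
}

#' Subtract each subject's unperturbed baseline error
#'
#' Removes, per subject and pooled uncertainty class, the mean residual
#' error of the unperturbed (level 0) trials from every trial's residual
#' error. This centers the bias-vs-perturbation relation without
#' affecting its slope (regression on the same perturbation values is
#' shift-invariant).
#'
#' @param records A response tibble containing test-phase trials.
#' @return The tibble with columns added by [pool_sides()] plus
#'   `delta_adj` (baseline-subtracted, mirrored residual error).
#' @export
baseline_subtract <- function(records) {
  pooled <- pool_sides(records)
  base <- pooled |>
    dplyr::filter(.data$perturbation_level == 0) |>
    dplyr::group_by(.data$subject_id, .data$uncertainty) |>
    dplyr::summarise(baseline = mean(.data$delta_p), .groups = "drop")
  if (!all(unique(pooled$subject_id) %in% base$subject_id)) {
    abort("Some subjects have no unperturbed trials to define a baseline.",
          class = "comreach_invalid_parameter")
  }
  pooled |>
    dplyr::left_join(base, by = c("subject_id", "uncertainty")) |>
    dplyr::mutate(delta_adj = .data$delta_p - .data$baseline)
}

#' Uncorrected-fraction slopes per subject and uncertainty class
#'
#' Ordinary least-squares regression of the baseline-subtracted residual
#' error on the continuous perturbation size (pooled left/right by
#' mirroring), per subject and class. The slope measures the fraction of
#' the perturbation left uncorrected: 0 is full correction, 1 none.
#'
#' @param records A response tibble of test-phase trials.
#' @return A tibble `subject_id`, `uncertainty_class`, `slope`,
#'   `intercept`, `n_trials`.
#' @export
slope_regression <- function(records) {
  dat <- baseline_subtract(records)
  dat |>
    dplyr::group_by(.data$subject_id, uncertainty_class = .data$uncertainty) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$b_p) < 2) {
        abort("Degenerate design: need >= 2 distinct perturbation values.",
              class = "comreach_invalid_parameter")
      }
      fit <- lm(delta_adj ~ b_p, data = d)
      tibble(slope = coef(fit)[["b_p"]],
             intercept = coef(fit)[["(Intercept)"]],
             n_trials = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Per-class response summaries
#'
#' Subject-level summaries per pooled uncertainty class — response-error
#' SD (averaged over perturbation levels), mean score (recomputed from
#' the residual error with the scoring rule, so perturbed no-feedback
#' trials are included), and the balance rate (fraction of trials with a
#' nonzero score, i.e. within 1 cm) — followed by between-subject group
#' means and SEs. Scores are reported both over unperturbed trials only
#' and over all trials, since both aggregations are in common use.
#'
#' @param records A response tibble of test-phase trials.
#' @param config A [score_config()].
#' @return A list of class `condition_summary` with `per_subject` and
#'   `group` tibbles.
#' @export
condition_summaries <- function(records, config = score_config()) {
  pooled <- pool_sides(records)
  if (nrow(pooled) == 0) {
    abort("Empty records.", class = "comreach_invalid_parameter")
  }
  per_subject <- pooled |>
    dplyr::mutate(score_all = score_points(.data$delta_s_cm, config)) |>
    dplyr::group_by(.data$subject_id, .data$uncertainty) |>
    dplyr::summarise(
      sd_delta = mean(tapply(.data$delta_p, abs(.data$level_p), sd)),
      mean_score_all = mean(.data$score_all),
      mean_score_unperturbed =
        mean(.data$score_all[.data$perturbation_level == 0]),
      balance_rate = mean(.data$score_all >= 1),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  group <- per_subject |>
    tidyr::pivot_longer(c("sd_delta", "mean_score_all",
                          "mean_score_unperturbed", "balance_rate"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$uncertainty, .data$metric) |>
    dplyr::summarise(group_mean = mean(.data$value),
                     group_se = sd(.data$value) / sqrt(dplyr::n()),
                     n_subjects = dplyr::n(), .groups = "drop")
  structure(list(per_subject = per_subject, group = group),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary> group means +/- SE between subjects\n")
  print(x$group)
  invisible(x)
}

#' @export
tidy.condition_summary <- function(x, ...) x$group

#' Per-subject correction-strategy bias table
#'
#' Mean baseline-subtracted residual error per subject, strategy and
#' absolute perturbation level, where the `almost_full` strategy is read
#' off the low-uncertainty trials and the `partial` strategy off the
#' high-uncertainty trials. Input to [hypothetical_rescoring()].
#'
#' @param records A response tibble of test-phase trials.
#' @return A tibble `subject_id`, `strategy`, `level`, `bias_cm`.
#' @export
strategy_bias_table <- function(records) {
  baseline_subtract(records) |>
    dplyr::filter(.data$perturbation_level != 0) |>
    dplyr::group_by(.data$subject_id,
                    strategy = ifelse(.data$uncertainty == "low",
                                      "almost_full", "partial"),
                    level = abs(.data$perturbation_level)) |>
    dplyr::summarise(bias_cm = mean(.data$delta_adj), .groups = "drop")
}

#' Rescore baseline responses under hypothetical correction strategies
#'
#' Counterfactual: what would the unperturbed low-uncertainty score have
#' been had the subject corrected as sloppily (or as fully) as under a
#' given strategy? Each subject's unperturbed low-uncertainty responses
#' are shifted by the tabulated mean residual bias for that strategy and
#' perturbation level and rescored with the task's scoring rule.
#'
#' @param records A response tibble of test-phase trials.
#' @param bias_table A tibble from [strategy_bias_table()] (or the same
#'   shape); must cover every strategy/level pair requested.
#' @param config A [score_config()].
#' @return A list of class `rescoring` with `per_subject` and `group`
#'   tibbles (mean score per strategy and level, and the score change
#'   from baseline).
#' @export
hypothetical_rescoring <- function(records, bias_table = NULL,
                                   config = score_config()) {
  if (is.null(bias_table)) bias_table <- strategy_bias_table(records)
  need <- c("subject_id", "strategy", "level", "bias_cm")
  if (!all(need %in% names(bias_table))) {
    abort("`bias_table` must have columns subject_id, strategy, level, bias_cm.",
          class = "comreach_invalid_parameter")
  }
  if (any(!is.finite(bias_table$bias_cm))) {
    abort("`bias_table` contains missing bias entries.",
          class = "comreach_invalid_parameter")
  }
  baseline <- pool_sides(records) |>
    dplyr::filter(.data$uncertainty == "low", .data$perturbation_level == 0)
  per_subject <- bias_table |>
    dplyr::left_join(baseline, by = "subject_id",
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$subject_id, .data$strategy, .data$level) |>
    dplyr::summarise(
      mean_score = mean(score_points(.data$delta_s_cm + .data$bias_cm,
                                     config)),
      baseline_score = mean(score_points(.data$delta_s_cm, config)),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_score = .data$mean_score - .data$baseline_score)
  group <- per_subject |>
    dplyr::group_by(.data$strategy, .data$level) |>
    dplyr::summarise(
      group_score = mean(.data$mean_score),
      group_score_se = sd(.data$mean_score) / sqrt(dplyr::n()),
      group_delta = mean(.data$delta_score),
      group_delta_se = sd(.data$delta_score) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  structure(list(per_subject = per_subject, group = group),
            class = "rescoring")
}

#' @export
print.rescoring <- function(x, ...) {
  cat("<rescoring> hypothetical strategy scores (group mean +/- SE)\n")
  print(x$group)
  invisible(x)
}

#' @export
tidy.rescoring <- function(x, ...) x$group

#' Ideal-observer score benchmark
#'
#' Expected score of ideal observers (veridical mapping `dim_d = 2`, no
#' adjustment cost, no motor noise) sharing each subject's sensory noise,
#' per uncertainty class, aggregated over subjects with a bootstrap SD.
#'
#' @param sigma_rho Vector of per-subject sensory noise estimates.
#' @param n_sim Simulated trials per subject and class.
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples over subjects.
#' @return A tibble `trial_class`, `mean_score`, `boot_sd`, `n_subjects`.
#' @export
ideal_observer_benchmark <- function(sigma_rho, n_sim = 20000, seed = 1,
                                     n_boot = 1000) {
  stopifnot(length(sigma_rho) >= 1, all(sigma_rho > 0))
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, length(sigma_rho))
  per_subject <- purrr::map_dfr(seq_along(sigma_rho), function(i) {
    p <- ideal_observer_params(sigma_rho[i])
    dplyr::bind_rows(
      expected_score(p, "low", n_sim = n_sim, seed = child[i]),
      expected_score(p, "high", n_sim = n_sim, seed = child[i] + 1)
    ) |>
      dplyr::mutate(subject = i)
  })
  per_subject |>
    dplyr::group_by(.data$trial_class) |>
    dplyr::group_modify(function(d, key) {
      boot <- replicate(n_boot, mean(sample(d$mean_score, replace = TRUE)))
      tibble(mean_score = mean(d$mean_score), boot_sd = sd(boot),
             n_subjects = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Binned residual-error (bias) curve versus center-of-mass location
#'
#' Mean residual error as a function of the true center-of-mass location,
#' binned for visualization, separately per signed perturbation level.
#' Subject-level bin means are computed first; group means and SEs are
#' across subjects. Empty bins are absent from the output, not zero.
#'
#' @param records A response tibble of test-phase trials.
#' @param n_bins Number of equal-width bins over the occupied location
#'   range.
#' @return A tibble of class `comreach_bias_curve`:
#'   `perturbation_level`, `bin_mid`, `mean_bias`, `se_bias`,
#'   `n_subjects`, `n_trials`.
#' @export
bias_curve <- function(records, n_bins = 9) {
  rng <- range(records$s_true_cm)
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  mids <- (head(brk, -1) + brk[-1]) / 2
  out <- records |>
    dplyr::mutate(bin = cut(.data$s_true_cm, brk, labels = FALSE)) |>
    dplyr::group_by(.data$subject_id, .data$perturbation_level, .data$bin) |>
    dplyr::summarise(bias = mean(.data$delta_s_cm), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(.data$perturbation_level, .data$bin) |>
    dplyr::summarise(mean_bias = mean(.data$bias),
                     se_bias = sd(.data$bias) / sqrt(dplyr::n()),
                     n_subjects = dplyr::n(),
                     n_trials = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(bin_mid = mids[.data$bin], .after = "perturbation_level") |>
    dplyr::select(-"bin")
  class(out) <- c("comreach_bias_curve", class(out))
  out
}

#' Agreement between data and model-predicted slopes
#'
#' Pairs per-subject, per-class uncorrected-fraction slopes measured from
#' data with the slopes predicted by the fitted observer model, and
#' summarizes the agreement as the coefficient of determination about the
#' identity line: \eqn{R^2 = 1 - \sum(y - x)^2 / \sum(y - \bar y)^2}.
#'
#' @param data_slopes Tibble from [slope_regression()] on the data.
#' @param model_slopes Tibble with the same columns for the model
#'   predictions (e.g. from [predict_slopes()] per subject).
#' @return A list of class `slope_agreement` with `pairs` and
#'   `r_squared`.
#' @export
slope_agreement <- function(data_slopes, model_slopes) {
  pairs <- dplyr::inner_join(
    dplyr::select(data_slopes, "subject_id", "uncertainty_class",
                  data_slope = "slope"),
    dplyr::select(model_slopes, "subject_id", "uncertainty_class",
                  model_slope = "slope"),
    by = c("subject_id", "uncertainty_class")
  )
  if (nrow(pairs) < 3) {
    abort("slope_agreement() needs at least 3 paired slopes.",
          class = "comreach_invalid_parameter")
  }
  y <- pairs$data_slope
  x <- pairs$model_slope
  r2 <- 1 - sum((y - x)^2) / sum((y - mean(y))^2)
  structure(list(pairs = pairs, r_squared = r2), class = "slope_agreement")
}

#' @export
print.slope_agreement <- function(x, ...) {
  cat(sprintf("<slope_agreement> %d pairs, R^2 = %.3f\n",
              nrow(x$pairs), x$r_squared))
  invisible(x)
}

#' @export
glance.slope_agreement <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_pairs = nrow(x$pairs))
}
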