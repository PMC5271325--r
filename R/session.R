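#' Session configuration
#'
#' Stimulus, perturbation and session-composition parameters of the
#' center-of-mass reaching experiment: a 120-trial training session with
#' performance feedback, then a 576-trial test session with 192 standard
#' trials and 192 small (mean ±0.5 cm) and 192 large (mean ±1.5 cm)
#' cursor perturbations (SD 0.2 cm, truncated at 2.5 SD so the levels
#' never overlap). One third of trials show equal disks (low uncertainty);
#' otherwise the radius ratio is log-normal with mean log 1.5 and SD 0.1
#' in log space, the larger disk's side counterbalanced within blocks.
#'
#' @param n_training Training-session trial count.
#' @param n_test_standard,n_test_small,n_test_large Test-session trial
#'   counts by perturbation level.
#' @param perturbation_sd SD of the perturbation draw (cm).
#' @param perturbation_trunc Truncation, in SD units.
#' @param radius_log_mean,radius_log_sd Base-disk radius distribution
#'   (log cm).
#' @param ratio_log_mean,ratio_log_sd Radius-ratio distribution of
#'   unequal trials (log space).
#' @param p_equal Probability of an equal-disk trial.
#' @param jitter_half Half-range of the uniform horizontal display jitter
#'   (cm).
#' @param block_size Test-session counterbalancing block (trials).
#' @param geometry A [task_geometry()].
#' @param score A [score_config()].
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_training = 120, n_test_standard = 192,
                           n_test_small = 192, n_test_large = 192,
                           perturbation_sd = 0.2, perturbation_trunc = 2.5,
                           radius_log_mean = log(1), radius_log_sd = 0.1,
                           ratio_log_mean = log(1.5), ratio_log_sd = 0.1,
                           p_equal = 1 / 3, jitter_half = 3,
                           block_size = 36, geometry = task_geometry(),
                           score = score_config()) {
  stopifnot(n_training > 0, n_test_standard > 0, n_test_small > 0,
            n_test_large > 0, perturbation_sd > 0, perturbation_trunc > 0,
            p_equal >= 0, p_equal <= 1, block_size > 0)
  structure(
    list(n_training = n_training, n_test_standard = n_test_standard,
         n_test_small = n_test_small, n_test_large = n_test_large,
         perturbation_sd = perturbation_sd,
         perturbation_trunc = perturbation_trunc,
         radius_log_mean = radius_log_mean, radius_log_sd = radius_log_sd,
         ratio_log_mean = ratio_log_mean, ratio_log_sd = ratio_log_sd,
         p_equal = p_equal, jitter_half = jitter_half,
         block_size = block_size, geometry = geometry, score = score),
    class = "session_config"
  )
}

#' Sample stimuli from the task's generative model
#'
#' Draws disk-radius configurations: with probability `p_equal` the disks
#' are equal (log ratio 0, low uncertainty); otherwise the base radius is
#' multiplied by a log-normal ratio to form the larger disk, whose side is
#' random unless forced. The true center of mass is computed with the
#' veridical mapping (`dim_d = 2`).
#'
#' @param n Number of stimuli.
#' @param cfg A [session_config()].
#' @param uncertainty_class Optional vector recycling over
#'   `"low"`, `"high-left"`, `"high-right"` to force trial classes (used
#'   by [generate_session()] for counterbalancing).
#' @return A tibble with `r1_cm`, `r2_cm`, `rho`, `s_true_cm`,
#'   `jitter_cm`, `uncertainty_class`.
#' @export
sample_stimulus <- function(n, cfg = session_config(),
                            uncertainty_class = NULL) {
  if (is.null(uncertainty_class)) {
    equal <- runif(n) < cfg$p_equal
    side <- sample(c(-1, 1), n, replace = TRUE)
    uncertainty_class <- ifelse(equal, "low",
                                ifelse(side < 0, "high-left", "high-right"))
  } else {
    uncertainty_class <- rep(uncertainty_class, length.out = n)
  }
  stopifnot(all(uncertainty_class %in% c("low", "high-left", "high-right")))
  base <- exp(rnorm(n, cfg$radius_log_mean, cfg$radius_log_sd))
  ratio <- exp(rnorm(n, cfg$ratio_log_mean, cfg$ratio_log_sd))
  r1 <- base
  r2 <- base
  right <- uncertainty_class == "high-right"
  left <- uncertainty_class == "high-left"
  r2[right] <- base[right] * ratio[right]
  r1[left] <- base[left] * ratio[left]
  rho <- log(r2 / r1)
  tibble(
    r1_cm = r1, r2_cm = r2, rho = rho,
    s_true_cm = com_map(rho, 2, cfg$geometry),
    jitter_cm = runif(n, -cfg$jitter_half, cfg$jitter_half),
    uncertainty_class = uncertainty_class
  )
}

#' Sample perturbations at a given level
#'
#' Gaussian with mean `level` and SD `perturbation_sd`, truncated at
#' `perturbation_trunc` SDs (rejection sampling), so draws at level
#' ±0.5 and ±1.5 cm never overlap.
#'
#' @param level Mean perturbation in cm (e.g. 0.5, -1.5).
#' @param n Number of draws.
#' @param cfg A [session_config()].
#' @return Numeric vector of perturbations (cm).
#' @export
sample_perturbation <- function(level, n = 1, cfg = session_config()) {
  stopifnot(is.numeric(level), length(level) == 1, is.finite(level))
  lim <- cfg$perturbation_trunc * cfg$perturbation_sd
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 8, level, cfg$perturbation_sd)
    out <- c(out, draw[abs(draw - level) <= lim])
  }
  out[seq_len(n)]
}

# balanced class assignment for one block: n_eq equal trials, the rest
# split exactly half left / half right
balanced_classes <- function(n, p_equal) {
  n_eq <- round(n * p_equal)
  n_side <- n - n_eq
  stopifnot(n_side %% 2 == 0)
  sample(c(rep("low", n_eq),
           rep("high-left", n_side / 2), rep("high-right", n_side / 2)))
}

#' Generate one synthetic experimental session
#'
#' Assembles the trial list for one subject: a training phase (all
#' standard trials with feedback) and a test phase mixing standard,
#' small- and large-perturbation trials. Perturbation signs and the side
#' of the larger disk are counterbalanced exactly within blocks
#' (`block_size` trials in the test phase, 12-trial blocks in training),
#' and trial order is shuffled within each block. Feedback is shown on
#' every trial except perturbed test trials. Deterministic given the
#' RNG state (use `set.seed()` or the `seed` argument).
#'
#' @param cfg A [session_config()].
#' @param subject_id Subject label stored in the table.
#' @param seed Optional integer seed.
#' @return A trial-table tibble (one row per trial) with the columns of
#'   the canonical schema minus the response fields (see
#'   [write_trial_table()]).
#' @export
generate_session <- function(cfg = session_config(), subject_id = "S01",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_block <- function(n, levels, phase, block) {
    # levels: vector of signed mean perturbation levels for this block
    stopifnot(length(levels) == n)
    stim <- sample_stimulus(n, cfg, balanced_classes(n, cfg$p_equal))
    b <- numeric(n)
    for (lv in unique(levels[levels != 0])) {
      idx <- which(levels == lv)
      b[idx] <- sample_perturbation(lv, length(idx), cfg)
    }
    ord <- sample.int(n)
    dplyr::mutate(stim[ord, ],
                  phase = phase, block = block,
                  perturbation_level = levels[ord], b_cm = b[ord],
                  feedback = phase == "training" | levels[ord] == 0)
  }

  # training: standard feedback trials, 12-trial counterbalancing blocks
  tr_block_size <- 12
  stopifnot(cfg$n_training %% tr_block_size == 0)
  training <- purrr::map(seq_len(cfg$n_training / tr_block_size), function(i) {
    make_block(tr_block_size, rep(0, tr_block_size), "training", i)
  })

  # test: blocks of block_size with exact level/sign composition
  n_test <- cfg$n_test_standard + cfg$n_test_small + cfg$n_test_large
  n_blocks <- n_test / cfg$block_size
  stopifnot(n_blocks == round(n_blocks),
            cfg$n_test_standard %% n_blocks == 0,
            cfg$n_test_small %% (2 * n_blocks) == 0,
            cfg$n_test_large %% (2 * n_blocks) == 0)
  per_std <- cfg$n_test_standard / n_blocks
  per_sm <- cfg$n_test_small / (2 * n_blocks)
  per_lg <- cfg$n_test_large / (2 * n_blocks)
  test_levels <- c(rep(0, per_std), rep(0.5, per_sm), rep(-0.5, per_sm),
                   rep(1.5, per_lg), rep(-1.5, per_lg))
  test <- purrr::map(seq_len(n_blocks), function(i) {
    make_block(cfg$block_size, sample(test_levels), "test", i)
  })

  out <- dplyr::bind_rows(c(training, test))
  dplyr::mutate(out,
                subject_id = subject_id,
                trial_index = dplyr::row_number(),
                .before = 1) |>
    dplyr::select("subject_id", "phase", "block", "trial_index", "r1_cm",
                  "r2_cm", "rho", "s_true_cm", "jitter_cm",
                  "perturbation_level", "b_cm", "uncertainty_class",
                  "feedback")
}

#' Simulate observer responses for a session
#'
#' Runs the two-stage decision model on every trial: draw the internal
#' measurement \eqn{\rho_m \sim N(\rho, \sigma_\rho^2)}, compute the
#' preliminary endpoint, add the perturbation to get the arrival position
#' `r0`, compute the adjusted endpoint, and add motor noise. Scores are
#' recorded on feedback trials only (as experienced by the subject).
#'
#' @param session A trial table from [generate_session()].
#' @param params An [observer_params()], or for alternative observers see
#'   [simulate_responses_variant()].
#' @param seed Optional integer seed.
#' @param prior Observer prior over log ratios.
#' @param cfg A [session_config()] (for geometry and scoring).
#' @param engine `"compiled"` (default) or `"reference"` (pure R decision
#'   path; slow, used for cross-checking).
#' @return The session tibble with added columns `rho_m`, `s_pre_cm`,
#'   `r0_cm`, `s_star_cm`, `r_cm`, `delta_s_cm`, `score`.
#' @export
simulate_responses <- function(session, params, seed = NULL,
                               prior = prior_log_ratio(),
                               cfg = session_config(),
                               engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(session)
  rho_m <- rnorm(n, session$rho, params$sigma_rho)
  dec <- if (engine == "compiled") {
    decide_trials_cpp(rho_m, session$b_cm, params, cfg$geometry, prior)
  } else {
    purrr::map2_dfr(rho_m, session$b_cm, decide_endpoint, params = params,
                    geometry = cfg$geometry, prior = prior)
  }
  r <- dec$s_star +
    if (params$sigma_motor > 0) rnorm(n, 0, params$sigma_motor) else 0
  delta_s <- r - session$s_true_cm
  sc <- score_points(delta_s, cfg$score)
  dplyr::mutate(session,
                rho_m = rho_m, s_pre_cm = dec$s_pre, r0_cm = dec$r0,
                s_star_cm = dec$s_star, r_cm = r, delta_s_cm = delta_s,
                score = ifelse(session$feedback, sc, NA_real_))
}

#' Simulate a cohort of synthetic subjects
#'
#' Generates and simulates full sessions (training + test) for
#' `n_subjects` observers. `params` may be a single [observer_params()]
#' shared by all subjects or a list of per-subject parameter objects.
#'
#' @param params Observer parameters (single object or list).
#' @param n_subjects Number of subjects.
#' @param cfg A [session_config()].
#' @param seed Integer seed; per-subject child seeds are derived from it.
#' @param prior Observer prior over log ratios.
#' @return A single tibble with all subjects' trials.
#' @export
simulate_cohort <- function(params, n_subjects = 16, cfg = session_config(),
                            seed = 1, prior = prior_log_ratio()) {
  if (inherits(params, "observer_params")) {
    params <- rep(list(params), n_subjects)
  }
  stopifnot(length(params) == n_subjects)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, n_subjects)
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    id <- sprintf("S%02d", i)
    ses <- generate_session(cfg, subject_id = id, seed = child[i])
    simulate_responses(ses, params[[i]], prior = prior, cfg = cfg)
  })
}
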