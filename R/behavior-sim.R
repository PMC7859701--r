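#' Parameters for a simulated behavioural cohort
#'
#' Describes one genotype's cohort across the three cilia-dependent assays:
#' dye filling (number of dye-filled phasmid neurons, 0-4, drawn from a
#' 5-category distribution), roaming (grid squares entered, drawn from a
#' negative binomial so overdispersion relative to Poisson is allowed),
#' and osmotic avoidance (exponential escape hazard, right-censored at the
#' 10-minute observation limit).
#'
#' @param n_worms number of worms in the cohort.
#' @param dye_category_probs 5 probabilities over 0-4 filled neurons;
#'   must sum to 1 within 1e-9.
#' @param roaming_mean mean number of squares entered.
#' @param roaming_dispersion negative-binomial size parameter (larger =
#'   closer to Poisson).
#' @param escape_rate per-minute escape hazard (0 = no worm ever escapes).
#' @param censor_time_min observation limit in minutes (default 10).
#' @param n_trials number of independent trials the worms are split over
#'   (default 3, the usual replication of these assays).
#' @param genotype genotype label recorded in the cohort.
#' @param seed integer seed.
#' @return An object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_worms,
                                dye_category_probs = c(0, 0, 0, 0, 1),
                                roaming_mean = 50,
                                roaming_dispersion = 5,
                                escape_rate = 0,
                                censor_time_min = 10,
                                n_trials = 3L,
                                genotype = "sim",
                                seed = 1L) {
  check_that(n_worms >= 1, "n_worms must be at least 1")
  check_that(length(dye_category_probs) == 5 && all(dye_category_probs >= 0),
             "dye_category_probs must be 5 nonnegative probabilities")
  if (abs(sum(dye_category_probs) - 1) > 1e-9)
    stop("dye_category_probs must sum to 1", call. = FALSE)
  check_that(roaming_mean >= 0, "roaming_mean must be nonnegative")
  check_that(roaming_dispersion > 0, "roaming_dispersion must be positive")
  check_that(escape_rate >= 0, "escape_rate must be nonnegative")
  check_that(censor_time_min > 0, "censor_time_min must be positive")
  check_that(n_trials >= 1, "n_trials must be at least 1")
  structure(list(n_worms = as.integer(n_worms),
                 dye_category_probs = dye_category_probs,
                 roaming_mean = roaming_mean,
                 roaming_dispersion = roaming_dispersion,
                 escape_rate = escape_rate,
                 censor_time_min = censor_time_min,
                 n_trials = as.integer(n_trials),
                 genotype = as.character(genotype),
                 seed = as.integer(seed)),
            class = "behavior_sim_params")
}

#' Simulate a behavioural assay cohort
#'
#' Draws per-worm records for the dye-filling, roaming and osmotic
#' avoidance assays from a [behavior_sim_params] description; the result
#' is seed-reproducible.
#'
#' @param params a [behavior_sim_params].
#' @return A `data.frame` with columns `worm_id`, `genotype`, `trial_id`,
#'   `dye_filled_count`, `squares_entered`, `escape_time_min`, `censored`.
#' @export
simulate_behavior_cohort <- function(params) {
  check_that(inherits(params, "behavior_sim_params"),
             "params must be a behavior_sim_params object")
  set.seed(params$seed)
  n <- params$n_worms
  dye <- sample(0:4, n, replace = TRUE, prob = params$dye_category_probs)
  squares <- rnbinom(n, size = params$roaming_dispersion,
                     mu = params$roaming_mean)
  if (params$escape_rate > 0) {
    t_esc <- rexp(n, rate = params$escape_rate)
  } else {
    t_esc <- rep(Inf, n)
  }
  censored <- t_esc >= params$censor_time_min
  t_obs <- pmin(t_esc, params$censor_time_min)
  data.frame(
    worm_id = sprintf("%s_w%03d", params$genotype, seq_len(n)),
    genotype = params$genotype,
    trial_id = rep_len(seq_len(params$n_trials), n),
    dye_filled_count = dye,
    squares_entered = squares,
    escape_time_min = t_obs,
    censored = censored,
    stringsAsFactors = FALSE)
}
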