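#' Observer configuration
#'
#' Parameters of the simulated observer. The ideal observer (all defaults)
#' is a perfect integrator: the intermittent choice is the sign of the mean
#' of the first six samples, and the estimate is the arithmetic mean of all
#' twelve samples. Deviations from ideality:
#'
#' * `decision_noise`: with this probability the intermittent choice is
#'   replaced by a fair coin flip ("fraction of trials with random
#'   judgments").
#' * `estimation_noise_sd`: Gaussian noise added to the estimate, degrees.
#' * `consistency_gain`: length-12 multiplicative weight applied, per sample
#'   position, to samples whose sign is *inconsistent* with the trial's
#'   category event (choice or cue). 1 everywhere = unbiased; values < 1 in
#'   the second interval produce a confirmation-bias-like down-weighting.
#'
#' @param decision_noise probability in `[0, 1]`.
#' @param estimation_noise_sd degrees, `>= 0`.
#' @param consistency_gain numeric vector of length 12 (or
#'   `n_samples_per_trial`), all `>= 0`.
#' @return A list of class `observer_config`.
#' @export
observer_config <- function(decision_noise = 0,
                            estimation_noise_sd = 0,
                            consistency_gain = rep(1, 12)) {
  assert_that(decision_noise >= 0 && decision_noise <= 1,
              "decision_noise must be in [0, 1]")
  assert_that(estimation_noise_sd >= 0, "estimation_noise_sd must be >= 0")
  assert_that(all(consistency_gain >= 0), "consistency gains must be >= 0")
  structure(list(decision_noise = decision_noise,
                 estimation_noise_sd = estimation_noise_sd,
                 consistency_gain = consistency_gain),
            class = "observer_config")
}

#' Simulate observer behavior on task trials
#'
#' Fills in the intermittent choice (Choice condition), correctness, and the
#' continuous estimate for every trial. The estimate is a linear readout of
#' the samples: `sum(w_i * s_i) / n_samples`, with weight 1 for samples
#' consistent with the category event and `consistency_gain[i]` for
#' inconsistent samples, plus Gaussian estimation noise. With all gains at 1
#' and zero noise this is exactly the perfect-integrator mean of the twelve
#' samples.
#'
#' Samples equal to exactly 0 degrees are labeled consistent with
#' probability 1/2 (a measure-zero event for continuous draws).
#'
#' @param trials a `trial_table`; Cue rows must already carry cues.
#' @param obs an [observer_config()].
#' @param seed integer seed.
#' @return The trial table with `category_event`, `event_correct` and
#'   `estimate` populated.
#' @export
simulate_observer <- function(trials, obs = observer_config(), seed = NULL) {
  if (!inherits(obs, "observer_config")) stop_config("obs must be an observer_config")
  smp <- sample_matrix(trials)
  n_smp <- ncol(smp)
  gain <- rep_len(obs$consistency_gain, n_smp)
  first_half <- seq_len(n_smp %/% 2)
  with_seed(seed, {
    ## --- intermittent choice (Choice condition) ---
    idx <- which(trials$condition == "Choice")
    if (length(idx) > 0L) {
      m6 <- rowMeans(smp[idx, first_half, drop = FALSE])
      choice <- sign_lr(m6)
      und <- is.na(choice) # exact zero mean of first interval
      choice[und] <- sample(c("left", "right"), sum(und), replace = TRUE)
      rand <- runif(length(idx)) < obs$decision_noise
      choice[rand] <- sample(c("left", "right"), sum(rand), replace = TRUE)
      trials$category_event[idx] <- choice
      corr <- choice == sign_lr(trials$mu[idx])
      zero <- trials$mu[idx] == 0
      corr[zero] <- runif(sum(zero)) < 0.5
      trials$event_correct[idx] <- corr
    }
    if (anyNA(trials$category_event)) {
      stop_config("trials without category event: assign cues before simulating")
    }
    ## --- estimate: consistency-weighted mean of all samples ---
    cons <- label_consistency(trials, seed = NULL) # uses current stream for s == 0
    w <- matrix(1, nrow(trials), n_smp)
    w[!cons] <- matrix(gain, nrow(trials), n_smp, byrow = TRUE)[!cons]
    est <- rowSums(w * smp) / n_smp
    if (obs$estimation_noise_sd > 0) {
      est <- est + rnorm(nrow(trials), 0, obs$estimation_noise_sd)
    }
    trials$estimate <- est
  })
  trials
}

#' Label each sample's consistency with the trial's category event
#'
#' A sample is consistent when its sign matches the sign of the category
#' event (choice or cue): for first-interval positions this is consistency
#' with the *upcoming* event, for second-interval positions with the
#' *preceding* event. Samples at exactly 0 degrees are assigned consistent
#' with probability 1/2.
#'
#' @param trials a `trial_table` with category events.
#' @param seed integer seed (only used for zero samples).
#' @return Logical matrix, trials by sample position; `TRUE` = consistent.
#' @export
label_consistency <- function(trials, seed = NULL) {
  if (anyNA(trials$category_event)) {
    stop_config("all trials must carry a category event")
  }
  smp <- sample_matrix(trials)
  ev <- ifelse(trials$category_event == "right", 1, -1)
  with_seed(seed, {
    cons <- sweep(sign(smp), 1, ev, `*`) > 0
    zero <- smp == 0
    if (any(zero)) cons[zero] <- runif(sum(zero)) < 0.5
    dimnames(cons) <- dimnames(smp)
    cons
  })
}

#' Calibrate decision noise to a target choice accuracy
#'
#' Finds, by bisection on simulated accuracy, the `decision_noise` level at
#' which the observer's fraction of correct category events within a trial
#' subset (typically the near-zero-mean trials) matches a target. Used to
#' match simulated observers to an empirical accuracy before consistency
#' analyses.
#'
#' @param trials a `trial_table` (Choice condition rows are used).
#' @param target_accuracy fraction correct to match.
#' @param subset optional logical/integer index of trials over which
#'   accuracy is evaluated (after simulation); default: near-zero trials.
#' @param bound near-zero bound in degrees used for the default subset.
#' @param tol accuracy tolerance of the bisection.
#' @param seed integer seed (the same seed is used at every probe so the
#'   simulated accuracy is monotone in the noise level).
#' @return The calibrated `decision_noise` value.
#' @export
calibrate_decision_noise <- function(trials, target_accuracy,
                                     subset = NULL, bound = 4,
                                     tol = 0.002, seed = 1L) {
  choice_rows <- trials$condition == "Choice"
  assert_that(any(choice_rows), "no Choice-condition trials to calibrate on")
  acc_at <- function(p) {
    sim <- simulate_observer(trials, observer_config(decision_noise = p),
                             seed = seed)
    keep <- if (is.null(subset)) abs(sim$mu) <= bound else subset
    mean(sim$event_correct[choice_rows & keep])
  }
  lo <- 0; hi <- 1
  a_lo <- acc_at(lo); a_hi <- acc_at(hi)
  if (target_accuracy >= a_lo) return(0)
  if (target_accuracy <= a_hi) return(1)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    a <- acc_at(mid)
    if (abs(a - target_accuracy) < tol) return(mid)
    if (a > target_accuracy) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
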