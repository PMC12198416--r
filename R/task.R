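#' Task configuration
#'
#' Parameters of the sequential evidence-estimation task. Per trial, twelve
#' evidence samples (angular positions in degrees, positive = right of the
#' vertical reference) are drawn from a Gaussian around a hidden generative
#' mean with fixed standard deviation, truncated to a band around the mean.
#' Generative means are drawn uniformly from a symmetric grid. Halfway
#' through the sequence the observer either reports a categorical choice
#' (Choice condition) or is shown a cue of fixed validity (Cue condition).
#'
#' @param n_samples_per_trial samples per trial (default 12).
#' @param generative_sd Gaussian SD of samples around the mean, degrees
#'   (default 20).
#' @param mean_grid grid of generative means, degrees; must be symmetric
#'   about 0 (default -14..14 in 1 degree steps).
#' @param truncation samples are constrained to `mu +/- truncation` degrees
#'   by rejection sampling (default 40).
#' @param cue_validity probability that the cue matches the true source
#'   category (default 0.75).
#' @param trials_per_block,blocks_per_session,sessions_per_condition session
#'   structure (defaults 58, 8, 2: 928 trials per condition).
#' @param rng_seed integer seed for the generator.
#' @return A list of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' trials <- generate_trials(cfg)
#' table(trials$condition)
task_config <- function(n_samples_per_trial = 12L,
                        generative_sd = 20,
                        mean_grid = seq(-14, 14, by = 1),
                        truncation = 40,
                        cue_validity = 0.75,
                        trials_per_block = 58L,
                        blocks_per_session = 8L,
                        sessions_per_condition = 2L,
                        rng_seed = 1L) {
  assert_that(n_samples_per_trial >= 1, "n_samples_per_trial must be >= 1")
  assert_that(generative_sd > 0, "generative_sd must be positive")
  assert_that(truncation > 0, "truncation must be positive")
  assert_that(cue_validity >= 0 && cue_validity <= 1,
              "cue_validity must be in [0, 1]")
  assert_that(length(mean_grid) >= 1 &&
                isTRUE(all.equal(sort(mean_grid), sort(-mean_grid))),
              "mean_grid must be symmetric about 0")
  assert_that(trials_per_block >= 1 && blocks_per_session >= 1 &&
                sessions_per_condition >= 1, "session structure must be positive")
  structure(list(
    n_samples_per_trial = as.integer(n_samples_per_trial),
    generative_sd = generative_sd,
    mean_grid = mean_grid,
    truncation = truncation,
    cue_validity = cue_validity,
    trials_per_block = as.integer(trials_per_block),
    blocks_per_session = as.integer(blocks_per_session),
    sessions_per_condition = as.integer(sessions_per_condition),
    rng_seed = as.integer(rng_seed)
  ), class = "task_config")
}

#' Draw evidence samples around a generative mean
#'
#' Gaussian draws with SD `sd`, redrawn (rejection sampling, not clipping)
#' until they fall within `mu +/- truncation`. Rejection avoids the atoms at
#' the band edges that clipping would create. `truncation = Inf` gives the
#' raw pre-truncation distribution.
#'
#' @param n number of samples.
#' @param mu generative mean(s), degrees (scalar or length `n`).
#' @param sd Gaussian SD, degrees.
#' @param truncation half-width of the allowed band around `mu`, degrees.
#' @return Numeric vector of `n` sample angles.
#' @export
draw_evidence_samples <- function(n, mu, sd = 20, truncation = 40) {
  mu <- rep_len(mu, n)
  s <- rnorm(n, mu, sd)
  if (is.finite(truncation)) {
    bad <- which(abs(s - mu) > truncation)
    while (length(bad) > 0L) {
      s[bad] <- rnorm(length(bad), mu[bad], sd)
      bad <- bad[abs(s[bad] - mu[bad]) > truncation]
    }
  }
  s
}

#' Generate a table of task trials
#'
#' Draws the generative mean of each trial uniformly from the configured
#' grid and the evidence samples by truncated Gaussian sampling, organised
#' into sessions and blocks. Cue-condition trials receive a cue category of
#' the configured validity (see [assign_cues()]); Choice-condition trials
#' have no category event until an observer is simulated
#' ([simulate_observer()]).
#'
#' @param cfg a [task_config()].
#' @param conditions which task conditions to generate.
#' @return A `trial_table`: a data frame with one row per trial, columns
#'   `trial_id`, `condition`, `session`, `block`, `mu`,
#'   `sample_1`..`sample_12`, `category_event`, `event_correct`, `estimate`,
#'   and the configuration in `attr(, "task_config")`.
#' @export
generate_trials <- function(cfg = task_config(),
                            conditions = c("Choice", "Cue")) {
  if (!inherits(cfg, "task_config")) stop_config("cfg must be a task_config")
  conditions <- match.arg(conditions, c("Choice", "Cue"), several.ok = TRUE)
  n_per <- cfg$sessions_per_condition * cfg$blocks_per_session *
    cfg$trials_per_block
  out <- list()
  for (cond in conditions) {
    tab <- with_seed(child_seed(cfg$rng_seed, paste0("trials_", cond)), {
      mu <- sample(cfg$mean_grid, n_per, replace = TRUE)
      smp <- matrix(
        draw_evidence_samples(n_per * cfg$n_samples_per_trial,
                              rep(mu, cfg$n_samples_per_trial),
                              cfg$generative_sd, cfg$truncation),
        nrow = n_per)
      colnames(smp) <- paste0("sample_", seq_len(cfg$n_samples_per_trial))
      data.frame(
        condition = cond,
        session = rep(seq_len(cfg$sessions_per_condition),
                      each = cfg$blocks_per_session * cfg$trials_per_block),
        block = rep(rep(seq_len(cfg$blocks_per_session),
                        each = cfg$trials_per_block),
                    times = cfg$sessions_per_condition),
        mu = mu, smp,
        category_event = NA_character_,
        event_correct = NA,
        estimate = NA_real_,
        stringsAsFactors = FALSE)
    })
    out[[cond]] <- tab
  }
  trials <- do.call(rbind, out)
  trials <- cbind(trial_id = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  class(trials) <- c("trial_table", "data.frame")
  attr(trials, "task_config") <- cfg
  if ("Cue" %in% conditions) {
    trials <- assign_cues(trials, validity = cfg$cue_validity,
                          seed = child_seed(cfg$rng_seed, "cues"))
  }
  trials
}

#' Assign cue categories to Cue-condition trials
#'
#' The cue matches the sign of the generative mean with probability
#' `validity`; on zero-mean trials the cue category is drawn uniformly at
#' random (mirroring the task's random-correctness rule for zero means).
#'
#' @param trials a `trial_table`.
#' @param validity cue validity in `[0, 1]`.
#' @param seed integer seed.
#' @return The trial table with `category_event` and `event_correct` filled
#'   in for Cue-condition rows.
#' @export
assign_cues <- function(trials, validity = 0.75, seed = NULL) {
  assert_that(validity >= 0 && validity <= 1, "validity must be in [0, 1]")
  idx <- which(trials$condition == "Cue")
  if (length(idx) == 0L) return(trials)
  with_seed(seed, {
    mu <- trials$mu[idx]
    src <- sign_lr(mu)
    zero <- is.na(src)
    src[zero] <- sample(c("left", "right"), sum(zero), replace = TRUE)
    valid <- runif(length(idx)) < validity
    flip <- c(left = "right", right = "left")
    cue <- ifelse(valid, src, flip[src])
    trials$category_event[idx] <- cue
    # correctness relative to true source; random for zero means
    corr <- cue == sign_lr(mu)
    corr[zero] <- runif(sum(zero)) < 0.5
    trials$event_correct[idx] <- corr
  })
  trials
}

#' Extract the samples of a trial table as a matrix
#'
#' @param trials a `trial_table`.
#' @return Numeric matrix, trials by sample position.
#' @export
sample_matrix <- function(trials) {
  cols <- grep("^sample_", names(trials), value = TRUE)
  cols <- cols[order(as.integer(sub("^sample_", "", cols)))]
  as.matrix(trials[, cols, drop = FALSE])
}

#' @export
print.trial_table <- function(x, ...) {
  cfg <- attr(x, "task_config")
  cat(sprintf("Trial table: %d trials (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$condition)),
                            as.integer(table(x$condition))), collapse = ", ")))
  if (!is.null(cfg)) {
    cat(sprintf("  %d samples/trial, SD %g deg, truncation +/- %g deg, grid |mu| <= %g\n",
                cfg$n_samples_per_trial, cfg$generative_sd, cfg$truncation,
                max(abs(cfg$mean_grid))))
  }
  cat(sprintf("  estimates present: %d, category events: %d\n",
              sum(is.finite(x$estimate)), sum(!is.na(x$category_event))))
  invisible(x)
}
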