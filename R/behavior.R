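#' Select near-zero-mean trials
#'
#' Consistency analyses are restricted to trials whose generative mean is
#' close to the category boundary, to isolate stochastic evidence
#' fluctuations from the systematic trial-to-trial variation of the mean
#' (which correlates evidence, category event, and estimate and would
#' otherwise produce spurious consistency effects). The -4..+4 degree range
#' is the smallest that retains enough trials for the intersection
#' information computations.
#'
#' @param trials a `trial_table`.
#' @param bound inclusive bound on `|mu|`, degrees (default 4).
#' @return The subset of trials with `|mu| <= bound`.
#' @export
select_near_zero <- function(trials, bound = 4) {
  out <- trials[abs(trials$mu) <= bound, , drop = FALSE]
  class(out) <- class(trials)
  attr(out, "task_config") <- attr(trials, "task_config")
  out
}

# measure factory: bias-corrected I(S;E) on equipopulated bins
mi_se_measure <- function(n_bins = 3L, n_shuffles = 100L) {
  function(vars, seed = NULL) {
    s <- equipopulated_bin(vars$s, n_bins)
    e <- equipopulated_bin(vars$e, n_bins)
    bias_corrected(function(v) mi_codes(v$s, v$e),
                   list(s = s, e = e), "s", n_shuffles = n_shuffles,
                   seed = seed)
  }
}

# +1 for 'right' category events, -1 for 'left'
#
# Consistency-split information measures are computed in the event-aligned
# frame (samples, estimates and activity multiplied by the event sign).
# Without this, the coupling of both variables to the categorical event
# produces large spurious consistency effects even for a noise-free unbiased
# integrator; in the aligned frame the ideal observer shows none.
event_sign <- function(trials) {
  if (anyNA(trials$category_event)) {
    stop_config("all trials must carry a category event")
  }
  ifelse(trials$category_event == "right", 1, -1)
}

#' Mutual-information psychophysical kernel
#'
#' Quantifies the weight of each evidence sample on the final estimation
#' report as the bias-corrected mutual information I(S;E) between the sample
#' value at each sequence position and the estimate. With
#' `split = "consistency"` the kernel is computed separately for samples
#' consistent versus inconsistent with the trial's category event,
#' restricted to near-zero-mean trials, with trial counts matched between
#' the two splits by random subsampling, and with samples and estimates
#' expressed in the event-aligned frame (multiplied by the event sign) so
#' that the shared coupling of both variables to the categorical event does
#' not masquerade as a consistency effect.
#'
#' @param trials a `trial_table` with estimates (and category events if
#'   splitting by consistency).
#' @param split `"all"` or `"consistency"`.
#' @param n_bins bins for the equipopulated discretization (default 3).
#' @param n_shuffles shuffles for the bias correction (default 100).
#' @param n_subsamples subsample draws for trial matching (default 5).
#' @param min_trials minimum trials per split (default 81).
#' @param bound near-zero bound in degrees used for the consistency split.
#' @param seed integer seed.
#' @return A `kernel_profile` data frame: one row per sample position (and
#'   consistency label), with corrected/raw information and trial counts.
#' @export
psychophysical_kernel_mi <- function(trials, split = c("all", "consistency"),
                                     n_bins = 3L, n_shuffles = 100L,
                                     n_subsamples = 5L, min_trials = 81L,
                                     bound = 4, seed = NULL) {
  split <- match.arg(split)
  measure <- mi_se_measure(n_bins, n_shuffles)
  smp <- sample_matrix(trials)
  rows <- list()
  if (split == "all") {
    for (i in seq_len(ncol(smp))) {
      res <- measure(list(s = smp[, i], e = trials$estimate),
                     child_seed(seed %||% 0L, "kernel", i))
      rows[[length(rows) + 1L]] <- kernel_row(i, "all", res)
    }
  } else {
    nz <- select_near_zero(trials, bound)
    cons <- label_consistency(nz, seed = child_seed(seed %||% 0L, "conslab"))
    ev <- event_sign(nz)
    smp <- sample_matrix(nz) * ev      # event-aligned frame
    est <- nz$estimate * ev
    for (i in seq_len(ncol(smp))) {
      ic <- cons[, i]
      cmp <- matched_trial_compare(
        measure,
        vars_a = list(s = smp[ic, i], e = est[ic]),
        vars_b = list(s = smp[!ic, i], e = est[!ic]),
        n_subsamples = n_subsamples, min_trials = min_trials,
        seed = child_seed(seed %||% 0L, "kernel_split", i))
      rows[[length(rows) + 1L]] <- kernel_row(i, "consistent", cmp$a)
      rows[[length(rows) + 1L]] <- kernel_row(i, "inconsistent", cmp$b)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kernel_profile", "data.frame")
  attr(out, "measure") <- "I(S;E)"
  out
}

kernel_row <- function(position, label, res) {
  data.frame(position = position, label = label,
             value = res$value_corrected, value_raw = res$value_raw,
             shuffle_mean = res$shuffle_mean,
             n_trials = res$n_trials_used, stringsAsFactors = FALSE)
}

#' Regression psychophysical kernel
#'
#' Linear-regression version of the kernel: per sample position, the
#' estimate is regressed on the sample value (univariate), and the absolute
#' slope quantifies the sample's weight. Optionally split by consistency on
#' near-zero trials.
#'
#' @inheritParams psychophysical_kernel_mi
#' @return A `kernel_profile` data frame with columns `position`, `label`,
#'   `beta` (signed slope) and `value` (absolute slope).
#' @export
psychophysical_kernel_regression <- function(trials,
                                             split = c("all", "consistency"),
                                             bound = 4, seed = NULL) {
  split <- match.arg(split)
  fit_beta <- function(s, e) {
    if (length(s) < 3 || var(s) == 0 || var(e) == 0) return(0)
    unname(coef(lm(e ~ s))[2])
  }
  rows <- list()
  if (split == "all") {
    smp <- sample_matrix(trials)
    for (i in seq_len(ncol(smp))) {
      b <- fit_beta(smp[, i], trials$estimate)
      rows[[length(rows) + 1L]] <-
        data.frame(position = i, label = "all", beta = b, value = abs(b),
                   n_trials = nrow(smp))
    }
  } else {
    nz <- select_near_zero(trials, bound)
    cons <- label_consistency(nz, seed = child_seed(seed %||% 0L, "conslab"))
    ev <- event_sign(nz)
    smp <- sample_matrix(nz) * ev
    est <- nz$estimate * ev
    for (i in seq_len(ncol(smp))) {
      for (lab in c("consistent", "inconsistent")) {
        ic <- if (lab == "consistent") cons[, i] else !cons[, i]
        b <- fit_beta(smp[ic, i], est[ic])
        rows[[length(rows) + 1L]] <-
          data.frame(position = i, label = lab, beta = b, value = abs(b),
                     n_trials = sum(ic))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kernel_profile", "data.frame")
  attr(out, "measure") <- "|beta|"
  out
}

#' @export
print.kernel_profile <- function(x, ...) {
  cat(sprintf("Psychophysical kernel (%s), %d positions\n",
              attr(x, "measure") %||% "?", length(unique(x$position))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Characterize the distribution of estimation reports
#'
#' Estimates are z-scored within participant (and condition), pooled, and
#' tested for deviation from unimodality with the dip statistic (Monte Carlo
#' p-value against the uniform null). If the trial table has no
#' `participant` column, all trials form one participant.
#'
#' @param trials a `trial_table` with estimates.
#' @param n_mc Monte Carlo replicates for the dip p-value.
#' @param seed integer seed.
#' @return List with `pooled` (dip, p_value, z-scored values) and
#'   `per_participant` (data frame of dip and p per participant).
#' @export
estimation_distribution_stats <- function(trials, n_mc = 500L, seed = 1L) {
  part <- trials$participant %||% rep(1L, nrow(trials))
  key <- interaction(part, trials$condition, drop = TRUE)
  z <- unsplit(lapply(split(trials$estimate, key),
                      function(v) (v - mean(v)) / max(sd(v), 1e-12)), key)
  per <- do.call(rbind, lapply(unique(part), function(p) {
    dt <- dip_test(z[part == p], n_mc = n_mc,
                   seed = child_seed(seed, "dip_part", as.integer(p)))
    data.frame(participant = p, dip = dt$statistic, p_value = dt$p_value)
  }))
  pooled <- dip_test(z, n_mc = n_mc, seed = child_seed(seed, "dip_pooled"))
  list(pooled = list(dip = pooled$statistic, p_value = pooled$p_value,
                     z_scored = z),
       per_participant = per)
}

#' Dip test of unimodality
#'
#' Computes the dip statistic (sup-norm distance of the empirical cdf to the
#' nearest unimodal cdf, via convex-minorant / concave-majorant envelope
#' fits over candidate modes) and a Monte Carlo p-value against samples of
#' the same size from the uniform distribution, the least favorable unimodal
#' null.
#'
#' @param x numeric vector.
#' @param n_mc Monte Carlo replicates (default 500).
#' @param seed integer seed.
#' @return List with `statistic`, `p_value`, `n_mc`.
#' @export
dip_test <- function(x, n_mc = 500L, seed = NULL) {
  x <- sort(x[is.finite(x)])
  d <- dip_stat_cpp(x)
  null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) dip_stat_cpp(sort(runif(length(x)))),
           numeric(1))
  })
  list(statistic = d, p_value = (1 + sum(null >= d)) / (n_mc + 1), n_mc = n_mc)
}

#' Category-conditioned estimation bias by evidence strength
#'
#' On near-zero trials, the mean estimate is computed separately for trials
#' with 'right' versus 'left' category events, within equipopulated bins of
#' category-evidence strength (the absolute mean of the first-interval
#' samples, binned on the pooled distribution). The right-minus-left
#' difference per bin quantifies how strongly the categorical event biased
#' the final estimate; its interaction with condition is testable with
#' [anova_interaction()].
#'
#' @param trials a `trial_table` with estimates and category events.
#' @param strength_bins number of evidence-strength bins (default 3).
#' @param bound near-zero bound, degrees.
#' @return Data frame with condition, strength bin, per-category mean
#'   estimates, their difference, and trial counts.
#' @export
category_conditioned_bias <- function(trials, strength_bins = 3L, bound = 4) {
  nz <- select_near_zero(trials, bound)
  smp <- sample_matrix(nz)
  strength <- abs(rowMeans(smp[, seq_len(ncol(smp) %/% 2), drop = FALSE]))
  sbin <- equipopulated_bin(strength, strength_bins)$codes
  rows <- list()
  for (cond in unique(nz$condition)) {
    for (b in seq_len(strength_bins)) {
      idx <- nz$condition == cond & sbin == b
      mr <- mean(nz$estimate[idx & nz$category_event == "right"])
      ml <- mean(nz$estimate[idx & nz$category_event == "left"])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, strength_bin = b, mean_right = mr, mean_left = ml,
        diff = mr - ml, n_trials = sum(idx))
    }
  }
  do.call(rbind, rows)
}

#' Psychometric function of the intermittent choice
#'
#' Fits a cumulative Gaussian with a symmetric lapse rate to the probability
#' of a 'right' choice as a function of the mean of the first-interval
#' samples: `P(right) = lapse + (1 - 2 lapse) * Phi((x - bias) / sigma)`.
#' Maximum likelihood via [stats::optim()]; `sigma` is bounded below so a
#' noiseless step response yields a finite (boundary) slope.
#'
#' @param trials a `trial_table` with Choice-condition category events.
#' @param min_sigma lower bound on sigma, degrees.
#' @return List with `bias`, `sigma`, `slope` (`= 1/sigma`), `lapse`, and
#'   the negative log-likelihood `nll`.
#' @export
psychometric_fit <- function(trials, min_sigma = 1e-2) {
  ch <- trials[trials$condition == "Choice" & !is.na(trials$category_event), ]
  assert_that(nrow(ch) > 10, "need Choice trials with recorded choices")
  smp <- sample_matrix(ch)
  x <- rowMeans(smp[, seq_len(ncol(smp) %/% 2), drop = FALSE])
  y <- as.integer(ch$category_event == "right")
  nll <- function(par) {
    bias <- par[1]; sigma <- min_sigma + exp(par[2])
    lapse <- 0.5 / (1 + exp(-par[3])) # lapse in (0, 0.5)
    p <- lapse + (1 - 2 * lapse) * pnorm((x - bias) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  fit <- optim(c(0, log(max(sd(x), 1)), -4), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  sigma <- min_sigma + exp(fit$par[2])
  list(bias = fit$par[1], sigma = sigma, slope = 1 / sigma,
       lapse = 0.5 / (1 + exp(-fit$par[3])), nll = fit$value)
}
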