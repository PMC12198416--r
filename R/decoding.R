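#' Cross-validated linear decoding of component activity
#'
#' For each principal component (and timepoint, unless a window is given),
#' a univariate linear regression predicting the stimulus sample from the
#' component activity is fitted on the training folds of a k-fold partition
#' and evaluated on the held-out fold. Decoding accuracy is the correlation
#' between the decoder prediction and the actual stimulus in the held-out
#' data; the linear analog of intersection information is the correlation
#' between the decoder prediction and the behavioral estimate on the same
#' held-out data. Fold-wise correlations are averaged across folds
#' (simple mean).
#'
#' @param tensor a `neural_tensor`.
#' @param s per-epoch stimulus values (decoder target; default
#'   `tensor$epochs$s`).
#' @param e optional per-epoch estimate values, for the prediction-behavior
#'   correlation.
#' @param k number of folds (default 10).
#' @param window if non-`NULL`, activity is window-averaged first and a
#'   single set of correlations per component is returned.
#' @param stratify optional factor (e.g. consistency labels); folds are
#'   formed within its levels so each fold contains all classes.
#' @param seed integer seed for the fold assignment.
#' @return A `decoding_result`: matrices `corr_s` and `corr_e`
#'   (`component x time`, single column if windowed), fold assignments, and
#'   window-averaged absolute correlations `abs_corr_s` / `abs_corr_e`.
#' @export
cv_decode <- function(tensor, s = NULL, e = NULL, k = 10L, window = NULL,
                      stratify = NULL, seed = NULL) {
  s <- s %||% tensor$epochs$s
  n <- dim(tensor$activity)[1]
  assert_that(length(s) == n, "length of s must match the number of epochs")
  if (n < k) stop_config("fewer trials (", n, ") than folds (", k, ")")
  folds <- with_seed(seed, {
    f <- integer(n)
    groups <- if (is.null(stratify)) list(seq_len(n)) else
      split(seq_len(n), stratify)
    for (g in groups) f[sample(g)] <- rep_len(seq_len(k), length(g))
    f
  })
  act <- if (is.null(window)) tensor$activity else {
    wa <- window_activity(tensor, window)
    array(wa, dim = c(n, ncol(wa), 1L))
  }
  n_comp <- dim(act)[2]; n_time <- dim(act)[3]
  corr_s <- matrix(NA_real_, n_comp, n_time)
  corr_e <- if (!is.null(e)) matrix(NA_real_, n_comp, n_time)
  for (kc in seq_len(n_comp)) {
    for (ti in seq_len(n_time)) {
      r <- act[, kc, ti]
      cs <- ce <- numeric(k)
      for (f in seq_len(k)) {
        test <- folds == f
        b <- coef(lm(s[!test] ~ r[!test]))
        pred <- b[1] + b[2] * r[test]
        cs[f] <- safe_cor(pred, s[test])
        if (!is.null(e)) ce[f] <- safe_cor(pred, e[test])
      }
      corr_s[kc, ti] <- mean(cs)
      if (!is.null(e)) corr_e[kc, ti] <- mean(ce)
    }
  }
  structure(list(corr_s = corr_s, corr_e = corr_e, folds = folds, k = k,
                 time = if (is.null(window)) tensor$time else mean(window),
                 abs_corr_s = mean(abs(corr_s)),
                 abs_corr_e = if (!is.null(e)) mean(abs(corr_e))),
            class = "decoding_result")
}

safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Cross-validated decoding (%d folds, %d components):\n",
              x$k, nrow(x$corr_s)))
  cat(sprintf("  mean |corr(s_hat, s)| = %.3f\n", x$abs_corr_s))
  if (!is.null(x$abs_corr_e)) {
    cat(sprintf("  mean |corr(s_hat, E)| = %.3f\n", x$abs_corr_e))
  }
  invisible(x)
}

#' Paired encoding/readout differences between decoding results
#'
#' Differences (consistent minus inconsistent) of the window-averaged
#' absolute decoder correlations: `d_encoding` for corr(s_hat, s)
#' (stimulus decodability) and `d_readout` for corr(s_hat, E) (how well the
#' decoded stimulus predicts behavior). Absolute values make the contrast
#' invariant to overall sign flips of weights or predictions.
#'
#' @param res_consistent,res_inconsistent `decoding_result`s from
#'   [cv_decode()] computed on matched trial counts.
#' @return List with `d_encoding`, `d_readout` and the per-side values.
#' @export
readout_contrast <- function(res_consistent, res_inconsistent) {
  list(d_encoding = res_consistent$abs_corr_s - res_inconsistent$abs_corr_s,
       d_readout = if (!is.null(res_consistent$abs_corr_e))
         res_consistent$abs_corr_e - res_inconsistent$abs_corr_e,
       consistent = list(abs_corr_s = res_consistent$abs_corr_s,
                         abs_corr_e = res_consistent$abs_corr_e),
       inconsistent = list(abs_corr_s = res_inconsistent$abs_corr_s,
                           abs_corr_e = res_inconsistent$abs_corr_e))
}

#' Decoding-based consistency contrast
#'
#' Convenience wrapper applying [cv_decode()] separately to consistent and
#' inconsistent epochs (near-zero trials, pooled sample positions, matched
#' trial counts by random subsampling) and returning the paired contrast via
#' [readout_contrast()].
#'
#' @inheritParams consistency_contrast
#' @param k folds for the decoder.
#' @return Output of [readout_contrast()] plus `n_trials_used`.
#' @export
decoding_consistency_contrast <- function(tensor, trials, positions = c(7, 8),
                                          estimates = NULL,
                                          window = c(0.1, 0.5), bound = 4,
                                          k = 10L, min_trials = 81L,
                                          seed = NULL) {
  ep <- tensor$epochs
  estimates <- estimates %||%
    (if (!is.null(ep$readout)) "epoch" else "trial")
  nz_ids <- trials$trial_id[abs(trials$mu) <= bound]
  keep <- which(ep$trial_id %in% nz_ids & ep$position %in% positions)
  assert_that(length(keep) > 0, "no epochs in the near-zero/position pool")
  act <- window_activity(tensor, window)[keep, , drop = FALSE]
  ep <- ep[keep, , drop = FALSE]
  est <- if (identical(estimates, "epoch") && !is.null(ep$readout)) {
    ep$readout
  } else {
    trials$estimate[match(ep$trial_id, trials$trial_id)]
  }
  ## event-aligned frame (see consistency_contrast)
  ev <- event_sign(trials)[match(ep$trial_id, trials$trial_id)]
  ep$s <- ep$s * ev
  est <- est * ev
  act <- act * ev
  sides <- split(seq_along(ep$s), ifelse(ep$consistent, "cons", "incons"))
  n <- min(lengths(sides))
  if (n < min_trials) {
    stop(structure(class = c("readoutbias_exclusion", "error", "condition"),
                   list(message = sprintf("matched count %d below floor %d",
                                          n, min_trials), call = sys.call())))
  }
  decode_side <- function(idx, tag) {
    idx <- with_seed(child_seed(seed %||% 0L, paste0("decfold_", tag)),
                     sample(idx, n))
    tens <- neural_tensor(
      array(act[idx, , drop = FALSE], dim = c(n, ncol(act), 1L)),
      time = mean(window), sfreq = 1, epochs = ep[idx, , drop = FALSE])
    cv_decode(tens, s = ep$s[idx], e = est[idx], k = k,
              seed = child_seed(seed %||% 0L, paste0("decode_", tag)))
  }
  out <- readout_contrast(decode_side(sides$cons, "cons"),
                          decode_side(sides$incons, "incons"))
  out$n_trials_used <- n
  out
}
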