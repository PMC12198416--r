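#' Reduce vertex-level parcel activity with PCA
#'
#' Principal component analysis across vertices (computed over all
#' observations, i.e. trials and timepoints), selecting the smallest number
#' of components that cumulatively explain at least `var_threshold` of the
#' variance, capped at `max_components`.
#'
#' @param vertex_activity either a matrix `observations x vertices` or a 3-d
#'   array `epoch x vertex x time` (flattened over epochs and time for the
#'   PCA, then projected back to a component tensor).
#' @param var_threshold cumulative explained-variance threshold (default
#'   0.90).
#' @param max_components cap on the number of retained components (default
#'   15).
#' @return A list of class `component_set`: `loadings` (vertices x M),
#'   `n_components`, `explained_variance_cumulative` (for the selected set),
#'   `cumvar` (full profile), and `scores` (matrix) or `tensor`
#'   (`neural_tensor`) depending on the input form.
#' @export
reduce_parcel <- function(vertex_activity, var_threshold = 0.90,
                          max_components = 15L) {
  is_tensor_input <- length(dim(vertex_activity)) == 3L
  if (is_tensor_input) {
    d <- dim(vertex_activity)
    # [epoch, vertex, time] -> [(epoch, time), vertex]
    X <- matrix(aperm(vertex_activity, c(1, 3, 2)), d[1] * d[3], d[2])
  } else {
    X <- as.matrix(vertex_activity)
  }
  keep <- which(apply(X, 2, var) > 0)
  assert_that(length(keep) >= 1, "no vertex has nonzero variance")
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  M <- which(cumvar >= var_threshold)[1]
  if (is.na(M)) M <- length(cumvar)
  M <- min(M, max_components, length(cumvar))
  loadings <- matrix(0, ncol(X), M)
  loadings[keep, ] <- pc$rotation[, seq_len(M), drop = FALSE]
  scores <- pc$x[, seq_len(M), drop = FALSE]
  out <- list(loadings = loadings, n_components = M,
              explained_variance_cumulative = cumvar[M], cumvar = cumvar)
  if (is_tensor_input) {
    d <- dim(vertex_activity)
    arr <- array(scores, dim = c(d[1], d[3], M)) # [epoch, time, comp]
    out$tensor <- neural_tensor(aperm(arr, c(1, 3, 2)),
                                time = attr(vertex_activity, "time") %||%
                                  seq_len(d[3]),
                                sfreq = attr(vertex_activity, "sfreq") %||% 1,
                                epochs = attr(vertex_activity, "epochs"))
  } else {
    out$scores <- scores
  }
  class(out) <- "component_set"
  out
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("Component set: %d components, %.1f%% variance explained\n",
              x$n_components, 100 * x$explained_variance_cumulative))
  invisible(x)
}

#' Gaussian smoothing of a time course
#'
#' Discrete Gaussian kernel (truncated at 4 sigma) with reflective edge
#' handling.
#'
#' @param v numeric vector (time course).
#' @param sigma kernel SD in seconds (default 0.0375 s).
#' @param sfreq sampling rate, Hz.
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth <- function(v, sigma = 0.0375, sfreq = 160) {
  sig_pts <- sigma * sfreq
  if (sig_pts <= 0) return(v)
  r <- max(1L, ceiling(4 * sig_pts))
  k <- exp(-0.5 * ((-r:r) / sig_pts)^2)
  k <- k / sum(k)
  n <- length(v)
  pad_l <- v[pmin(pmax(r:1, 1), n)]
  pad_r <- v[pmin(pmax(n:(n - r + 1), 1), n)]
  vp <- c(pad_l, v, pad_r)
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
}

# fast plug-in MI for 1-based integer codes
mi_codes <- function(cx, cy, nx = max(cx), ny = max(cy)) {
  n <- length(cx)
  joint <- tabulate(cx + nx * (cy - 1L), nx * ny) / n
  jm <- matrix(joint, nx, ny)
  entropy_bits(rowSums(jm)) + entropy_bits(colSums(jm)) - entropy_bits(joint)
}

# per-component, bias-corrected measure on window-averaged or single-time data
component_info_measure <- function(measure = c("ISR", "IRE", "II"),
                                   n_bins = 3L, n_shuffles = 100L) {
  measure <- match.arg(measure)
  function(vars, seed = NULL) {
    r <- as.matrix(vars$r)
    per_comp <- lapply(seq_len(ncol(r)), function(k) {
      rk <- equipopulated_bin(r[, k], n_bins)
      switch(measure,
        ISR = bias_corrected(function(v) mi_codes(v$s, v$r),
                             list(s = equipopulated_bin(vars$s, n_bins), r = rk),
                             "s", n_shuffles, child_seed(seed %||% 0L, "c")),
        IRE = bias_corrected(function(v) mi_codes(v$r, v$e),
                             list(r = rk, e = equipopulated_bin(vars$e, n_bins)),
                             "e", n_shuffles, child_seed(seed %||% 0L, "c")),
        II = bias_corrected(
          function(v) as.numeric(intersection_information(v$s, v$r, v$e)),
          list(s = equipopulated_bin(vars$s, n_bins), r = rk,
               e = equipopulated_bin(vars$e, n_bins)),
          "s", n_shuffles, child_seed(seed %||% 0L, "c")))
    })
    average_info_results(per_comp, NROW(r))
  }
}

#' Time-resolved information in component activity
#'
#' For each principal component and timepoint, the bias-corrected measure
#' (I(S;R), I(R;E), or II(S;R;E)) is computed between the component activity
#' and the target variable(s); values are then averaged across components,
#' smoothed with a Gaussian kernel, and baseline-corrected by subtracting the
#' mean over the baseline window.
#'
#' @param tensor a `neural_tensor`.
#' @param s per-epoch stimulus values (default `tensor$epochs$s`).
#' @param e per-epoch estimate values (required for `"IRE"` and `"II"`).
#' @param measure `"ISR"`, `"IRE"` or `"II"`.
#' @param n_bins bins for discretization (default 3).
#' @param n_shuffles shuffles for bias correction (default 20, the overview
#'   setting; use 100 for consistency contrasts).
#' @param sigma smoothing kernel SD, seconds (default 0.0375).
#' @param baseline baseline window in seconds (default c(-0.1, 0)); `NULL`
#'   disables baseline correction.
#' @param seed integer seed.
#' @return An `info_timecourse`: list with `values` (bits per timepoint),
#'   `time`, `measure`, plus the unsmoothed per-component matrix.
#' @export
timecourse_info <- function(tensor, s = NULL, e = NULL,
                            measure = c("ISR", "IRE", "II"),
                            n_bins = 3L, n_shuffles = 20L, sigma = 0.0375,
                            baseline = c(-0.1, 0), seed = NULL) {
  measure <- match.arg(measure)
  s <- s %||% tensor$epochs$s
  if (measure %in% c("IRE", "II")) e <- e %||% tensor$epochs$readout
  if (measure %in% c("IRE", "II") && is.null(e)) {
    stop_config("measure ", measure, " requires per-epoch estimates e")
  }
  d <- dim(tensor$activity)
  n_comp <- d[2]; n_time <- d[3]
  sbin <- if (!is.null(s)) equipopulated_bin(s, n_bins)$codes
  ebin <- if (!is.null(e)) equipopulated_bin(e, n_bins)$codes
  raw <- matrix(0, n_comp, n_time)
  for (k in seq_len(n_comp)) {
    for (ti in seq_len(n_time)) {
      rk <- equipopulated_bin(tensor$activity[, k, ti], n_bins)$codes
      res <- switch(measure,
        ISR = bias_corrected(function(v) mi_codes(v$s, v$r),
                             list(s = sbin, r = rk), "s", n_shuffles,
                             child_seed(seed %||% 0L, "tc", ti)),
        IRE = bias_corrected(function(v) mi_codes(v$r, v$e),
                             list(r = rk, e = ebin), "e", n_shuffles,
                             child_seed(seed %||% 0L, "tc", ti)),
        II = bias_corrected(
          function(v) as.numeric(intersection_information(v$s, v$r, v$e)),
          list(s = sbin, r = rk, e = ebin), "s", n_shuffles,
          child_seed(seed %||% 0L, "tc", ti)))
      raw[k, ti] <- res$value_corrected
    }
  }
  values <- gaussian_smooth(colMeans(raw), sigma, tensor$sfreq)
  if (!is.null(baseline)) {
    bl <- tensor$time >= baseline[1] & tensor$time <= baseline[2]
    assert_that(any(bl), "baseline window outside the tensor's time axis")
    values <- values - mean(values[bl])
  }
  structure(list(values = values, time = tensor$time, measure = measure,
                 per_component = raw, sigma = sigma, baseline = baseline),
            class = "info_timecourse")
}

#' Average an information time course over a window
#'
#' @param tc an `info_timecourse` (or a list with `values` and `time`).
#' @param window two-element window in seconds (default 0.1-0.5 s, the
#'   interval containing most of the stimulus information).
#' @return Mean of the time course over the window, in bits.
#' @export
window_average <- function(tc, window = c(0.1, 0.5)) {
  idx <- tc$time >= window[1] & tc$time <= window[2]
  assert_that(any(idx), "window outside the time axis")
  mean(tc$values[idx])
}

# window-averaged component activity matrix [epoch, comp]
window_activity <- function(tensor, window = c(0.1, 0.5)) {
  idx <- which(tensor$time >= window[1] & tensor$time <= window[2])
  assert_that(length(idx) > 0, "window outside the time axis")
  apply(tensor$activity[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Consistency contrast of a neural information measure
#'
#' Compares an information measure between evidence samples consistent
#' versus inconsistent with the trial's category event, on near-zero-mean
#' trials, pooled over the requested sample positions, with matched trial
#' counts (random subsampling of the larger split) and a minimum-trial
#' floor. The measure is computed per principal component on
#' window-averaged activity and averaged across components.
#'
#' @param tensor a `neural_tensor` whose `epochs` carry `trial_id`,
#'   `position`, `s`, `consistent`.
#' @param trials the corresponding `trial_table` (supplies `mu` for the
#'   near-zero filter and, with `estimates = "trial"`, the estimate E).
#' @param positions sample positions to pool (default c(7, 8), immediately
#'   after the category event).
#' @param measure `"ISR"`, `"IRE"`, `"II"`, or `"ISE"` (the behavioral
#'   sample-estimate information, no neural activity involved).
#' @param estimates source of the estimate E: `"epoch"` uses the per-sample
#'   model readout stored in `tensor$epochs$readout` (the resolution at
#'   which the encoding/readout model validates the analyses), `"trial"`
#'   the final estimation report from `trials`. Defaults to `"epoch"` when
#'   epoch readouts are available.
#' @param window averaging window, seconds.
#' @param bound near-zero bound, degrees.
#' @param n_bins,n_shuffles,n_subsamples,min_trials estimation settings.
#' @param seed integer seed.
#' @return A `consistency_contrast`: consistent / inconsistent
#'   `info_result`s, their difference `delta` (consistent minus
#'   inconsistent), and bookkeeping.
#' @export
consistency_contrast <- function(tensor, trials, positions = c(7, 8),
                                 measure = c("ISR", "IRE", "II", "ISE"),
                                 estimates = NULL,
                                 window = c(0.1, 0.5), bound = 4,
                                 n_bins = 3L, n_shuffles = 100L,
                                 n_subsamples = 5L, min_trials = 81L,
                                 seed = NULL) {
  measure <- match.arg(measure)
  ep <- tensor$epochs
  estimates <- estimates %||%
    (if (!is.null(ep$readout)) "epoch" else "trial")
  estimates <- match.arg(estimates, c("epoch", "trial"))
  nz_ids <- trials$trial_id[abs(trials$mu) <= bound]
  keep <- which(ep$trial_id %in% nz_ids & ep$position %in% positions)
  assert_that(length(keep) > 0, "no epochs in the near-zero/position pool")
  act <- window_activity(tensor, window)[keep, , drop = FALSE]
  ep <- ep[keep, , drop = FALSE]
  est <- if (estimates == "epoch") {
    assert_that(!is.null(ep$readout), "tensor epochs carry no readouts")
    ep$readout
  } else {
    trials$estimate[match(ep$trial_id, trials$trial_id)]
  }
  ## event-aligned frame: removes the spurious consistency effect produced
  ## by the shared coupling of evidence, activity and estimate to the event
  ev <- event_sign(trials)[match(ep$trial_id, trials$trial_id)]
  s_al <- ep$s * ev
  est <- est * ev
  act <- act * ev
  ep$s <- s_al
  cons <- ep$consistent
  fn <- if (measure == "ISE") {
    mi_se_measure(n_bins, n_shuffles)
  } else {
    component_info_measure(measure, n_bins, n_shuffles)
  }
  cmp <- matched_trial_compare(
    fn,
    vars_a = list(s = ep$s[cons], e = est[cons],
                  r = act[cons, , drop = FALSE]),
    vars_b = list(s = ep$s[!cons], e = est[!cons],
                  r = act[!cons, , drop = FALSE]),
    n_subsamples = n_subsamples, min_trials = min_trials, seed = seed)
  structure(list(measure = measure, positions = positions,
                 estimates = estimates,
                 consistent = cmp$a, inconsistent = cmp$b,
                 delta = cmp$a$value_corrected - cmp$b$value_corrected,
                 n_trials_used = cmp$a$n_trials_used,
                 n_components = ncol(act)),
            class = "consistency_contrast")
}

#' @export
print.consistency_contrast <- function(x, ...) {
  cat(sprintf("Consistency contrast, %s (positions %s, n = %d matched trials):\n",
              x$measure, paste(x$positions, collapse = ","), x$n_trials_used))
  cat(sprintf("  consistent   %.4f bits\n  inconsistent %.4f bits\n  delta        %+.4f bits\n",
              x$consistent$value_corrected, x$inconsistent$value_corrected,
              x$delta))
  invisible(x)
}

#' Average per-parcel values into area groups
#'
#' Averages a per-parcel statistic within each named area group; when a
#' hemisphere label is supplied, parcels are first averaged within group and
#' hemisphere and then across hemispheres.
#'
#' @param values numeric vector, one value per parcel.
#' @param groups group label per parcel.
#' @param hemisphere optional hemisphere label per parcel.
#' @return Named numeric vector of group means.
#' @export
area_group_maps <- function(values, groups, hemisphere = NULL) {
  assert_that(length(values) == length(groups),
              "values and groups must have equal length")
  if (is.null(hemisphere)) {
    return(vapply(split(values, groups), mean, numeric(1)))
  }
  per_hemi <- tapply(values, list(groups, hemisphere), mean)
  rowMeans(per_hemi, na.rm = TRUE)
}
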