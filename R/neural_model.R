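#' Linear neural encoding/readout model configuration
#'
#' Configures the population model used to dissect encoding versus readout
#' accounts of consistency-dependent evidence weighting. Each evidence
#' sample `s` drives `K` neural populations linearly,
#' `z_k = e_k * s + eps_k` (encoding noise `eps`), and the behavioral
#' readout of that sample is `y = sum_k a_k * z_k + eta` (decoding noise
#' `eta`). Samples *consistent* with the trial's category event use encoding
#' weights whose sign matches the readout weights; *inconsistent* samples
#' use sign-flipped encoding weights, reproducing the empirical feature that
#' inconsistent samples and estimates have, on average, opposite signs
#' (mutual information is blind to this flip, so the `matched` scenario
#' yields no consistency contrast).
#'
#' Scenarios modify the processing of inconsistent samples within
#' `affected_positions` only:
#'
#' * `matched`: no difference - control.
#' * `encoding_deficit`: encoding noise multiplied by `enc_noise_factor`
#'   (reduced encoding precision; lowers I(S;R) and everything downstream).
#' * `decoding_noise`: decoding noise increased to
#'   `dec_noise_sd_inconsistent` (encoding intact; lowers I(R;E) and II).
#' * `weight_mismatch`: the readout weight vector is rotated away from the
#'   encoding pattern (norm preserved) so that its alignment with the
#'   encoding weights shrinks to `mismatch_alignment`. Population activity
#'   is untouched, so I(S;R) is exactly unchanged; the encoded information
#'   simply no longer propagates to the readout, and II drops.
#'
#' When the scenario parameters are left `NULL` they are calibrated in
#' closed form (see [calibrate_scenarios()]) so that all three deficit
#' scenarios produce the same correlation between an inconsistent sample and
#' its readout - i.e. the same behavioral consistency effect.
#'
#' @param n_populations number of neural populations `K` (>= 2).
#' @param encoding_weights per-population encoding weights (scalar recycled);
#'   units: activity per degree.
#' @param readout_weights per-population readout weights; default
#'   `1 / (K * mean(encoding_weights))`, which makes the readout an unbiased
#'   estimate of the sample.
#' @param encoding_noise_sd,decoding_noise_sd Gaussian noise SDs (activity
#'   and degree units respectively).
#' @param scenario one of `"matched"`, `"encoding_deficit"`,
#'   `"decoding_noise"`, `"weight_mismatch"`.
#' @param enc_noise_factor multiplier on encoding noise for inconsistent
#'   samples (`encoding_deficit` only).
#' @param dec_noise_sd_inconsistent decoding noise SD for inconsistent
#'   samples (`decoding_noise` only).
#' @param mismatch_alignment residual alignment (cosine) between readout and
#'   encoding weights for inconsistent samples under `weight_mismatch`, in
#'   (0, 1); default 0.5.
#' @param sample_var nominal variance (deg^2) of consistency-conditioned
#'   evidence samples, used for closed-form calibration of `NULL` scenario
#'   parameters. 103 matches event-conditioned, truncated samples on
#'   near-zero trials under task defaults.
#' @param sensor_noise_sd white measurement noise added per timepoint of the
#'   simulated tensor.
#' @param sfreq sampling rate of the simulated tensor, Hz (default 160).
#' @param t_start,t_end tensor time axis relative to sample onset, seconds.
#' @param response_window interval (s) during which the evoked response
#'   carries the stimulus-dependent signal (boxcar), default 0.1-0.5 s.
#' @param affected_positions sample positions at which the scenario's
#'   inconsistency deficit applies (default 7:12, the post-event interval).
#' @param rng_seed integer seed.
#' @return A list of class `neural_model_config`.
#' @export
neural_model_config <- function(n_populations = 4L,
                                encoding_weights = 0.05,
                                readout_weights = NULL,
                                encoding_noise_sd = 1,
                                decoding_noise_sd = 5,
                                scenario = c("matched", "encoding_deficit",
                                             "decoding_noise", "weight_mismatch"),
                                enc_noise_factor = NULL,
                                dec_noise_sd_inconsistent = NULL,
                                mismatch_alignment = 0.5,
                                sample_var = 103,
                                sensor_noise_sd = 1,
                                sfreq = 160,
                                t_start = -0.2, t_end = 0.7,
                                response_window = c(0.1, 0.5),
                                affected_positions = 7:12,
                                rng_seed = 1L) {
  if (is.character(scenario) && length(scenario) == 1L &&
      !scenario %in% c("matched", "encoding_deficit", "decoding_noise",
                       "weight_mismatch")) {
    stop_config("unknown scenario: ", scenario)
  }
  scenario <- match.arg(scenario)
  K <- as.integer(n_populations)
  assert_that(K >= 2, "need at least 2 populations")
  e <- rep_len(encoding_weights, K)
  assert_that(all(e != 0), "encoding weights must be nonzero")
  if (is.null(readout_weights)) readout_weights <- 1 / (K * mean(e))
  a <- rep_len(readout_weights, K)
  assert_that(all(a != 0), "readout weights must be nonzero")
  assert_that(encoding_noise_sd >= 0 && decoding_noise_sd >= 0 &&
                sensor_noise_sd >= 0, "noise SDs must be >= 0")
  assert_that(mismatch_alignment > 0 && mismatch_alignment < 1,
              "mismatch_alignment must be in (0, 1)")
  cfg <- structure(list(
    n_populations = K, encoding_weights = e, readout_weights = a,
    encoding_noise_sd = encoding_noise_sd,
    decoding_noise_sd = decoding_noise_sd,
    scenario = scenario,
    enc_noise_factor = enc_noise_factor,
    dec_noise_sd_inconsistent = dec_noise_sd_inconsistent,
    mismatch_alignment = mismatch_alignment,
    sample_var = sample_var,
    sensor_noise_sd = sensor_noise_sd,
    sfreq = sfreq, t_start = t_start, t_end = t_end,
    response_window = response_window,
    affected_positions = as.integer(affected_positions),
    rng_seed = as.integer(rng_seed)
  ), class = "neural_model_config")
  ## calibrate missing deficit parameters to the mismatch-equivalent level
  if (scenario == "encoding_deficit" && is.null(cfg$enc_noise_factor)) {
    cfg$enc_noise_factor <- calibrate_scenarios(cfg)$encoding_deficit$enc_noise_factor
  }
  if (scenario == "decoding_noise" && is.null(cfg$dec_noise_sd_inconsistent)) {
    cfg$dec_noise_sd_inconsistent <-
      calibrate_scenarios(cfg)$decoding_noise$dec_noise_sd_inconsistent
  }
  cfg
}

#' Calibrate the three deficit scenarios to a common behavioral effect
#'
#' The defining signature of each scenario lies in the *neural* measures;
#' behaviorally the three must be indistinguishable. This function equates,
#' in closed form, the correlation between an inconsistent sample and its
#' behavioral readout across scenarios, anchored at the `weight_mismatch`
#' scenario: a readout rotated to alignment `alpha = mismatch_alignment`
#' yields target correlation `rho^2 = alpha^2 V / (alpha^2 V + N0)`, where
#' `V = sample_var` and `N0` is the readout noise variance. Encoding and
#' decoding noise levels of the other two scenarios are then solved to reach
#' the same `rho`.
#'
#' @param cfg a [neural_model_config()] (its consistent-side parameters and
#'   `mismatch_alignment` anchor the calibration).
#' @param sample_var optional override of `cfg$sample_var` (deg^2), e.g. an
#'   empirical variance of consistency-conditioned samples.
#' @return Named list of three `neural_model_config`s
#'   (`encoding_deficit`, `decoding_noise`, `weight_mismatch`) sharing the
#'   calibrated behavioral effect; also reports `target_cor`, the common
#'   inconsistent sample-readout correlation.
#' @export
calibrate_scenarios <- function(cfg, sample_var = NULL) {
  V <- sample_var %||% cfg$sample_var
  K <- cfg$n_populations
  a <- cfg$readout_weights
  e <- cfg$encoding_weights
  A <- sum(a * e)                        # consistent readout alignment
  alpha <- cfg$mismatch_alignment
  N0 <- sum(a^2) * cfg$encoding_noise_sd^2 + cfg$decoding_noise_sd^2
  A2V <- A^2 * V
  rho2 <- alpha^2 * A2V / (alpha^2 * A2V + N0)
  ## total readout-noise variance that yields rho2 at full alignment
  Nt <- A2V * (1 - rho2) / rho2
  enc_var <- (Nt - cfg$decoding_noise_sd^2) / sum(a^2)
  assert_that(enc_var > 0, "calibration failed: decoding noise already exceeds target")
  f <- sqrt(enc_var) / cfg$encoding_noise_sd
  dec_sd <- sqrt(Nt - sum(a^2) * cfg$encoding_noise_sd^2)
  remake <- function(scenario, ...) {
    args <- list(n_populations = K, encoding_weights = e, readout_weights = a,
                 encoding_noise_sd = cfg$encoding_noise_sd,
                 decoding_noise_sd = cfg$decoding_noise_sd,
                 scenario = scenario, mismatch_alignment = alpha,
                 sample_var = V,
                 sensor_noise_sd = cfg$sensor_noise_sd, sfreq = cfg$sfreq,
                 t_start = cfg$t_start, t_end = cfg$t_end,
                 response_window = cfg$response_window,
                 affected_positions = cfg$affected_positions,
                 rng_seed = cfg$rng_seed)
    do.call(neural_model_config, c(args, list(...)))
  }
  out <- list(
    encoding_deficit = remake("encoding_deficit", enc_noise_factor = f),
    decoding_noise = remake("decoding_noise", dec_noise_sd_inconsistent = dec_sd),
    weight_mismatch = remake("weight_mismatch"))
  attr(out, "target_cor") <- sqrt(rho2)
  out
}

# rotate a weight vector within the plane spanned by itself and a fixed
# orthogonalized alternating direction, preserving its norm, so that the
# cosine between original and rotated vector equals `alignment`
rotate_readout <- function(a, alignment) {
  K <- length(a)
  u <- rep_len(c(1, -1), K)
  u <- u - sum(u * a) / sum(a^2) * a
  nu <- sqrt(sum(u^2))
  assert_that(nu > 1e-12, "cannot construct a rotation direction")
  u <- u / nu
  alignment * a + sqrt(1 - alignment^2) * sqrt(sum(a^2)) * u
}

#' Simulate neural population activity and model-generated estimates
#'
#' Applies the linear encoding/readout model to every sample of every trial:
#' computes per-sample population signals and readouts, builds a time-resolved
#' activity tensor for the requested sample positions (signal as a boxcar in
#' the response window plus white sensor noise), and replaces each trial's
#' estimate with the model-generated estimate (the mean of the per-sample
#' readouts across all sample positions).
#'
#' @param trials a `trial_table` with category events (run
#'   [simulate_observer()] / [assign_cues()] first).
#' @param cfg a [neural_model_config()].
#' @param positions sample positions for which tensor epochs are built
#'   (default `cfg$affected_positions`).
#' @return A list with components:
#'   * `tensor`: a `neural_tensor` - activity array `[epoch, component,
#'     time]` with an `epochs` data frame (`trial_id`, `position`, `s`,
#'     `consistent`, `readout`) and time axis metadata;
#'   * `trials`: the trial table with model-generated estimates.
#' @export
simulate_neural <- function(trials, cfg = neural_model_config(),
                            positions = NULL) {
  if (!inherits(cfg, "neural_model_config")) {
    stop_config("cfg must be a neural_model_config")
  }
  positions <- as.integer(positions %||% cfg$affected_positions)
  smp <- sample_matrix(trials)
  n_tr <- nrow(smp); n_pos <- ncol(smp); K <- cfg$n_populations
  assert_that(all(positions >= 1 & positions <= n_pos), "positions out of range")
  cons <- label_consistency(trials,
                            seed = child_seed(cfg$rng_seed, "consistency"))
  affected <- matrix(FALSE, n_tr, n_pos)
  affected[, cfg$affected_positions] <- TRUE

  with_seed(child_seed(cfg$rng_seed, "neural"), {
    ## long format over all (trial, position) pairs
    s <- as.vector(smp)                       # trial-major
    cns <- as.vector(cons)
    aff <- as.vector(affected)
    n_ep <- length(s)
    ## encoding weights: sign matched to the readout for consistent samples,
    ## flipped for inconsistent ones (the empirical sign feature; information
    ## measures are blind to the overall flip)
    u <- ifelse(cns, 1, -1)
    ew <- outer(u, cfg$encoding_weights)
    enc_sd <- rep(cfg$encoding_noise_sd, n_ep)
    if (cfg$scenario == "encoding_deficit") {
      enc_sd[!cns & aff] <- cfg$encoding_noise_sd * cfg$enc_noise_factor
    }
    dec_sd <- rep(cfg$decoding_noise_sd, n_ep)
    if (cfg$scenario == "decoding_noise") {
      dec_sd[!cns & aff] <- cfg$dec_noise_sd_inconsistent
    }
    z <- ew * s + matrix(rnorm(n_ep * K, 0, enc_sd), n_ep, K)
    ## per-sample behavioral readout; under weight_mismatch the readout of
    ## inconsistent samples uses a rotated weight vector (same norm, reduced
    ## alignment), leaving the activity z - hence I(S;R) - untouched
    y <- as.vector(z %*% cfg$readout_weights)
    if (cfg$scenario == "weight_mismatch") {
      a_mis <- rotate_readout(cfg$readout_weights, cfg$mismatch_alignment)
      mm <- !cns & aff
      y[mm] <- as.vector(z[mm, , drop = FALSE] %*% a_mis)
    }
    y <- y + rnorm(n_ep, 0, dec_sd)
    ## trial-level estimate: per-sample readouts, sign-aligned with the
    ## encoding convention so every sample contributes with positive gain
    est <- rowMeans(matrix(u * y, n_tr, n_pos))
    trials$estimate <- est

    ## tensor for requested positions
    time <- seq(cfg$t_start, cfg$t_end, by = 1 / cfg$sfreq)
    box <- as.numeric(time >= cfg$response_window[1] &
                        time <= cfg$response_window[2])
    keep <- as.vector(outer(seq_len(n_tr), positions,
                            function(i, p) i + (p - 1L) * n_tr))
    n_keep <- length(keep)
    act <- array(rnorm(n_keep * K * length(time), 0, cfg$sensor_noise_sd),
                 dim = c(n_keep, K, length(time)))
    for (ti in which(box > 0)) act[, , ti] <- act[, , ti] + z[keep, ]
    epochs <- data.frame(
      trial_id = trials$trial_id[((keep - 1L) %% n_tr) + 1L],
      position = rep(positions, each = n_tr),
      s = s[keep], consistent = cns[keep], readout = y[keep])
    tensor <- neural_tensor(act, time = time, sfreq = cfg$sfreq,
                            epochs = epochs,
                            meta = list(scenario = cfg$scenario,
                                        seed = cfg$rng_seed))
    list(tensor = tensor, trials = trials)
  })
}

#' Construct a neural activity tensor
#'
#' @param activity numeric array `[epoch, component, time]`.
#' @param time time axis in seconds (0 = sample onset).
#' @param sfreq sampling rate, Hz.
#' @param epochs data frame of per-epoch metadata (one row per epoch).
#' @param meta optional named list of provenance metadata.
#' @return An object of class `neural_tensor`.
#' @export
neural_tensor <- function(activity, time, sfreq, epochs = NULL, meta = list()) {
  stopifnot(length(dim(activity)) == 3L, dim(activity)[3] == length(time))
  if (!is.null(epochs)) stopifnot(nrow(epochs) == dim(activity)[1])
  structure(list(activity = activity, time = time, sfreq = sfreq,
                 epochs = epochs, meta = meta),
            class = "neural_tensor")
}

#' @export
print.neural_tensor <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Neural tensor: %d epochs x %d components x %d timepoints (%g Hz, %.2f..%.2f s)\n",
              d[1], d[2], d[3], x$sfreq, min(x$time), max(x$time)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate vertex-level parcel activity with known latent dimensionality
#'
#' Fixture generator for the dimensionality-reduction stage: observations
#' are a low-rank latent signal mixed into `n_vertices` vertices plus
#' isotropic Gaussian noise.
#'
#' @param n_vertices number of vertices in the parcel.
#' @param n_obs number of observations (trial-time points).
#' @param n_latent true latent dimensionality.
#' @param noise_sd isotropic noise SD.
#' @param latent_scale SD of the strongest latent signal; latent SDs decay
#'   linearly to half this value.
#' @param seed integer seed.
#' @return Numeric matrix `n_obs x n_vertices`, with the mixing matrix in
#'   `attr(, "loadings")`.
#' @export
simulate_vertex_parcel <- function(n_vertices = 20L, n_obs = 500L,
                                   n_latent = 4L, noise_sd = 1,
                                   latent_scale = 3, seed = 1L) {
  assert_that(n_latent <= n_vertices, "n_latent must be <= n_vertices")
  with_seed(seed, {
    sds <- seq(latent_scale, latent_scale / 2, length.out = n_latent)
    L <- matrix(rnorm(n_obs * n_latent), n_obs) %*% diag(sds, n_latent)
    W <- matrix(rnorm(n_latent * n_vertices), n_latent)
    W <- W / sqrt(rowSums(W^2)) # unit mixing rows
    X <- L %*% W
    if (noise_sd > 0) X <- X + matrix(rnorm(n_obs * n_vertices, 0, noise_sd),
                                      n_obs)
    attr(X, "loadings") <- W
    X
  })
}
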