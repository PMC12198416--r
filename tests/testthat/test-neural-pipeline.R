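# small simulated dataset shared by the neural tests
neural_fixture <- function(scenario = "matched", sessions = 1, seed = 201,
                           positions = 7:8, ...) {
  tr <- small_choice_trials(sessions = sessions, decision_noise = 0.1,
                            seed = seed)
  cfg <- neural_model_config(scenario = scenario, rng_seed = seed + 1, ...)
  simulate_neural(tr, cfg, positions = positions)
}

test_that("the neural model is deterministic and faithful at zero noise", {
  tr <- small_choice_trials(sessions = 1, seed = 101)
  cfg0 <- neural_model_config(encoding_noise_sd = 0, decoding_noise_sd = 0,
                              sensor_noise_sd = 0, rng_seed = 5)
  sim <- simulate_neural(tr, cfg0, positions = 7)
  ep <- sim$tensor$epochs
  # consistent samples: readout equals the sample exactly
  expect_equal(ep$readout[ep$consistent], ep$s[ep$consistent],
               tolerance = 1e-10)
  expect_equal(abs(cor(ep$readout[ep$consistent], ep$s[ep$consistent])), 1,
               tolerance = 1e-12)
  # inconsistent samples: sign-flipped encoding, same magnitude
  expect_equal(ep$readout[!ep$consistent], -ep$s[!ep$consistent],
               tolerance = 1e-10)
  # reproducibility
  sim2 <- simulate_neural(tr, cfg0, positions = 7)
  expect_identical(sim$tensor$activity, sim2$tensor$activity)
  expect_identical(sim$trials$estimate, sim2$trials$estimate)
})

test_that("scenario calibration equates the inconsistent readout correlation", {
  base <- neural_model_config(rng_seed = 7)
  scen <- calibrate_scenarios(base)
  expect_named(scen, c("encoding_deficit", "decoding_noise", "weight_mismatch"))
  rho <- attr(scen, "target_cor")
  expect_true(rho > 0 && rho < 1)
  # closed-form check: each calibrated parameter reproduces rho
  V <- base$sample_var
  A <- sum(base$readout_weights * base$encoding_weights)
  sa2 <- sum(base$readout_weights^2)
  rho_enc <- sqrt(A^2 * V / (A^2 * V +
    sa2 * (base$encoding_noise_sd * scen$encoding_deficit$enc_noise_factor)^2 +
    base$decoding_noise_sd^2))
  rho_dec <- sqrt(A^2 * V / (A^2 * V + sa2 * base$encoding_noise_sd^2 +
    scen$decoding_noise$dec_noise_sd_inconsistent^2))
  expect_equal(rho_enc, rho, tolerance = 1e-10)
  expect_equal(rho_dec, rho, tolerance = 1e-10)
})

test_that("readout rotation preserves the norm and hits the alignment", {
  a <- rep(2.5, 4)
  for (al in c(0.25, 0.5, 0.8)) {
    ar <- readoutbias:::rotate_readout(a, al)
    expect_equal(sqrt(sum(ar^2)), sqrt(sum(a^2)), tolerance = 1e-12)
    expect_equal(sum(ar * a) / sum(a^2), al, tolerance = 1e-12)
  }
})

test_that("window averaging and smoothing behave on canonical shapes", {
  tvec <- seq(-0.2, 0.7, by = 1 / 160)
  const <- list(values = rep(0.3, length(tvec)), time = tvec)
  expect_equal(window_average(const), 0.3)
  box <- list(values = as.numeric(tvec >= 0.1 & tvec <= 0.5) * 2, time = tvec)
  expect_equal(window_average(box), 2)
  # oracle: plain mean over the window indices
  set.seed(11)
  v <- rnorm(length(tvec))
  idx <- tvec >= 0.1 & tvec <= 0.5
  expect_equal(window_average(list(values = v, time = tvec)), mean(v[idx]))
  # smoothing preserves a constant and the overall mean (reflective edges)
  expect_equal(gaussian_smooth(rep(1, 50), 0.0375, 160), rep(1, 50))
  expect_equal(mean(gaussian_smooth(v, 0.05, 160)), mean(v), tolerance = 0.02)
})

test_that("information time courses localize stimulus information in time", {
  sim <- neural_fixture(sessions = 1, seed = 202, positions = 7)
  # consistent epochs only (the model encodes inconsistent samples with
  # flipped sign, so pooling the two would fold the relation onto itself),
  # and a thinned time axis to keep the computation small
  tens <- sim$tensor
  keep_e <- which(tens$epochs$consistent)
  keep_t <- seq(1, length(tens$time), by = 4)
  tens$activity <- tens$activity[keep_e, , keep_t]
  tens$epochs <- tens$epochs[keep_e, ]
  tens$time <- tens$time[keep_t]
  tens$sfreq <- tens$sfreq / 4
  tc <- timecourse_info(tens, measure = "ISR", n_shuffles = 10, seed = 3)
  expect_s3_class(tc, "info_timecourse")
  # baseline window averages to zero after correction
  bl <- tens$time >= -0.1 & tens$time <= 0
  expect_equal(mean(tc$values[bl]), 0, tolerance = 1e-10)
  # stimulus information confined to the response window
  inside <- window_average(tc)
  outside <- mean(tc$values[tens$time > 0.55 | tens$time < 0.05])
  expect_gt(inside, 0.05)
  expect_lt(abs(outside), 0.02)
  # pure-noise tensor carries none
  noise <- tens
  noise$activity <- with_seed(4, array(rnorm(length(tens$activity)),
                                       dim = dim(tens$activity)))
  tcn <- timecourse_info(noise, measure = "ISR", n_shuffles = 10, seed = 5,
                         baseline = NULL)
  expect_lt(max(abs(tcn$values)), 0.02)
  # component averaging is order-invariant
  perm <- tens
  perm$activity <- perm$activity[, c(3, 1, 4, 2), ]
  tcp <- timecourse_info(perm, measure = "ISR", n_shuffles = 10, seed = 3)
  expect_equal(sort(tcp$per_component[, 5]), sort(tc$per_component[, 5]),
               tolerance = 1e-9)
})

test_that("the II time course respects its information bounds", {
  sim <- neural_fixture(sessions = 1, seed = 203, positions = 7)
  tens <- sim$tensor
  keep_t <- which(tens$time >= 0.05 & tens$time <= 0.6)[c(TRUE, rep(FALSE, 7))]
  tens$activity <- tens$activity[, 1:2, keep_t, drop = FALSE]
  tens$time <- tens$time[keep_t]
  args <- list(tensor = tens, n_shuffles = 5, baseline = NULL, seed = 6)
  tc_ii <- do.call(timecourse_info, c(args, list(measure = "II")))
  tc_isr <- do.call(timecourse_info, c(args, list(measure = "ISR")))
  tc_ire <- do.call(timecourse_info, c(args, list(measure = "IRE")))
  # raw (uncorrected) per-component values obey the bound pointwise
  expect_true(all(tc_ii$per_component <=
                    pmin(tc_isr$per_component, tc_ire$per_component) + 0.02))
})

test_that("area group maps average parcels as designed", {
  groups <- rep(letters[1:4], each = 5)
  expect_equal(unname(area_group_maps(rep(2.5, 20), groups)), rep(2.5, 4))
  one_hot <- c(7, rep(0, 19))
  expect_equal(unname(area_group_maps(one_hot, groups)),
               c(7 / 5, 0, 0, 0))
  # hemisphere averaging equals the oracle two-stage mean
  set.seed(12)
  v <- rnorm(20)
  hemi <- rep(c("L", "R"), 10)
  m <- area_group_maps(v, groups, hemi)
  oracle <- vapply(split(seq_along(v), groups), function(i) {
    mean(vapply(split(v[i], hemi[i]), mean, numeric(1)))
  }, numeric(1))
  expect_equal(m, oracle)
})

test_that("consistency contrasts carry matched-trial bookkeeping", {
  sim <- neural_fixture(sessions = 2, seed = 204)
  ct <- consistency_contrast(sim$tensor, sim$trials, measure = "ISR",
                             n_shuffles = 20, min_trials = 50, seed = 7)
  expect_s3_class(ct, "consistency_contrast")
  expect_equal(ct$consistent$n_trials_used, ct$inconsistent$n_trials_used)
  expect_gte(ct$consistent$n_trials_used, 50)
  expect_equal(ct$delta, ct$consistent$value_corrected -
                 ct$inconsistent$value_corrected)
  # the minimum-trial floor raises an exclusion condition
  expect_error(
    consistency_contrast(sim$tensor, sim$trials, measure = "ISR",
                         n_shuffles = 5, min_trials = 10000, seed = 8),
    class = "readoutbias_exclusion")
})
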