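test_that("session scheduler yields the designed trial counts, reproducibly", {
  cfg <- task_config(rng_seed = 7)
  tr <- generate_trials(cfg)
  expect_equal(unname(table(tr$condition)["Choice"]), 928)
  expect_equal(unname(table(tr$condition)["Cue"]), 928)
  expect_equal(max(tr$block), 8)
  expect_equal(max(tr$session), 2)
  expect_true(all(tr$mu %in% seq(-14, 14)))
  expect_lte(max(abs(tr$mu)), 14)
  # same seed, same table; different seed, different draws
  expect_identical(tr, generate_trials(cfg))
  tr2 <- generate_trials(task_config(rng_seed = 8))
  expect_false(identical(tr$mu, tr2$mu))
})

test_that("evidence samples respect the truncation band and generative SD", {
  tr <- generate_trials(task_config(rng_seed = 3))
  dev <- abs(sample_matrix(tr) - tr$mu)
  expect_lte(max(dev), 40)
  # degenerate truncation collapses samples onto the mean
  tiny <- generate_trials(task_config(truncation = 1e-3, rng_seed = 3), "Choice")
  expect_lt(max(abs(sample_matrix(tiny) - tiny$mu)), 1e-3 + 1e-12)
  # pre-truncation draws have SD 20 (Monte-Carlo tolerance)
  raw <- with_seed(42, draw_evidence_samples(2e5, mu = 0, sd = 20,
                                             truncation = Inf))
  expect_equal(sd(raw), 20, tolerance = 0.01)
  expect_equal(mean(raw), 0, tolerance = 0.2)
})

test_that("cue categories follow the configured validity", {
  cfg <- task_config(trials_per_block = 100, blocks_per_session = 25,
                     sessions_per_condition = 8, rng_seed = 5)
  tr <- generate_trials(cfg, "Cue")
  nz <- tr[tr$mu != 0, ]
  match_frac <- mean(nz$category_event == ifelse(nz$mu > 0, "right", "left"))
  expect_equal(match_frac, 0.75, tolerance = 0.01)
  expect_true(all(tr$event_correct[tr$mu != 0] ==
                    (nz$category_event == ifelse(nz$mu > 0, "right", "left"))))
  # perfect validity
  tr1 <- assign_cues(generate_trials(task_config(rng_seed = 6), "Cue"),
                     validity = 1, seed = 1)
  nz1 <- tr1[tr1$mu != 0, ]
  expect_true(all(nz1$category_event == ifelse(nz1$mu > 0, "right", "left")))
  # chance validity: cue carries no information about the source sign
  tr5 <- assign_cues(tr, validity = 0.5, seed = 2)
  nz5 <- tr5[tr5$mu != 0, ]
  mi <- mutual_information(as.integer(nz5$category_event == "right") + 1L,
                           as.integer(nz5$mu > 0) + 1L)
  expect_lt(mi, 5e-4)
})

test_that("ideal observer is a perfect integrator; gains reweight samples", {
  tr <- small_choice_trials(sessions = 2, decision_noise = 0, seed = 31)
  smp <- sample_matrix(tr)
  expect_equal(tr$estimate, rowMeans(smp), tolerance = 1e-12)
  # all-positive first-interval samples force a 'right' choice
  allpos <- rowSums(smp[, 1:6] > 0) == 6
  expect_true(all(tr$category_event[allpos] == "right"))
  # decision noise fraction of random judgments
  trn <- simulate_observer(generate_trials(task_config(rng_seed = 31), "Choice"),
                           observer_config(decision_noise = 1), seed = 4)
  acc <- mean(trn$event_correct[abs(trn$mu) >= 10])
  expect_equal(acc, 0.5, tolerance = 0.06)
})

test_that("zeroed consistency gains remove a sample's behavioral weight", {
  # zero-mean trials isolate the stochastic evidence fluctuations; the
  # closed-form linear-observer weights are then w_i / 12 per position
  cfg <- task_config(mean_grid = 0, trials_per_block = 100,
                     blocks_per_session = 25, sessions_per_condition = 8,
                     rng_seed = 77)
  tr <- generate_trials(cfg, "Choice")
  gains <- rep(1, 12); gains[7:8] <- 0
  trb <- simulate_observer(tr, observer_config(consistency_gain = gains),
                           seed = 78)
  kr <- psychophysical_kernel_regression(trb, split = "consistency", seed = 79)
  incons <- kr[kr$label == "inconsistent", ]
  cons <- kr[kr$label == "consistent", ]
  expect_lt(max(incons$value[incons$position %in% 7:8]), 0.012)
  expect_lt(abs(cons$value[cons$position == 7] - 1 / 12), 0.007)
  # graded gain halves the inconsistent slope
  gains2 <- rep(1, 12); gains2[7] <- 0.5
  trh <- simulate_observer(tr, observer_config(consistency_gain = gains2),
                           seed = 80)
  kh <- psychophysical_kernel_regression(trh, split = "consistency", seed = 81)
  ratio <- kh$value[kh$label == "inconsistent" & kh$position == 7] /
    kh$value[kh$label == "consistent" & kh$position == 7]
  expect_equal(ratio, 0.5, tolerance = 0.12)
})

test_that("vertex parcel generator has the designed latent dimensionality", {
  # noiseless rank-2 signal
  x2 <- simulate_vertex_parcel(n_vertices = 12, n_obs = 300, n_latent = 2,
                               noise_sd = 0, seed = 1)
  cs2 <- reduce_parcel(x2)
  expect_equal(cs2$n_components, 2)
  expect_equal(cs2$explained_variance_cumulative, 1, tolerance = 1e-8)
  # eigen-spectrum oracle: with 5 latents and moderate noise the selection
  # routine needs at least 5 components for 90% of the variance
  x5 <- simulate_vertex_parcel(n_vertices = 20, n_obs = 600, n_latent = 5,
                               noise_sd = 1, seed = 2)
  ev <- svd(scale(x5, scale = FALSE))$d^2
  oracle_m <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  cs5 <- reduce_parcel(x5)
  expect_gte(cs5$n_components, 5)
  expect_equal(cs5$n_components, oracle_m)
  expect_gte(cs5$explained_variance_cumulative, 0.9)
  # white noise across 40 vertices hits the component cap
  xw <- with_seed(3, matrix(rnorm(400 * 40), 400))
  expect_equal(reduce_parcel(xw)$n_components, 15)
  # a single constant vertex leaves one informative component
  xc <- cbind(simulate_vertex_parcel(n_vertices = 1, n_obs = 200, n_latent = 1,
                                     noise_sd = 0, seed = 4), 0)
  expect_equal(reduce_parcel(xc)$n_components, 1)
})

test_that("invalid configurations are rejected", {
  expect_error(task_config(cue_validity = 1.5), "cue_validity")
  expect_error(task_config(truncation = -1), "truncation")
  expect_error(task_config(mean_grid = c(-3, 1, 2)), "symmetric")
  expect_error(observer_config(decision_noise = 2), "decision_noise")
  expect_error(neural_model_config(scenario = "banana"), "scenario")
  expect_error(neural_model_config(encoding_weights = 0), "nonzero")
})
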