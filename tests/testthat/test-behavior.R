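test_that("near-zero selection keeps the designed fraction of trials", {
  tr <- generate_trials(task_config(rng_seed = 21), "Choice")
  nz <- select_near_zero(tr)
  expect_true(all(abs(nz$mu) <= 4))
  # 9 of the 29 grid values lie in [-4, 4]
  expect_equal(nrow(nz) / nrow(tr), 9 / 29, tolerance = 0.12)
  z <- select_near_zero(tr, bound = 0)
  expect_true(all(z$mu == 0))
})

test_that("consistency labels follow the sign rule", {
  tr <- small_choice_trials(seed = 22)
  cons <- label_consistency(tr, seed = 1)
  smp <- sample_matrix(tr)
  right <- tr$category_event == "right"
  expect_true(all(cons[right, ][smp[right, ] > 0]))
  expect_true(all(!cons[right, ][smp[right, ] < 0]))
  expect_true(all(!cons[!right, ][smp[!right, ] > 0]))
})

test_that("information kernels track evidence weighting", {
  tr <- small_choice_trials(sessions = 2, decision_noise = 0, seed = 23)
  k <- psychophysical_kernel_mi(tr, n_shuffles = 30, seed = 24)
  expect_equal(nrow(k), 12)
  # the perfect integrator weights every sample: information at all positions
  expect_true(all(k$value > 0))
  # estimates replaced by noise carry no information
  trn <- tr
  trn$estimate <- with_seed(9, rnorm(nrow(tr), 0, 10))
  kn <- psychophysical_kernel_mi(trn, n_shuffles = 30, seed = 25)
  expect_lt(max(abs(kn$value)), 0.01)
})

test_that("a biased observer shows the consistency effect only where biased", {
  cfg <- task_config(sessions_per_condition = 6, rng_seed = 26)
  tr <- generate_trials(cfg, "Choice")
  gains <- rep(1, 12); gains[7:8] <- 0.3
  trb <- simulate_observer(tr, observer_config(decision_noise = 0.1,
                                               consistency_gain = gains),
                           seed = 27)
  k <- psychophysical_kernel_mi(trb, split = "consistency", n_shuffles = 40,
                                seed = 28)
  d <- vapply(split(k, k$position), function(x) {
    x$value[x$label == "consistent"] - x$value[x$label == "inconsistent"]
  }, numeric(1))
  # effect at the down-weighted positions, none elsewhere
  expect_gt(mean(d[7:8]), 0.008)
  expect_lt(abs(mean(d[c(1:6, 9:12)])), 0.006)
  # the regression kernels agree in ordering with the information kernels
  kr <- psychophysical_kernel_regression(trb, split = "consistency", seed = 29)
  dr <- vapply(split(kr, kr$position), function(x) {
    x$value[x$label == "consistent"] - x$value[x$label == "inconsistent"]
  }, numeric(1))
  expect_gt(mean(dr[7:8]), 0)
  expect_gt(mean(d[7:8]), mean(d[c(1:6, 9:12)]))
  expect_gt(mean(dr[7:8]), mean(dr[c(1:6, 9:12)]))
})

test_that("regression kernels are flat for the ideal observer", {
  cfg <- task_config(mean_grid = 0, trials_per_block = 100,
                     blocks_per_session = 20, sessions_per_condition = 4,
                     rng_seed = 30)
  tr <- simulate_observer(generate_trials(cfg, "Choice"), observer_config(),
                          seed = 31)
  kr <- psychophysical_kernel_regression(tr)
  expect_equal(kr$beta, rep(1 / 12, 12), tolerance = 0.05)
  # constant estimates have no kernel
  trc <- tr; trc$estimate <- 5
  krc <- psychophysical_kernel_regression(trc)
  expect_true(all(krc$value == 0))
})

test_that("dip statistic separates unimodal from bimodal estimates", {
  set.seed(32)
  uni <- rnorm(800)
  bi <- c(rnorm(400, -8, 3), rnorm(400, 8, 3))
  d_uni <- dip_test(uni, n_mc = 200, seed = 1)
  d_bi <- dip_test(bi, n_mc = 200, seed = 2)
  expect_gt(d_bi$statistic, d_uni$statistic)
  expect_lt(d_bi$p_value, 0.01)
  expect_gt(d_uni$p_value, 0.05)
  # scale and shift invariance of the statistic
  expect_equal(dip_test(3 * uni + 10, n_mc = 2, seed = 3)$statistic,
               d_uni$statistic)
})

test_that("estimation distributions are z-scored per participant", {
  tr <- small_choice_trials(sessions = 1, decision_noise = 0.1, seed = 33)
  tr$participant <- rep(1:2, length.out = nrow(tr))
  st <- estimation_distribution_stats(tr, n_mc = 100, seed = 34)
  expect_equal(mean(st$pooled$z_scored), 0, tolerance = 1e-10)
  for (p in 1:2) {
    z <- st$pooled$z_scored[tr$participant == p]
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  expect_equal(nrow(st$per_participant), 2)
  expect_true(all(st$per_participant$p_value > 0 &
                    st$per_participant$p_value <= 1))
})

test_that("category-conditioned bias recovers a constructed shift", {
  tr <- small_choice_trials(sessions = 2, decision_noise = 0.2, seed = 35)
  shift <- 3
  trs <- tr
  trs$estimate <- tr$estimate +
    ifelse(tr$category_event == "right", shift, -shift)
  cb <- category_conditioned_bias(trs)
  cb0 <- category_conditioned_bias(tr)
  expect_equal(nrow(cb), 3)
  expect_equal(mean(cb$diff) - mean(cb0$diff), 2 * shift, tolerance = 0.15)
})

test_that("psychometric fit recovers bias, slope and lapse structure", {
  # noiseless sign rule: steep slope at the boundary, no bias
  tr0 <- small_choice_trials(sessions = 4, decision_noise = 0, seed = 36)
  f0 <- psychometric_fit(tr0)
  expect_lt(abs(f0$bias), 1)
  expect_gt(f0$slope, 5)
  expect_lt(f0$lapse, 0.03)
  # 20% random judgments produce ~0.9/0.1 asymptotes, i.e. lapse ~0.1
  tr2 <- small_choice_trials(sessions = 4, decision_noise = 0.2, seed = 37)
  f2 <- psychometric_fit(tr2)
  expect_equal(f2$lapse, 0.1, tolerance = 0.35)
  expect_lt(abs(f2$bias), 1.5)
})

test_that("event alignment removes the conditioning artifact in splits", {
  # even a noise-free unbiased integrator shows strong spurious structure
  # when consistency splits are computed in the raw frame: conditioning on
  # agreement with the event couples the sample to the estimate through the
  # event itself; the aligned frame removes it
  tr <- small_choice_trials(sessions = 4, decision_noise = 0.1, seed = 401)
  nz <- select_near_zero(tr)
  cons <- label_consistency(nz, seed = 1)
  smp <- sample_matrix(nz)
  ev <- ifelse(nz$category_event == "right", 1, -1)
  i <- 8
  raw_cons <- cor(smp[cons[, i], i], nz$estimate[cons[, i]])
  raw_incons <- cor(smp[!cons[, i], i], nz$estimate[!cons[, i]])
  expect_gt(raw_cons, 0.4)
  expect_lt(raw_incons, 0)
  al_cons <- cor((smp[, i] * ev)[cons[, i]], (nz$estimate * ev)[cons[, i]])
  al_incons <- cor((smp[, i] * ev)[!cons[, i]], (nz$estimate * ev)[!cons[, i]])
  expect_lt(abs(al_cons - al_incons), 0.12)
  expect_gt(al_cons, 0)
  expect_gt(al_incons, 0)
})
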