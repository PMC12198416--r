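test_that("equipopulated binning splits values into equal groups", {
  b <- equipopulated_bin(1:9, 3)
  expect_equal(b$codes, rep(1:3, each = 3))
  expect_equal(b$n_bins, 3)
  expect_length(b$edges, 4)
  # order of values, not their position, decides the bin
  b2 <- equipopulated_bin(c(9:1), 3)
  expect_equal(b2$codes, rep(3:1, each = 3))
  expect_error(equipopulated_bin(1:2, 3), "fewer values")
  expect_error(equipopulated_bin(c(1, NA, 3), 2), "finite")
})

test_that("heavy ties are split deterministically by stable rank", {
  v <- c(rep(5, 7), 1, 9) # one value repeated > n/3 times
  b <- equipopulated_bin(v, 3)
  expect_equal(tabulate(b$codes, 3), c(3, 3, 3))
  expect_identical(b$codes, equipopulated_bin(v, 3)$codes)
  # tied values straddle a bin edge in input order
  expect_equal(b$codes[8], 1L) # the smallest value is in the first bin
  expect_equal(b$codes[9], 3L)
  expect_true(all(diff(b$codes[1:7]) >= 0))
})

test_that("plug-in mutual information matches the direct formula", {
  # identity on balanced bins
  x <- rep(1:3, each = 100)
  expect_equal(mutual_information(x, x), log2(3), tolerance = 1e-12)
  # hand-evaluated 2x2 count table [[30,10],[10,30]]
  cx <- rep(c(1, 1, 2, 2), times = c(30, 10, 10, 30))
  cy <- rep(c(1, 2, 1, 2), times = c(30, 10, 10, 30))
  expect_equal(mutual_information(cx, cy), 0.1887218755408671,
               tolerance = 1e-10)
  # positive bias for independent variables, but small
  set.seed(1)
  a <- sample(1:3, 400, TRUE); b <- sample(1:3, 400, TRUE)
  expect_gt(mutual_information(a, b), 0)
  expect_lt(mutual_information(a, b), 0.05)
  expect_equal(mutual_information(a, b), mutual_information(b, a))
  expect_error(mutual_information(1:5, 1:6), "equal length")
  # random joints against the reference implementation
  set.seed(2)
  for (i in 1:5) {
    cx <- sample(1:3, 200, TRUE); cy <- sample(1:4, 200, TRUE)
    joint <- table(cx, cy) / 200
    expect_equal(mutual_information(cx, cy), mi_ref(unclass(joint)),
                 tolerance = 1e-12)
  }
})

test_that("conditional MI equals brute-force summation over slices", {
  x <- rep(1:2, 50); y <- rep(c(1, 2, 2, 1), 25); z <- rep(1, 100)
  expect_equal(conditional_mi(x, y, z), mutual_information(x, y))
  expect_equal(conditional_mi(x, y, x), 0, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    cx <- sample(1:2, 300, TRUE); cy <- sample(1:2, 300, TRUE)
    cz <- sample(1:2, 300, TRUE)
    expect_equal(conditional_mi(cx, cy, cz),
                 cmi_ref(joint3_ref(cx, cy, cz)), tolerance = 1e-12)
  }
})

test_that("shared information matches exhaustive grid search on binary systems", {
  set.seed(11)
  for (i in 1:10) {
    p <- array(runif(8)^2, c(2, 2, 2)); p <- p / sum(p)
    p_xy <- apply(p, c(1, 2), sum); p_zy <- apply(p, c(3, 2), sum)
    # sample codes whose empirical distribution is exactly p (counts of 400)
    counts <- round(p * 400)
    idx <- which(counts > 0, arr.ind = TRUE)
    cx <- rep(idx[, 1], counts[counts > 0])
    cy <- rep(idx[, 2], counts[counts > 0])
    cz <- rep(idx[, 3], counts[counts > 0])
    emp <- joint3_ref(cx, cy, cz)
    si <- shared_information(cy, cx, cz)
    orc <- si_oracle_binary(apply(emp, c(1, 2), sum), apply(emp, c(3, 2), sum))
    expect_lt(abs(as.numeric(si) - orc), 1e-4)
    expect_true(attr(si, "converged"))
  }
})

test_that("shared information matches the grid oracle with a 3-bin target", {
  set.seed(12)
  for (i in 1:3) {
    p <- array(runif(12)^2, c(2, 3, 2)); p <- p / sum(p)
    counts <- round(p * 600)
    idx <- which(counts > 0, arr.ind = TRUE)
    cx <- rep(idx[, 1], counts[counts > 0])
    cy <- rep(idx[, 2], counts[counts > 0])
    cz <- rep(idx[, 3], counts[counts > 0])
    emp <- joint3_ref(cx, cy, cz)
    si <- shared_information(cy, cx, cz)
    orc <- si_oracle_binary(apply(emp, c(1, 2), sum), apply(emp, c(3, 2), sum),
                            ngrid = 101)
    expect_lt(abs(as.numeric(si) - orc), 1e-4)
  }
})

test_that("shared and intersection information handle degenerate structure", {
  x <- rep(1:3, each = 120)
  # full redundancy: everything is the same variable
  expect_equal(as.numeric(shared_information(x, x, x)), log2(3),
               tolerance = 1e-6)
  # a source independent of target and co-source shares nothing
  set.seed(4)
  s <- sample(1:3, 900, TRUE); e <- s
  r <- sample(1:3, 900, TRUE)
  expect_lt(abs(shared_information(e, s, r)), 0.02)
  expect_lt(abs(intersection_information(s, r, e)), 0.02)
})

test_that("intersection information is bounded by all pairwise informations", {
  set.seed(13)
  for (i in 1:25) {
    n <- 240
    # random soft couplings between s, r, e
    s <- sample(1:3, n, TRUE)
    r <- ifelse(runif(n) < runif(1), s, sample(1:3, n, TRUE))
    e <- ifelse(runif(n) < runif(1), s, sample(1:3, n, TRUE))
    ii <- intersection_information(s, r, e, restarts = 2)
    expect_gte(as.numeric(ii), -1e-4)
    bound <- min(mutual_information(s, r), mutual_information(r, e),
                 mutual_information(s, e))
    expect_lte(as.numeric(ii), bound + 1e-4)
  }
  # strong chain s -> r -> e carries shared information
  set.seed(14)
  s <- sample(1:3, 2000, TRUE)
  r <- ifelse(runif(2000) < 0.9, s, sample(1:3, 2000, TRUE))
  e <- ifelse(runif(2000) < 0.9, r, sample(1:3, 2000, TRUE))
  expect_gt(as.numeric(intersection_information(s, r, e)), 0.3)
})

test_that("shuffle correction removes the limited-sampling bias", {
  set.seed(5)
  measure <- function(v) mutual_information(v$x, v$y)
  # independent variables: corrected values center on zero
  reps <- vapply(1:60, function(i) {
    x <- equipopulated_bin(rnorm(200))
    y <- equipopulated_bin(rnorm(200))
    r <- bias_corrected(measure, list(x = x, y = y), "x", n_shuffles = 100,
                        seed = i)
    expect_equal(r$value_corrected, r$value_raw - r$shuffle_mean)
    expect_gt(r$value_raw, 0)
    r$value_corrected
  }, numeric(1))
  # 3-SE bound here; the acceptance suite asserts the 2-SE criterion form
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))
  # deterministic relation: correction only removes the small bias term
  x <- equipopulated_bin(seq_len(300))
  r <- bias_corrected(measure, list(x = x, y = x), "x", n_shuffles = 50,
                      seed = 1)
  expect_equal(r$value_raw, log2(3), tolerance = 1e-10)
  expect_gt(r$value_corrected, log2(3) - 0.05)
})

test_that("one shuffle and many shuffles agree in expectation", {
  set.seed(6)
  measure <- function(v) mutual_information(v$x, v$y)
  one <- many <- numeric(30)
  for (i in 1:30) {
    x <- equipopulated_bin(rnorm(150)); y <- equipopulated_bin(rnorm(150))
    one[i] <- bias_corrected(measure, list(x = x, y = y), "x", 1,
                             seed = i)$shuffle_mean
    many[i] <- bias_corrected(measure, list(x = x, y = y), "x", 60,
                              seed = i)$shuffle_mean
  }
  expect_lt(abs(mean(one) - mean(many)), 0.004)
  expect_gt(var(one), var(many))
})

test_that("trial-count matching subsamples the larger condition", {
  set.seed(7)
  measure <- function(vars, seed) {
    bias_corrected(function(v) mutual_information(v$s, v$e),
                   list(s = equipopulated_bin(vars$s),
                        e = equipopulated_bin(vars$e)), "s", 30, seed)
  }
  gen <- function(n) {
    s <- rnorm(n)
    list(s = s, e = s + rnorm(n, 0, 2))
  }
  # equal sizes: single evaluation, no subsampling
  cmp0 <- matched_trial_compare(measure, gen(120), gen(120), seed = 1)
  expect_equal(cmp0$a$n_subsamples, 1L)
  expect_equal(cmp0$a$n_trials_used, 120L)
  # unequal sizes: both sides report the matched count
  cmp <- matched_trial_compare(measure, gen(300), gen(100), seed = 2)
  expect_equal(cmp$a$n_trials_used, 100L)
  expect_equal(cmp$b$n_trials_used, 100L)
  expect_equal(cmp$a$n_subsamples, 5L)
  # identical generative process: no systematic difference
  diffs <- vapply(1:40, function(i) {
    cmp <- matched_trial_compare(measure, gen(300), gen(100), seed = i)
    cmp$a$value_corrected - cmp$b$value_corrected
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
  # minimum-trial floor raises an exclusion condition
  expect_error(matched_trial_compare(measure, gen(80), gen(200), seed = 1),
               class = "readoutbias_exclusion")
})

test_that("corrected estimates are stable in n and across bin counts", {
  set.seed(8)
  gen <- function(n) {
    s <- rnorm(n)
    list(s = s, e = 0.8 * s + rnorm(n, 0, 1))
  }
  mi_at <- function(n, n_bins = 3, seed) {
    v <- with_seed(seed, gen(n))
    bias_corrected(function(w) mutual_information(w$s, w$e),
                   list(s = equipopulated_bin(v$s, n_bins),
                        e = equipopulated_bin(v$e, n_bins)),
                   "s", 50, seed)$value_corrected
  }
  asymptotic <- mean(vapply(1:4, function(i) mi_at(6000, seed = i), numeric(1)))
  small_n <- mean(vapply(1:10, function(i) mi_at(200, seed = 100 + i),
                         numeric(1)))
  expect_equal(small_n, asymptotic, tolerance = 0.12)
  # qualitative stability: condition ordering is preserved across bin counts
  strong <- with_seed(21, { s <- rnorm(1500); list(s = s, e = s + rnorm(1500, 0, 1)) })
  weak <- with_seed(22, { s <- rnorm(1500); list(s = s, e = 0.3 * s + rnorm(1500, 0, 1)) })
  for (nb in c(3, 5, 7, 9)) {
    mi_strong <- mutual_information(equipopulated_bin(strong$s, nb),
                                    equipopulated_bin(strong$e, nb))
    mi_weak <- mutual_information(equipopulated_bin(weak$s, nb),
                                  equipopulated_bin(weak$e, nb))
    expect_gt(mi_strong, mi_weak)
  }
})
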