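#' Paired two-sided permutation test
#'
#' Sign-flip permutation test of the mean paired difference. The two-sided
#' p-value is `min(1, 2 * min(upper tail, lower tail))` with add-one
#' smoothing, so p-values respect the `1/(n_perm + 1)` resolution floor.
#'
#' @param a,b paired per-participant values (equal length), or `b = NULL` to
#'   test `a` against zero.
#' @param n_perm number of permutations (default 2000).
#' @param seed integer seed.
#' @return A `perm_test`: observed mean difference, p-value, null
#'   distribution.
#' @export
paired_permutation <- function(a, b = NULL, n_perm = 2000L, seed = NULL) {
  d <- if (is.null(b)) a else a - b
  obs <- mean(d)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE))
    }, numeric(1))
  })
  p_hi <- (1 + sum(null >= obs)) / (n_perm + 1)
  p_lo <- (1 + sum(null <= obs)) / (n_perm + 1)
  structure(list(observed = obs, p_value = min(1, 2 * min(p_hi, p_lo)),
                 null = null, n_perm = n_perm),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %.4g, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  if (!is.null(x$clusters)) {
    cat(sprintf("  %d cluster(s):\n", nrow(x$clusters)))
    print.data.frame(x$clusters, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Cluster-based permutation test on time courses
#'
#' One-sample test of per-participant time courses against zero, correcting
#' for multiple comparisons across time: timepoints exceeding the two-sided
#' t threshold at `threshold_p` are grouped into contiguous clusters whose
#' mass is the sum of t-values; the null distribution of the maximum
#' absolute cluster mass is built by randomly sign-flipping participants.
#'
#' @param timecourses matrix `participants x timepoints`.
#' @param threshold_p cluster-forming threshold (default 0.01).
#' @param n_perm number of permutations (default 2000).
#' @param seed integer seed.
#' @return A `perm_test` with a `clusters` data frame (start, end, mass,
#'   p_value) and the timepoint t-values.
#' @export
cluster_permutation_time <- function(timecourses, threshold_p = 0.01,
                                     n_perm = 2000L, seed = NULL) {
  tc <- as.matrix(timecourses)
  n <- nrow(tc)
  assert_that(n >= 2, "need at least two participants")
  tcrit <- qt(1 - threshold_p / 2, df = n - 1)
  tvals_of <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(n)
    ifelse(se > 0, mu / se, 0)
  }
  find_clusters <- function(tv) {
    supra <- abs(tv) > tcrit
    if (!any(supra)) return(NULL)
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(keep, function(i) {
                 sum(tv[starts[i]:ends[i]])
               }, numeric(1)))
  }
  tv <- tvals_of(tc)
  clusters <- find_clusters(tv)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      cl <- find_clusters(tvals_of(tc * flip))
      if (is.null(cl)) 0 else max(abs(cl$mass))
    }, numeric(1))
  })
  if (!is.null(clusters)) {
    clusters$p_value <- vapply(clusters$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
  }
  structure(list(observed = if (is.null(clusters)) 0 else
                   max(abs(clusters$mass)),
                 p_value = if (is.null(clusters)) 1 else min(clusters$p_value),
                 clusters = clusters, t_values = tv, t_threshold = tcrit,
                 null = null_max, n_perm = n_perm),
            class = "perm_test")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control across a family of p-values.
#'
#' @param p_values numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` p-values and logical `rejected` decisions.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj <= q, q = q)
}

#' JZS Bayes factor for a paired (one-sample) t-test
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor BF10 computed from the
#' paired t-statistic, with a Cauchy prior of scale `rscale` on effect size.
#' Values between 0.3 and 0.1 are conventionally read as strong support for
#' the null, below 0.1 as decisive.
#'
#' @param a,b paired samples (`b` optional: one-sample test of `a`), or pass
#'   `t` and `n` directly.
#' @param t,n t-statistic and sample size (alternative interface).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return BF10 (support for the alternative over the null).
#' @export
bayes_factor_paired_t <- function(a = NULL, b = NULL, t = NULL, n = NULL,
                                  rscale = sqrt(2) / 2) {
  if (is.null(t)) {
    d <- if (is.null(b)) a else a - b
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
  }
  nu <- n - 1
  null_lik <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g * rscale^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * rscale^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt_lik <- integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  alt_lik / null_lik
}

#' Fibonacci lattice on the unit sphere
#'
#' Near-uniform arrangement of `n` points on the sphere, used as synthetic
#' parcel coordinates for spin permutation tests.
#'
#' @param n number of points (default 180).
#' @return Matrix `n x 3` of unit vectors.
#' @export
fibonacci_sphere <- function(n = 180L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# uniform random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin permutation test for the correlation of two spatial maps
#'
#' Tests the Pearson correlation between two per-parcel maps against a null
#' that preserves spatial autocorrelation: the parcel coordinates of the
#' first map are randomly rotated on the sphere and parcels are reassigned
#' values by a greedy nearest-neighbor matching between original and rotated
#' positions (a bijection, so each null map is a permutation of the original
#' values). Naive parametric p-values are anticonservative for spatially
#' smooth maps; the spin null is calibrated.
#'
#' @param map_a,map_b numeric per-parcel values (equal length).
#' @param coords `n x 3` matrix of unit-sphere parcel coordinates (default: a
#'   Fibonacci lattice).
#' @param n_rot number of random rotations (default 10000).
#' @param seed integer seed.
#' @return A `perm_test` with the observed correlation, two-sided p-value and
#'   the null correlations.
#' @export
spin_permutation_correlation <- function(map_a, map_b,
                                         coords = fibonacci_sphere(length(map_a)),
                                         n_rot = 10000L, seed = NULL) {
  n <- length(map_a)
  assert_that(length(map_b) == n && nrow(coords) == n,
              "maps and coordinates must have matching length")
  coords <- coords / sqrt(rowSums(coords^2))
  obs <- cor(map_a, map_b)
  null <- with_seed(seed, {
    vapply(seq_len(n_rot), function(i) {
      rot <- coords %*% random_rotation()
      dots <- coords %*% t(rot) # [original, rotated]
      perm <- greedy_match(dots)
      cor(map_a[perm], map_b)
    }, numeric(1))
  })
  p_hi <- (1 + sum(null >= obs)) / (n_rot + 1)
  p_lo <- (1 + sum(null <= obs)) / (n_rot + 1)
  structure(list(observed = obs, p_value = min(1, 2 * min(p_hi, p_lo)),
                 null = null, n_perm = n_rot),
            class = "perm_test")
}

# greedy bijective matching maximizing total similarity: repeatedly take the
# highest-similarity unassigned (original, rotated) pair
greedy_match <- function(similarity) {
  n <- nrow(similarity)
  ord <- order(similarity, decreasing = TRUE)
  perm <- integer(n)
  used_row <- logical(n); used_col <- logical(n)
  assigned <- 0L
  for (idx in ord) {
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    if (!used_row[i] && !used_col[j]) {
      perm[i] <- j
      used_row[i] <- TRUE; used_col[j] <- TRUE
      assigned <- assigned + 1L
      if (assigned == n) break
    }
  }
  perm
}

#' Two-factorial repeated-measures ANOVA interaction
#'
#' Tests the condition-by-strength interaction with a repeated-measures
#' ANOVA (participant as error stratum) and reports the interaction F, its
#' partial eta squared, and a confidence interval for eta_p^2 based on a
#' jackknife standard error over participants
#' (point estimate +/- t_crit * SE).
#'
#' @param values numeric outcome.
#' @param participant,condition,strength factors of equal length; every
#'   participant must contribute all condition-by-strength cells.
#' @param conf_level confidence level (default 0.95).
#' @return List with `F`, `df`, `p_value`, `eta_p_sq`, `ci`.
#' @export
anova_interaction <- function(values, participant, condition, strength,
                              conf_level = 0.95) {
  df <- data.frame(y = values, id = factor(participant),
                   cond = factor(condition), str = factor(strength))
  if (var(values) == 0) {
    return(list(F = NA_real_, df = c(NA, NA), p_value = NA_real_,
                eta_p_sq = 0, ci = c(0, 0)))
  }
  eta_of <- function(d) {
    fit <- aov(y ~ cond * str + Error(id / (cond * str)), data = d)
    strat <- summary(fit)[["Error: id:cond:str"]][[1]]
    ss <- strat[, "Sum Sq"]
    int_row <- grep("cond:str", rownames(strat))
    res_row <- grep("Residuals", rownames(strat))
    list(F = strat[int_row, "F value"], df = strat[c(int_row, res_row), "Df"],
         p = strat[int_row, "Pr(>F)"],
         eta = ss[int_row] / (ss[int_row] + ss[res_row]))
  }
  full <- tryCatch(eta_of(df), error = function(e) NULL)
  if (is.null(full) || !is.finite(full$eta)) {
    return(list(F = NA_real_, df = c(NA, NA), p_value = NA_real_,
                eta_p_sq = 0, ci = c(0, 0)))
  }
  ids <- levels(df$id)
  jack <- vapply(ids, function(i) {
    r <- tryCatch(eta_of(df[df$id != i, ])$eta, error = function(e) NA_real_)
    r
  }, numeric(1))
  jack <- jack[is.finite(jack)]
  m <- length(jack)
  se <- if (m >= 2) sqrt((m - 1) / m * sum((jack - mean(jack))^2)) else NA_real_
  tcrit <- qt(1 - (1 - conf_level) / 2, df = max(m - 1, 1))
  ci <- if (is.finite(se)) full$eta + c(-1, 1) * tcrit * se else c(NA, NA)
  list(F = full$F, df = full$df, p_value = full$p, eta_p_sq = full$eta,
       ci = ci)
}
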