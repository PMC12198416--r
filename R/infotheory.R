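#' Discretize a continuous variable into equipopulated bins
#'
#' Quantile-based discretization giving (near-)equal trial counts per bin,
#' which maximizes the marginal entropy for a given number of bins. Bin
#' membership is assigned by the stable rank of each value (ties broken by
#' position in the vector), so bin counts are equal up to a remainder of at
#' most one even under ties - tied values may then straddle a bin edge. The
#' quantile edges are stored for provenance. Deterministic.
#'
#' @param values numeric vector (finite values required).
#' @param n_bins number of bins (default 3, the package-wide default).
#' @return An object of class `discretized_var`: list with integer `codes`
#'   in `1..n_bins`, numeric `edges` (length `n_bins + 1`), and `n_bins`.
#' @export
#' @examples
#' equipopulated_bin(1:9, 3)$codes
equipopulated_bin <- function(values, n_bins = 3L) {
  n_bins <- as.integer(n_bins)
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  if (any(!is.finite(values))) stop_config("values must be finite")
  n <- length(values)
  if (n < n_bins) stop_config("fewer values (", n, ") than bins (", n_bins, ")")
  r <- rank(values, ties.method = "first")
  codes <- as.integer(ceiling(r * n_bins / n))
  edges <- unname(quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7))
  structure(list(codes = codes, edges = edges, n_bins = n_bins),
            class = "discretized_var")
}

#' @export
print.discretized_var <- function(x, ...) {
  cat(sprintf("Discretized variable: %d trials in %d equipopulated bins\n",
              length(x$codes), x$n_bins))
  cat("  counts:", paste(tabulate(x$codes, x$n_bins), collapse = " "), "\n")
  invisible(x)
}

# accept discretized_var, factor, or integer codes; return integer codes
as_codes <- function(x) {
  if (inherits(x, "discretized_var")) return(x$codes)
  if (is.factor(x)) return(as.integer(x))
  if (is.numeric(x) && all(x == round(x))) return(as.integer(x))
  stop_config("expected a discretized_var or integer codes; ",
              "use equipopulated_bin() for continuous values")
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in mutual information between two discrete variables
#'
#' Direct-method estimate: the joint distribution is estimated by counting
#' occurrences of each value pair across trials, and
#' `I(X;Y) = sum p(x,y) log2[ p(x,y) / (p(x) p(y)) ]`. The plug-in estimate
#' carries a positive limited-sampling bias; see [bias_corrected()].
#'
#' @param x,y `discretized_var`s or integer code vectors of equal length.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  cx <- as_codes(x); cy <- as_codes(y)
  if (length(cx) != length(cy)) stop_config("x and y must have equal length")
  joint <- table(cx, cy) / length(cx)
  px <- rowSums(joint); py <- colSums(joint)
  entropy_bits(px) + entropy_bits(py) - entropy_bits(as.vector(joint))
}

#' Plug-in conditional mutual information
#'
#' `I(X;Y | Z) = sum_z p(z) I(X;Y | Z = z)`, each slice estimated by the
#' direct method.
#'
#' @param x,y,z `discretized_var`s or integer code vectors of equal length.
#' @return Conditional mutual information in bits.
#' @export
conditional_mi <- function(x, y, z) {
  cx <- as_codes(x); cy <- as_codes(y); cz <- as_codes(z)
  if (length(cx) != length(cy) || length(cx) != length(cz)) {
    stop_config("x, y and z must have equal length")
  }
  n <- length(cx)
  out <- 0
  for (zv in unique(cz)) {
    idx <- cz == zv
    out <- out + (sum(idx) / n) * mutual_information(cx[idx], cy[idx])
  }
  out
}

# empirical pairwise marginals p(source, target) as a matrix [source, target]
pair_table <- function(source, target, ns, nt) {
  tab <- matrix(0, ns, nt)
  counts <- table(factor(source, levels = seq_len(ns)),
                  factor(target, levels = seq_len(nt)))
  tab[] <- counts / length(source)
  tab
}

#' Shared information about a target carried by two sources
#'
#' `SI(Y; {A, B})`, the maximum shared dependency between the sources `A`
#' and `B` with respect to target `Y`: the maximum over all joint
#' distributions `q(a, y, b)` that preserve the observed pairwise marginals
#' `p(a, y)` and `p(b, y)` of the co-information
#' `I_q(A;Y) - I_q(A;Y|B)`. On the feasible set `I_q(A;Y)` and `H_q(Y|B)`
#' are fixed, so the search reduces to a concave maximization of
#' `H_q(Y|A,B)` over a product of per-target-slice transportation polytopes,
#' solved by projected gradient ascent with random restarts (see package
#' vignette for numerical details). Non-convergence is flagged via the
#' `converged` attribute and a warning, never silently.
#'
#' @param target,a,b `discretized_var`s or integer code vectors of equal
#'   length.
#' @param restarts number of random restarts (first start is the
#'   conditional-independence coupling).
#' @param maxit maximum gradient iterations per restart.
#' @param tol convergence tolerance on the objective change (bits).
#' @return Shared information in bits, with attributes `converged` and
#'   `iterations`.
#' @export
shared_information <- function(target, a, b, restarts = 10L, maxit = 2000L,
                               tol = 1e-8) {
  cy <- as_codes(target); ca <- as_codes(a); cb <- as_codes(b)
  if (length(cy) != length(ca) || length(cy) != length(cb)) {
    stop_config("target, a and b must have equal length")
  }
  # map codes to consecutive 1..k alphabets
  cy <- match(cy, sort(unique(cy)))
  ca <- match(ca, sort(unique(ca)))
  cb <- match(cb, sort(unique(cb)))
  na <- max(ca); nb <- max(cb); ny <- max(cy)
  p_ay <- pair_table(ca, cy, na, ny)
  p_by <- pair_table(cb, cy, nb, ny)
  sol <- si_solver_cpp(p_ay, p_by, restarts = as.integer(restarts),
                       maxit = as.integer(maxit), tol = tol * log(2))
  if (!isTRUE(sol$converged)) {
    warning("shared_information solver did not converge; result is flagged")
  }
  py <- colSums(p_ay)
  h_y_given_b <- entropy_bits(as.vector(p_by)) - entropy_bits(rowSums(p_by))
  i_ay <- mutual_information(ca, cy)
  si <- i_ay - h_y_given_b + sol$h_y_given_xz / log(2)
  structure(si, converged = sol$converged, iterations = sol$iterations)
}

#' Intersection information II(S; R; E)
#'
#' The part of the stimulus information encoded in the neural response `R`
#' that is also used for the behavioral report `E`:
#' `II = min[ SI(E; {S, R}), SI(S; {E, R}) ]`. Taking the minimum of the two
#' shared-information terms makes II non-negative (up to solver tolerance)
#' and bounded by each of `I(S;R)`, `I(R;E)` and `I(S;E)`.
#'
#' @param s,r,e `discretized_var`s or integer code vectors: stimulus, neural
#'   response, estimation report.
#' @param ... passed to [shared_information()].
#' @return Intersection information in bits, with attribute `converged`.
#' @export
intersection_information <- function(s, r, e, ...) {
  si_e <- shared_information(e, s, r, ...)
  si_s <- shared_information(s, e, r, ...)
  structure(min(si_e, si_s),
            converged = attr(si_e, "converged") && attr(si_s, "converged"))
}

#' Bias-corrected information result
#'
#' Constructs an `info_result`: a raw plug-in information value together
#' with its shuffle-based limited-sampling correction,
#' `value_corrected = value_raw - shuffle_mean`, where `shuffle_mean` is the
#' average of the measure recomputed after permuting one task variable
#' across trials `n_shuffles` times. No floor at zero is imposed: corrected
#' values may be slightly negative, and significance is left to the
#' inference layer.
#'
#' @param measure function taking a named list of code vectors and returning
#'   a value in bits, e.g. `function(v) mutual_information(v$s, v$e)`.
#' @param vars named list of `discretized_var`s or code vectors, all of
#'   equal length.
#' @param shuffle_var name (or index) of the variable in `vars` to permute.
#'   For intersection information the stimulus is shuffled, which destroys
#'   both the S-R and S-E dependencies.
#' @param n_shuffles number of permutations (100 for consistency analyses,
#'   20 for overview maps).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `info_result`.
#' @export
#' @examples
#' s <- equipopulated_bin(rnorm(300))
#' e <- equipopulated_bin(rnorm(300))
#' bias_corrected(function(v) mutual_information(v$s, v$e),
#'                list(s = s, e = e), "s", n_shuffles = 20, seed = 1)
bias_corrected <- function(measure, vars, shuffle_var, n_shuffles = 100L,
                           seed = NULL) {
  vars <- lapply(vars, as_codes)
  n <- unique(lengths(vars))
  assert_that(length(n) == 1L, "all variables must have equal length")
  raw <- measure(vars)
  shuffled <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      v <- vars
      v[[shuffle_var]] <- sample(v[[shuffle_var]])
      measure(v)
    }, numeric(1))
  })
  info_result(value_raw = raw, shuffle_mean = mean(shuffled),
              n_shuffles = n_shuffles, n_trials_used = n)
}

#' @rdname bias_corrected
#' @param value_raw,shuffle_mean,n_shuffles,n_trials_used,n_subsamples
#'   components of the result; `value_corrected` is always
#'   `value_raw - shuffle_mean`.
#' @export
info_result <- function(value_raw, shuffle_mean = 0, n_shuffles = 0L,
                        n_trials_used = NA_integer_, n_subsamples = 1L) {
  structure(list(value_corrected = value_raw - shuffle_mean,
                 value_raw = value_raw,
                 shuffle_mean = shuffle_mean,
                 n_shuffles = as.integer(n_shuffles),
                 n_subsamples = as.integer(n_subsamples),
                 n_trials_used = as.integer(n_trials_used)),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("Information: %.4f bits (raw %.4f - shuffle mean %.4f; %d shuffles, %d subsample(s), n = %d)\n",
              x$value_corrected, x$value_raw, x$shuffle_mean, x$n_shuffles,
              x$n_subsamples, x$n_trials_used))
  invisible(x)
}

# average a list of info_results (used for subsample averaging)
average_info_results <- function(results, n_trials_used) {
  info_result(
    value_raw = mean(vapply(results, `[[`, numeric(1), "value_raw")),
    shuffle_mean = mean(vapply(results, `[[`, numeric(1), "shuffle_mean")),
    n_shuffles = results[[1]]$n_shuffles,
    n_trials_used = n_trials_used,
    n_subsamples = length(results))
}

#' Compare an information measure between conditions at matched trial counts
#'
#' Residual estimation bias depends on the number of trials, so conditions
#' are never compared at unequal counts: the larger condition is randomly
#' subsampled to the smaller one's count and the measure averaged over
#' `n_subsamples` draws. Computations with fewer than `min_trials` trials on
#' either side are refused (raised as a condition of class
#' `readoutbias_exclusion`), mirroring the minimum-trial floor used for
#' consistency analyses.
#'
#' @param measure function `(vars, seed) -> info_result`, where `vars` is a
#'   named list of numeric vectors; typically it bins its inputs and calls
#'   [bias_corrected()].
#' @param vars_a,vars_b named lists of equal-length numeric vectors, one per
#'   condition.
#' @param n_subsamples number of random subsample draws (default 5).
#' @param min_trials minimum trials required on both sides (default 81).
#' @param seed integer seed.
#' @return List with `info_result`s `a` and `b`, both carrying the same
#'   `n_trials_used`.
#' @export
matched_trial_compare <- function(measure, vars_a, vars_b, n_subsamples = 5L,
                                  min_trials = 81L, seed = NULL) {
  take <- function(v, idx) if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  na <- unique(vapply(vars_a, NROW, integer(1)))
  nb <- unique(vapply(vars_b, NROW, integer(1)))
  assert_that(length(na) == 1L && length(nb) == 1L,
              "variables within a condition must have equal length")
  if (na < min_trials || nb < min_trials) {
    stop(structure(
      class = c("readoutbias_exclusion", "error", "condition"),
      list(message = sprintf(
        "trial counts (%d, %d) below the minimum of %d for matched comparison",
        na, nb, min_trials), call = sys.call())))
  }
  n <- min(na, nb)
  eval_side <- function(vars, n_full, side) {
    if (n_full == n) {
      return(measure(vars, child_seed(seed %||% 0L, paste0("measure_", side))))
    }
    subs <- lapply(seq_len(n_subsamples), function(i) {
      idx <- with_seed(child_seed(seed %||% 0L, paste0("subsample_", side), i),
                       sample(n_full, n))
      measure(lapply(vars, take, idx),
              child_seed(seed %||% 0L, paste0("measure_", side), i))
    })
    average_info_results(subs, n)
  }
  a <- eval_side(vars_a, na, "a")
  b <- eval_side(vars_b, nb, "b")
  a$n_trials_used <- n; b$n_trials_used <- n
  list(a = a, b = b)
}
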