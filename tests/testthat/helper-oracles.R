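# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain-formula information measures and an
# exhaustive grid search over the shared-information coupling polytope.

h_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# plug-in MI from a joint probability matrix, straight from the definition
mi_ref <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      if (joint[i, j] > 0) {
        s <- s + unname(joint[i, j] * log2(joint[i, j] / (px[i] * py[j])))
      }
    }
  }
  s
}

# conditional MI by direct summation over slices of a joint [x, y, z] array
cmi_ref <- function(pxyz) {
  s <- 0
  for (z in seq_len(dim(pxyz)[3])) {
    pz <- sum(pxyz[, , z])
    if (pz > 0) s <- s + pz * mi_ref(pxyz[, , z] / pz)
  }
  s
}

# SI(Y; {X, Z}) by exhaustive grid search for binary X and Z: each target
# slice of the coupling polytope has one free parameter (the (1,1) cell)
si_oracle_binary <- function(p_xy, p_zy, ngrid = 301) {
  ny <- ncol(p_xy)
  py <- colSums(p_xy)
  grids <- lapply(seq_len(ny), function(y) {
    lo <- max(0, p_xy[1, y] + p_zy[1, y] - py[y])
    hi <- min(p_xy[1, y], p_zy[1, y])
    seq(lo, hi, length.out = ngrid)
  })
  # slice cells as functions of the free parameter t
  cells <- function(y, t) {
    cbind(t, p_xy[1, y] - t, p_zy[1, y] - t,
          py[y] - p_xy[1, y] - p_zy[1, y] + t)
  }
  hx <- function(m) { # rowwise entropy of a matrix of probabilities
    m2 <- m
    m2[m2 <= 0] <- 1
    -rowSums(m * log2(m2))
  }
  idx <- as.matrix(expand.grid(lapply(seq_len(ny), function(y) seq_len(ngrid))))
  hxyz <- 0
  qxz <- matrix(0, nrow(idx), 4)
  for (y in seq_len(ny)) {
    cy <- cells(y, grids[[y]])
    hxyz <- hxyz + hx(cy)[idx[, y]]
    qxz <- qxz + cy[idx[, y], , drop = FALSE]
  }
  h_y_given_xz <- max(hxyz - hx(qxz))
  i_xy <- h_bits(rowSums(p_xy)) + h_bits(py) - h_bits(as.vector(p_xy))
  h_y_given_z <- h_bits(as.vector(p_zy)) - h_bits(rowSums(p_zy))
  i_xy - h_y_given_z + h_y_given_xz
}

# Simpson-rule evaluation of the JZS Bayes-factor integral (independent of
# stats::integrate)
bf_oracle <- function(t, n, rscale = sqrt(2) / 2, steps = 2e5) {
  nu <- n - 1
  f <- function(g) {
    (1 + n * g * rscale^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * rscale^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  # substitute g = u / (1 - u) to map (0, Inf) onto (0, 1); Simpson rule
  u <- seq(1e-9, 1 - 1e-9, length.out = steps + 1)
  fu <- f(u / (1 - u)) / (1 - u)^2
  w <- rep(c(4, 2), length.out = steps - 1)
  integral <- (u[2] - u[1]) / 3 * sum(c(1, w, 1) * fu)
  integral / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# empirical joint [x, y, z] probability array from code vectors
joint3_ref <- function(cx, cy, cz, nx = max(cx), ny = max(cy), nz = max(cz)) {
  arr <- array(0, c(nx, ny, nz))
  for (i in seq_along(cx)) {
    arr[cx[i], cy[i], cz[i]] <- arr[cx[i], cy[i], cz[i]] + 1
  }
  arr / length(cx)
}

# small simulated task + observer shared across tests
small_choice_trials <- function(sessions = 2, decision_noise = 0.1,
                                seed = 101, conditions = "Choice") {
  cfg <- task_config(sessions_per_condition = sessions, rng_seed = seed)
  tr <- generate_trials(cfg, conditions)
  simulate_observer(tr, observer_config(decision_noise = decision_noise),
                    seed = seed + 1)
}
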