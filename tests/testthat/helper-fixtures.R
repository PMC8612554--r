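# Shared fixtures and small utilities for the test suite.

# a reproducible random rigid transform (rotation + translation)
random_rigid_transform <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_dec <- qr(m)
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(coords, tf) {
  sweep(coords %*% t(tf$R), 2, tf$t, "+")
}

# 99% sampling interval for an occupancy estimated from a two-state Markov
# chain with switching scale s: the lag-1 autocorrelation is (1 - s), which
# inflates the binomial variance by (1 + lambda) / (1 - lambda)
markov_interval_99 <- function(p, n, switch_prob) {
  lambda <- 1 - switch_prob
  n_eff <- n * (1 - lambda) / (1 + lambda)
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n_eff)
  c(p - half, p + half)
}

binom_interval_99 <- function(p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

# independent point-in-polygon oracle (ray casting) for the rectangle test
point_in_polygon <- function(pt, corners) {
  n <- nrow(corners)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- corners[i, 1]; yi <- corners[i, 2]
    xj <- corners[j, 1]; yj <- corners[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

make_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_complex()
    cache
  }
})

single_frame_traj <- function(toy) {
  trajectory(array(toy$reference, c(1, nrow(toy$reference), 3)),
             toy$topology)
}
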