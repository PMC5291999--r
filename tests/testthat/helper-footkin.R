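# Shared fixtures and independent oracles, built in code.

quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Horn's closed-form quaternion absolute orientation: rotation mapping the
# (centered) reference cluster onto the (centered) observed cluster.
# Independent of the SVD route used by the package.
horn_rotation <- function(reference, frame) {
  A <- sweep(reference, 2, colMeans(reference))
  B <- sweep(frame, 2, colMeans(frame))
  S <- crossprod(A, B)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  quat_to_mat(q)
}

random_rotation <- function(max_mid = 85) {
  cardan_compose(stats::runif(1, -170, 170),
                 stats::runif(1, -max_mid, max_mid),
                 stats::runif(1, -170, 170))
}

random_cluster <- function(n = 4, spread = 60) {
  m <- matrix(stats::runif(n * 3, -spread, spread), n, 3)
  # re-draw degenerate clusters
  while (svd(sweep(m, 2, colMeans(m)))$d[2] < 1) {
    m <- matrix(stats::runif(n * 3, -spread, spread), n, 3)
  }
  m
}

# harmonic channel evaluated independently of the package implementation
raw_harmonic <- function(u, amp, phase, offset = 0) {
  y <- rep(offset, length(u))
  for (k in seq_along(amp)) {
    y <- y + amp[k] * cos(2 * pi * k * (u - phase[k]))
  }
  y
}

symmetric_leg_points <- function() {
  pts <- rbind(c(40, 0, 0), c(-40, 0, 0), c(50, 0, 400), c(-50, 0, 400))
  rownames(pts) <- c("med_malleolus", "lat_malleolus", "med_knee",
                     "lat_knee")
  pts
}

# a small walking waveform set with known solved extrema
demo_waveforms <- function(targets = c(ever = -4, df = 6, hallux = 44),
                           stance_fraction = 0.62, cycle_duration = 1.1) {
  base <- footkin:::participant_waveforms(targets, stance_fraction,
                                          cycle_duration)
  angle_waveforms(base$params, stance_fraction, cycle_duration)
}
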