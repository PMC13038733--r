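# Brute-force circular-statistics oracle: explicit per-element
# accumulation, independent of the package's vectorized implementation.
oracle_resultant <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  C <- 0; S <- 0; W <- 0
  for (i in seq_along(angles)) {
    rad <- angles[i] * pi / 180
    C <- C + weights[i] * cos(rad)
    S <- S + weights[i] * sin(rad)
    W <- W + weights[i]
  }
  r <- sqrt(C * C + S * S) / W
  mu <- (atan2(S, C) * 180 / pi) %% 360
  list(mean_direction = mu, r = r)
}

oracle_phi_max <- function(angles, periodicity) {
  a <- angles
  if (periodicity == 180) a <- (2 * a) %% 360
  res <- oracle_resultant(a)
  phi <- res$mean_direction
  if (periodicity == 180) phi <- ((phi %% 360) / 2) %% 180
  list(phi_max = phi, r = res$r)
}

# smallest angular difference, signed magnitude only
axial_err <- function(a, b, periodicity = 180) {
  d <- (a - b) %% periodicity
  min(d, periodicity - d)
}

# quick deterministic spike train: spikes placed at given stimulus angles
# within a cw segment of the given velocity
spikes_at_angles <- function(angles, segment) {
  s <- if (segment$direction == "cw") 1 else -1
  dt <- ((s * (angles - segment$start_angle)) %% 360) / segment$angular_velocity
  spike_train(segment$start_time + dt)
}
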