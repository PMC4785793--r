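# Build a one-row landmark table with prescribed head-head (hh) and
# head-hinge (g1, g2) distances: hinge at the origin, head1 on the +x axis,
# head2 placed by the law of cosines.  NA for g1/g2/hh marks the
# corresponding landmark(s) missing.
frame_with_distances <- function(g1, g2, hh, frame_id = 0L, time_s = 0) {
  if (any(is.na(c(g1, g2, hh)))) {
    return(dimer_frames(frame_id, time_s,
                        head1 = c(if (is.na(g1)) NA else g1, 0),
                        head2 = c(NA, NA), hinge = c(0, 0)))
  }
  cosphi <- (g1^2 + g2^2 - hh^2) / (2 * g1 * g2)
  stopifnot(abs(cosphi) <= 1 + 1e-12)
  phi <- acos(min(1, max(-1, cosphi)))
  dimer_frames(frame_id, time_s,
               head1 = c(g1, 0),
               head2 = g2 * c(cos(phi), sin(phi)),
               hinge = c(0, 0))
}

# Apply a random rigid motion (rotation + translation, optionally a
# reflection) to every landmark of a frame table.
apply_rigid_motion <- function(frames, angle, shift, reflect = FALSE) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  if (reflect) R <- R %*% diag(c(1, -1))
  out <- frames
  for (lm in c("head1", "head2", "hinge")) {
    xy <- as.matrix(frames[, paste0(lm, c("_x_nm", "_y_nm"))])
    new <- t(R %*% t(xy)) + matrix(shift, nrow(xy), 2, byrow = TRUE)
    out[[paste0(lm, "_x_nm")]] <- new[, 1]
    out[[paste0(lm, "_y_nm")]] <- new[, 2]
  }
  out
}

# Straight polyline of given length from the origin along direction theta
straight_arm <- function(length, theta, step = 0.5) {
  s <- seq(0, length, by = step)
  cbind(x = s * cos(theta), y = s * sin(theta))
}

# Moments of a N(mean, sd^2) truncated to [0, Inf)
truncnorm0_moments <- function(mean, sd) {
  a <- -mean / sd
  lambda <- dnorm(a) / (1 - pnorm(a))
  m <- mean + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  c(mean = m, sd = sqrt(v))
}
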