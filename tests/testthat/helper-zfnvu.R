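# Greedy one-to-one matching of detected peak times to true event times.
match_peaks <- function(peaks, truth, tol) {
  used <- rep(FALSE, length(peaks))
  tp <- 0L
  for (et in truth) {
    d <- abs(peaks - et)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# Independent brute-force oracle for the minimum enclosing ellipse: direct
# parametric minimisation of the area over (centre, orientation, aspect),
# with the scale fixed by the farthest point. Multi-start Nelder-Mead.
oracle_ellipse_area <- function(P, n_starts = 24) {
  P <- as.matrix(P)
  spread <- mean(apply(P, 2, sd))
  obj <- function(par) {
    cx <- par[1]; cy <- par[2]; th <- par[3]; k <- exp(par[4])
    u <- (P[, 1] - cx) * cos(th) + (P[, 2] - cy) * sin(th)
    v <- -(P[, 1] - cx) * sin(th) + (P[, 2] - cy) * cos(th)
    pi * max(u^2 + (v / k)^2) * k
  }
  ctr <- colMeans(P)
  ev <- eigen(cov(P))
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  k0 <- log(sqrt(max(ev$values[2], 1e-12) / ev$values[1]))
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1) c(ctr, ang, k0)
            else c(ctr + rnorm(2, 0, 0.3 * spread),
                   runif(1, -pi / 2, pi / 2),
                   k0 + rnorm(1, 0, 0.7))
    fit <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    # polish from the incumbent
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Trajectory with scripted zones and speeds: each schedule row gives a
# duration (s), a zone ("light" = x < 0) and a speed (mm/s); dt = 1 s.
# Speed is realised by alternating y displacement inside the fixed zone x.
scripted_trajectory <- function(schedule, well = well_geometry()) {
  t <- 0; x <- numeric(0); y <- numeric(0); tt <- numeric(0)
  up <- 1
  for (i in seq_len(nrow(schedule))) {
    n <- schedule$duration[i]
    xi <- if (schedule$zone[i] == "light") -5 else 5
    for (j in seq_len(n)) {
      tt <- c(tt, t)
      x <- c(x, xi)
      y <- c(y, if (length(y)) y[length(y)] + up * schedule$speed[i] else 0)
      up <- -up
      t <- t + 1
    }
  }
  # clamp y inside the well by construction: speeds used are <= 8 mm/s and
  # alternate, so y stays within [-8, 8]
  trajectory(t = tt, x = x, y = y, well = well, tol_mm = 2)
}
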