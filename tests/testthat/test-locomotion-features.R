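test_that("instantaneous speeds are displacement over time", {
  tr <- trajectory(t = 0:2, x = c(0, 7, 7), y = c(0, 0, 0))
  expect_equal(instantaneous_speeds(tr), c(7, 0))
  # uniform circular motion: closed-form chord speed
  r <- 5; theta <- 0.3; dt <- 0.5
  ang <- theta * (0:20)
  tr2 <- trajectory(t = dt * (0:20), x = r * cos(ang), y = r * sin(ang))
  expect_equal(instantaneous_speeds(tr2),
               rep(2 * r * sin(theta / 2) / dt, 20), tolerance = 1e-12)
})

test_that("speed classes use the half-open tracker bands", {
  cls <- classify_speed(c(3.2, 6.4, 4.8, 0, 3.3, 6.3999))
  expect_equal(as.character(cls),
               c("inactive", "high", "low", "inactive", "low", "low"))
  expect_error(classify_speed(-1), "negative")
})

test_that("time budgets reproduce a hand-computed piecewise schedule", {
  # 3 minutes: min1 light@7 (high), min2 dark@2 (inactive),
  # min3: 30 s light@4 (low), 30 s dark@4 (low)
  # one extra dark point so the third bin holds a full 60 intervals
  sched <- tibble::tibble(duration = c(60, 60, 30, 31),
                          zone = c("light", "dark", "light", "dark"),
                          speed = c(7, 2, 4, 4))
  tr <- scripted_trajectory(sched)
  well <- well_geometry()
  labels <- assign_zone(tr, well)
  classes <- classify_speed(instantaneous_speeds(tr))
  b <- time_budgets(tr, labels, classes, bin_s = 60)
  # bins: 100%, 0%, 50% light -> mean 50%
  expect_equal(b$pct_time_light, 50)
  li <- b$zones[b$zones$zone == "light", ]
  da <- b$zones[b$zones$zone == "dark", ]
  # light bins: min1 all high; min3 light half: 29 s low + 1 s crossing
  # (10 mm in 1 s -> high): per-bin normalised percentages averaged
  expect_equal(li$pct_high, mean(c(100, 100 * 1 / 30)))
  expect_equal(li$pct_low, mean(c(0, 100 * 29 / 30)))
  expect_equal(li$pct_inactive, 0)
  # dark bins: min2: 59 s inactive + 1 s crossing (high); min3 dark half low
  expect_equal(da$pct_inactive, mean(c(100 * 59 / 60, 0)))
  expect_equal(da$pct_high, mean(c(100 * 1 / 60, 0)))
  expect_equal(da$pct_low, mean(c(0, 100)))
  # class percentages per zone sum to 100 per bin
  sums <- b$bins$pct_inactive + b$bins$pct_low + b$bins$pct_high
  expect_equal(sums, rep(100, nrow(b$bins)), tolerance = 1e-9)
})

test_that("zone-time normalisation decouples activity from preference", {
  sched <- tibble::tibble(duration = c(90, 31), zone = c("light", "dark"),
                          speed = c(7, 2))
  tr <- scripted_trajectory(sched)
  well <- well_geometry()
  b <- time_budgets(tr, assign_zone(tr, well),
                    classify_speed(instantaneous_speeds(tr)))
  li <- b$zones[b$zones$zone == "light", ]
  expect_equal(li$pct_high, 100)  # always fast while in light
  expect_equal(b$pct_time_light, 75)
  expect_error(time_budgets(tr[1:30, ], rep("light", 30),
                            classify_speed(rep(1, 29))),
               "shorter than one bin")
})

test_that("15-min blocks average their own bins", {
  sim <- simulate_trajectory(behaviour_params(duration = 1800, seed = 2),
                             well_geometry())
  tr <- sim$trajectory
  labels <- assign_zone(tr, well_geometry())
  classes <- classify_speed(instantaneous_speeds(tr))
  b <- time_budgets(tr, labels, classes, bin_s = 60, block_s = 900)
  expect_equal(sort(unique(b$blocks$block)), c(1, 2))
  b1 <- b$bins[b$bins$bin <= 15 & b$bins$zone == "light", ]
  blk <- b$blocks[b$blocks$block == 1 & b$blocks$zone == "light", ]
  expect_equal(blk$pct_low, mean(b1$pct_low))
})

test_that("the enclosing ellipse solves the rectangle-corner case exactly", {
  fit <- min_enclosing_ellipse(rbind(c(2, 1), c(2, -1), c(-2, 1), c(-2, -1)))
  expect_equal(fit$centre, c(0, 0), tolerance = 1e-6)
  expect_equal(fit$a, 2 * sqrt(2), tolerance = 1e-4)
  expect_equal(fit$b, sqrt(2), tolerance = 1e-4)
  expect_equal(eccentricity(fit), sqrt(3) / 2, tolerance = 1e-4)
})

test_that("ellipse handles symmetric and degenerate inputs", {
  th <- seq(0, 2 * pi, length.out = 10)[-10]
  circ <- min_enclosing_ellipse(cbind(3 * cos(th), 3 * sin(th)))
  expect_equal(circ$a, 3, tolerance = 1e-5)
  expect_equal(circ$b, 3, tolerance = 1e-5)
  expect_equal(eccentricity(circ), 0, tolerance = 1e-2)

  two <- min_enclosing_ellipse(rbind(c(0, 0), c(4, 0)))
  expect_true(two$degenerate)
  expect_equal(two$a, 2)
  expect_equal(two$b, 0)
  expect_equal(eccentricity(two), 1)

  coll <- min_enclosing_ellipse(cbind(1:5, 2 * (1:5)))
  expect_true(coll$degenerate)
  expect_equal(coll$a, sqrt(16 + 64) / 2)
  expect_equal(eccentricity(coll), 1)

  one <- min_enclosing_ellipse(rbind(c(1, 1)))
  expect_true(one$degenerate)
  expect_error(eccentricity(one), "semi-major")
  expect_error(min_enclosing_ellipse(matrix(numeric(0), 0, 2)), "empty")
})

test_that("ellipse containment and near-minimality hold on random sets", {
  set.seed(41)
  for (i in 1:40) {
    P <- matrix(rnorm(2 * sample(5:12, 1), sd = sample(c(0.5, 2, 10), 1)),
                ncol = 2)
    fit <- min_enclosing_ellipse(P)
    expect_lte(max(ellipse_form(fit, P)), 1 + 1e-6)
    area <- pi * fit$a * fit$b
    oracle <- oracle_ellipse_area(P)
    expect_lte(area, 1.01 * oracle)
    expect_gte(area, oracle * (1 - 1e-3))
  }
})

test_that("MPDE and MPDC match direct-loop oracles and their examples", {
  P <- rbind(c(2, 1), c(2, -1), c(-2, 1), c(-2, -1))
  fit <- min_enclosing_ellipse(P)
  expect_equal(mpde(P, fit), sqrt(5), tolerance = 1e-6)

  well <- well_geometry()
  expect_equal(mpdc(rbind(c(3, 4), c(0, 5)), well), 5)
  expect_equal(mpdc(rbind(c(0, 0)), well), 0)
  expect_equal(mpdc(rbind(c(3, 0), c(0, 4), c(5, 0)), well), 4)

  set.seed(52)
  for (i in 1:20) {
    P <- matrix(rnorm(20), ncol = 2)
    fit <- min_enclosing_ellipse(P)
    direct_mpde <- mean(apply(P, 1, function(p)
      sqrt(sum((p - fit$centre)^2))))
    expect_equal(mpde(P, fit), direct_mpde, tolerance = 1e-9)
    direct_mpdc <- mean(apply(P, 1, function(p) sqrt(sum(p^2))))
    expect_equal(mpdc(P, well), direct_mpdc, tolerance = 1e-9)
  }
})

test_that("features are invariant under rigid motions about the well centre", {
  set.seed(63)
  P <- matrix(rnorm(24, sd = 2), ncol = 2)
  well <- well_geometry()
  rot <- function(P, th) P %*% rbind(c(cos(th), sin(th)),
                                     c(-sin(th), cos(th)))
  f0 <- min_enclosing_ellipse(P)
  for (th in c(0.3, 1.2, 2.8)) {
    Pr <- rot(P, th)
    fr <- min_enclosing_ellipse(Pr)
    expect_equal(eccentricity(fr), eccentricity(f0), tolerance = 1e-5)
    expect_equal(mpde(Pr, fr), mpde(P, f0), tolerance = 1e-5)
    expect_equal(mpdc(Pr, well), mpdc(P, well), tolerance = 1e-9)
  }
  # translation: eccentricity and MPDE unchanged (MPDC is positional)
  Pt <- sweep(P, 2, c(1.5, -2))
  ft <- min_enclosing_ellipse(Pt)
  expect_equal(eccentricity(ft), eccentricity(f0), tolerance = 1e-5)
  expect_equal(mpde(Pt, ft), mpde(P, f0), tolerance = 1e-5)
})

test_that("per-larva features aggregate segments per zone and flag absent zones", {
  well <- well_geometry()
  sim <- simulate_trajectory(behaviour_params(duration = 600, seed = 8), well)
  lf <- larva_features(sim$trajectory, well)
  expect_setequal(lf$zone, c("light", "dark"))
  expect_equal(unique(lf$transitions), sim$truth$transitions)
  expect_true(all(lf$pct_time >= 0 & lf$pct_time <= 100))

  # never leaves the light: dark-zone features are absent, not zero
  stay <- simulate_trajectory(
    behaviour_params(crossing_bias = Inf, duration = 300, seed = 4), well)
  lf2 <- larva_features(stay$trajectory, well)
  dark <- lf2[lf2$zone == "dark", ]
  expect_true(is.na(dark$mean_eccentricity))
  expect_true(is.na(dark$mean_mpdc))
  expect_equal(dark$pct_time, 0)
  expect_false(is.na(lf2[lf2$zone == "light", ]$mean_mpdc))
})

test_that("zone means equal the mean of per-segment features", {
  well <- well_geometry()
  sim <- simulate_trajectory(behaviour_params(duration = 900, seed = 12), well)
  tr <- sim$trajectory
  labels <- assign_zone(tr, well)
  kept <- filter_short_segments(segment_by_zone(tr, labels), 1)
  eps <- vapply(seq_len(nrow(kept)), function(i) {
    pts <- cbind(tr$x[kept$start[i]:kept$end[i]],
                 tr$y[kept$start[i]:kept$end[i]])
    fit <- min_enclosing_ellipse(pts)
    if (fit$a > 0) eccentricity(fit) else NA_real_
  }, 0)
  lf <- larva_features(tr, well)
  for (z in c("light", "dark")) {
    expect_equal(lf$mean_eccentricity[lf$zone == z],
                 mean(eps[kept$zone == z], na.rm = TRUE), tolerance = 1e-9)
  }
})
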