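tiny_stack <- function(arr, vox = c(0.6, 0.6, 1.0), name = "red") {
  image_stack(setNames(list(arr), name), voxel_size = vox)
}

test_that("maximum-intensity projection equals the brute-force per-pixel max", {
  set.seed(5)
  arr <- array(runif(6 * 7 * 4, 0, 100), c(6, 7, 4))
  st <- tiny_stack(arr)
  mip <- max_intensity_projection(st, "red")
  brute <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7) brute[i, j] <- max(arr[i, j, ])
  expect_equal(mip, brute)

  single <- tiny_stack(array(arr[, , 1], c(6, 7, 1)))
  expect_equal(max_intensity_projection(single, "red"), arr[, , 1])

  spike <- array(0, c(5, 5, 3)); spike[3, 4, 2] <- 255
  expect_equal(max_intensity_projection(tiny_stack(spike), "red")[3, 4], 255)
  expect_error(max_intensity_projection(st, "blue"), "unknown channel")
})

test_that("thresholding recovers a separable two-level image exactly", {
  img <- matrix(10, 50, 60)
  img[20:30, 10:50] <- 200
  mask <- suppressMessages(segment_vessels(img, smooth_sigma = 0))
  expect_equal(unname(mask != 0), unname(img > 100))
  expect_equal(attr(mask, "threshold") > 10 && attr(mask, "threshold") < 200,
               TRUE)
  expect_error(suppressMessages(segment_vessels(matrix(7, 20, 20))),
               "no foreground")
})

test_that("vessel mask overlaps the ground-truth tube at low noise", {
  p <- stack_params(seed = 21, n_nuclei = 0, noise_sd = 1)
  sim <- simulate_tectum_stack(p)
  mip <- max_intensity_projection(sim$stack, "red")
  mask <- suppressMessages(segment_vessels(mip))
  ny <- nrow(mip); nx <- ncol(mip)
  xs <- (seq_len(nx) - 1) * 0.6; ys <- (seq_len(ny) - 1) * 0.6
  X <- matrix(rep(xs, each = ny), ny); Y <- matrix(rep(ys, nx), ny)
  d2min <- NULL
  for (pl in p$vessel_polylines) {
    for (i in seq_len(nrow(pl$points) - 1)) {
      a <- pl$points[i, 1:2]; b <- pl$points[i + 1, 1:2]
      v <- b - a; L2 <- sum(v^2)
      tt <- pmin(pmax(((X - a[1]) * v[1] + (Y - a[2]) * v[2]) / L2, 0), 1)
      d2 <- (X - a[1] - tt * v[1])^2 + (Y - a[2] - tt * v[2])^2
      d2min <- if (is.null(d2min)) d2 else pmin(d2min, d2)
    }
  }
  # the tube's footprint is its full-width-at-half-maximum region
  truth <- sqrt(d2min) <= 2.5 * sqrt(2 * log(2))
  mx <- max(mip)
  half <- suppressMessages(segment_vessels(mip, method = "fixed",
                                           threshold = 10 + (mx - 10) / 2))
  dice_half <- 2 * sum(half & truth) / (sum(half) + sum(truth))
  expect_gte(dice_half, 0.9)
  # Otsu lands lower on a background-dominated histogram; still close
  dice_otsu <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice_otsu, 0.8)
})

test_that("skeleton length matches exact digital geometry", {
  m <- matrix(FALSE, 20, 120); m[10, 10:110] <- TRUE
  expect_equal(as.numeric(vessel_length(m, 0.6)), 60)
  # additivity over disjoint objects
  m2 <- matrix(FALSE, 30, 120); m2[10, 10:60] <- TRUE; m2[20, 10:60] <- TRUE
  expect_equal(as.numeric(vessel_length(m2, 0.6)), 60)
  # clean diagonal: sqrt(2) steps
  m3 <- matrix(FALSE, 120, 120); for (i in 10:110) m3[i, i] <- TRUE
  expect_equal(as.numeric(vessel_length(m3, 0.6)), 100 * sqrt(2) * 0.6)
  expect_error(vessel_length(matrix(FALSE, 5, 5), 0.6), "empty mask")
})

test_that("a rotated tube reads nearly the same length as an aligned one", {
  mk <- function(pts) stack_params(
    vessel_polylines = list(list(points = pts, radius = 2.5)),
    n_nuclei = 0, seed = 4, shape = c(z = 30, y = 150, x = 150))
  f <- function(stk) {
    m <- suppressMessages(segment_vessels(max_intensity_projection(stk, "red")))
    as.numeric(vessel_length(m, 0.6))
  }
  axis <- f(simulate_tectum_stack(mk(cbind(
    x = c(10, 70), y = c(44.7, 44.7), z = c(15, 15))))$stack)
  diag <- f(simulate_tectum_stack(mk(cbind(
    x = c(10, 10 + 60 / sqrt(2)), y = c(10, 10 + 60 / sqrt(2)),
    z = c(15, 15))))$stack)
  expect_lt(abs(diag - axis) / axis, 0.08)
})

test_that("vessel-normalised intensity follows its formula and ignores out-of-mask signal", {
  mask <- matrix(FALSE, 10, 10); mask[4:6, 2:9] <- TRUE
  sig <- matrix(0, 10, 10); sig[mask] <- 3.5
  expect_equal(normalized_vascular_intensity(sig, mask, 12),
               3.5 * sum(mask) / 12)
  expect_equal(normalized_vascular_intensity(sig * 0, mask, 12), 0)
  outside <- sig; outside[1, 1] <- 1e6
  expect_equal(normalized_vascular_intensity(outside, mask, 12),
               normalized_vascular_intensity(sig, mask, 12))
  expect_error(normalized_vascular_intensity(sig, mask, 0), "positive")
})

test_that("normalised intensity rises with the expression level", {
  vals <- vapply(c(40, 120, 360), function(g) {
    sim <- simulate_tectum_stack(stack_params(
      seed = 6, n_nuclei = 0, green_level = g,
      shape = c(z = 20, y = 100, x = 120)))
    suppressMessages(quantify_vessels(sim$stack))$normalized_intensity
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("ROI mean intensity equals a brute-force voxel loop", {
  set.seed(8)
  arr <- array(runif(8 * 9 * 5, 0, 50), c(8, 9, 5))
  st <- tiny_stack(arr)
  roi <- list(y = c(2, 5), x = c(3, 7), z = c(2, 4))
  got <- roi_mean_intensity(st, "red", roi)
  acc <- 0; n <- 0
  for (i in 2:5) for (j in 3:7) for (k in 2:4) {
    acc <- acc + arr[i, j, k]; n <- n + 1
  }
  expect_equal(got, acc / n)
  uni <- tiny_stack(array(7, c(4, 4, 4)))
  expect_equal(roi_mean_intensity(uni, "red",
                                  list(y = c(1, 4), x = c(1, 4), z = c(1, 4))),
               7)
  half <- array(0, c(4, 4, 2)); half[, , 2] <- 10
  expect_equal(roi_mean_intensity(tiny_stack(half), "red",
                                  list(y = c(1, 4), x = c(1, 4), z = c(1, 2))),
               5)
  expect_error(roi_mean_intensity(st, "red",
                                  list(y = c(1, 20), x = c(1, 2), z = c(1, 2))),
               "out of bounds")
})

test_that("3-D component labelling separates and counts blobs", {
  m <- array(FALSE, c(6, 6, 4))
  m[1:2, 1:2, 1:2] <- TRUE          # blob 1
  m[5:6, 5:6, 3:4] <- TRUE          # blob 2
  m[4, 4, 2] <- TRUE                # touches blob 2 diagonally (26-conn)
  lab <- label_components_3d(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[4, 4, 2], lab[5, 5, 3])
  expect_true(all(lab[m] > 0) && all(lab[!m] == 0))
})

test_that("mural-nuclei counting recovers the generated count", {
  sim <- simulate_tectum_stack(stack_params(seed = 13, n_nuclei = 12))
  cnt <- suppressMessages(count_mural_nuclei(
    sim$stack, threshold_method = "fixed", threshold = 140))
  expect_equal(as.integer(cnt), 12)

  none <- simulate_tectum_stack(stack_params(seed = 13, n_nuclei = 0))
  cnt0 <- suppressMessages(count_mural_nuclei(
    none$stack, threshold_method = "fixed", threshold = 140))
  expect_equal(as.integer(cnt0), 0)
})

test_that("well-separated nuclei stay two components", {
  sp <- stack_params(shape = c(z = 20, y = 60, x = 60), n_nuclei = 0,
                     vessel_polylines = list(list(
                       points = cbind(x = c(3, 30), y = c(3, 3), z = c(3, 3)),
                       radius = 1.5)),
                     noise_sd = 1, seed = 2)
  sim <- simulate_tectum_stack(sp)
  arr <- sim$stack$channels$red
  # add two synthetic nuclei 4 sigma apart by hand (the generator default
  # minimum separation); simple thresholding cannot split closer pairs
  sig <- 1.5
  ctrs <- rbind(c(18, 18, 10), c(18 + 4 * sig / 0.6, 18, 10))
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nz <- dim(arr)[3]
  xs <- (seq_len(nx) - 1) * 0.6; ys <- (seq_len(ny) - 1) * 0.6
  zs <- (seq_len(nz) - 1) * 1.0
  X <- array(rep(xs, each = ny, times = nz), c(ny, nx, nz))
  Y <- array(rep(ys, times = nx * nz), c(ny, nx, nz))
  Z <- array(rep(zs, each = ny * nx), c(ny, nx, nz))
  for (cc in 1:2) {
    cx <- ctrs[cc, 1] * 0.6; cy <- 18 * 0.6; cz <- 10
    arr <- arr + 220 * exp(-((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) /
                             (2 * sig^2))
  }
  st2 <- image_stack(list(red = round(arr)), voxel_size = c(0.6, 0.6, 1.0))
  cnt <- suppressMessages(count_mural_nuclei(
    st2, threshold_method = "fixed", threshold = 140))
  expect_equal(as.integer(cnt), 2)
})

test_that("Otsu-based nuclei counting is invariant to intensity gain", {
  sim <- simulate_tectum_stack(stack_params(
    seed = 14, n_nuclei = 8, vessel_polylines = list(list(
      points = cbind(x = c(5, 80), y = c(10, 10), z = c(5, 5)), radius = 2)),
    shape = c(z = 25, y = 90, x = 150)))
  base <- suppressMessages(count_mural_nuclei(sim$stack))
  scaled <- image_stack(list(red = sim$stack$channels$red * 3,
                             green = sim$stack$channels$green),
                        voxel_size = sim$stack$voxel_size)
  expect_equal(as.integer(suppressMessages(count_mural_nuclei(scaled))),
               as.integer(base))
})
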