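test_that("square initialization insets by the margin fraction", {
  st <- init_square(c(100, 100), 0.25)
  fg <- which(st$u == 1L, arr.ind = TRUE)
  # 0-based foreground spans [25, 75) in both axes
  expect_equal(range(fg[, 1]) - 1, c(25, 74))
  expect_equal(range(fg[, 2]) - 1, c(25, 74))

  # degenerate margin keeps a one-pixel background border
  st0 <- init_square(c(10, 10), 0)
  fg0 <- which(st0$u == 1L, arr.ind = TRUE)
  expect_equal(range(fg0[, 1]) - 1, c(1, 8))
  expect_equal(sum(st0$u), 64)

  for (shape in list(c(3, 3), c(7, 5), c(40, 80))) {
    u <- init_square(shape, 0.1)$u
    expect_gt(sum(u), 0)
    expect_lt(sum(u), prod(shape))
  }
  expect_error(init_square(c(2, 5), 0.1), "3x3")
  expect_error(init_square(c(10, 10), 0.6), "margin")
})

test_that("region means equal brute-force per-pixel accumulation", {
  img <- matrix(0.2, 20, 20)
  st <- init_square(c(20, 20), 0.25)
  img[st$u == 1L] <- 0.9
  expect_equal(unname(region_means(img, st)), c(0.9, 0.2))

  const <- matrix(0.4, 20, 20)
  expect_equal(unname(region_means(const, st)), c(0.4, 0.4))

  set.seed(9)
  rimg <- matrix(runif(100), 10, 10)
  rst <- init_square(c(10, 10), 0.2)
  rst$u <- matrix(as.integer(runif(100) < 0.5), 10, 10)
  if (sum(rst$u) %in% c(0L, 100L)) rst$u[1, 1] <- 1L - rst$u[1, 1]
  s1 <- s2 <- 0; n1 <- n2 <- 0
  for (i in 1:100) {
    if (rst$u[i] == 1L) { s1 <- s1 + rimg[i]; n1 <- n1 + 1 }
    else { s2 <- s2 + rimg[i]; n2 <- n2 + 1 }
  }
  expect_equal(unname(region_means(rimg, rst)), c(s1 / n1, s2 / n2))
})

test_that("discrete energy matches its brute-force double loop", {
  # single foreground pixel, mu = 1, lambda terms off: 4 adjacencies
  st <- init_square(c(5, 5), 0)
  st$u <- matrix(0L, 5, 5); st$u[3, 3] <- 1L
  img <- matrix(0.5, 5, 5)
  p <- cv_params(mu = 1, lam1 = 1e-12, lam2 = 1e-12)
  expect_equal(cv_energy(img, st, p), 4, tolerance = 1e-9)

  # exact partition of a two-level image has zero residual energy
  d <- disk_crop()
  st2 <- init_square(dim(d$image), 0.1)
  st2$u <- d$mask * 1L
  expect_equal(cv_energy(d$image, st2, cv_params(mu = 0)), 0)

  # random instance vs brute-force sums
  set.seed(10)
  rimg <- matrix(runif(64), 8, 8)
  rst <- init_square(c(8, 8), 0.2)
  rst$u <- matrix(as.integer(runif(64) < 0.4), 8, 8)
  if (sum(rst$u) %in% c(0L, 64L)) rst$u[1, 1] <- 1L - rst$u[1, 1]
  pr <- cv_params(mu = 0.7, lam1 = 1.3, lam2 = 0.9)
  c1 <- mean(rimg[rst$u == 1L]); c2 <- mean(rimg[rst$u == 0L])
  e_in <- e_out <- 0; len <- 0
  for (r in 1:8) for (c in 1:8) {
    if (rst$u[r, c] == 1L) e_in <- e_in + (rimg[r, c] - c1)^2
    else e_out <- e_out + (rimg[r, c] - c2)^2
    if (r < 8 && rst$u[r, c] != rst$u[r + 1, c]) len <- len + 1
    if (c < 8 && rst$u[r, c] != rst$u[r, c + 1]) len <- len + 1
  }
  expect_equal(cv_energy(rimg, rst, pr),
               0.7 * len + 1.3 * e_in + 0.9 * e_out, tolerance = 1e-12)
})

test_that("evolution step obeys the pointwise region force", {
  # aligned state on a two-level image is a fixed point without smoothing
  d <- disk_crop()
  st <- init_square(dim(d$image), 0.1)
  st$u <- d$mask * 1L
  p0 <- cv_params(n_smooth = 0)
  st2 <- evolve_step(d$image, st, p0)
  expect_identical(st2$u, st$u)
  expect_equal(st2$iteration, 1L)

  # a deviant interior pixel flips region in one step
  img <- matrix(0.2, 21, 21)
  st3 <- init_square(c(21, 21), 0.2)
  img[st3$u == 1L] <- 0.9
  img[11, 11] <- 0.21                    # bright region pixel that is dark
  st4 <- evolve_step(img, st3, p0)
  expect_equal(st4$u[11, 11], 0L)
  flipped <- st3$u != st4$u
  expect_identical(which(flipped), which(seq_len(441) == (10 * 21 + 11)))

  # constant crop: force has no preference, state reverts unchanged
  const <- matrix(0.5, 20, 20)
  st5 <- init_square(c(20, 20), 0.25)
  st6 <- evolve_step(const, st5, cv_params())
  expect_identical(st6$u, st5$u)
})

test_that("full run recovers a noiseless disk and is deterministic", {
  d <- disk_crop(n = 80, radius = 20)
  mask <- run_chan_vese(d$image, cv_params(n_iter = 50))
  expect_gte(bf_dice(mask, d$mask), 0.99)

  mask2 <- run_chan_vese(d$image, cv_params(n_iter = 50))
  expect_identical(mask, mask2)

  # constant crop returns the initialization mask unchanged
  const <- matrix(0.7, 30, 30)
  expect_identical(run_chan_vese(const, cv_params(n_iter = 10)),
                   init_square(c(30, 30), 0.1)$u == 1L)
})

test_that("energy trace decreases on noiseless and noisy disks", {
  d <- disk_crop(n = 60, radius = 15)
  st <- run_chan_vese(d$image, cv_params(n_iter = 30), return_state = TRUE)
  tr <- st$energy_trace
  expect_equal(length(tr), 31L)   # init + one entry per iteration
  expect_lte(tr[length(tr)], tr[1])

  noisy <- add_rician_noise(d$image, 0.05, seed = 3L)
  stn <- run_chan_vese(noisy, cv_params(n_iter = 30), return_state = TRUE)
  expect_lte(stn$energy_trace[31], stn$energy_trace[1])
})

test_that("more smoothing never lengthens the final contour on clean disks", {
  d <- disk_crop(n = 60, radius = 16)
  lens <- vapply(c(0L, 2L, 8L), function(k) {
    st <- run_chan_vese(d$image, cv_params(n_iter = 20, n_smooth = k),
                        return_state = TRUE)
    cv_energy(d$image, st, cv_params(mu = 1, lam1 = 1e-12, lam2 = 1e-12))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("prewitt baseline finds strong edges and closes clean disks", {
  expect_warning(p <- prewitt_segment(matrix(0.4, 10, 10)), "zero gradient")
  expect_false(any(p))

  # vertical two-level step: gradient magnitude peaks on the step columns
  step <- cbind(matrix(0, 10, 5), matrix(1, 10, 5))
  g <- cvseg:::prewitt_gradient(step)
  expect_true(all(apply(g, 1, which.max) %in% c(5, 6)))
  # hand-convolved interior value: 3-pixel column sum difference
  expect_equal(g[5, 5], 3)
  expect_equal(g[5, 2], 0)

  d <- disk_crop(n = 60, radius = 15)
  m <- prewitt_segment(d$image, 0.3)
  expect_gte(bf_dice(m, d$mask), 0.9)
})

test_that("segment_tumor confines output to the box and recovers the tumor", {
  spec <- phantom_spec(image_size = 128L, tumor_center = c(88, 80),
                       tumor_axes = c(12, 9), rician_sigma = 0.02)
  ph <- generate_phantom(spec)
  box <- oracle_localizer(ph$truth, jitter_frac = 0, margin_frac = 0.2)
  full <- segment_tumor(ph$image, box, cv_params(n_iter = 60))
  outside <- full
  outside[(box$r0 + 1):box$r1, (box$c0 + 1):box$c1] <- FALSE
  expect_false(any(outside))
  expect_gte(bf_dice(full, ph$truth$mask), 0.95)

  # a box excluding the tumor never marks pixels outside itself
  off_box <- bbox(2, 2, 34, 34)
  m2 <- segment_tumor(ph$image, off_box, cv_params(n_iter = 20))
  out2 <- m2
  out2[3:34, 3:34] <- FALSE
  expect_false(any(out2))

  # both methods are deterministic end to end
  p2 <- segment_tumor(ph$image, box, method = "prewitt")
  expect_identical(p2, segment_tumor(ph$image, box, method = "prewitt"))
})
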