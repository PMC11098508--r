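test_that("distance_matrix computes planar and great-circle distances", {
  expect_equal(distance_matrix(data.frame(x = c(0, 3), y = c(0, 4))),
               matrix(c(0, 5, 5, 0), 2))
  expect_equal(distance_matrix(data.frame(x = 0, y = 0)), matrix(0, 1, 1))

  d <- distance_matrix(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)))
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))
  expect_equal(sort(d[upper.tri(d)]), c(1, 1, sqrt(2)))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)

  # one degree of latitude on a sphere of radius 6371008.8 m
  dh <- distance_matrix(data.frame(x = c(0, 0), y = c(0, 1)), mode = "haversine")
  expect_equal(dh[1, 2], pi * 6371008.8 / 180, tolerance = 1e-9)
  expect_error(distance_matrix(data.frame(x = 0, y = 91), mode = "haversine"),
               "lat")
  expect_error(distance_matrix(data.frame(x = NA_real_, y = 0)), "finite")
})

test_that("kernel families evaluate to the documented forms", {
  expect_equal(kernel_eval(dispersal_kernel("exponential", m = 1), 0), 1)
  w <- kernel_eval(dispersal_kernel("exponential", m = 1), c(1, 2))
  expect_equal(w / sum(w), c(exp(-1), exp(-2)) / (exp(-1) + exp(-2)))
  expect_equal(w[1] / sum(w), 0.7311, tolerance = 1e-4)

  # Lomax form at stated parameters, converging to exponential for large b
  lt <- dispersal_kernel("long_tailed", m = 2, b = 3)
  expect_equal(kernel_eval(lt, 4), (1 + 4 / (2 * 2))^-3)
  big_b <- dispersal_kernel("long_tailed", m = 1, b = 500)
  expect_equal(kernel_eval(big_b, 2), exp(-2), tolerance = 1e-2)

  expect_error(dispersal_kernel("exponential", m = -1), "positive")
  expect_error(dispersal_kernel("zero_inflated_exponential", m = 1, z = 1.2), "\\[0, 1\\]")
  expect_error(dispersal_kernel("long_tailed", m = 1, b = 1), "> 1")
})

test_that("built-in kernels are non-increasing in distance", {
  d <- seq(0, 10, by = 0.25)
  for (k in list(dispersal_kernel("exponential", m = 0.7),
                 dispersal_kernel("zero_inflated_exponential", m = 0.7, z = 0.5),
                 dispersal_kernel("long_tailed", m = 0.7, b = 2.5))) {
    w <- kernel_eval(k, d)
    expect_true(all(diff(w) <= 0))
    expect_true(all(w >= 0))
  }
})

test_that("masking multiplies weights element-wise by current-node type", {
  set.seed(42)
  w <- matrix(runif(16), 4)
  types <- c(0L, 1L, 0L, 1L)
  mask <- matrix(c(0.2, 0.9, 0.8, 0.1), 2)  # rows: source type
  got <- apply_mask(w, types, mask)
  for (i in 1:4) for (j in 1:4)
    expect_equal(got[i, j], w[i, j] * mask[types[i] + 1, types[j] + 1])

  expect_equal(apply_mask(w, types, matrix(1, 2, 2)), w)

  # zero mask annihilates same-type movement from blood sites
  mask0 <- matrix(c(0, 1, 1, 1), 2, byrow = TRUE)
  got0 <- apply_mask(w, types, mask0)
  expect_true(all(got0[c(1, 3), c(1, 3)] == 0))
  expect_true(all(got0[c(1, 3), c(2, 4)] > 0))

  expect_error(apply_mask(w, c(0L, 1L, 2L, 0L), mask), "absent")
  expect_error(apply_mask(w, types, matrix(0, 2, 2)), "positive")
})

test_that("movement matrix is row-stochastic with the documented diagonal", {
  expect_equal(build_movement_matrix(data.frame(x = 0, y = 0),
                                     dispersal_kernel("exponential")),
               matrix(1, 1, 1))

  # six-node demo landscape: staying probability imposed exactly
  lh <- landscape(make_landscape("hexad"),
                  dispersal_kernel("zero_inflated_exponential", m = 1, z = 0.75))
  expect_equal(rowSums(lh$tau), rep(1, 6), tolerance = 1e-12)
  expect_equal(diag(lh$tau), rep(0.75, 6))

  # collinear 3-site landscape vs brute-force normalization of exp weights
  sites <- data.frame(x = c(0, 1, 3), y = 0)
  tau <- build_movement_matrix(sites, dispersal_kernel("exponential", m = 1))
  d <- as.matrix(dist(cbind(sites$x, sites$y)))
  w <- exp(-d)
  expect_equal(tau, unname(w / rowSums(w)), tolerance = 1e-14)

  # degenerate: custom kernel that vanishes everywhere
  expect_error(build_movement_matrix(sites,
    dispersal_kernel("custom", fun = function(d) d * 0)), "degenerate")
})

test_that("zero-inflated staying probability is symmetric-split on equidistant sites", {
  sites <- data.frame(x = c(0, 1, -1), y = 0)
  tau <- build_movement_matrix(sites,
    dispersal_kernel("zero_inflated_exponential", m = 1, z = 0.75))
  expect_equal(tau[1, ], c(0.75, 0.125, 0.125))
})

test_that("row-stochasticity and mask identity hold on random landscapes", {
  for (s in 1:100) {
    ls <- random_landscape(s)
    expect_equal(rowSums(ls$tau), rep(1, nrow(ls$tau)), tolerance = 1e-12)
    expect_true(all(ls$tau >= 0 & ls$tau <= 1))
    if (ls$kernel$family == "zero_inflated_exponential")
      expect_equal(diag(ls$tau), rep(ls$kernel$z, nrow(ls$tau)))
  }
  # identity mask is a no-op
  for (s in 1:5) {
    sites <- random_sites(s, n_types = 2)
    k <- dispersal_kernel("exponential", m = 0.4)
    tau_plain <- build_movement_matrix(sites, k)
    tau_mask <- build_movement_matrix(sites, k, mask = matrix(1, 2, 2))
    expect_equal(tau_mask, tau_plain, tolerance = 1e-14)
  }
})

test_that("an isolated site under the zero-inflated kernel keeps all its mass", {
  sites <- data.frame(x = c(0, 10, 11), y = 0, t = c(0L, 1L, 1L))
  mask <- matrix(c(0, 1, 1, 1), 2, byrow = TRUE)  # type-0 cannot go to type-0
  # site 0 is type 0 and can still reach the type-1 sites
  tau <- build_movement_matrix(sites,
    dispersal_kernel("zero_inflated_exponential", m = 1, z = 0.6), mask = mask)
  expect_equal(diag(tau), c(0.6, 0.6, 0.6))
  # but with all destinations masked off it keeps probability 1
  mask_all <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  tau2 <- build_movement_matrix(sites,
    dispersal_kernel("zero_inflated_exponential", m = 1, z = 0.6),
    mask = mask_all)
  expect_equal(tau2[1, ], c(1, 0, 0))
})

test_that("landscape objects print and summarise", {
  ls <- landscape(make_landscape("hexad"),
                  dispersal_kernel("zero_inflated_exponential", m = 1, z = 0.75))
  expect_output(print(ls), "6 sites")
  s <- summary(ls)
  expect_equal(s$n_sites, 6)
  expect_output(print(s), "staying probabilities")
})
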