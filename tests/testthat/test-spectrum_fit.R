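test_that("nnls_solve handles the elementary cases and rejects bad input", {
  expect_equal(nnls_solve(diag(3), c(2, 0, 5)), c(2, 0, 5))
  expect_equal(nnls_solve(diag(2), c(3, -1)), c(3, 0))
  expect_equal(nnls_solve(diag(4), numeric(4)), numeric(4))
  expect_error(nnls_solve(diag(3), c(1, 2)), "length")
})

test_that("nnls solutions satisfy the KKT certificate on random problems", {
  set.seed(202)
  for (i in 1:30) {
    m <- sample(8:40, 1)
    p <- sample(4:50, 1)
    A <- matrix(abs(rnorm(m * p)), m, p)
    b <- rnorm(m)
    x <- nnls_solve(A, b)
    expect_true(nnls_kkt_ok(A, b, x))
  }
})

test_that("nnls agrees with exhaustive active-set enumeration", {
  set.seed(203)
  for (i in 1:12) {
    A <- matrix(abs(rnorm(10 * 8)), 10, 8)
    b <- rnorm(10)
    x <- nnls_solve(A, b)
    xb <- nnls_bruteforce(A, b)
    expect_equal(sum((A %*% x - b)^2), sum((A %*% xb - b)^2),
                 tolerance = 1e-9)
    expect_equal(x, xb, tolerance = 1e-6)
  }
})

test_that("nnls recovers sparse non-negative truth from noiseless data", {
  set.seed(204)
  for (i in 1:10) {
    A <- matrix(abs(rnorm(32 * 40)), 32, 40)
    x_true <- numeric(40)
    x_true[sample(40, 4)] <- runif(4, 0.5, 2)
    x <- nnls_solve(A, as.numeric(A %*% x_true))
    expect_lt(max(abs(x - x_true)), 1e-6)
  }
})

test_that("regularized_nnls respects its contract", {
  g <- t2_grid()
  b <- build_decay_basis(g, sequence_params(refocus_deg = 180))
  # zero signal: zero everything
  r0 <- regularized_nnls(b, numeric(32))
  expect_equal(r0$coefficients, numeric(40))
  expect_equal(r0$mu, 0)
  expect_equal(r0$chi2, 0)
  expect_error(regularized_nnls(b, numeric(32), chi2_window = c(0.9, 1.1)),
               "chi2_window")

  # chi2 is non-decreasing in mu (random noisy problems, log-mu sweep)
  set.seed(205)
  for (i in 1:4) {
    sig <- as.numeric(b$matrix %*% c(numeric(10), runif(20), numeric(10))) +
      rnorm(32, sd = 0.05)
    sig <- pmax(sig, 0)
    chis <- vapply(10^seq(-4, 1, length.out = 10), function(mu) {
      Aa <- rbind(b$matrix, diag(mu, 40))
      x <- nnls_solve(Aa, c(sig, numeric(40)))
      sum((b$matrix %*% x - sig)^2)
    }, numeric(1))
    expect_true(all(diff(chis) > -1e-10))
  }

  # noisy problem: selected ratio lands inside the window
  sig <- as.numeric(b$matrix %*% rep(0.02, 40)) + rnorm(32, sd = 0.01)
  r <- regularized_nnls(b, pmax(sig, 0))
  expect_identical(r$flag, "ok")
  expect_gte(r$chi2_ratio, 1.02)
  expect_lte(r$chi2_ratio, 1.025)
  expect_true(all(r$coefficients >= 0))
})

test_that("two-pool noiseless decay keeps its myelin-window mass", {
  g <- t2_grid()
  p <- sequence_params(refocus_deg = 180)
  b <- build_decay_basis(g, p)
  sig <- 0.15 * epg_echo_amplitudes(20, p) +
    0.85 * epg_echo_amplitudes(80, p)
  r <- regularized_nnls(b, sig)
  comp <- compartmentalize(r$coefficients, g)
  expect_lt(abs(comp$mw - 0.15), 0.02)
})

test_that("flip-angle estimation recovers the generating angle", {
  g <- t2_grid()
  p180 <- sequence_params(refocus_deg = 180)
  sig180 <- 0.1 * epg_echo_amplitudes(20, p180) +
    0.9 * epg_echo_amplitudes(90, p180)
  est <- estimate_flip_angle(sig180, sequence_params(), g)
  expect_equal(est$flip_deg, 180, tolerance = 0.5)

  p155 <- sequence_params(refocus_deg = 155)
  sig155 <- 0.15 * epg_echo_amplitudes(25, p155) +
    0.85 * epg_echo_amplitudes(85, p155)
  est155 <- estimate_flip_angle(sig155, sequence_params(), g)
  expect_equal(est155$flip_deg, 155, tolerance = 1)

  # all-zero signal: flagged midpoint
  flat <- estimate_flip_angle(numeric(32), sequence_params(), g)
  expect_identical(flat$flag, "flat")
  expect_equal(flat$flip_deg, 135)
  expect_error(estimate_flip_angle(sig155, sequence_params(), g,
                                   alpha_range = c(60, 180)), "alpha_range")
})

test_that("flip-angle recovery stays within 2 degrees at SNR 100", {
  g <- t2_grid()
  p155 <- sequence_params(refocus_deg = 155)
  sig <- 0.12 * epg_echo_amplitudes(22, p155) +
    0.83 * epg_echo_amplitudes(82, p155) +
    0.05 * epg_echo_amplitudes(1000, p155)
  set.seed(206)
  alphas <- replicate(100, {
    noisy <- pmax(sig + rnorm(32, sd = sig[1] / 100), 0)
    estimate_flip_angle(noisy, sequence_params(), g)$flip_deg
  })
  expect_lt(abs(mean(alphas) - 155), 2)
  expect_lt(sd(alphas), 6)  # spread reported sanity bound
})

test_that("fit_voxel recovers a noiseless three-pool voxel", {
  g <- t2_grid()
  p <- sequence_params(refocus_deg = 165)
  sig <- as.numeric(
    cbind(epg_echo_amplitudes(20, p), epg_echo_amplitudes(80, p),
          epg_echo_amplitudes(1000, p)) %*% c(0.10, 0.80, 0.10))
  fit <- fit_voxel(sig, sequence_params(), g)
  comp <- compartmentalize(fit)
  expect_lt(abs(comp$mw - 0.10), 0.03)
  expect_lt(abs(comp$iew - 0.80), 0.03)
  expect_lt(abs(comp$fw - 0.10), 0.03)
  expect_lt(abs(fit$flip_deg - 165), 1)
  expect_true(all(fit$spectrum >= 0))

  # background voxel
  bg <- fit_voxel(numeric(32), sequence_params(), g)
  expect_true(bg$background)
  expect_equal(bg$snr, 0)
  expect_equal(sum(bg$spectrum), 0)
  expect_error(fit_voxel(rep(-1, 32), sequence_params(), g), "non-negative")

  # free-water-only voxel: nearly all mass above 250 ms
  sigf <- epg_echo_amplitudes(1000, p)
  compf <- compartmentalize(fit_voxel(sigf, sequence_params(), g))
  expect_gte(compf$fw, 0.95)
})

test_that("pool fractions are insensitive to the assumed T1 at 180 deg", {
  g <- t2_grid()
  fr <- lapply(c(600, 1000, 2000), function(t1) {
    p <- sequence_params(t1_assumed = t1, refocus_deg = 180)
    sig <- as.numeric(
      cbind(epg_echo_amplitudes(20, p), epg_echo_amplitudes(80, p),
            epg_echo_amplitudes(1000, p)) %*% c(0.10, 0.85, 0.05))
    fit <- fit_voxel(sig, sequence_params(t1_assumed = t1), g)
    unlist(compartmentalize(fit)[c("mw", "iew", "fw")])
  })
  for (k in 2:3) expect_lt(max(abs(fr[[k]] - fr[[1]])), 0.01)
})

test_that("fit_volume maps voxels, flags background, is deterministic", {
  g <- t2_grid()
  p <- sequence_params(refocus_deg = 170)
  sig <- as.numeric(
    cbind(epg_echo_amplitudes(20, p), epg_echo_amplitudes(80, p),
          epg_echo_amplitudes(1000, p)) %*% c(0.1, 0.85, 0.05))
  vol <- array(0, c(2, 2, 1, 32))
  for (x in 1:2) for (y in 1:2) vol[x, y, 1, ] <- sig
  mask <- array(TRUE, c(2, 2, 1))
  fit <- fit_volume(vol, mask, sequence_params(), g)
  expect_length(fit$voxels, 4L)
  # identical inputs give identical outputs
  expect_equal(fit$spectra[1, ], fit$spectra[4, ])
  expect_equal(fit$flip_deg[1], fit$flip_deg[3])
  # empty mask: valid empty result
  fit0 <- fit_volume(vol, array(FALSE, c(2, 2, 1)), sequence_params(), g)
  expect_length(fit0$voxels, 0L)
  expect_true(all(fit0$background))
  expect_error(fit_volume(vol, array(TRUE, c(3, 2, 1)), sequence_params(),
                          g), "shape")
})
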