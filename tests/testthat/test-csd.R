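test_that("rectangle potential integral matches the known singular value and far field", {
  # observation point at the centre of the unit square: 4 ln(1 + sqrt(2))
  expect_equal(rect_potential_integral(-0.5, 0.5, -0.5, 0.5, 0),
               4 * log(1 + sqrt(2)), tolerance = 1e-12)
  # far field: area / d
  A <- 0.1 * 0.04
  d <- 20 * sqrt(0.1^2 + 0.04^2)
  v <- rect_potential_integral(-0.05, 0.05, -0.02, 0.02, d)
  expect_lt(abs(v - A / d) / (A / d), 0.01)
  # observation point on a corner is finite
  expect_true(is.finite(rect_potential_integral(0, 1, -1, 1, 0)))
})

test_that("forward matrix scales inversely with sigma and is structurally sound", {
  geom <- test_geometry()
  cs <- compartmentize(geom)
  fm1 <- forward_matrix(cs, sigma = 5)
  fm2 <- forward_matrix(cs, sigma = 10)
  expect_equal(fm1$matrix, 2 * fm2$matrix, tolerance = 1e-12)
  expect_true(all(fm2$matrix > 0))
  expect_lt(fm2$condition, 1e8)
  # the compartment containing the electrode dominates its potential
  expect_equal(apply(fm2$matrix, 1L, which.max), 1:4)
  # mirror symmetry of the default layout: F[i,j] = F[N+1-i, N+1-j]
  n <- nrow(fm2$matrix)
  expect_equal(fm2$matrix, fm2$matrix[n:1, n:1], tolerance = 1e-6)
})

test_that("forward entries match the independent quadrature oracle", {
  for (seed in 1:5) {
    geom <- random_geometry(seed)
    cs <- compartmentize(geom)
    fm <- forward_matrix(cs)
    q <- attr(cs, "q_mm")
    for (i in seq_len(nrow(cs))) {
      for (j in seq_len(nrow(cs))) {
        expected <- oracle_rect_integral(cs$x_lo_mm[i], cs$x_hi_mm[i], q,
                                         cs$center_x_mm[j]) /
          (4 * pi * geom$sigma)
        expect_equal(fm$matrix[j, i], expected, tolerance = 1e-3)
      }
    }
  }
})

test_that("forward/inverse are linear and round-trip to machine precision", {
  fm <- forward_matrix(compartmentize(test_geometry()))
  expect_equal(forward_potentials(fm, rep(0, 4)), rep(0, 4))
  set.seed(10)
  C1 <- runif(4, -1, 1); C2 <- runif(4, -1, 1)
  expect_equal(forward_potentials(fm, 2 * C1 - 3 * C2),
               2 * forward_potentials(fm, C1) - 3 * forward_potentials(fm, C2),
               tolerance = 1e-12)
  # single nonzero source picks one column
  Ck <- c(0, 0, 1.7, 0)
  expect_equal(forward_potentials(fm, Ck), fm$matrix[, 3] * 1.7)
  # round trips
  expect_equal(invert_csd(fm, rep(0, 4)), rep(0, 4))
  for (r in 1:50) {
    C <- runif(4, -1, 1)
    expect_lt(max(abs(invert_csd(fm, forward_potentials(fm, C)) - C)), 1e-9)
  }
  expect_error(forward_potentials(fm, 1:3),
               class = "olfactomap_validation_error")
})

test_that("per-sample inversion recovers a noiseless synthetic time course", {
  geom <- test_geometry()
  fm <- forward_matrix(compartmentize(geom))
  t <- seq(0, 3, by = 0.002)
  k <- ifelse(t >= 1, exp(-(t - 1) / 0.4) - exp(-(t - 1) / 0.05), 0)
  C <- c(0, -0.8, -0.2, 0)
  phi <- outer(k, as.numeric(fm$matrix %*% C))
  rec <- eag_recording(phi, time_s = t, stimulus_onset_s = 1)
  res <- csd_timecourse(fm, rec)
  expect_equal(res$sources, outer(k, C), tolerance = 1e-9)
  # zero traces give zero sources
  rec0 <- eag_recording(matrix(0, length(t), 4), time_s = t,
                        stimulus_onset_s = 1)
  expect_true(all(csd_timecourse(fm, rec0)$sources == 0))
})

test_that("noise propagation through the inversion respects the norm bound", {
  geom <- test_geometry()
  fm <- forward_matrix(compartmentize(geom))
  Minv <- solve(fm$matrix)
  bound <- norm(Minv, "2") * 0.01 * sqrt(4)
  set.seed(99)
  errs <- replicate(1000, {
    eps <- rnorm(4, sd = 0.01)
    sqrt(sum((Minv %*% eps)^2))
  })
  # RMS source error is bounded by ||F^-1||_2 * sigma_n * sqrt(N)
  expect_lte(sqrt(mean(errs^2)), bound)
  expect_gt(mean(errs), 0)  # noise actually propagates
})

test_that("response areas integrate sign-flipped sources over 1.5 s", {
  t <- seq(0, 3, by = 0.002)
  # -1 source-unit plateau covering the whole window: area +1.5
  src <- matrix(0, length(t), 2)
  src[t >= 1 & t <= 2.5, 1] <- -1
  areas <- csd_response_area(src, t, onset_s = 1)
  expect_equal(areas[1], 1.5, tolerance = 2e-3)
  expect_equal(areas[2], 0)
  # rectangle of height -h, duration d
  src2 <- matrix(0, length(t), 1)
  src2[t >= 1.2 & t <= 1.2 + 0.6, 1] <- -0.7
  expect_equal(csd_response_area(src2, t, onset_s = 1), 0.7 * 0.6,
               tolerance = 0.7 * 0.002)
  expect_error(csd_response_area(src, t, onset_s = 2),
               class = "olfactomap_validation_error")
})

test_that("barycenter is the positive-part weighted mean of positions", {
  p <- c(0, 1/3, 2/3, 1)
  expect_equal(csd_barycenter(c(0, 0, 1, 0), p), 2/3)
  expect_equal(csd_barycenter(c(1, 1, 1, 1), p), 0.5)
  expect_equal(csd_barycenter(c(1, 0, 0, 1), p), 0.5)
  # negative areas are clipped, not subtracted
  expect_equal(csd_barycenter(c(-5, 0, 1, 0), p), 2/3)
  expect_error(csd_barycenter(c(-1, 0, 0, 0), p),
               class = "olfactomap_numerical_error")
  expect_error(csd_barycenter(c(1, 1), p),
               class = "olfactomap_validation_error")
})

test_that("localized sources are recovered without leakage, exactly at the electrode", {
  geom <- test_geometry()
  cs <- compartmentize(geom)
  fm <- forward_matrix(cs)
  for (k in 1:4) {
    C <- numeric(4); C[k] <- -1
    sim_cfg <- sim_config(geom, center_norm = geom$positions_norm[k],
                          width_norm = 1e-4, noise_sd_mv = 0)
    sim <- simulate_recording(sim_cfg, seed = 1)
    res <- csd_analyze(sim$recording, geom)
    rel_leak <- max(abs(res$areas[-k])) / abs(res$areas[k])
    expect_lt(rel_leak, 1e-8)
    expect_equal(res$barycenter_norm, geom$positions_norm[k],
                 tolerance = 1e-9)
  }
})

test_that("barycenters and area ratios are invariant to the conductivity scalar", {
  geom1 <- test_geometry(sigma = 1)
  geom2 <- test_geometry(sigma = 42)
  sim1 <- simulate_recording(sim_config(geom1, center_norm = 0.4,
                                        noise_sd_mv = 0), seed = 5)
  sim2 <- simulate_recording(sim_config(geom2, center_norm = 0.4,
                                        noise_sd_mv = 0), seed = 5)
  r1 <- csd_analyze(sim1$recording, geom1)
  r2 <- csd_analyze(sim2$recording, geom2)
  expect_equal(r1$barycenter_norm, r2$barycenter_norm, tolerance = 1e-9)
  expect_equal(r1$areas / sum(r1$areas), r2$areas / sum(r2$areas),
               tolerance = 1e-9)
})

test_that("CSD areas are spatially sharper than raw EAG amplitudes", {
  geom <- test_geometry()
  for (k in 1:4) {
    cfg <- sim_config(geom, center_norm = geom$positions_norm[k],
                      width_norm = 1e-4, noise_sd_mv = 0)
    sim <- simulate_recording(cfg, seed = k)
    res <- csd_analyze(sim$recording, geom)
    amps <- response_amplitude(preprocess_recording(sim$recording)$traces,
                               sim$recording$time_s, 1)
    expect_lte(participation_ratio(pmax(res$areas, 0)),
               participation_ratio(amps))
  }
})
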