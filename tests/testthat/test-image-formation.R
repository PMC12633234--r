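test_that("Fourier translation implements the DFT shift theorem", {
  set.seed(3)
  img <- matrix(stats::rnorm(32 * 32), 32, 32)
  sl <- fourier_slice(cryosim:::cfft(img), pixel_size = 1)
  # zero shift is a no-op
  expect_identical(apply_translation(sl, 0, 0)$coefficients, sl$coefficients)
  # one-pixel shift in x equals a circular column shift
  sh <- apply_translation(sl, 1, 0)
  back <- Re(cryosim:::cifft(sh$coefficients))
  expect_lt(max(abs(back - img[, c(32, 1:31)])), 1e-10)
  # opposite shifts cancel
  there_back <- apply_translation(apply_translation(sl, 2.7, -1.3), -2.7, 1.3)
  expect_lt(max(Mod(there_back$coefficients - sl$coefficients)), 1e-12)
})

test_that("no-CTF mode returns sigma_e times the shifted projection", {
  gmm <- compact_phantom(6, seed = 2)
  cfg <- image_config(32, 1, sigma_e = 2.5)
  img <- simulate_image(gmm, euler_pose(10, 20, 30), NULL, cfg)
  pr <- project_gmm_analytic(gmm, rotation_from_euler(10, 20, 30), c(32, 32), 1)
  expect_lt(max(abs(img$pixels - 2.5 * pr$pixels)), 1e-9)
  # zero volume -> zero image
  z <- gaussian_mixture_volume(matrix(0, 1, 3), 0, 1)
  expect_true(all(simulate_image(z, euler_pose(), ctf_params(), cfg)$pixels == 0))
})

test_that("the noiseless model is linear in the volume and in sigma_e", {
  a <- compact_phantom(3, seed = 1)
  b <- compact_phantom(4, seed = 2)
  ab <- gaussian_mixture_volume(rbind(a$centers, b$centers),
                                c(a$amplitudes, b$amplitudes),
                                c(a$variances, b$variances))
  pose <- euler_pose(40, 60, 10, tx = 1, ty = 2)
  ctf <- ctf_params(defocus_u = 12000, cs = 2.7, amplitude_contrast = 0.07)
  cfg <- image_config(32, 1)
  ia <- simulate_image(a, pose, ctf, cfg)$pixels
  ib <- simulate_image(b, pose, ctf, cfg)$pixels
  iab <- simulate_image(ab, pose, ctf, cfg)$pixels
  expect_lt(max(abs(iab - (ia + ib))), 1e-9)
  cfg3 <- image_config(32, 1, sigma_e = 3)
  expect_equal(simulate_image(a, pose, ctf, cfg3)$pixels, 3 * ia,
               tolerance = 1e-12)
})

test_that("the image spectrum is sigma_e sin(chi) times the projection spectrum", {
  gmm <- compact_phantom(5, seed = 5)
  cfg <- image_config(32, 1, sigma_e = 1.7)
  ctf <- ctf_params(defocus_u = 9000, cs = 0, voltage = 300)
  img <- simulate_image(gmm, euler_pose(15, 75, 0), ctf, cfg)
  proj <- project_gmm_analytic(gmm, rotation_from_euler(15, 75, 0), c(32, 32), 1)
  q <- frequency_grid_2d(c(32, 32), 1)
  lhs <- cryosim:::cfft(img$pixels)
  rhs <- 1.7 * evaluate_ctf(q, ctf) * cryosim:::cfft(proj$pixels)
  expect_lt(max(Mod(lhs - rhs)), 1e-9 * max(Mod(rhs)))
})

test_that("analytic and voxel representations produce matching images", {
  gmm <- compact_phantom(10, seed = 1)
  cfg <- image_config(64, 1)
  fv <- fourier_from_real(rasterize_gmm(gmm, 64, 1))
  pose <- euler_pose(31, 57, 12, tx = 2, ty = -1)
  i1 <- simulate_image(gmm, pose, ctf_params(), cfg)
  i2 <- simulate_image(fv, pose, ctf_params(), cfg)
  expect_gt(ncc(i1$pixels, i2$pixels), 0.999)
})

test_that("white noise has the stated variance and is seed-reproducible", {
  n <- sample_noise(noise_model_white(1), c(256, 256), seed = 1)
  # chi-square bound: sd of the sample variance is sqrt(2/(N-1))
  se <- sqrt(2 / (256^2 - 1))
  expect_lt(abs(stats::var(as.vector(n)) - 1), 3 * se)
  expect_lt(abs(mean(n)), 3 / 256)
  expect_identical(n, sample_noise(noise_model_white(1), c(256, 256), seed = 1))
  n2 <- sample_noise(noise_model_white(1), c(256, 256), seed = 2)
  expect_lt(abs(ncc(n, n2)), 0.05)
})

test_that("a flat colored profile is statistically white", {
  flat <- noise_model_colored(function(q) rep(1, length(q)))
  spectra <- sapply(1:50, function(s) {
    f <- sample_noise(flat, c(64, 64), 1, seed = s)
    radial_power_spectrum(f, 1, 8)$power
  })
  avg <- rowMeans(spectra)
  # expected power for variance-1 white noise is n_pixels in every bin
  expect_lt(max(abs(avg / (64 * 64) - 1)), 0.1)
  v <- mean(sapply(1:50, function(s)
    stats::var(as.vector(sample_noise(flat, c(64, 64), 1, seed = s + 100)))))
  expect_equal(v, 1, tolerance = 0.05)
})

test_that("colored noise reproduces its target radial power profile", {
  prof <- noise_profile_power_law(amplitude = 0.02, exponent = 1, offset = 0.5)
  model <- noise_model_colored(prof)
  spectra <- sapply(1:50, function(s) {
    f <- sample_noise(model, c(64, 64), 1, seed = s)
    radial_power_spectrum(f, 1, 8)$power
  })
  ps <- radial_power_spectrum(sample_noise(model, c(64, 64), 1, seed = 1), 1, 8)
  target <- prof(ps$q) * 64 * 64
  got <- rowMeans(spectra)
  # Monte-Carlo agreement, skipping the DC bin where the profile is capped
  expect_lt(max(abs(got[-1] / target[-1] - 1)), 0.1)
})

test_that("the radial power spectrum localizes known signals", {
  # constant image: all power at zero frequency
  ps <- radial_power_spectrum(matrix(5, 32, 32), 1, 8)
  expect_equal(ps$power[1] * ps$n_modes[1], sum(Mod(stats::fft(matrix(5, 32, 32)))^2),
               tolerance = 1e-9)
  expect_true(all(ps$power[-1] < 1e-18 * ps$power[1]))
  # pure sinusoid: power concentrated in its annulus
  x <- cryosim:::centered_coords(64, 1)
  sine <- outer(rep(1, 64), sin(2 * pi * 8 * x / 64))  # |q| = 8/64
  ps <- radial_power_spectrum(sine, 1, 16)
  hot <- which.max(ps$power)
  expect_true(ps$q[hot] <= 8 / 64 + 0.045 && ps$q[hot] >= 8 / 64 - 0.045)
  expect_gt(ps$power[hot] * ps$n_modes[hot] / sum(ps$power * ps$n_modes), 0.99)
  # Parseval consistency
  set.seed(8)
  r <- matrix(stats::rnorm(64^2), 64, 64)
  ps <- radial_power_spectrum(r, 1, 9)
  expect_equal(sum(ps$power * ps$n_modes), sum(Mod(stats::fft(r))^2),
               tolerance = 1e-6)
})

test_that("noise addition hits the requested SNR", {
  gmm <- compact_phantom(8, seed = 4)
  img <- simulate_image(gmm, euler_pose(30, 50, 10), ctf_params(),
                        image_config(64, 1))
  # vanishing noise at extreme SNR
  quiet <- add_noise_at_snr(img, noise_model_white(1), 1e12, seed = 1)
  expect_lt(max(abs(quiet$pixels - img$pixels)) / max(abs(img$pixels)), 1e-5)
  # unit SNR: added variance matches signal variance within sampling error
  sv <- stats::var(as.vector(img$pixels))
  noisy <- add_noise_at_snr(img, noise_model_white(1), 1, seed = 2)
  added <- noisy$pixels - img$pixels
  se <- sv * sqrt(2 / (64^2 - 1))
  expect_lt(abs(stats::var(as.vector(added)) - sv), 3 * se)
  expect_error(add_noise_at_snr(matrix(0, 8, 8), noise_model_white(1), 1),
               "zero variance|variance")
})

test_that("a 100-image stack at SNR 0.1 has pooled empirical SNR near 0.1", {
  fx <- make_refinement_fixture(n_atoms = 10, n_images = 100, snr = 0.1,
                                perturbation_scale = 0, seed = 6, shape = 32)
  clean <- simulate_stack(fx$truth, fx$stack$poses, fx$stack$ctfs, fx$stack$cfg)
  sig <- apply(clean$pixels, 3, function(m) stats::var(as.vector(m)))
  noi <- sapply(seq_len(100), function(i)
    stats::var(as.vector(fx$stack$pixels[, , i] - clean$pixels[, , i])))
  pooled <- mean(sig) / mean(noi)
  expect_lt(abs(pooled - 0.1) / 0.1, 0.1)
})
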