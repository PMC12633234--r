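test_that("cross-correlation loss is affine-invariant and bounded", {
  set.seed(1)
  a <- matrix(stats::rnorm(64), 8, 8)
  expect_equal(cross_correlation_loss(a, a), -1)
  expect_equal(cross_correlation_loss(a, -a), 1)
  expect_equal(cross_correlation_loss(a, 3 * a + 7), -1, tolerance = 1e-12)
  b <- matrix(stats::rnorm(64), 8, 8)
  l <- cross_correlation_loss(a, b)
  expect_true(l >= -1 && l <= 1)
  expect_error(cross_correlation_loss(a, matrix(1, 8, 8)), "variance")
  expect_error(cross_correlation_loss(a, matrix(0, 4, 4)), "shape")
})

test_that("center gradients vanish at the optimum of noiseless data", {
  truth <- compact_phantom(6, seed = 5)
  poses <- lapply(1:3, function(i) quaternion_pose(random_rotation(seed = i)))
  stack <- simulate_stack(truth, poses, ctf_params(), image_config(32, 1))
  lg <- loss_gradient_wrt_centers(refinement_problem(stack, truth))
  expect_equal(lg$loss, -3, tolerance = 1e-9)
  expect_lt(sqrt(sum(lg$gradient^2)), 1e-6)
})

test_that("center gradients match central finite differences", {
  fx <- make_refinement_fixture(n_atoms = 8, n_images = 4, snr = 0.5,
                                perturbation_scale = 2, seed = 3, shape = 32)
  prob <- fx$problem
  lg <- loss_gradient_wrt_centers(prob)
  cen <- fx$start$centers
  h <- 1e-3
  coords <- cryosim:::with_seed(11, cbind(sample(nrow(cen), 12, replace = TRUE),
                                          sample(3, 12, replace = TRUE)))
  for (r in seq_len(nrow(coords))) {
    i <- coords[r, 1]; d <- coords[r, 2]
    cp <- cen; cp[i, d] <- cp[i, d] + h
    cm <- cen; cm[i, d] <- cm[i, d] - h
    fd <- (loss_gradient_wrt_centers(prob, cp)$loss -
             loss_gradient_wrt_centers(prob, cm)$loss) / (2 * h)
    expect_lt(abs(fd - lg$gradient[i, d]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("a displaced center feels a restoring gradient", {
  truth <- gaussian_mixture_volume(matrix(0, 1, 3), 1, 16)
  pose <- list(quaternion_pose(rotation_identity()))
  stack <- simulate_stack(truth, pose, ctf_params(), image_config(32, 1))
  moved <- gaussian_mixture_volume(matrix(c(2, 0, 0), 1, 3), 1, 16)
  lg <- loss_gradient_wrt_centers(refinement_problem(stack, moved))
  # moving +x increased the loss, so the x-gradient must be positive and
  # match finite differences; gradient descent then points back to x = 0
  expect_gt(lg$gradient[1, 1], 0)
  h <- 1e-3
  lp <- loss_gradient_wrt_centers(refinement_problem(stack,
          gaussian_mixture_volume(matrix(c(2 + h, 0, 0), 1, 3), 1, 16)))$loss
  lm <- loss_gradient_wrt_centers(refinement_problem(stack,
          gaussian_mixture_volume(matrix(c(2 - h, 0, 0), 1, 3), 1, 16)))$loss
  fd <- (lp - lm) / (2 * h)
  expect_lt(abs(fd - lg$gradient[1, 1]) / abs(fd), 1e-4)
})

test_that("the stack gradient is the sum of per-image gradients", {
  fx <- make_refinement_fixture(n_atoms = 5, n_images = 3, snr = 1,
                                perturbation_scale = 1, seed = 9, shape = 32)
  whole <- loss_gradient_wrt_centers(fx$problem)
  parts <- lapply(1:3, function(i) {
    sub <- image_stack(fx$stack$pixels[, , i, drop = FALSE],
                       fx$stack$poses[i], fx$stack$ctfs[[i]], fx$stack$cfg)
    loss_gradient_wrt_centers(refinement_problem(sub, fx$start))
  })
  expect_equal(whole$loss, sum(sapply(parts, `[[`, "loss")), tolerance = 1e-9)
  expect_equal(whole$gradient, Reduce(`+`, lapply(parts, `[[`, "gradient")),
               tolerance = 1e-9)
})

test_that("refinement is deterministic and nearly stationary at the optimum", {
  truth <- compact_phantom(5, seed = 2)
  poses <- lapply(1:2, function(i) quaternion_pose(random_rotation(seed = i)))
  stack <- simulate_stack(truth, poses, ctf_params(), image_config(32, 1))
  prob <- refinement_problem(stack, truth)
  tr1 <- refine_centers(prob, steps = 1)
  expect_equal(tr1$loss$loss[1], -2, tolerance = 1e-9)
  expect_error(refine_centers(prob, steps = 0), ">= 1")
  # two identical runs give bitwise-identical traces
  fx <- make_refinement_fixture(n_atoms = 6, n_images = 4, snr = 0.2,
                                perturbation_scale = 2, seed = 4, shape = 32)
  a <- refine_centers(fx$problem, steps = 5)
  b <- refine_centers(fx$problem, steps = 5)
  expect_identical(a$loss, b$loss)
  expect_identical(a$centers, b$centers)
})

test_that("refinement recovers a perturbed toy structure", {
  fx <- make_refinement_fixture(n_atoms = 20, n_images = 16, snr = 0.1,
                                perturbation_scale = 3, seed = 1)
  tr <- refine_centers(fx$problem, steps = 100)
  expect_lt(tr$loss$loss[100], tr$loss$loss[1])
  d0 <- sqrt(rowSums((fx$start$centers - fx$truth$centers)^2))
  d1 <- sqrt(rowSums((tr$centers - fx$truth$centers)^2))
  expect_lt(mean(d1), mean(d0))
})

test_that("FSC is 1 for identical volumes and scale-invariant", {
  g <- compact_phantom(6, seed = 7)
  v <- rasterize_gmm(g, 32, 1)
  f <- fourier_shell_correlation(v, v)
  expect_true(all(abs(f$fsc[f$n_modes > 0] - 1) < 1e-9))
  v2 <- real_voxel_volume(2 * v$grid, 1)
  f2 <- fourier_shell_correlation(v, v2)
  expect_true(all(abs(f2$fsc[f2$n_modes > 0] - 1) < 1e-9))
})

test_that("independent noise volumes decorrelate in every shell", {
  a <- real_voxel_volume(cryosim:::with_seed(1, array(stats::rnorm(64^3), rep(64, 3))), 1)
  b <- real_voxel_volume(cryosim:::with_seed(2, array(stats::rnorm(64^3), rep(64, 3))), 1)
  f <- fourier_shell_correlation(a, b)
  big <- f$n_modes >= 100
  expect_lt(mean(abs(f$fsc[big])), 0.1)
})

test_that("the mismatch score takes its three canonical values", {
  g <- compact_phantom(4, seed = 3)
  u0 <- rasterize_gmm(g, 32, 1)
  # u = u0: no mismatch anywhere unmasked
  s <- mismatch_score(u0, u0)
  expect_true(all(abs(s$grid[!is.na(s$grid)]) < 1e-12))
  # u = 0: score +1 (density missing from the test volume)
  zero <- real_voxel_volume(array(0, rep(32, 3)), 1)
  s1 <- mismatch_score(u0, zero)
  expect_true(all(abs(s1$grid[!is.na(s1$grid)] - 1) < 1e-12))
  # u0 = 0: score -1 (excess density in the test volume)
  sm1 <- mismatch_score(zero, u0, mask_frac = 0)
  vals <- sm1$grid[!is.na(sm1$grid)]
  expect_true(all(abs(vals + 1) < 1e-12))
  # masked voxel count is reported
  expect_gt(attr(s, "n_masked"), 0)
})

test_that("the synthetic fixture honors its contracts", {
  # zero perturbation: start equals truth
  fx <- make_refinement_fixture(n_atoms = 5, n_images = 2, snr = 1,
                                perturbation_scale = 0, seed = 8, shape = 16)
  expect_identical(fx$start$centers, fx$truth$centers)
  # reproducibility
  fx2 <- make_refinement_fixture(n_atoms = 5, n_images = 2, snr = 1,
                                 perturbation_scale = 0, seed = 8, shape = 16)
  expect_identical(fx$stack$pixels, fx2$stack$pixels)
  expect_identical(fx$truth$centers, fx2$truth$centers)
  # equal weights and variances across atoms
  expect_equal(length(unique(fx$truth$amplitudes)), 1L)
  expect_equal(length(unique(fx$truth$variances)), 1L)
})
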