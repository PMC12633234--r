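test_that("electron wavelength matches the relativistic formula", {
  # independent oracle: evaluate h/sqrt(2 m e V (1 + eV/(2 m c^2))) with
  # CODATA constants, written out separately from the implementation
  oracle <- function(kv) {
    V <- kv * 1e3
    num <- 6.62607015e-34
    den <- sqrt(2 * 9.1093837015e-31 * 1.602176634e-19 * V *
                  (1 + 1.602176634e-19 * V /
                     (2 * 9.1093837015e-31 * 299792458^2)))
    num / den * 1e10
  }
  expect_equal(electron_wavelength(300), oracle(300), tolerance = 1e-10)
  expect_equal(electron_wavelength(300), 0.01969, tolerance = 1e-3)
  expect_equal(electron_wavelength(200), 0.02508, tolerance = 1e-3)
  # monotone decreasing in voltage
  expect_true(electron_wavelength(300) < electron_wavelength(200))
  expect_true(electron_wavelength(200) < electron_wavelength(100))
  expect_error(electron_wavelength(0), "> 0")
})

test_that("the defocus aberration phase is -pi lambda df |q|^2", {
  q <- frequency_grid_2d(c(40, 40), 0.5)  # q = k/20, so |q| = 0.05 at k = 1
  chi <- aberration_phase_defocus(q, 10000, 0.02)
  # zero frequency -> zero phase
  expect_equal(chi[21, 21], 0)
  # hand evaluation at |q| = 0.05: chi = -pi * 0.02 * 1e4 * 0.0025 = -pi/2
  qsel <- abs(sqrt(q$qx^2 + q$qy^2) - 0.05) < 1e-12
  expect_true(any(qsel))
  expect_equal(max(abs(chi[qsel] + pi / 2)), 0, tolerance = 1e-10)
  # linear in defocus
  expect_equal(aberration_phase_defocus(q, 20000, 0.02), 2 * chi,
               tolerance = 1e-12)
})

test_that("the astigmatic model reduces to and extends the defocus term", {
  q <- frequency_grid_2d(c(64, 64), 1)
  p0 <- ctf_params(defocus_u = 9000, defocus_v = 9000, cs = 0, voltage = 300)
  lam <- electron_wavelength(300)
  expect_lt(max(abs(aberration_phase_astigmatic(q, p0) -
                      aberration_phase_defocus(q, 9000, lam))), 1e-12)
  # principal axes: df(angle) = du along the astigmatism azimuth, dv at +90
  p <- ctf_params(defocus_u = 12000, defocus_v = 8000, astig_angle = 0,
                  cs = 0, voltage = 300)
  chi <- aberration_phase_astigmatic(q, p)
  ix <- 33 + 10  # +qx axis, angle 0
  expect_equal(chi[33, ix],
               aberration_phase_defocus(q, 12000, lam)[33, ix],
               tolerance = 1e-9)
  expect_equal(chi[ix, 33],
               aberration_phase_defocus(q, 8000, lam)[ix, 33],
               tolerance = 1e-9)
  # 180-degree periodicity in the polar angle
  expect_equal(chi[33, 33 - 10], chi[33, 33 + 10], tolerance = 1e-12)
})

test_that("defocus canonicalization removes the two-fold degeneracy", {
  a <- ctf_params(defocus_u = 8000, defocus_v = 12000, astig_angle = 30)
  expect_gte(a$defocus_u, a$defocus_v)
  expect_equal(a$defocus_u, 12000)
  expect_equal(a$astig_angle, 120)
  q <- frequency_grid_2d(c(32, 32), 1)
  b <- ctf_params(defocus_u = 12000, defocus_v = 8000, astig_angle = 120)
  expect_equal(aberration_phase_astigmatic(q, a),
               aberration_phase_astigmatic(q, b), tolerance = 1e-12)
})

test_that("the CTF is sin chi (plus amplitude-contrast mixing) and bounded", {
  q <- frequency_grid_2d(c(64, 64), 1)
  p <- ctf_params(defocus_u = 10000, cs = 2.7, voltage = 300)
  ctf <- evaluate_ctf(q, p)
  expect_equal(ctf[33, 33], 0)   # sin(0) at q = 0, w = 0
  expect_lte(max(abs(ctf)), 1)
  pw <- ctf_params(defocus_u = 10000, cs = 2.7, voltage = 300,
                   amplitude_contrast = 0.1)
  chi <- aberration_phase_astigmatic(q, pw)
  expect_equal(evaluate_ctf(q, pw),
               sqrt(1 - 0.01) * sin(chi) + 0.1 * cos(chi), tolerance = 1e-12)
  expect_lte(max(abs(evaluate_ctf(q, pw))), 1)
  # rotational symmetry when du = dv
  qmag <- round(sqrt(q$qx^2 + q$qy^2), 10)
  spread <- tapply(as.vector(ctf), as.vector(qmag), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
})

test_that("the first CTF zero sits at |q| = sqrt(1/(lambda df))", {
  # defocus-only model with lambda = 0.02 A, df = 10000 A
  px <- 1
  n <- 512  # fine grid to localize the sign change
  qs <- seq(1e-4, 0.1, length.out = n)
  ctfvals <- sin(-pi * 0.02 * 10000 * qs^2)
  flip <- which(diff(sign(ctfvals)) != 0)[1]
  q_zero <- (qs[flip] + qs[flip + 1]) / 2
  expect_equal(q_zero, sqrt(1 / (0.02 * 10000)), tolerance = 1e-3)
  # and the package's CTF crosses zero at the same frequency
  chi_fn <- function(grid, p) aberration_phase_defocus(grid, 10000, 0.02)
  expect_equal(ctf_first_zero(ctf_params(defocus_u = 10000), chi_fn),
               sqrt(1 / (0.02 * 10000)), tolerance = 1e-6)
})

test_that("a custom aberration-phase plug-in is a first-class CTF", {
  q <- frequency_grid_2d(c(32, 32), 1.5)
  p <- ctf_params(defocus_u = 15000, defocus_v = 15000, cs = 0, voltage = 300,
                  amplitude_contrast = 0, phase_shift = 0)
  custom <- function(grid, params) {
    lam <- electron_wavelength(params$voltage)
    -pi * lam * params$defocus_u * (grid$qx^2 + grid$qy^2)
  }
  expect_equal(evaluate_ctf(q, p, chi_fn = custom), evaluate_ctf(q, p),
               tolerance = 1e-12)
  # the whole image pipeline is identical under the plug-in
  gmm <- compact_phantom(5, seed = 1)
  cfg <- image_config(32, 1.5)
  i1 <- simulate_image(gmm, euler_pose(10, 40, 5), p, cfg)
  i2 <- simulate_image(gmm, euler_pose(10, 40, 5), p, cfg, chi_fn = custom)
  expect_equal(i1$pixels, i2$pixels, tolerance = 1e-12)
  # contract violation: wrong output shape is an interface error
  bad <- function(grid, params) matrix(0, 2, 2)
  expect_error(evaluate_ctf(q, p, chi_fn = bad), "shape")
})

test_that("parameter validation rejects unphysical optics", {
  expect_error(ctf_params(voltage = -1), "voltage")
  expect_error(ctf_params(amplitude_contrast = 1), "amplitude_contrast")
  expect_error(frequency_grid_2d(c(33, 32), 1), "even")
})
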