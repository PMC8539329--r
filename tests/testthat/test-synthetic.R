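test_that("freely-jointed chain fixture encodes the closed-form Rg", {
  # two equal beads one bond apart: every sample has Rg = b/2
  tr <- gen_gaussian_chain(2L, 1, n_samples = 25L, seed = 1L)
  rg <- analyze_rg(tr)
  expect_equal(rg$series, rep(0.5, 25L), tolerance = 1e-12)

  # collapsed chain
  tr0 <- gen_gaussian_chain(50L, 0, n_samples = 5L, seed = 1L)
  expect_equal(analyze_rg(tr0)$series, rep(0, 5L))

  # ensemble mean within 5% of sqrt(n b^2 / 6)
  tr <- gen_gaussian_chain(1000L, 0.1, n_samples = 200L, seed = 7L)
  m <- analyze_rg(tr)$mean
  expect_lt(abs(m / tr$ground_truth$rg - 1), 0.05)
})

test_that("Brownian tracer fixture has the stated step statistics", {
  tr <- gen_brownian_tracer(0, n_steps = 50L, seed = 1L)
  expect_true(all(tr$coords == 0))

  D <- 1e-5                                  # cm^2/s -> 1e-3 nm^2/ps
  tr <- gen_brownian_tracer(D, dt = 2, n_steps = 4000L, n_tracers = 4L,
                            seed = 5L)
  steps <- apply(tr$coords, c(1, 2), diff)   # [step, tracer, axis]
  expect_equal(mean(steps^2), 2 * (D * 100) * 2, tolerance = 0.05)
})

test_that("condensation fixture geometry matches its ground truth", {
  tr <- gen_condensation_fixture(L = 10, n_inside = 5L, n_outside = 10L,
                                 seed = 3L)
  topo <- tr$topology
  X <- tr$coords[, , 1L]
  poly <- which(topo$atoms$molecule == "polymer")
  ions <- which(topo$atoms$molecule == "ion")
  dmin <- vapply(ions, function(i) {
    min(vapply(poly, function(j) oracle_dist(X[i, ], X[j, ], tr$box[1L]),
               numeric(1)))
  }, numeric(1))
  expect_true(all(dmin[1:5] < 0.3))
  expect_true(all(dmin[6:15] > 0.4))
  expect_equal(tr$ground_truth$gamma, 0.5)
})

test_that("water-shell fixture reproduces prescribed orientations exactly", {
  want <- c(-1, -cos(54.7356 * pi / 180), 1, 0.25, 0)
  tr <- gen_water_shell(want, distances = c(0.3, 0.3, 0.45, 0.2, 0.49),
                        seed = 11L)
  oh <- water_orientation(tr)
  expect_equal(sort(oh$samples), sort(want), tolerance = 1e-9)
  # rigid geometry of every generated water
  topo <- tr$topology
  for (i in seq_along(want)) {
    o <- tr$coords[2L + 3L * (i - 1L), , 1L]
    h1 <- tr$coords[3L + 3L * (i - 1L), , 1L]
    h2 <- tr$coords[4L + 3L * (i - 1L), , 1L]
    expect_equal(sqrt(sum((h1 - o)^2)), 0.1, tolerance = 1e-12)
    cosang <- sum((h1 - o) * (h2 - o)) / 0.01
    expect_equal(acos(cosang) * 180 / pi, 109.47, tolerance = 1e-9)
  }
  # out-of-shell water contributes no sample
  far <- gen_water_shell(-1, distances = 0.6, seed = 2L)
  expect_equal(water_orientation(far)$n_samples, 0L)
})

test_that("Debye length follows the closed form and decreases with salt", {
  expect_equal(debye_length(0.6), 0.3927, tolerance = 1e-3)
  lam <- debye_length(c(0.006, 0.06, 0.6))
  expect_true(all(diff(lam) < 0))
  expect_equal(debye_length(0), Inf)
})

test_that("CG integrator: static at zero temperature, bit-reproducible, and
           failing loudly on blow-up", {
  m0 <- cg_model(6L, bead_charges = 0, molarity = 0, temperature = 0,
                 seed = 1L)
  tr <- run_cg_langevin(m0, n_steps = 200L, sample_every = 20L)
  expect_equal(max(abs(tr$coords[, , 10L] - tr$coords[, , 1L])), 0)

  m <- cg_model(12L, bead_charges = -1, molarity = 0.06, seed = 42L)
  a <- run_cg_langevin(m, n_steps = 500L, sample_every = 50L)
  b <- run_cg_langevin(m, n_steps = 500L, sample_every = 50L)
  expect_identical(a$coords, b$coords)

  bad <- cg_model(8L, bond_k = 1000, dt = 100, seed = 1L)
  expect_error(run_cg_langevin(bad, n_steps = 500L, max_disp = Inf),
               "non-finite coordinate at step")
})
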