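test_that("radius of gyration: closed cases and invariances", {
  expect_equal(radius_of_gyration(matrix(1, 5, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_error(radius_of_gyration(matrix(0, 0, 3)), "empty")

  set.seed(8)
  for (rep in 1:10) {
    X <- matrix(stats::rnorm(30), 10, 3)
    m <- stats::runif(10, 0.5, 2)
    rg <- radius_of_gyration(X, m)
    # translation
    expect_equal(radius_of_gyration(sweep(X, 2, stats::rnorm(3), "+"), m), rg)
    # rotation (random orthogonal matrix via QR)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    expect_equal(radius_of_gyration(X %*% Q, m), rg)
    # scaling by alpha scales Rg by alpha
    a <- stats::runif(1, 0.2, 3)
    expect_equal(radius_of_gyration(a * X, m), a * rg)
  }
})

test_that("Rg over a wrapped trajectory unwraps by bond walking and
           detects broken molecules", {
  # 5-bead chain straddling the periodic boundary of a 2 nm box
  xs <- c(1.8, 1.9, 0.0, 0.1, 0.2)   # wrapped x positions, bonds of 0.1
  coords <- cbind(xs, 0.5, 0.5)
  atoms <- tiny_atoms(rep("C", 5))
  sys <- tiny_system(atoms, coords, bonds = cbind(1:4, 2:5), box = 2)
  sys$backbone <- 1:5
  tr <- system_trajectory(sys)
  tr$box <- 2
  rg <- analyze_rg(tr)
  # same chain laid out contiguously
  ref <- radius_of_gyration(cbind(c(1.8, 1.9, 2.0, 2.1, 2.2), 0.5, 0.5),
                            atoms$mass)
  expect_equal(rg$mean, ref, tolerance = 1e-12)

  # genuinely broken: a bond that no unwrapping can shorten
  sys2 <- sys
  sys2$coords[3, 1] <- 0.8
  tr2 <- system_trajectory(sys2)
  tr2$box <- 2
  expect_error(analyze_rg(tr2), "broken molecule")
})

test_that("counterion condensation recovers fixture ground truth and
           applies a strict cutoff", {
  tr <- gen_condensation_fixture(L = 10, n_inside = 5L, n_outside = 10L,
                                 seed = 3L, n_frames = 3L)
  res <- counterion_condensation(tr)
  expect_equal(res$mean, tr$ground_truth$gamma)

  # ion at exactly 0.30 nm is not counted; just inside is
  atoms <- rbind(tiny_atoms("C"), tiny_atoms("Na", "ion"))
  for (d in c(0.30, 0.2999999)) {
    sys <- tiny_system(atoms, rbind(c(0, 0, 0), c(d, 0, 0)), length_nm = 1)
    res <- counterion_condensation(system_trajectory(sys), L = 1)
    expect_equal(res$mean, if (d < 0.3) 1 else 0)
  }
  expect_error(counterion_condensation(tr, L = -1), "L must be > 0")
})

test_that("condensation count around an isolated atom matches the
           ideal-gas expectation", {
  set.seed(31)
  box <- 5; n_ion <- 1500L; nf <- 150L
  atoms <- rbind(tiny_atoms("C"), tiny_atoms(rep("Na", n_ion), "ion"))
  frames <- lapply(seq_len(nf), function(f) {
    rbind(c(box / 2, box / 2, box / 2),
          matrix(stats::runif(3 * n_ion, 0, box), ncol = 3))
  })
  sys <- tiny_system(atoms, frames[[1]], box = box, length_nm = 1)
  tr <- trajectory(frames, box = box, topology = sys)
  res <- counterion_condensation(tr, cutoff = 0.3, L = 1)
  expected <- n_ion / box^3 * 4 / 3 * pi * 0.3^3
  se <- sqrt(expected / nf)
  expect_lt(abs(res$mean - expected), 4 * se)
})

test_that("condensation and bridge counts are non-decreasing in cutoff", {
  fix <- make_contact_fixture(seed = 10L)
  cuts <- c(0.15, 0.3, 0.5, 0.8)
  cond <- vapply(cuts, function(cc)
    counterion_condensation(fix$traj, cutoff = cc, L = 1)$mean, numeric(1))
  brid <- vapply(cuts, function(cc)
    cation_bridges(fix$traj, cutoff = cc, L = 1)$mean, numeric(1))
  expect_true(all(diff(cond) >= 0))
  expect_true(all(diff(brid) >= 0))
})

test_that("Manning parameter arithmetic and threshold", {
  m <- manning_parameter(11.8, 48)
  expect_equal(m$xi, 0.714 * 48 / 11.8, tolerance = 1e-12)
  expect_true(m$condensation_predicted)
  m <- manning_parameter(11.8, 12)
  expect_equal(m$xi, 0.714 * 12 / 11.8, tolerance = 1e-12)
  expect_false(m$condensation_predicted)
  # boundary: xi = 1 exactly is not condensation (strict >)
  m <- manning_parameter(2, 2, bjerrum_length = 1)
  expect_equal(m$xi, 1)
  expect_false(m$condensation_predicted)
  # no charges
  m <- manning_parameter(11.8, 0)
  expect_equal(m$xi, 0)
  expect_false(m$condensation_predicted)
  expect_error(manning_parameter(0, 5), "> 0")
})

test_that("water orientation histogram: landmarks, normalization,
           rotation invariance", {
  tr <- gen_water_shell(c(-1, -0.577, 1), seed = 2L)
  oh <- water_orientation(tr, n_bins = 40L)
  expect_equal(sum(oh$frequencies), 1, tolerance = 1e-9)
  expect_equal(oh$bin_edges[1], -1)
  expect_equal(oh$bin_edges[41], 1)
  # -0.577 lands in the bin spanning (-0.6, -0.55]; -1 and +1 in the
  # outermost bins
  hit <- oh$bin_mid[oh$counts > 0]
  expect_true(all(vapply(hit, function(x)
    min(abs(x - c(-0.975, -0.575, 0.975))) < 1e-9, logical(1))))

  # rigid rotation of every frame leaves the histogram unchanged
  set.seed(9)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  tr2 <- tr
  tr2$coords[, , 1] <- tr$coords[, , 1] %*% Q
  tr2$topology$coords <- tr2$coords[, , 1]
  oh2 <- water_orientation(tr2, n_bins = 40L)
  expect_equal(oh2$frequencies, oh$frequencies)
  expect_equal(sort(oh2$samples), sort(oh$samples), tolerance = 1e-9)

  expect_error(water_orientation(gen_condensation_fixture(seed = 1L)),
               "no waters")
})

test_that("msd: static, ballistic and origin bookkeeping", {
  arr <- array(0, c(1, 3, 50))
  tr <- trajectory(arr, times = 0:49)
  m <- msd(tr, selection = 1L)
  expect_true(all(m$msd == 0))
  expect_equal(m$msd[1], 0)  # msd(0) = 0 by definition

  v <- 0.05
  arr[1, 1, ] <- v * (0:49)
  tr <- trajectory(arr, times = 0:49)
  m <- msd(tr, selection = 1L, lags = c(1, 5, 10, 20))
  expect_equal(m$msd[-1], (v * c(1, 5, 10, 20))^2, tolerance = 1e-12)
  expect_true(all(diff(m$lag) > 0))

  expect_error(msd(trajectory(array(0, c(1, 3, 1)))), "fewer than 2 frames")
})

test_that("diffusion fit recovers exact linear input and documents the
           unit conversion", {
  # msd(tau) = 6 D tau with D = 0.2e-5 cm^2/s = 0.2e-3 nm^2/ps
  lag <- c(0, 10^(0:4))
  curve <- structure(list(lag = lag, msd = 6 * 0.2e-3 * lag,
                          n_origins = rep(1L, 6)), class = "msd_curve")
  fit <- fit_diffusion(curve)
  expect_equal(fit$D, 0.2e-5, tolerance = 1e-12)
  expect_equal(fit$D_se, 0, tolerance = 1e-15)

  zero <- structure(list(lag = lag, msd = lag * 0, n_origins = rep(1L, 6)),
                    class = "msd_curve")
  expect_equal(fit_diffusion(zero)$D, 0)
  expect_error(fit_diffusion(curve, t_min = 2e4, t_max = 3e4), "empty fit")
})

test_that("Brownian fixtures recover D within 10% across seeds", {
  for (seed in c(101L, 202L, 303L)) {
    tr <- gen_brownian_tracer(1.0e-5, dt = 1, n_steps = 2e4,
                              n_tracers = 16L, seed = seed)
    fit <- fit_diffusion(msd(tr, n_restarts = 20000L), t_min = 1,
                         t_max = 2000)
    expect_lt(abs(fit$D / 1.0e-5 - 1), 0.10, label = paste("seed", seed))
  }
})

test_that("cation bridges follow the two-contact rule", {
  # one cation flanked by two carboxylate oxygens at 0.25 nm
  atoms <- rbind(tiny_atoms(c("O", "O"), roles = "carboxylate-O"),
                 tiny_atoms("Na", "ion"))
  sys <- tiny_system(atoms, rbind(c(-0.25, 0, 0), c(0.25, 0, 0), c(0, 0, 0)),
                     length_nm = 1)
  expect_equal(cation_bridges(system_trajectory(sys), L = 1)$mean, 1)

  # single contact: no bridge
  sys$coords[2, ] <- c(0.9, 0, 0)
  expect_equal(cation_bridges(system_trajectory(sys), L = 1)$mean, 0)

  # three contacts: one bridging cation, or three pairs under count="pairs"
  atoms <- rbind(tiny_atoms(c("O", "O", "O"), roles = "carboxylate-O"),
                 tiny_atoms("Na", "ion"))
  sys <- tiny_system(atoms, rbind(c(-0.25, 0, 0), c(0.25, 0, 0),
                                  c(0, 0.25, 0), c(0, 0, 0)), length_nm = 1)
  tr <- system_trajectory(sys)
  expect_equal(cation_bridges(tr, L = 1)$mean, 1)
  expect_equal(cation_bridges(tr, L = 1, count = "pairs")$mean, 3)
  expect_error(cation_bridges(system_trajectory(tiny_system(
    tiny_atoms("C"), matrix(0, 1, 3)))), "no tagged")
})

test_that("hydrogen bonds follow the distance criterion with covalent
           exclusions", {
  # donor amide N-H with a carbonyl O acceptor
  make_sys <- function(d_no) {
    atoms <- rbind(tiny_atoms("N", roles = "amide-N"),
                   tiny_atoms("H"),
                   tiny_atoms("O", roles = "carbonyl-O"))
    tiny_system(atoms, rbind(c(0, 0, 0), c(0.1, 0, 0), c(d_no, 0, 0)),
                bonds = cbind(1L, 2L), donors = cbind(1L, 2L), length_nm = 1)
  }
  expect_equal(hydrogen_bonds(system_trajectory(make_sys(0.29)), L = 1)$mean, 1)
  expect_equal(hydrogen_bonds(system_trajectory(make_sys(0.31)), L = 1)$mean, 0)

  # covalently adjacent O-C=O within one group is excluded (1-3 pair)
  atoms <- rbind(tiny_atoms("O", roles = "hydroxyl-O"),
                 tiny_atoms("H"), tiny_atoms("C"),
                 tiny_atoms("O", roles = "carbonyl-O"))
  coords <- rbind(c(0, 0, 0), c(-0.1, 0, 0), c(0.13, 0, 0), c(0.25, 0, 0))
  sys <- tiny_system(atoms, coords,
                     bonds = rbind(c(1L, 2L), c(1L, 3L), c(3L, 4L)),
                     donors = cbind(1L, 2L), length_nm = 1)
  expect_equal(hydrogen_bonds(system_trajectory(sys), L = 1)$mean, 0)

  expect_error(hydrogen_bonds(system_trajectory(tiny_system(
    tiny_atoms("C"), matrix(0, 1, 3), bonds = cbind(1L, 1L)))), "donor")
})

test_that("distance-count statistics match the brute-force oracle", {
  fix <- make_contact_fixture(n_frames = 12L, seed = 77L)
  tr <- fix$traj
  topo <- tr$topology
  a <- topo$atoms
  tagged <- which(a$molecule == "polymer" &
                    a$role %in% c("carbonyl-O", "carboxylate-O",
                                  "sulfonate-O", "ether-O", "hydroxyl-O"))
  donors <- unique(topo$donors[, 1])
  acceptors <- which(a$molecule == "polymer" &
                       a$role %in% c("carbonyl-O", "carboxylate-O",
                                     "sulfonate-O", "ether-O", "hydroxyl-O",
                                     "amide-N"))
  cond <- counterion_condensation(tr, L = 1)
  brid <- cation_bridges(tr, L = 1)
  brid_p <- cation_bridges(tr, L = 1, count = "pairs")
  hb <- hydrogen_bonds(tr, L = 1)
  any_nonzero <- FALSE
  for (f in seq_len(n_frames(tr))) {
    X <- tr$coords[, , f]
    box <- tr$box[f]
    expect_equal(attr(cond, "counts")[f],
                 oracle_condensed(X, fix$poly, fix$cations, box, 0.3))
    expect_equal(brid$series[f],
                 oracle_bridges(X, fix$cations, tagged, box, 0.3))
    expect_equal(brid_p$series[f],
                 oracle_bridges(X, fix$cations, tagged, box, 0.3, pairs = TRUE))
    expect_equal(hb$series[f],
                 oracle_hbonds(X, donors, acceptors, topo$bonds, box, 0.30))
    any_nonzero <- any_nonzero || cond$series[f] > 0 || hb$series[f] > 0
  }
  expect_true(any_nonzero)  # the comparison must not be vacuous
})
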