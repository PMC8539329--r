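test_that("ions respect the 0.8 nm exclusion and the counterion-first order", {
  spec <- build_spec("HPAM", nacl_molarity = 0.06, seed = 5L)
  s <- place_ions(build_chain(spec))
  a <- s$atoms
  ions <- which(a$molecule == "ion")
  expect_equal(length(ions), 12L + 36L + 36L)
  # counterions (Na) come first, then salt Na, then Cl
  expect_equal(a$element[ions[1:48]], rep("Na", 48L))
  expect_equal(a$element[ions[49:84]], rep("Cl", 36L))
  poly <- s$coords[a$molecule == "polymer", ]
  d <- vapply(ions, function(i) {
    min(vapply(seq_len(nrow(poly)), function(j)
      oracle_dist(s$coords[i, ], poly[j, ], s$box), numeric(1)))
  }, numeric(1))
  expect_true(all(d >= 0.8))
})

test_that("neutral PAM at 0.006 M gets 0 counterions and 4+4 salt ions", {
  s <- place_ions(build_chain(build_spec("PAM", nacl_molarity = 0.006)),
                  seed = 2L)
  expect_equal(s$counterion_count, 0L)
  expect_equal(s$salt_na, 4L)
  expect_equal(s$salt_cl, 4L)
  expect_equal(sum(s$atoms$element == "Na"), 4L)
})

test_that("an overcrowded box raises a capacity error", {
  spec <- build_spec("PAM", n_monomers = 2L, box_edge = 0.8, seed = 1L)
  spec$nacl_molarity <- 0.6   # force a nonzero ion count in the tiny box
  spec$ion_box_edge <- 10
  sys <- build_chain(spec)
  expect_error(place_ions(sys, seed = 1L, max_tries = 20L), "capacity")
})

test_that("water fills an empty box to bulk density within 2%", {
  s <- insert_water(empty_system(10), seed = 3L)
  expect_lt(abs(s$water_count / 33400 - 1), 0.02)
  # SPC/E internal geometry of the first few molecules
  w <- which(s$atoms$molecule == "water")
  for (res in 1:5) {
    idx <- w[s$atoms$resid[w] == res]
    o <- s$coords[idx[1], ]; h1 <- s$coords[idx[2], ]; h2 <- s$coords[idx[3], ]
    expect_equal(sqrt(sum((h1 - o)^2)), 0.1, tolerance = 1e-9)
    expect_equal(sqrt(sum((h2 - o)^2)), 0.1, tolerance = 1e-9)
    cosang <- sum((h1 - o) * (h2 - o)) / 0.01
    expect_equal(acos(cosang) * 180 / pi, 109.47, tolerance = 1e-6)
  }
})

test_that("waters overlapping the solute are deleted", {
  base <- empty_system(4)
  base$atoms <- tiny_atoms("C")
  base$coords <- matrix(2, 1L, 3L)
  s <- insert_water(base, seed = 7L)
  wat <- s$coords[s$atoms$molecule == "water", , drop = FALSE]
  dmin <- min(vapply(seq_len(nrow(wat)), function(i)
    oracle_dist(wat[i, ], c(2, 2, 2), 4), numeric(1)))
  expect_gte(dmin, 0.2)
})

test_that("solvated PAM water count is within 3% of the reference 32408", {
  s <- build_system(build_spec("PAM", nacl_molarity = 0.006, seed = 1L))
  expect_lt(abs(s$water_count / 32408 - 1), 0.03)
  # bookkeeping: GRO atom count = polymer + ions + 3 * waters
  f <- tempfile(fileext = ".gro")
  write_gro(s, f)
  g <- read_gro(f)
  expect_equal(nrow(g$coords),
               sum(s$atoms$molecule == "polymer") + 8L + 3L * s$water_count)
})
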