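REF <- utils::read.csv(system.file("extdata", "table1_reference.csv",
                                   package = "polysalt"))

test_that("chain composition follows the specification", {
  hp <- build_chain(build_spec("HPAM"))
  tab <- table(hp$atoms$resname[!duplicated(hp$atoms$monomer)])
  expect_equal(unname(tab[["AM"]]), 36L)
  expect_equal(unname(tab[["AA"]]), 12L)

  pa <- build_chain(build_spec("PAA"))
  expect_equal(pa$counterion_count, 48L)

  pm <- build_chain(build_spec("PAMPS"))
  tab <- table(pm$atoms$resname[!duplicated(pm$atoms$monomer)])
  expect_equal(unname(tab[["AMPS"]]), 12L)
})

test_that("single-monomer PAM is acrylamide with two hydrogen caps", {
  s <- build_chain(build_spec("PAM", n_monomers = 1L))
  expect_equal(molecular_weight(s), 73.0951, tolerance = 1e-6)
  expect_equal(sum(s$atoms$charge), 0, tolerance = 1e-9)
  comp <- table(s$atoms$element)
  expect_equal(unname(comp[c("C", "H", "N", "O")]), c(3L, 7L, 1L, 1L),
               ignore_attr = TRUE)
})

test_that("extended chain lengths match the reference within 5%", {
  for (i in seq_len(nrow(REF))) {
    s <- build_chain(build_spec(REF$polymer[i]))
    expect_lt(abs(contour_length(s) / REF$length_nm[i] - 1), 0.05,
              label = paste(REF$polymer[i], "length"))
  }
})

test_that("molecular weight bookkeeping is consistent between HPAM and PAA", {
  mw_hpam <- molecular_weight(build_chain(build_spec("HPAM")))
  mw_paa <- molecular_weight(build_chain(build_spec("PAA")))
  expect_lt(abs(mw_hpam - mw_paa), 1)
})

test_that("salt ion counts scale with molarity and box volume", {
  expect_equal(unname(salt_ion_count(0, 10)), c(0L, 0L))
  # monotone non-decreasing in molarity
  cs <- seq(0, 1, by = 0.02)
  ns <- vapply(cs, function(c) salt_ion_count(c, 10)[[1L]], integer(1))
  expect_true(all(diff(ns) >= 0L))
  # volume scaling: doubling the edge multiplies the count by 8 (rounding)
  for (c in c(0.006, 0.05, 0.31)) {
    n1 <- salt_ion_count(c, 5)[[1L]]
    n8 <- salt_ion_count(c, 10)[[1L]]
    expect_lt(abs(n8 - 8 * c * 0.6022140857 * 125), 0.5 + 1e-9)
    expect_equal(n8, as.integer(floor(8 * c * 0.6022140857 * 5^3 + 0.5)))
    expect_gte(n8, n1)
  }
  expect_error(salt_ion_count(-0.1, 10), "negative")
})

test_that("build is deterministic: same spec and seed, identical system", {
  spec <- build_spec("HPAM", nacl_molarity = 0.06, seed = 9L)
  a <- place_ions(build_chain(spec))
  b <- place_ions(build_chain(spec))
  expect_identical(a$coords, b$coords)
  expect_identical(a$atoms, b$atoms)
})

test_that("charge closure holds for every neutralized system", {
  for (p in REF$polymer) {
    s <- place_ions(build_chain(build_spec(p, nacl_molarity = 0.006)),
                    seed = 3L)
    expect_lt(abs(sum(s$atoms$charge)), 1e-6)
  }
})

test_that("backbone atoms are mutually bonded in order", {
  for (p in c("PAM", "PEO", "GUAR")) {
    s <- build_chain(build_spec(p))
    key <- paste(pmin(s$bonds[, 1], s$bonds[, 2]),
                 pmax(s$bonds[, 1], s$bonds[, 2]))
    bb <- s$backbone
    need <- paste(pmin(bb[-length(bb)], bb[-1]), pmax(bb[-length(bb)], bb[-1]))
    expect_true(all(need %in% key), label = paste(p, "backbone bonded"))
  }
})

test_that("contour length of a bare two-bead chain is the bond length", {
  atoms <- tiny_atoms(c("C", "C"))
  sys <- tiny_system(atoms, rbind(c(0, 0, 0), c(0.154, 0, 0)))
  sys$backbone <- 1:2
  expect_equal(contour_length(sys), 0.154)
})

test_that("invalid build specifications are rejected", {
  expect_error(build_spec("PVC"), "unknown polymer")
  expect_error(build_spec("HPAM", n_monomers = 10L,
                          substitution_fraction = 0.25), "integer")
  expect_error(build_spec("PAM", box_edge = -1), "box_edge")
  expect_error(build_spec("PAM", nacl_molarity = -0.1), "molarity")
})
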