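# Brute-force reference implementations, independent of the package's
# vectorized/chunked distance code paths.  Used as oracles for the
# pairwise-distance-based counting statistics.

oracle_dist <- function(a, b, box = NA) {
  d <- a - b
  if (is.finite(box)) d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# number of distinct cations with distance < cutoff to any polymer atom
oracle_condensed <- function(X, poly, cations, box, cutoff) {
  n <- 0L
  for (i in cations) {
    for (j in poly) {
      if (oracle_dist(X[i, ], X[j, ], box) < cutoff) { n <- n + 1L; break }
    }
  }
  n
}

# cations touching >= 2 tagged atoms (and the pair-count variant)
oracle_bridges <- function(X, cations, tagged, box, cutoff, pairs = FALSE) {
  total <- 0L
  for (i in cations) {
    k <- 0L
    for (j in tagged) {
      if (oracle_dist(X[i, ], X[j, ], box) < cutoff) k <- k + 1L
    }
    if (k >= 2L) total <- total + (if (pairs) choose(k, 2L) else 1L)
  }
  total
}

# hydrogen bonds: unordered electronegative pairs < cutoff with at least
# one donor partner, excluding pairs within 2 covalent bonds.  The
# covalent exclusion is derived from powers of the adjacency matrix -- a
# mechanism unrelated to the package's breadth-first search.
oracle_hbonds <- function(X, donors, acceptors, bonds, box, cutoff) {
  n <- nrow(X)
  A <- matrix(0L, n, n)
  A[bonds] <- 1L
  A[bonds[, 2:1, drop = FALSE]] <- 1L
  near2 <- (A + A %*% A) > 0
  seen <- character(0)
  for (d in donors) {
    for (a in acceptors) {
      if (a == d || near2[d, a]) next
      if (oracle_dist(X[d, ], X[a, ], box) < cutoff) {
        seen <- c(seen, paste(min(d, a), max(d, a)))
      }
    }
  }
  length(unique(seen))
}

# a contact-rich test system: a built PAM chain plus cations scattered
# through the chain's bounding region; frames squeeze and jitter the
# polymer so that contacts, bridges and hydrogen bonds actually occur
make_contact_fixture <- function(n_mono = 12L, n_cations = 30L,
                                 n_frames = 10L, seed = 1L) {
  set.seed(seed)
  sys <- build_chain(build_spec("PAM", n_monomers = n_mono))
  npoly <- nrow(sys$coords)
  lo <- apply(sys$coords, 2L, min) - 0.4
  hi <- apply(sys$coords, 2L, max) + 0.4
  ion_atoms <- data.frame(
    name = "NA", element = "Na", mass = atomic_mass("Na"), charge = 1,
    role = NA_character_, monomer = NA_integer_, molecule = "ion",
    resid = max(sys$atoms$resid) + seq_len(n_cations), resname = "NA",
    stringsAsFactors = FALSE)
  sys$atoms <- rbind(sys$atoms, ion_atoms)
  frames <- vector("list", n_frames)
  cm <- colMeans(sys$coords[seq_len(npoly), ])
  for (f in seq_len(n_frames)) {
    squeeze <- stats::runif(1, 0.35, 1)
    poly <- sweep(sweep(sys$coords[seq_len(npoly), ], 2L, cm), 1, squeeze, "*")
    poly <- sweep(poly, 2L, cm, "+") +
      matrix(stats::runif(npoly * 3L, -0.05, 0.05), npoly, 3L)
    ions <- cbind(stats::runif(n_cations, lo[1], hi[1]),
                  stats::runif(n_cations, lo[2], hi[2]),
                  stats::runif(n_cations, lo[3], hi[3]))
    frames[[f]] <- rbind(poly, ions)
  }
  sys$coords <- frames[[1L]]
  list(traj = trajectory(frames, box = sys$box, topology = sys),
       poly = seq_len(npoly),
       cations = npoly + seq_len(n_cations))
}

# minimal hand-built topology for explicit hydrogen-bond / bridge cases
tiny_system <- function(atoms, coords, bonds = NULL, donors = NULL,
                        box = NA, length_nm = 1) {
  structure(list(atoms = atoms, coords = coords, bonds = bonds,
                 donors = donors, backbone = integer(0), box = box,
                 spec = NULL, counterion_count = 0L, salt_na = 0L,
                 salt_cl = 0L, water_count = 0L, length_nm = length_nm),
            class = "polymer_system")
}

tiny_atom <- function(element, molecule = "polymer", role = NA_character_) {
  data.frame(name = element, element = element,
             mass = atomic_mass(element), charge = 0, role = role,
             monomer = NA_integer_, molecule = molecule, resid = 1L,
             resname = element, stringsAsFactors = FALSE)
}

tiny_atoms <- function(elements, molecules = "polymer",
                       roles = NA_character_) {
  do.call(rbind, Map(tiny_atom, elements,
                     rep_len(molecules, length(elements)),
                     rep_len(roles, length(elements))))
}
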