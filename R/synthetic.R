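## Synthetic trajectories with known ground truth: the desk-scale stand-in
## for long atomistic production runs.  Every fixture records the value(s)
## it encodes in traj$ground_truth so analyses can be tested as
## parameter-recovery problems.

# minimal topology for fixtures
.fixture_system <- function(atoms, coords, box = NA, bonds = NULL,
                            backbone = integer(0), length_nm = NA_real_,
                            donors = NULL) {
  structure(list(atoms = atoms, coords = coords, bonds = bonds,
                 donors = donors, backbone = backbone, box = box,
                 spec = NULL, counterion_count = 0L, salt_na = 0L,
                 salt_cl = 0L, water_count = 0L, length_nm = length_nm),
            class = "polymer_system")
}

.bead_atoms <- function(n, element = "C", molecule = "polymer",
                        name = element, role = NA_character_) {
  data.frame(name = rep_len(name, n), element = rep_len(element, n),
             mass = atomic_mass(rep_len(element, n)),
             charge = 0, role = rep_len(role, n),
             monomer = NA_integer_, molecule = rep_len(molecule, n),
             resid = seq_len(n), resname = rep_len(element, n),
             stringsAsFactors = FALSE)
}

#' Freely-jointed chain samples
#'
#' Generates independent conformations of an ideal freely-jointed chain of
#' `n_beads` beads with fixed bond length `bond_length`; each frame is a
#' fresh sample.  The ensemble-average squared radius of gyration of this
#' model is `n_beads * bond_length^2 / 6` (to leading order in 1/n), which
#' is stored as ground truth.
#'
#' @param n_beads number of beads (>= 2)
#' @param bond_length bond length in nm
#' @param n_samples number of independent conformations (frames)
#' @param seed integer seed
#' @return a `trajectory` with `ground_truth$rg = sqrt(n b^2 / 6)`
#' @export
gen_gaussian_chain <- function(n_beads, bond_length, n_samples = 200L,
                               seed = 1L) {
  stopifnot(n_beads >= 2L, bond_length >= 0, n_samples >= 1L)
  set.seed(seed)
  arr <- array(NA_real_, c(n_beads, 3L, n_samples))
  for (f in seq_len(n_samples)) {
    steps <- bond_length * random_unit_vectors(n_beads - 1L)
    arr[, , f] <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
  }
  atoms <- .bead_atoms(n_beads)
  bonds <- cbind(seq_len(n_beads - 1L), 2:n_beads)
  topo <- .fixture_system(atoms, arr[, , 1L], bonds = bonds,
                          backbone = seq_len(n_beads))
  trajectory(arr, box = NA, topology = topo,
             ground_truth = list(rg = sqrt(n_beads * bond_length^2 / 6)))
}

#' Brownian tracer trajectories with known diffusion coefficient
#'
#' Random walks with per-step displacement variance `2 D dt` per axis, the
#' exact discrete realisation of Brownian motion with diffusion coefficient
#' `D`.  Several independent tracers may be generated; the mean-squared
#' displacement machinery averages over them, which is what makes a 10%
#' recovery of `D` statistically attainable on a desk-scale trajectory
#' (a single tracer's time-averaged MSD at lag tau carries a relative
#' standard deviation of roughly `sqrt(4 tau / (3 T))`, about 35% at the
#' top of a 1:10 lag:length ratio).
#'
#' @param D diffusion coefficient in cm^2/s
#' @param dt time step in ps
#' @param n_steps number of steps (frames = n_steps + 1)
#' @param n_tracers number of independent tracers
#' @param seed integer seed
#' @return a `trajectory` with `ground_truth$D = D` (cm^2/s)
#' @export
gen_brownian_tracer <- function(D, dt = 1, n_steps = 1e5, n_tracers = 1L,
                                seed = 1L) {
  stopifnot(D >= 0, dt > 0, n_steps >= 1L, n_tracers >= 1L)
  set.seed(seed)
  D_nm2ps <- D * 100   # 1 cm^2/s = 100 nm^2/ps
  sd_step <- sqrt(2 * D_nm2ps * dt)
  nf <- n_steps + 1L
  arr <- array(0, c(n_tracers, 3L, nf))
  if (sd_step > 0) {
    for (ax in 1:3) {
      steps <- matrix(stats::rnorm(n_tracers * n_steps, sd = sd_step),
                      n_tracers, n_steps)
      arr[, ax, -1L] <- t(apply(steps, 1L, cumsum))
    }
  }
  atoms <- .bead_atoms(n_tracers, element = "C", molecule = "tracer")
  topo <- .fixture_system(atoms, matrix(arr[, , 1L], ncol = 3L))
  trajectory(arr, times = (seq_len(nf) - 1) * dt, box = NA, topology = topo,
             ground_truth = list(D = D))
}

#' Counterion-condensation fixture with a known condensed count
#'
#' A straight polymer of length `L` along x (atoms every `spacing` nm) with
#' `n_inside` cations placed at distances in (0.05, 0.29) nm from polymer
#' atoms and `n_outside` cations farther than 0.4 nm from every polymer
#' atom.  With the strict `< 0.3 nm` contact criterion the condensation
#' per unit length is `n_inside / L` by construction.
#'
#' @param L polymer length in nm
#' @param n_inside,n_outside cation counts inside/outside the shell
#' @param seed integer seed
#' @param n_frames number of (identical) frames
#' @param spacing polymer atom spacing in nm
#' @return a `trajectory` with `ground_truth$gamma = n_inside / L`
#' @export
gen_condensation_fixture <- function(L = 10, n_inside = 5L, n_outside = 10L,
                                     seed = 1L, n_frames = 1L, spacing = 0.2) {
  stopifnot(L > 0, n_inside >= 0L, n_outside >= 0L)
  set.seed(seed)
  margin <- 1
  box <- L + 2 * margin
  px <- seq(margin, margin + L, by = spacing)
  poly <- cbind(px, box / 2, box / 2)
  ions <- matrix(NA_real_, n_inside + n_outside, 3L)
  if (n_inside > 0L) {
    host <- sample.int(nrow(poly), n_inside, replace = TRUE)
    u <- random_unit_vectors(n_inside)
    d <- stats::runif(n_inside, 0.05, 0.29)
    ions[seq_len(n_inside), ] <- poly[host, , drop = FALSE] + d * u
  }
  got <- 0L
  while (got < n_outside) {
    cand <- matrix(stats::runif(3L * 64L, 0, box), ncol = 3L)
    ok <- min_dist_to_set(cand, poly, box) > 0.4
    take <- which(ok)[seq_len(min(sum(ok), n_outside - got))]
    take <- take[!is.na(take)]
    if (length(take)) {
      ions[n_inside + got + seq_along(take), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  atoms <- rbind(.bead_atoms(nrow(poly)),
                 .bead_atoms(n_inside + n_outside, element = "Na",
                             molecule = "ion", name = "NA"))
  atoms$resid <- seq_len(nrow(atoms))
  coords <- rbind(poly, ions)
  topo <- .fixture_system(atoms, coords, box = box,
                          backbone = seq_len(nrow(poly)), length_nm = L)
  arr <- array(rep(coords, n_frames), c(nrow(coords), 3L, n_frames))
  trajectory(arr, box = box, topology = topo,
             ground_truth = list(gamma = n_inside / L,
                                 n_condensed = n_inside))
}

#' Rigid three-site water from its geometry
#'
#' Builds SPC/E water site coordinates (O-H 0.1 nm, H-O-H 109.47 deg) given
#' the oxygen position and the direction of the first O-H bond; the second
#' hydrogen is placed at the tetrahedral water angle from the first, in the
#' plane selected by `azimuth`.
#'
#' @param o oxygen position (length-3)
#' @param h1_dir direction of the first O-H bond (normalized internally)
#' @param azimuth vector fixing the H-O-H plane (any vector not parallel to
#'   `h1_dir`); a default is chosen if NULL
#' @return 3 x 3 matrix of O, H1, H2 positions (nm)
#' @export
rigid_water <- function(o, h1_dir, azimuth = NULL) {
  u1 <- h1_dir / sqrt(sum(h1_dir^2))
  p <- orthogonal_unit(u1, azimuth)
  th <- .WATER_HOH * pi / 180
  u2 <- cos(th) * u1 + sin(th) * p
  rbind(o, o + .WATER_OH * u1, o + .WATER_OH * u2)
}

#' Water-shell fixture with prescribed dipole orientations
#'
#' Places rigid three-site waters around a single reference (polymer) atom
#' at the origin, each with an exactly prescribed cosine between its dipole
#' (O toward the H-H midpoint) and the outward radial direction.  A value
#' of -1 corresponds to both hydrogens pointing at the reference atom;
#' `-cos(54.735 deg) = -0.577` corresponds to one O-H bond in direct line
#' with it.
#'
#' @param orientations target cos(phi) values, in `[-1, 1]`
#' @param distances O-reference distances in nm (recycled)
#' @param seed integer seed (random azimuthal placement)
#' @return a `trajectory` with `ground_truth$cos = orientations`
#' @export
gen_water_shell <- function(orientations, distances = 0.3, seed = 1L) {
  stopifnot(all(abs(orientations) <= 1))
  set.seed(seed)
  nw <- length(orientations)
  distances <- rep_len(distances, nw)
  coords <- matrix(c(0, 0, 0), 1L, 3L)
  atoms <- .bead_atoms(1L)
  for (i in seq_len(nw)) {
    u <- as.vector(random_unit_vectors(1L))       # atom -> O direction
    o <- distances[i] * u
    cc <- orientations[i]
    w <- orthogonal_unit(u, as.vector(random_unit_vectors(1L)))
    dhat <- cc * u + sqrt(max(0, 1 - cc^2)) * w   # prescribed dipole
    vhat <- orthogonal_unit(dhat, as.vector(random_unit_vectors(1L)))
    coords <- rbind(coords, .water_sites(o, dhat, vhat))
    atoms <- rbind(atoms, data.frame(
      name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
      mass = atomic_mass(c("O", "H", "H")),
      charge = c(.WATER_Q_O, .WATER_Q_H, .WATER_Q_H),
      role = NA_character_, monomer = NA_integer_, molecule = "water",
      resid = 1L + i, resname = "SOL", stringsAsFactors = FALSE))
  }
  topo <- .fixture_system(atoms, coords, backbone = 1L)
  arr <- array(coords, c(nrow(coords), 3L, 1L))
  trajectory(arr, box = NA, topology = topo,
             ground_truth = list(cos = orientations))
}

#' Debye screening length of a NaCl solution
#'
#' `kappa^-1 = (8 pi lB NA c)^(-1/2)` for a 1:1 salt of molarity `c`;
#' decreases monotonically with concentration, infinite at zero salt.
#'
#' @param molarity NaCl concentration in mol/L
#' @param bjerrum_length Bjerrum length in nm (0.714 at 300 K in water)
#' @return Debye length in nm
#' @export
#' @examples
#' debye_length(c(0.006, 0.06, 0.6))
debye_length <- function(molarity, bjerrum_length = .BJERRUM_300K) {
  if (any(molarity < 0)) stop("molarity must be >= 0")
  c_nm3 <- molarity * .AVOGADRO_NM3
  ifelse(c_nm3 > 0, 1 / sqrt(8 * pi * bjerrum_length * c_nm3), Inf)
}

#' Coarse-grained bead-spring model definition
#'
#' Parameters of the overdamped Langevin surrogate used for qualitative
#' salt-response trends: harmonic bonds, Weeks-Chandler-Andersen excluded
#' volume, and Debye-Hueckel screened Coulomb interactions between charged
#' beads (1-2 bonded pairs excluded from non-bonded terms).
#'
#' @param n_beads chain length
#' @param bond_k bond spring constant in kJ/mol/nm^2
#' @param bond_r0 equilibrium bond length in nm
#' @param bead_charges per-bead charges in e (recycled)
#' @param sigma WCA diameter in nm
#' @param epsilon WCA energy in kJ/mol
#' @param molarity NaCl molarity used to derive the Debye length (ignored
#'   if `debye` is given)
#' @param debye Debye screening length in nm
#' @param bjerrum_length Bjerrum length in nm
#' @param friction drag coefficient per unit bead mass, 1/ps
#' @param temperature temperature in K
#' @param dt time step in ps
#' @param seed integer seed
#' @return object of class `cg_model`
#' @export
cg_model <- function(n_beads, bond_k = 1000, bond_r0 = 0.25,
                     bead_charges = 0, sigma = 0.25, epsilon = 2.5,
                     molarity = 0, debye = NULL,
                     bjerrum_length = .BJERRUM_300K,
                     friction = 50, temperature = 300, dt = 0.01, seed = 1L) {
  if (is.null(debye)) debye <- debye_length(molarity, bjerrum_length)
  if (!(debye > 0)) stop("debye length must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  stopifnot(n_beads >= 2L, bond_r0 > 0, friction > 0)
  structure(list(
    n_beads = as.integer(n_beads), bond_k = bond_k, bond_r0 = bond_r0,
    bead_charges = rep_len(bead_charges, n_beads), sigma = sigma,
    epsilon = epsilon, debye = debye, bjerrum_length = bjerrum_length,
    friction = friction, temperature = temperature, dt = dt,
    seed = as.integer(seed)
  ), class = "cg_model")
}

#' Overdamped Langevin dynamics of a bead-spring chain
#'
#' Brownian-dynamics integration `dr = F dt / gamma + sqrt(2 kB T dt /
#' gamma) xi` of the [cg_model()] energy surface, starting from an extended
#' straight chain.  Reproducible per seed; aborts with the step index if a
#' coordinate becomes non-finite.
#'
#' @param model a [cg_model()]
#' @param n_steps number of integration steps
#' @param sample_every store one frame every this many steps
#' @param n_equil discard this many initial steps before sampling
#' @param max_disp per-step displacement clamp in nm; tames the stiff WCA
#'   core on transient overlaps (it only engages where the Boltzmann
#'   weight is negligible, leaving equilibrium averages unaffected)
#' @return a `trajectory` of the sampled frames
#' @export
run_cg_langevin <- function(model, n_steps = 20000L, sample_every = 20L,
                            n_equil = 0L, max_disp = 0.2) {
  stopifnot(inherits(model, "cg_model"))
  n <- model$n_beads
  set.seed(model$seed)
  x <- cbind((seq_len(n) - 1) * model$bond_r0, 0, 0)
  kT <- .KB * model$temperature
  gam <- model$friction          # unit bead mass
  noise_sd <- sqrt(2 * kT * model$dt / gam)
  rc <- 2^(1 / 6) * model$sigma
  q <- model$bead_charges
  # non-bonded pair list: all pairs except bonded neighbours
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pr[, 2L] - pr[, 1L] > 1L
  pi_ <- pr[keep, 1L]; pj_ <- pr[keep, 2L]
  qq <- q[pi_] * q[pj_]
  lB <- model$bjerrum_length
  lam <- model$debye
  bi <- seq_len(n - 1L); bj <- bi + 1L

  total <- n_equil + n_steps
  keep_steps <- which(seq_len(total) > n_equil &
                        (seq_len(total) - n_equil) %% sample_every == 0L)
  frames <- array(NA_real_, c(n, 3L, length(keep_steps)))
  fi <- 0L
  for (step in seq_len(total)) {
    Fb <- matrix(0, n, 3L)
    # bonds
    dv <- x[bj, , drop = FALSE] - x[bi, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    fmag <- model$bond_k * (r - model$bond_r0) / pmax(r, 1e-12)
    fv <- dv * fmag
    acc <- rowsum(rbind(fv, -fv), c(bi, bj))
    Fb[as.integer(rownames(acc)), ] <- Fb[as.integer(rownames(acc)), ] + acc
    # non-bonded
    if (length(pi_)) {
      dv <- x[pj_, , drop = FALSE] - x[pi_, , drop = FALSE]
      r2 <- rowSums(dv * dv)
      r <- sqrt(r2)
      f <- numeric(length(r))
      wca <- r < rc
      if (any(wca)) {
        sr6 <- (model$sigma^2 / r2[wca])^3
        # repulsive force magnitude / r (force on j along +dv)
        f[wca] <- f[wca] - 24 * model$epsilon * (2 * sr6^2 - sr6) / r2[wca]
      }
      el <- qq != 0
      if (any(el)) {
        pref <- kT * lB * qq[el] * exp(-r[el] / lam) / r[el]
        f[el] <- f[el] - pref * (1 / r[el] + 1 / lam) / r[el]
      }
      fv <- dv * f   # force on i along +dv when f > 0 (attraction)
      acc <- rowsum(rbind(fv, -fv), c(pi_, pj_))
      idx <- as.integer(rownames(acc))
      Fb[idx, ] <- Fb[idx, ] + acc
    }
    disp <- Fb * (model$dt / gam) +
      matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    dn <- sqrt(rowSums(disp * disp))
    over <- which(is.finite(dn) & dn > max_disp)
    if (length(over)) disp[over, ] <- disp[over, ] * (max_disp / dn[over])
    x <- x + disp
    if (!all(is.finite(x))) {
      stop("numerical instability: non-finite coordinate at step ", step)
    }
    if (fi < length(keep_steps) && step == keep_steps[fi + 1L]) {
      fi <- fi + 1L
      frames[, , fi] <- x
    }
  }
  atoms <- .bead_atoms(n)
  atoms$charge <- q
  bonds <- cbind(bi, bj)
  topo <- .fixture_system(atoms, frames[, , 1L], bonds = bonds,
                          backbone = seq_len(n))
  trajectory(frames, times = keep_steps * model$dt, box = NA,
             topology = topo)
}
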