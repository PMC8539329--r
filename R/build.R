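#' Declarative build specification for a polymer-salt system
#'
#' Captures the recipe for one solvated polyelectrolyte system: polymer
#' identity, chain length in monomers, charged-monomer substitution
#' fraction, NaCl molarity, periodic cubic box edge and random seed.
#' Defaults reproduce the reference systems: 48 monomers for the
#' acrylamide family, 32 for PEO, 12 for guar; 25% substitution for the
#' HPAM and PAMPS copolymers; a 10 nm box (12 nm for guar, whose salt ion
#' counts nevertheless use the nominal 10 nm volume so that all six
#' polymers see identical ion numbers at a given molarity).
#'
#' @param polymer one of "PAM", "HPAM", "PAMPS", "PAA", "PEO", "GUAR"
#' @param n_monomers chain length in monomers (default per polymer)
#' @param substitution_fraction fraction of charged monomers in copolymers
#' @param nacl_molarity NaCl concentration in mol/L
#' @param box_edge cubic box edge in nm
#' @param tacticity only "syndiotactic" is supported
#' @param seed integer seed controlling ion and water placement
#' @param ion_box_edge box edge used for salt ion counts (defaults to
#'   `box_edge`, except 10 nm for GUAR)
#' @return object of class `build_spec`
#' @export
#' @examples
#' build_spec("HPAM", nacl_molarity = 0.6)
build_spec <- function(polymer, n_monomers = NULL, substitution_fraction = NULL,
                       nacl_molarity = 0, box_edge = NULL,
                       tacticity = "syndiotactic", seed = 1L,
                       ion_box_edge = NULL) {
  known <- c("PAM", "HPAM", "PAMPS", "PAA", "PEO", "GUAR")
  if (!is.character(polymer) || length(polymer) != 1L || !(polymer %in% known)) {
    stop("unknown polymer name: ", paste(polymer, collapse = ","),
         " (expected one of ", paste(known, collapse = ", "), ")")
  }
  if (!identical(tacticity, "syndiotactic")) {
    stop("only syndiotactic chains are supported")
  }
  if (is.null(n_monomers)) {
    n_monomers <- switch(polymer, PEO = 32L, GUAR = 12L, 48L)
  }
  n_monomers <- as.integer(n_monomers)
  if (n_monomers < 1L) stop("n_monomers must be >= 1")
  if (is.null(substitution_fraction)) {
    substitution_fraction <- if (polymer %in% c("HPAM", "PAMPS")) 0.25 else 0
  }
  if (polymer %in% c("HPAM", "PAMPS")) {
    n_ch <- substitution_fraction * n_monomers
    if (abs(n_ch - round(n_ch)) > 1e-9) {
      stop("substitution_fraction * n_monomers must be an integer")
    }
  } else if (substitution_fraction != 0) {
    stop("substitution_fraction only applies to HPAM and PAMPS")
  }
  if (is.null(box_edge)) box_edge <- if (polymer == "GUAR") 12 else 10
  if (box_edge <= 0) stop("box_edge must be > 0")
  if (nacl_molarity < 0) stop("nacl_molarity must be >= 0")
  if (is.null(ion_box_edge)) {
    ion_box_edge <- if (polymer == "GUAR") 10 else box_edge
  }
  structure(list(
    polymer = polymer, n_monomers = n_monomers,
    substitution_fraction = substitution_fraction,
    nacl_molarity = nacl_molarity, box_edge = box_edge,
    ion_box_edge = ion_box_edge,
    tacticity = tacticity, seed = as.integer(seed)
  ), class = "build_spec")
}

#' @export
print.build_spec <- function(x, ...) {
  cat(sprintf(
    "<build_spec> %s, %d monomers (f_sub = %g), %g M NaCl, box %g nm, seed %d\n",
    x$polymer, x$n_monomers, x$substitution_fraction, x$nacl_molarity,
    x$box_edge, x$seed))
  invisible(x)
}

# monomer template sequence for a spec; charged comonomer every
# 1/substitution-th position (3 acrylamides then one charged monomer)
.monomer_sequence <- function(spec) {
  n <- spec$n_monomers
  switch(spec$polymer,
    PAM = rep("AM", n),
    PAA = rep("AA", n),
    PEO = rep("EO", n),
    GUAR = rep("GUAR", n),
    HPAM = ,
    PAMPS = {
      charged <- if (spec$polymer == "HPAM") "AA" else "AMPS"
      if (spec$substitution_fraction == 0) return(rep("AM", n))
      period <- round(1 / spec$substitution_fraction)
      ifelse(seq_len(n) %% period == 0L, charged, "AM")
    })
}

# all-trans zigzag backbone positions for n_slots atoms (bond 0.154 nm,
# tetrahedral angles); x is the chain axis
.zigzag <- function(n_slots, bond = 0.154) {
  half <- 109.47 / 2 * pi / 180
  dx <- bond * sin(half)
  zamp <- bond * cos(half)
  k <- seq_len(n_slots) - 1L
  cbind(x = k * dx, y = 0, z = zamp * (k %% 2L))
}

# reference lengths of the extended chains [nm]
.REF_LENGTH <- c(PAM = 11.8, HPAM = 11.8, PAMPS = 11.8, PAA = 11.8,
                 PEO = 11.5, GUAR = 12.5)
.REF_NMONO <- c(PAM = 48L, HPAM = 48L, PAMPS = 48L, PAA = 48L,
                PEO = 32L, GUAR = 12L)

# uniform scale applied to the ideal geometry so that the end-to-end
# length of the reference-size chain equals the reference length
.chain_scale_factor <- function(polymer) {
  n_ref <- .REF_NMONO[[polymer]]
  if (polymer == "GUAR") {
    tpl <- get_monomer("GUAR")
    a <- tpl$atoms
    first <- unlist(a[a$name == tpl$backbone[1L], c("x", "y", "z")])
    last <- unlist(a[a$name == tpl$backbone[length(tpl$backbone)], c("x", "y", "z")])
    last[1L] <- last[1L] + (n_ref - 1L) * tpl$advance
    ete <- sqrt(sum((last - first)^2))
  } else {
    per <- if (polymer == "PEO") 3L else 2L
    bb <- .zigzag(per * n_ref)
    ete <- sqrt(sum((bb[nrow(bb), ] - bb[1L, ])^2))
  }
  .REF_LENGTH[[polymer]] / ete
}

#' Build the extended polymer chain of a specification
#'
#' Constructs the all-atom chain in an extended conformation: an all-trans
#' zigzag backbone (C-C 0.154 nm, tetrahedral angles) with pendant groups
#' alternating sides on consecutive monomers (syndiotactic), or translated
#' idealized ring units for guar.  The geometry is scaled uniformly so the
#' end-to-end length of the reference-size chain matches the reference
#' extended length (11.8 nm for the acrylamide family, 11.5 nm for PEO,
#' 12.5 nm for guar).  End groups are two hydrogens for the vinyl polymers
#' and an H/OH pair for PEO and guar.  Partial charges of every monomer
#' (terminal caps included) are normalized to the monomer's formal charge
#' with [normalize_charges()], so the chain's net charge is exactly minus
#' the number of charged monomers.
#'
#' @param spec a [build_spec()]
#' @return object of class `polymer_system` containing only the polymer,
#'   centred in the periodic box
#' @export
#' @examples
#' sys <- build_chain(build_spec("PAM", n_monomers = 4))
#' molecular_weight(sys)
build_chain <- function(spec) {
  stopifnot(inherits(spec, "build_spec"))
  seq_names <- .monomer_sequence(spec)
  tpls <- lapply(unique(seq_names), get_monomer)
  names(tpls) <- unique(seq_names)
  n <- spec$n_monomers

  atom_rows <- vector("list", n)
  coord_rows <- vector("list", n)
  bond_rows <- vector("list", n)
  donor_rows <- vector("list", n)
  backbone_idx <- integer(0)
  offset <- 0L
  kind <- tpls[[1L]]$kind

  if (kind == "vinyl") {
    per <- length(tpls[[seq_names[1L]]]$backbone)
    bb <- .zigzag(per * n)
    zamp <- max(bb[, "z"])
  }

  for (m in seq_len(n)) {
    tpl <- tpls[[seq_names[m]]]
    a <- tpl$atoms
    s <- if (m %% 2L == 1L) 1 else -1   # syndiotactic side alternation
    if (tpl$kind == "vinyl") {
      slots <- (m - 1L) * length(tpl$backbone) + seq_along(tpl$backbone)
      pos <- matrix(NA_real_, nrow(a), 3L)
      rownames(pos) <- a$name
      pos[tpl$backbone, ] <- bb[slots, , drop = FALSE]
      side <- which(!is.na(a$parent))
      for (i in side) {
        p <- pos[a$parent[i], ]
        zsign <- if (p[3L] > zamp / 2) 1 else -1
        pos[i, ] <- p + c(a$ox[i], s * a$oy[i], zsign * a$oz[i])
      }
    } else {
      pos <- cbind(a$x + (m - 1L) * tpl$advance, s * a$y, a$z)
      rownames(pos) <- a$name
    }
    nm_map <- stats::setNames(offset + seq_len(nrow(a)), a$name)
    atom_rows[[m]] <- data.frame(
      name = a$name, element = a$element, mass = a$mass, charge = a$charge,
      role = a$role, monomer = m, molecule = "polymer", resid = m,
      resname = tpl$name, stringsAsFactors = FALSE)
    coord_rows[[m]] <- pos
    bond_rows[[m]] <- cbind(nm_map[tpl$bonds[, 1L]], nm_map[tpl$bonds[, 2L]])
    if (!is.null(tpl$hbond_donors)) {
      donor_rows[[m]] <- cbind(nm_map[tpl$hbond_donors[, 1L]],
                               nm_map[tpl$hbond_donors[, 2L]])
    }
    backbone_idx <- c(backbone_idx, unname(nm_map[tpl$backbone]))
    if (m > 1L) {
      bond_rows[[m]] <- rbind(bond_rows[[m]],
                              c(prev_last, unname(nm_map[tpl$backbone[1L]])))
    }
    prev_last <- unname(nm_map[tpl$backbone[length(tpl$backbone)]])
    offset <- offset + nrow(a)
  }

  atoms <- do.call(rbind, atom_rows)
  coords <- do.call(rbind, coord_rows)
  bonds <- do.call(rbind, bond_rows)
  donors <- do.call(rbind, donor_rows)
  rownames(coords) <- NULL

  # uniform scaling to the reference extended length
  f <- .chain_scale_factor(spec$polymer)
  origin <- coords[backbone_idx[1L], ]
  coords <- sweep(coords, 2L, origin)
  coords <- coords * f
  coords <- sweep(coords, 2L, origin, "+")

  # terminal caps
  unit_to <- function(v) v / sqrt(sum(v * v))
  bb1 <- coords[backbone_idx[1L], ]
  bb2 <- coords[backbone_idx[2L], ]
  bbl <- coords[backbone_idx[length(backbone_idx)], ]
  bbp <- coords[backbone_idx[length(backbone_idx) - 1L], ]
  head_dir <- unit_to(bb1 - bb2)
  tail_dir <- unit_to(bbl - bbp)
  cap_atom <- function(name, element, charge, role, monomer, resname, pos) {
    atoms <<- rbind(atoms, data.frame(
      name = name, element = element, mass = atomic_mass(element),
      charge = charge, role = role, monomer = monomer, molecule = "polymer",
      resid = monomer, resname = resname, stringsAsFactors = FALSE))
    coords <<- rbind(coords, matrix(pos, 1L))
    nrow(atoms)
  }
  first_res <- atoms$resname[1L]
  last_res <- atoms$resname[nrow(atoms)]
  if (spec$polymer %in% c("PAM", "HPAM", "PAMPS", "PAA")) {
    i1 <- cap_atom("HC1", "H", 0, NA, 1L, first_res, bb1 + 0.109 * head_dir)
    i2 <- cap_atom("HC2", "H", 0, NA, n, last_res, bbl + 0.109 * tail_dir)
    b_extra <- rbind(c(backbone_idx[1L], i1),
                     c(backbone_idx[length(backbone_idx)], i2))
  } else if (spec$polymer == "PEO") {
    # head O becomes a terminal hydroxyl; tail gets an OH group
    i1 <- cap_atom("HT1", "H", 0.40, NA, 1L, first_res, bb1 + 0.098 * head_dir)
    atoms$role[backbone_idx[1L]] <- "hydroxyl-O"
    ot <- bbl + 0.143 * tail_dir
    i2 <- cap_atom("OT", "O", -0.40, "hydroxyl-O", n, last_res, ot)
    hv <- unit_to(tail_dir + c(0, 1, 0))
    i3 <- cap_atom("HT2", "H", 0.40, NA, n, last_res, ot + 0.098 * hv)
    b_extra <- rbind(c(backbone_idx[1L], i1),
                     c(backbone_idx[length(backbone_idx)], i2), c(i2, i3))
    donors <- rbind(donors, c(backbone_idx[1L], i1), c(i2, i3))
  } else { # GUAR
    o1 <- bb1 + 0.14 * head_dir
    i1 <- cap_atom("O1T", "O", -0.65, "hydroxyl-O", 1L, first_res, o1)
    hv <- unit_to(head_dir + c(0, 1, 0))
    i2 <- cap_atom("HO1T", "H", 0.42, NA, 1L, first_res, o1 + 0.098 * hv)
    i3 <- cap_atom("HO4T", "H", 0.42, NA, n, last_res, bbl + 0.098 * tail_dir)
    last_bb <- backbone_idx[length(backbone_idx)]
    atoms$role[last_bb] <- "hydroxyl-O"
    b_extra <- rbind(c(backbone_idx[1L], i1), c(i1, i2), c(last_bb, i3))
    donors <- rbind(donors, c(i1, i2), c(last_bb, i3))
  }
  bonds <- rbind(bonds, b_extra)
  dimnames(bonds) <- NULL
  if (!is.null(donors)) dimnames(donors) <- NULL

  # per-monomer charge normalization (caps included in their monomer group)
  tpl_state <- vapply(seq_names, function(nm) tpls[[nm]]$charge_state,
                      integer(1))
  for (m in seq_len(n)) {
    grp <- which(atoms$monomer == m)
    atoms$charge[grp] <- normalize_charges(atoms$charge[grp], tpl_state[m])$q
  }

  # centre the chain in the box
  centre <- (apply(coords, 2L, min) + apply(coords, 2L, max)) / 2
  coords <- sweep(coords, 2L, centre - spec$box_edge / 2, "-")

  sys <- structure(list(
    atoms = atoms, coords = coords, bonds = bonds, donors = donors,
    backbone = backbone_idx, box = spec$box_edge, spec = spec,
    counterion_count = sum(tpl_state == -1L),
    salt_na = 0L, salt_cl = 0L, water_count = 0L,
    length_nm = .REF_LENGTH[[spec$polymer]] * n / .REF_NMONO[[spec$polymer]]
  ), class = "polymer_system")
  sys$length_nm <- contour_length(sys)
  sys
}

#' An empty periodic box
#'
#' @param box_edge cubic box edge in nm
#' @return an empty `polymer_system`
#' @export
empty_system <- function(box_edge) {
  stopifnot(box_edge > 0)
  structure(list(
    atoms = data.frame(name = character(0), element = character(0),
                       mass = numeric(0), charge = numeric(0),
                       role = character(0), monomer = integer(0),
                       molecule = character(0), resid = integer(0),
                       resname = character(0), stringsAsFactors = FALSE),
    coords = matrix(numeric(0), 0L, 3L), bonds = NULL, donors = NULL,
    backbone = integer(0), box = box_edge, spec = NULL,
    counterion_count = 0L, salt_na = 0L, salt_cl = 0L, water_count = 0L,
    length_nm = NA_real_
  ), class = "polymer_system")
}

#' @export
print.polymer_system <- function(x, ...) {
  np <- sum(x$atoms$molecule == "polymer")
  ni <- sum(x$atoms$molecule == "ion")
  cat(sprintf(
    "<polymer_system> %s: %d polymer atoms, %d ions, %d waters, box %g nm, net charge %.2e e\n",
    if (!is.null(x$spec)) x$spec$polymer else "(custom)",
    np, ni, x$water_count, x$box, sum(x$atoms$charge)))
  invisible(x)
}

#' Molecular weight of the polymer
#'
#' Sum of the atomic masses of all polymer atoms (charged monomers counted
#' as their anions, without counterions), using the fixed atomic mass table
#' of [atomic_mass()].
#'
#' @param system a `polymer_system`
#' @return molecular weight in g/mol
#' @export
molecular_weight <- function(system) {
  stopifnot(inherits(system, "polymer_system"))
  sum(system$atoms$mass[system$atoms$molecule == "polymer"])
}

#' End-to-end length of the extended chain
#'
#' Distance between the first and last backbone atoms of the extended
#' conformation; the normalizing length for all per-length ion and
#' interaction densities.
#'
#' @param system a `polymer_system` with a built chain
#' @return length in nm
#' @export
contour_length <- function(system) {
  stopifnot(inherits(system, "polymer_system"))
  bb <- system$backbone
  if (length(bb) < 2L) stop("no extended chain in system")
  d <- system$coords[bb[length(bb)], ] - system$coords[bb[1L], ]
  sqrt(sum(d * d))
}

#' Number of salt ion pairs for a concentration and box
#'
#' `n = round(molarity * 0.6022140857 nm^-3 M^-1 * box_edge^3)`, with
#' half-away-from-zero rounding; this reproduces the reference counts 4, 36
#' and 361 pairs for 0.006, 0.06 and 0.6 M in a 10 nm box.
#'
#' @param molarity NaCl concentration in mol/L
#' @param box_edge cubic box edge in nm
#' @return named integer vector c(na = n, cl = n)
#' @export
#' @examples
#' salt_ion_count(0.6, 10)
salt_ion_count <- function(molarity, box_edge) {
  if (molarity < 0) stop("negative molarity")
  if (box_edge <= 0) stop("box_edge must be > 0")
  n <- as.integer(floor(molarity * .AVOGADRO_NM3 * box_edge^3 + 0.5))
  c(na = n, cl = n)
}

#' Place counterions and salt ions around the polymer
#'
#' Adds the Na+ counterions needed to neutralize the chain first, then the
#' NaCl pairs implied by the specification's molarity.  Ions are placed
#' uniformly at random in the box, rejecting any position closer than
#' `min_dist` (minimum image) to a polymer atom.
#'
#' @param system a `polymer_system` with a built chain
#' @param seed integer seed (defaults to the build spec's seed)
#' @param min_dist minimum ion-polymer distance in nm (0.8)
#' @param max_tries proposals allowed per ion before giving up
#' @return the system with ions added and counts recorded
#' @export
place_ions <- function(system, seed = NULL, min_dist = 0.8, max_tries = 2000L) {
  stopifnot(inherits(system, "polymer_system"))
  if (is.null(seed)) seed <- if (!is.null(system$spec)) system$spec$seed else 1L
  set.seed(seed)
  n_counter <- system$counterion_count
  salt <- if (!is.null(system$spec)) {
    salt_ion_count(system$spec$nacl_molarity, system$spec$ion_box_edge)
  } else c(na = 0L, cl = 0L)
  species <- c(rep("Na", n_counter), rep("Na", salt[["na"]]),
               rep("Cl", salt[["cl"]]))
  n_ions <- length(species)
  if (n_ions == 0L) {
    system$salt_na <- salt[["na"]]; system$salt_cl <- salt[["cl"]]
    return(system)
  }
  poly <- system$coords[system$atoms$molecule == "polymer", , drop = FALSE]
  box <- system$box
  placed <- matrix(NA_real_, n_ions, 3L)
  got <- 0L
  tries <- 0L
  while (got < n_ions) {
    if (tries > max_tries) {
      stop("ion placement capacity error: box too crowded after ",
           tries, " proposal rounds")
    }
    batch <- matrix(stats::runif(3L * 256L, 0, box), ncol = 3L)
    ok <- if (nrow(poly)) min_dist_to_set(batch, poly, box) >= min_dist else
      rep(TRUE, nrow(batch))
    keep <- which(ok)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n_ions - got))]
      placed[got + seq_along(take), ] <- batch[take, , drop = FALSE]
      got <- got + length(take)
    }
    tries <- tries + 1L
  }
  resid0 <- if (nrow(system$atoms)) max(system$atoms$resid, 0L) else 0L
  ion_atoms <- data.frame(
    name = ifelse(species == "Na", "NA", "CL"),
    element = species, mass = atomic_mass(species),
    charge = ifelse(species == "Na", 1, -1),
    role = NA_character_, monomer = NA_integer_, molecule = "ion",
    resid = resid0 + seq_len(n_ions),
    resname = ifelse(species == "Na", "NA", "CL"), stringsAsFactors = FALSE)
  system$atoms <- rbind(system$atoms, ion_atoms)
  system$coords <- rbind(system$coords, placed)
  system$salt_na <- unname(salt[["na"]])
  system$salt_cl <- unname(salt[["cl"]])
  system
}

# rigid 3-site water site coordinates: O at `o`, dipole along unit vector
# `dhat`, H-H separation plane spanned with unit vector `vhat` (orthogonal
# to dhat); SPC/E internal geometry (O-H 0.1 nm, H-O-H 109.47 deg)
.water_sites <- function(o, dhat, vhat) {
  half <- .WATER_HOH / 2 * pi / 180
  h1 <- o + .WATER_OH * (cos(half) * dhat + sin(half) * vhat)
  h2 <- o + .WATER_OH * (cos(half) * dhat - sin(half) * vhat)
  rbind(o, h1, h2)
}

#' Fill the box with rigid 3-site water
#'
#' Waters are placed on a jittered simple-cubic lattice thinned to the bulk
#' density of 33.4 molecules/nm^3, each with a random rigid-body
#' orientation (SPC/E geometry: O-H 0.1 nm, H-O-H 109.47 deg), then every
#' water with any atom closer than `overlap` (minimum image) to a
#' non-water atom is deleted.
#'
#' @param system a `polymer_system` (ions placed, possibly empty)
#' @param seed integer seed (defaults to spec seed + 1)
#' @param overlap deletion distance in nm (0.2)
#' @param density target bulk density in molecules/nm^3
#' @return the system with waters appended and `water_count` recorded
#' @export
insert_water <- function(system, seed = NULL, overlap = 0.2,
                         density = .WATER_DENSITY) {
  stopifnot(inherits(system, "polymer_system"))
  if (is.null(seed)) {
    seed <- if (!is.null(system$spec)) system$spec$seed + 1L else 2L
  }
  set.seed(seed)
  box <- system$box
  n_target <- as.integer(floor(density * box^3 + 0.5))
  n_side <- ceiling(n_target^(1 / 3))
  a <- box / n_side
  g <- (seq_len(n_side) - 0.5) * a
  sites <- as.matrix(expand.grid(x = g, y = g, z = g))
  sites <- sites + matrix(stats::runif(length(sites), -0.1 * a, 0.1 * a),
                          ncol = 3L)
  sites <- sites %% box
  if (nrow(sites) > n_target) {
    sites <- sites[sort(sample.int(nrow(sites), n_target)), , drop = FALSE]
  }
  nw <- nrow(sites)
  dhat <- random_unit_vectors(nw)
  raw <- random_unit_vectors(nw)
  vhat <- raw - rowSums(raw * dhat) * dhat
  vn <- sqrt(rowSums(vhat * vhat))
  bad <- vn < 1e-8
  if (any(bad)) { vhat[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3L, byrow = TRUE) }
  vhat <- vhat / sqrt(rowSums(vhat * vhat))
  half <- .WATER_HOH / 2 * pi / 180
  h1 <- sites + .WATER_OH * (cos(half) * dhat + sin(half) * vhat)
  h2 <- sites + .WATER_OH * (cos(half) * dhat - sin(half) * vhat)

  solute <- system$coords
  if (nrow(solute)) {
    wat_atoms <- rbind(sites, h1, h2)
    dmin <- min_dist_to_set(wat_atoms, solute, box, chunk = 1024L)
    hit <- matrix(dmin < overlap, ncol = 3L)
    keep <- !(hit[, 1L] | hit[, 2L] | hit[, 3L])
  } else {
    keep <- rep(TRUE, nw)
  }
  sites <- sites[keep, , drop = FALSE]
  h1 <- h1[keep, , drop = FALSE]
  h2 <- h2[keep, , drop = FALSE]
  nw <- nrow(sites)

  resid0 <- if (nrow(system$atoms)) max(system$atoms$resid, 0L) else 0L
  wat <- data.frame(
    name = rep(c("OW", "HW1", "HW2"), nw),
    element = rep(c("O", "H", "H"), nw),
    mass = rep(atomic_mass(c("O", "H", "H")), nw),
    charge = rep(c(.WATER_Q_O, .WATER_Q_H, .WATER_Q_H), nw),
    role = NA_character_, monomer = NA_integer_, molecule = "water",
    resid = resid0 + rep(seq_len(nw), each = 3L),
    resname = "SOL", stringsAsFactors = FALSE)
  wcoords <- matrix(NA_real_, 3L * nw, 3L)
  wcoords[seq(1L, by = 3L, length.out = nw), ] <- sites
  wcoords[seq(2L, by = 3L, length.out = nw), ] <- h1
  wcoords[seq(3L, by = 3L, length.out = nw), ] <- h2
  system$atoms <- rbind(system$atoms, wat)
  system$coords <- rbind(system$coords, wcoords)
  system$water_count <- nw
  system
}

#' Build a complete solvated system from a specification
#'
#' Convenience wrapper: [build_chain()], [place_ions()], then (optionally)
#' [insert_water()].  All randomness derives from the spec's seed, so a
#' given spec always produces the identical system.
#'
#' @param spec a [build_spec()]
#' @param water logical, insert water (default TRUE)
#' @return a `polymer_system`
#' @export
build_system <- function(spec, water = TRUE) {
  sys <- build_chain(spec)
  sys <- place_ions(sys, seed = spec$seed)
  if (water) sys <- insert_water(sys, seed = spec$seed + 1L)
  sys
}
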