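## Built-in monomer library.
##
## Raw partial charges are reference values anchored to the published
## electronegative-atom charges for this polymer family (carbonyl O -0.52 e,
## carboxylate O -0.80 e, sulfonate O -0.61 e); the remaining atoms carry
## generic values chosen so each monomer's raw sum already equals its formal
## charge.  normalize_charges() is still applied at build time, so the net
## charge closure never depends on these numbers.
##
## Geometry: vinyl monomers give offsets from their parent backbone atom in
## a local frame (x chain axis, y pendant side, z zigzag normal); the guar
## repeat carries explicit idealized ring coordinates.  Coordinates are
## idealized starting structures, not energy-minimized geometry.

.va <- function(name, element, charge, role = NA_character_,
                parent = NA_character_, ox = 0, oy = 0, oz = 0) {
  data.frame(name = name, element = element, charge = charge, role = role,
             parent = parent, ox = ox, oy = oy, oz = oz,
             stringsAsFactors = FALSE)
}

.monomer_am <- function() {
  atoms <- rbind(
    .va("C1", "C", -0.12),
    .va("H11", "H", 0.06, parent = "C1", ox = 0, oy = 0.063, oz = 0.089),
    .va("H12", "H", 0.06, parent = "C1", ox = 0, oy = -0.063, oz = 0.089),
    .va("C2", "C", -0.06),
    .va("H21", "H", 0.06, parent = "C2", ox = 0, oy = -0.063, oz = 0.089),
    .va("C3", "C", 0.60, parent = "C2", ox = 0, oy = 0.151, oz = 0),
    .va("O", "O", -0.52, role = "carbonyl-O", parent = "C2",
        ox = -0.095, oy = 0.229, oz = 0),
    .va("N", "N", -0.80, role = "amide-N", parent = "C2",
        ox = 0.107, oy = 0.233, oz = 0),
    .va("HN1", "H", 0.36, parent = "C2", ox = 0.157, oy = 0.320, oz = 0),
    .va("HN2", "H", 0.36, parent = "C2", ox = 0.207, oy = 0.233, oz = 0)
  )
  bonds <- rbind(c("C1", "H11"), c("C1", "H12"), c("C1", "C2"),
                 c("C2", "H21"), c("C2", "C3"), c("C3", "O"), c("C3", "N"),
                 c("N", "HN1"), c("N", "HN2"))
  monomer_template("AM", atoms, bonds, backbone = c("C1", "C2"),
                   charge_state = 0L,
                   hbond_donors = rbind(c("N", "HN1"), c("N", "HN2")))
}

.monomer_aa <- function() {
  atoms <- rbind(
    .va("C1", "C", -0.15),
    .va("H11", "H", 0.05, parent = "C1", ox = 0, oy = 0.063, oz = 0.089),
    .va("H12", "H", 0.05, parent = "C1", ox = 0, oy = -0.063, oz = 0.089),
    .va("C2", "C", -0.10),
    .va("H21", "H", 0.05, parent = "C2", ox = 0, oy = -0.063, oz = 0.089),
    .va("C3", "C", 0.70, parent = "C2", ox = 0, oy = 0.151, oz = 0),
    .va("O1", "O", -0.80, role = "carboxylate-O", parent = "C2",
        ox = -0.095, oy = 0.229, oz = 0),
    .va("O2", "O", -0.80, role = "carboxylate-O", parent = "C2",
        ox = 0.095, oy = 0.229, oz = 0)
  )
  bonds <- rbind(c("C1", "H11"), c("C1", "H12"), c("C1", "C2"),
                 c("C2", "H21"), c("C2", "C3"), c("C3", "O1"), c("C3", "O2"))
  monomer_template("AA", atoms, bonds, backbone = c("C1", "C2"),
                   charge_state = -1L)
}

.monomer_amps <- function() {
  atoms <- rbind(
    .va("C1", "C", -0.12),
    .va("H11", "H", 0.06, parent = "C1", ox = 0, oy = 0.063, oz = 0.089),
    .va("H12", "H", 0.06, parent = "C1", ox = 0, oy = -0.063, oz = 0.089),
    .va("C2", "C", -0.06),
    .va("H21", "H", 0.06, parent = "C2", ox = 0, oy = -0.063, oz = 0.089),
    .va("C3", "C", 0.60, parent = "C2", ox = 0, oy = 0.151, oz = 0),
    .va("O3", "O", -0.52, role = "carbonyl-O", parent = "C2",
        ox = -0.110, oy = 0.206, oz = 0),
    .va("N", "N", -0.60, role = "amide-N", parent = "C2",
        ox = 0.100, oy = 0.241, oz = 0),
    .va("HN", "H", 0.32, parent = "C2", ox = 0.195, oy = 0.211, oz = 0),
    .va("C4", "C", 0.22, parent = "C2", ox = 0.140, oy = 0.386, oz = 0),
    .va("C5", "C", -0.24, parent = "C2", ox = 0.000, oy = 0.446, oz = 0.03),
    .va("H51", "H", 0.06, parent = "C2", ox = -0.060, oy = 0.526, oz = 0.03),
    .va("H52", "H", 0.06, parent = "C2", ox = -0.090, oy = 0.426, oz = 0.08),
    .va("H53", "H", 0.06, parent = "C2", ox = -0.090, oy = 0.426, oz = -0.02),
    .va("C6", "C", -0.24, parent = "C2", ox = 0.280, oy = 0.446, oz = -0.03),
    .va("H61", "H", 0.06, parent = "C2", ox = 0.340, oy = 0.526, oz = -0.03),
    .va("H62", "H", 0.06, parent = "C2", ox = 0.370, oy = 0.426, oz = 0.02),
    .va("H63", "H", 0.06, parent = "C2", ox = 0.370, oy = 0.426, oz = -0.08),
    .va("C7", "C", -0.14, parent = "C2", ox = 0.140, oy = 0.536, oz = 0.02),
    .va("H71", "H", 0.06, parent = "C2", ox = 0.050, oy = 0.586, oz = 0.08),
    .va("H72", "H", 0.06, parent = "C2", ox = 0.230, oy = 0.586, oz = 0.08),
    .va("S", "S", 0.95, parent = "C2", ox = 0.140, oy = 0.696, oz = 0.02),
    .va("OS1", "O", -0.61, role = "sulfonate-O", parent = "C2",
        ox = 0.010, oy = 0.756, oz = 0.02),
    .va("OS2", "O", -0.61, role = "sulfonate-O", parent = "C2",
        ox = 0.270, oy = 0.756, oz = 0.02),
    .va("OS3", "O", -0.61, role = "sulfonate-O", parent = "C2",
        ox = 0.140, oy = 0.776, oz = 0.14)
  )
  bonds <- rbind(c("C1", "H11"), c("C1", "H12"), c("C1", "C2"),
                 c("C2", "H21"), c("C2", "C3"), c("C3", "O3"), c("C3", "N"),
                 c("N", "HN"), c("N", "C4"),
                 c("C4", "C5"), c("C5", "H51"), c("C5", "H52"), c("C5", "H53"),
                 c("C4", "C6"), c("C6", "H61"), c("C6", "H62"), c("C6", "H63"),
                 c("C4", "C7"), c("C7", "H71"), c("C7", "H72"),
                 c("C7", "S"), c("S", "OS1"), c("S", "OS2"), c("S", "OS3"))
  monomer_template("AMPS", atoms, bonds, backbone = c("C1", "C2"),
                   charge_state = -1L,
                   hbond_donors = rbind(c("N", "HN")))
}

.monomer_eo <- function() {
  atoms <- rbind(
    .va("O", "O", -0.40, role = "ether-O"),
    .va("C1", "C", 0.14),
    .va("H11", "H", 0.03, parent = "C1", ox = 0, oy = 0.063, oz = 0.089),
    .va("H12", "H", 0.03, parent = "C1", ox = 0, oy = -0.063, oz = 0.089),
    .va("C2", "C", 0.14),
    .va("H21", "H", 0.03, parent = "C2", ox = 0, oy = 0.063, oz = 0.089),
    .va("H22", "H", 0.03, parent = "C2", ox = 0, oy = -0.063, oz = 0.089)
  )
  bonds <- rbind(c("O", "C1"), c("C1", "C2"),
                 c("C1", "H11"), c("C1", "H12"),
                 c("C2", "H21"), c("C2", "H22"))
  monomer_template("EO", atoms, bonds, backbone = c("O", "C1", "C2"),
                   charge_state = 0L)
}

## One guar repeat: two backbone beta-1,4 mannose residues (A carries the
## branch, B does not) plus one alpha-1,6 galactose (G) on A; three anhydro
## C6H10O5 residues, C18H30O15 in total.  Rings are idealized hexagons,
## not chair conformers.
.guar_unit <- function() {
  res_spacing <- 0.52
  ring_r <- 0.145
  # angles for C1,C2,C3,C4,C5,O5 around a backbone ring (x-z plane)
  ang <- c(150, 210, 270, 330, 30, 90) * pi / 180

  rows <- list()
  bonds <- list()
  donors <- list()
  add <- function(name, element, charge, role, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, charge = charge, role = role,
      x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  bond <- function(a, b) bonds[[length(bonds) + 1L]] <<- c(a, b)
  donor <- function(h_at, h) donors[[length(donors) + 1L]] <<- c(h_at, h)

  backbone_residue <- function(tag, cx, branched) {
    ring <- c("C1", "C2", "C3", "C4", "C5", "O5")
    pos <- cbind(cx + ring_r * cos(ang), 0, ring_r * sin(ang))
    for (i in seq_along(ring)) {
      nm <- paste0(ring[i], tag)
      if (ring[i] == "O5") {
        add(nm, "O", -0.40, "ether-O", pos[i, 1], pos[i, 2], pos[i, 3])
      } else {
        q <- if (ring[i] == "C1") 0.30 else 0.12
        add(nm, "C", q, NA_character_, pos[i, 1], pos[i, 2], pos[i, 3])
      }
    }
    for (i in 1:5) bond(paste0(ring[i], tag), paste0(ring[i + 1L], tag))
    bond(paste0("O5", tag), paste0("C1", tag))
    # ring hydrogens on C1..C5, pushed to +y
    for (i in 1:5) {
      nm <- paste0("H", i, tag)
      add(nm, "H", 0.05, NA_character_,
          pos[i, 1], 0.10, pos[i, 3])
      bond(nm, paste0(ring[i], tag))
    }
    # hydroxyls at C2 and C3 (-y side)
    o2 <- pos[2, ] + c(-0.09, -0.09, -0.03)
    add(paste0("O2", tag), "O", -0.65, "hydroxyl-O", o2[1], o2[2], o2[3])
    bond(paste0("O2", tag), paste0("C2", tag))
    add(paste0("HO2", tag), "H", 0.42, NA_character_,
        o2[1], o2[2] - 0.09, o2[3] + 0.04)
    bond(paste0("HO2", tag), paste0("O2", tag))
    donor(paste0("O2", tag), paste0("HO2", tag))
    o3 <- pos[3, ] + c(0.00, -0.09, -0.09)
    add(paste0("O3", tag), "O", -0.65, "hydroxyl-O", o3[1], o3[2], o3[3])
    bond(paste0("O3", tag), paste0("C3", tag))
    add(paste0("HO3", tag), "H", 0.42, NA_character_,
        o3[1] + 0.06, o3[2] - 0.08, o3[3])
    bond(paste0("HO3", tag), paste0("O3", tag))
    donor(paste0("O3", tag), paste0("HO3", tag))
    # exocyclic C6 with two hydrogens and O6
    c6 <- pos[5, ] + c(0.05, 0.10, 0.08)
    add(paste0("C6", tag), "C", 0.05, NA_character_, c6[1], c6[2], c6[3])
    bond(paste0("C6", tag), paste0("C5", tag))
    add(paste0("H61", tag), "H", 0.05, NA_character_,
        c6[1] + 0.08, c6[2] + 0.05, c6[3] + 0.02)
    bond(paste0("H61", tag), paste0("C6", tag))
    add(paste0("H62", tag), "H", 0.05, NA_character_,
        c6[1] - 0.05, c6[2] + 0.05, c6[3] + 0.08)
    bond(paste0("H62", tag), paste0("C6", tag))
    o6 <- c6 + c(0.00, 0.12, 0.05)
    if (branched) {
      add(paste0("O6", tag), "O", -0.42, "ether-O", o6[1], o6[2], o6[3])
    } else {
      add(paste0("O6", tag), "O", -0.65, "hydroxyl-O", o6[1], o6[2], o6[3])
      add(paste0("HO6", tag), "H", 0.42, NA_character_,
          o6[1] + 0.05, o6[2] + 0.08, o6[3])
      bond(paste0("HO6", tag), paste0("O6", tag))
      donor(paste0("O6", tag), paste0("HO6", tag))
    }
    bond(paste0("O6", tag), paste0("C6", tag))
    # glycosidic oxygen to the next backbone residue, midway along x
    o4 <- c(cx + res_spacing / 2, 0, 0)
    add(paste0("O4", tag), "O", -0.42, "ether-O", o4[1], o4[2], o4[3])
    bond(paste0("O4", tag), paste0("C4", tag))
    o6
  }

  o6a <- backbone_residue("A", 0, branched = TRUE)
  backbone_residue("B", res_spacing, branched = FALSE)
  bond("O4A", "C1B")   # A(1->4)B within the repeat

  # galactose branch on O6A, ring in the x-y plane above the backbone
  gc <- o6a + c(0, 0.285, 0)
  gang <- c(270, 330, 30, 90, 150, 210) * pi / 180
  gring <- c("C1", "C2", "C3", "C4", "C5", "O5")
  gpos <- cbind(gc[1] + ring_r * cos(gang), gc[2] + ring_r * sin(gang), gc[3])
  for (i in seq_along(gring)) {
    nm <- paste0(gring[i], "G")
    if (gring[i] == "O5") {
      add(nm, "O", -0.40, "ether-O", gpos[i, 1], gpos[i, 2], gpos[i, 3])
    } else {
      q <- if (gring[i] == "C1") 0.30 else 0.12
      add(nm, "C", q, NA_character_, gpos[i, 1], gpos[i, 2], gpos[i, 3])
    }
  }
  for (i in 1:5) bond(paste0(gring[i], "G"), paste0(gring[i + 1L], "G"))
  bond("O5G", "C1G")
  bond("O6A", "C1G")   # alpha(1->6) attachment
  for (i in 1:5) {
    nm <- paste0("H", i, "G")
    add(nm, "H", 0.05, NA_character_, gpos[i, 1], gpos[i, 2], gpos[i, 3] + 0.10)
    bond(nm, paste0(gring[i], "G"))
  }
  for (k in 2:4) {
    ck <- gpos[k, ]
    rad <- ck - c(gc[1], gc[2], gc[3])
    rad <- rad / sqrt(sum(rad * rad))
    ok <- ck + 0.08 * rad + c(0, 0, -0.10)
    add(paste0("O", k, "G"), "O", -0.65, "hydroxyl-O", ok[1], ok[2], ok[3])
    bond(paste0("O", k, "G"), paste0("C", k, "G"))
    hk <- ok + 0.03 * rad + c(0, 0, -0.09)
    add(paste0("HO", k, "G"), "H", 0.42, NA_character_, hk[1], hk[2], hk[3])
    bond(paste0("HO", k, "G"), paste0("O", k, "G"))
    donor(paste0("O", k, "G"), paste0("HO", k, "G"))
  }
  c6g <- gpos[5, ] + c(-0.08, 0.06, 0.10)
  add("C6G", "C", 0.05, NA_character_, c6g[1], c6g[2], c6g[3])
  bond("C6G", "C5G")
  add("H61G", "H", 0.05, NA_character_, c6g[1] + 0.03, c6g[2] + 0.09, c6g[3] + 0.03)
  bond("H61G", "C6G")
  add("H62G", "H", 0.05, NA_character_, c6g[1] + 0.02, c6g[2] - 0.02, c6g[3] + 0.10)
  bond("H62G", "C6G")
  o6g <- c6g + c(-0.10, 0, 0.06)
  add("O6G", "O", -0.65, "hydroxyl-O", o6g[1], o6g[2], o6g[3])
  bond("O6G", "C6G")
  add("HO6G", "H", 0.42, NA_character_, o6g[1] - 0.08, o6g[2], o6g[3] + 0.05)
  bond("HO6G", "O6G")
  donor("O6G", "HO6G")

  atoms <- do.call(rbind, rows)
  list(atoms = atoms,
       bonds = do.call(rbind, bonds),
       donors = do.call(rbind, donors),
       advance = 2 * res_spacing,
       backbone = c("C1A", "C2A", "C3A", "C4A", "O4A",
                    "C1B", "C2B", "C3B", "C4B", "O4B"))
}

.monomer_guar <- function() {
  u <- .guar_unit()
  comp <- table(rep(u$atoms$element, 1L))
  stopifnot(comp[["C"]] == 18L, comp[["H"]] == 30L, comp[["O"]] == 15L)
  tpl <- monomer_template("GUAR", u$atoms, u$bonds, backbone = u$backbone,
                          charge_state = 0L, hbond_donors = u$donors,
                          kind = "unit")
  tpl$advance <- u$advance
  tpl
}

.register_builtin_monomers <- function() {
  assign("AM", .monomer_am(), envir = .monomer_env)
  assign("AA", .monomer_aa(), envir = .monomer_env)
  assign("AMPS", .monomer_amps(), envir = .monomer_env)
  assign("EO", .monomer_eo(), envir = .monomer_env)
  assign("GUAR", .monomer_guar(), envir = .monomer_env)
  invisible(NULL)
}
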