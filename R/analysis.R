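#' Per-frame analysis result with block-averaged uncertainty
#'
#' @param series per-frame values
#' @param times frame times in ps (optional)
#' @param units character unit label
#' @param n_blocks number of blocks for the standard error of the mean
#' @return object of class `analysis_result` with elements `series`,
#'   `times`, `mean`, `stderr`, `units`
#' @export
analysis_result <- function(series, times = NULL, units = "", n_blocks = 5L) {
  structure(list(series = series, times = times, mean = mean(series),
                 stderr = block_stderr(series, n_blocks), units = units),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> mean = %.6g +/- %.2g %s over %d frames\n",
              x$mean, x$stderr, x$units, length(x$series)))
  invisible(x)
}

## ---- radius of gyration --------------------------------------------------

#' Radius of gyration of a set of atoms
#'
#' Mass-weighted root-mean-square distance from the centre of mass:
#' `Rg = sqrt( sum_i m_i |r_i - r_cm|^2 / sum_i m_i )`.  Coordinates must
#' describe a whole (unwrapped) molecule.
#'
#' @param coords n x 3 matrix of positions (nm)
#' @param masses atomic masses; equal masses if NULL
#' @return Rg in nm
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1 nm
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  w <- masses / sum(masses)
  cm <- colSums(coords * w)
  d <- sweep(coords, 2L, cm)
  sqrt(sum(w * rowSums(d * d)))
}

# default Rg selection: the carbon atoms of the main chain
.rg_selection <- function(topology) {
  if (is.null(topology)) stop("selection required when trajectory has no topology")
  a <- topology$atoms
  if (length(topology$backbone)) {
    bb <- topology$backbone
    bb[a$element[bb] == "C"]
  } else {
    which(a$molecule %in% c("polymer", "tracer"))
  }
}

#' Radius of gyration over a trajectory
#'
#' Computes [radius_of_gyration()] per frame over a selection (by default
#' the carbon atoms of the main chain).  In a periodic box the polymer is
#' first made whole by bond walking; a selected bond longer than
#' `max_bond` after unwrapping signals a broken molecule and raises an
#' error.
#'
#' @param traj a `trajectory`
#' @param selection integer atom indices; default backbone carbons
#' @param max_bond broken-molecule detection threshold in nm
#' @param n_blocks blocks for the standard error
#' @return an [analysis_result()] in nm
#' @export
analyze_rg <- function(traj, selection = NULL, max_bond = 0.25,
                       n_blocks = 5L) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  if (is.null(selection)) selection <- .rg_selection(topo)
  if (length(selection) == 0L) stop("empty selection")
  masses <- if (!is.null(topo)) topo$atoms$mass[selection] else NULL
  bonds <- if (!is.null(topo)) topo$bonds else NULL
  periodic <- is.finite(traj$box[1L])
  sel_bonds <- NULL
  if (!is.null(bonds)) {
    inb <- bonds[, 1L] %in% selection & bonds[, 2L] %in% selection
    sel_bonds <- bonds[inb, , drop = FALSE]
  }
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- traj$coords[, , f]
    if (periodic && !is.null(bonds)) X <- make_whole(X, bonds, traj$box[f])
    if (periodic && !is.null(sel_bonds) && nrow(sel_bonds)) {
      bl <- sqrt(rowSums((X[sel_bonds[, 1L], , drop = FALSE] -
                            X[sel_bonds[, 2L], , drop = FALSE])^2))
      if (any(bl > max_bond)) {
        stop("broken molecule: selected bond of ", format(max(bl)),
             " nm after unwrapping (limit ", max_bond, " nm)")
      }
    }
    out[f] <- radius_of_gyration(X[selection, , drop = FALSE], masses)
  }
  analysis_result(out, traj$times, units = "nm", n_blocks = n_blocks)
}

## ---- counterion condensation ---------------------------------------------

.polymer_idx <- function(topology) {
  if (is.null(topology)) stop("trajectory has no topology")
  which(topology$atoms$molecule == "polymer")
}

.cation_idx <- function(topology) {
  which(topology$atoms$molecule == "ion" & topology$atoms$element == "Na")
}

.norm_length <- function(L, topology) {
  if (is.null(L)) L <- topology$length_nm
  if (is.null(L) || is.na(L) || L <= 0) {
    stop("normalizing length L must be > 0 (none recorded in topology)")
  }
  L
}

#' Counterion condensation per unit polymer length
#'
#' Per frame, the number of distinct cations strictly closer than `cutoff`
#' (minimum image) to any polymer atom, divided by the extended polymer
#' length `L`; averaged over frames.
#'
#' @param traj a `trajectory` with topology
#' @param cutoff contact radius in nm (0.3)
#' @param L normalizing length in nm; defaults to the topology's extended
#'   chain length
#' @param cations integer indices; defaults to all Na+ ions
#' @param n_blocks blocks for the standard error
#' @return an [analysis_result()] in 1/nm, with per-frame raw counts in
#'   attribute `"counts"`
#' @export
counterion_condensation <- function(traj, cutoff = 0.3, L = NULL,
                                    cations = NULL, n_blocks = 5L) {
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  topo <- traj$topology
  poly <- .polymer_idx(topo)
  if (is.null(cations)) cations <- .cation_idx(topo)
  L <- .norm_length(L, topo)
  nf <- n_frames(traj)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    X <- traj$coords[, , f]
    if (length(cations)) {
      dmin <- min_dist_to_set(X[cations, , drop = FALSE],
                              X[poly, , drop = FALSE], traj$box[f])
      counts[f] <- sum(dmin < cutoff)
    }
  }
  res <- analysis_result(counts / L, traj$times, units = "1/nm",
                         n_blocks = n_blocks)
  attr(res, "counts") <- counts
  res
}

#' Manning charge-density parameter
#'
#' `xi = lB / b`, the ratio of the Bjerrum length to the mean axial spacing
#' between backbone charges `b = L / n_charges`.  Counterion condensation
#' onto a linear polyelectrolyte is predicted when `xi > 1` (strict).
#'
#' @param x extended chain length in nm, or a `polymer_system` (from which
#'   the length and the number of charged monomers are taken)
#' @param n_charges number of backbone charges
#' @param bjerrum_length Bjerrum length in nm (0.714 at 300 K in water)
#' @return list of class `manning_parameter`: `xi`, `b` (nm),
#'   `condensation_predicted`
#' @export
#' @examples
#' manning_parameter(11.8, 48)  # xi = 2.90, condensation predicted
manning_parameter <- function(x, n_charges = NULL,
                              bjerrum_length = .BJERRUM_300K) {
  if (inherits(x, "polymer_system")) {
    n_charges <- x$counterion_count
    x <- x$length_nm
  }
  if (is.null(n_charges)) stop("n_charges required")
  if (!(x > 0)) stop("contour length must be > 0")
  if (n_charges == 0L) {
    out <- list(xi = 0, b = Inf, condensation_predicted = FALSE)
  } else {
    b <- x / n_charges
    xi <- bjerrum_length / b
    out <- list(xi = xi, b = b, condensation_predicted = xi > 1)
  }
  structure(out, class = "manning_parameter")
}

#' @export
print.manning_parameter <- function(x, ...) {
  cat(sprintf("<manning_parameter> xi = %.4g (b = %.4g nm): condensation %s\n",
              x$xi, x$b,
              if (x$condensation_predicted) "predicted" else "not predicted"))
  invisible(x)
}

## ---- water orientation ---------------------------------------------------

# for each row of A, index and distance of the nearest row of B
.nearest_in_set <- function(A, B, box = NA, chunk = 256L) {
  nA <- nrow(A)
  dist <- numeric(nA)
  idx <- integer(nA)
  i <- 1L
  while (i <= nA) {
    j <- min(i + chunk - 1L, nA)
    rows <- i:j
    dx <- outer(A[rows, 1L], B[, 1L], "-")
    dy <- outer(A[rows, 2L], B[, 2L], "-")
    dz <- outer(A[rows, 3L], B[, 3L], "-")
    if (is.finite(box)) {
      dx <- dx - box * round(dx / box)
      dy <- dy - box * round(dy / box)
      dz <- dz - box * round(dz / box)
    }
    d2 <- dx * dx + dy * dy + dz * dz
    k <- max.col(-d2, ties.method = "first")
    idx[rows] <- k
    dist[rows] <- sqrt(d2[cbind(seq_along(rows), k)])
    i <- j + 1L
  }
  list(dist = dist, idx = idx)
}

#' Histogram of water dipole orientation cosines
#'
#' @param samples cos(phi) samples in `[-1, 1]`
#' @param n_bins number of equal-width bins spanning `[-1, 1]`
#' @return object of class `orientation_histogram`: `bin_edges`,
#'   `bin_mid`, `frequencies` (normalized), `counts`, `n_samples`,
#'   `samples`
#' @export
orientation_histogram <- function(samples, n_bins = 40L) {
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  n <- length(samples)
  structure(list(bin_edges = edges,
                 bin_mid = (edges[-1L] + edges[-length(edges)]) / 2,
                 frequencies = if (n > 0) counts / n else counts * 0,
                 counts = counts, n_samples = n, samples = samples),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("<orientation_histogram> %d samples in %d bins over [-1, 1]\n",
              x$n_samples, length(x$counts)))
  invisible(x)
}

#' Orientation of water around the polymer
#'
#' For every water whose oxygen lies within `cutoff` of at least one
#' polymer atom, accumulates `cos(phi) = d_hat . r_hat`, where `d_hat` is
#' the unit water dipole (O toward the H-H midpoint) and `r_hat` the unit
#' vector from the nearest polymer atom to the water oxygen.  Negative
#' values mean hydrogens oriented toward the polymer (-1: both hydrogens;
#' -0.577: one O-H bond in direct line); positive values mean the oxygen
#' points at the polymer.
#'
#' @param traj a `trajectory` whose topology contains water molecules
#' @param cutoff shell radius in nm (0.5: first shell and half of the
#'   second)
#' @param n_bins histogram bins over `[-1, 1]`
#' @return an [orientation_histogram()]
#' @export
water_orientation <- function(traj, cutoff = 0.5, n_bins = 40L) {
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  topo <- traj$topology
  a <- topo$atoms
  ow <- which(a$molecule == "water" & a$element == "O")
  if (!length(ow)) stop("no waters in topology")
  poly <- .polymer_idx(topo)
  # hydrogens of each water, matched by residue id
  hw <- which(a$molecule == "water" & a$element == "H")
  h_by_res <- split(hw, a$resid[hw])
  h1 <- vapply(h_by_res, `[`, integer(1), 1L)[as.character(a$resid[ow])]
  h2 <- vapply(h_by_res, `[`, integer(1), 2L)[as.character(a$resid[ow])]
  samples <- list()
  for (f in seq_len(n_frames(traj))) {
    X <- traj$coords[, , f]
    box <- traj$box[f]
    near <- .nearest_in_set(X[ow, , drop = FALSE], X[poly, , drop = FALSE], box)
    sel <- which(near$dist < cutoff)
    if (!length(sel)) next
    o <- X[ow[sel], , drop = FALSE]
    ref <- X[poly[near$idx[sel]], , drop = FALSE]
    rhat <- min_image(o - ref, box)
    rhat <- rhat / sqrt(rowSums(rhat * rhat))
    mid <- (min_image(X[h1[sel], , drop = FALSE] - o, box) +
              min_image(X[h2[sel], , drop = FALSE] - o, box)) / 2
    dhat <- mid / sqrt(rowSums(mid * mid))
    samples[[length(samples) + 1L]] <- rowSums(dhat * rhat)
  }
  orientation_histogram(unlist(samples), n_bins = n_bins)
}

## ---- mean-squared displacement and diffusion -----------------------------

#' Mean-squared displacement over multiple time origins
#'
#' `msd(tau)` averaged over up to `n_restarts` evenly spaced time origins
#' and over the selected particles.  For a trajectory with a polymer
#' topology the default selection is the polymer centre of mass; for
#' particle fixtures every atom is treated as an independent tracer.
#' Coordinates must be unwrapped (see [unwrap_trajectory()]).
#'
#' @param traj a `trajectory` (at least 2 frames, uniform time step)
#' @param selection "com" for the polymer centre of mass, integer atom
#'   indices, or NULL for the automatic choice
#' @param n_restarts maximum number of time origins per lag (20000)
#' @param lags lag times in frames; default about `n_lags` log-spaced
#' @param n_lags number of log-spaced lags when `lags` is NULL
#' @return object of class `msd_curve`: `lag` (ps), `msd` (nm^2),
#'   `n_origins`
#' @export
msd <- function(traj, selection = NULL, n_restarts = 20000L, lags = NULL,
                n_lags = 60L) {
  stopifnot(inherits(traj, "trajectory"), n_restarts >= 1L)
  nf <- n_frames(traj)
  if (nf < 2L) stop("fewer than 2 frames")
  dt <- diff(traj$times)
  if (max(dt) - min(dt) > 1e-6 * max(dt)) {
    stop("msd requires a uniform time step")
  }
  dt <- dt[1L]
  topo <- traj$topology
  use_com <- FALSE
  if (is.null(selection)) {
    if (!is.null(topo) && any(topo$atoms$molecule == "polymer")) {
      use_com <- TRUE
    } else {
      selection <- seq_len(dim(traj$coords)[1L])
    }
  } else if (identical(selection, "com")) {
    use_com <- TRUE
  }
  if (use_com) {
    poly <- .polymer_idx(topo)
    w <- topo$atoms$mass[poly]
    w <- w / sum(w)
    arr <- array(NA_real_, c(1L, 3L, nf))
    for (f in seq_len(nf)) {
      arr[1L, , f] <- colSums(traj$coords[poly, , f, drop = FALSE][, , 1L] * w)
    }
  } else {
    arr <- traj$coords[selection, , , drop = FALSE]
  }
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(log(1), log(nf - 1L), length.out = n_lags))))
  }
  lags <- sort(unique(as.integer(lags)))
  lags <- lags[lags >= 1L & lags <= nf - 1L]
  vals <- numeric(length(lags))
  nor <- integer(length(lags))
  for (k in seq_along(lags)) {
    lg <- lags[k]
    avail <- nf - lg
    origins <- unique(round(seq(1L, avail,
                                length.out = min(n_restarts, avail))))
    d <- arr[, , origins + lg, drop = FALSE] - arr[, , origins, drop = FALSE]
    vals[k] <- mean(d[, 1L, ]^2 + d[, 2L, ]^2 + d[, 3L, ]^2)
    nor[k] <- length(origins)
  }
  structure(list(lag = c(0, lags * dt), msd = c(0, vals),
                 n_origins = c(0L, nor)),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, tau = [%g, %g] ps, msd(max) = %.4g nm^2\n",
              length(x$lag), x$lag[2L], max(x$lag), max(x$msd)))
  invisible(x)
}

#' Einstein diffusion coefficient from an MSD curve
#'
#' Ordinary least-squares fit (with intercept) of `msd` against lag time on
#' the window `[t_min, t_max]`; `D = slope / 6`, converted from nm^2/ps to
#' cm^2/s with the exact factor 1 nm^2/ps = 1e-2 cm^2/s.
#'
#' @param curve an [msd()] result
#' @param t_min,t_max fit window in ps (1 to 10000)
#' @return list of class `diffusion_fit`: `D` and `D_se` in cm^2/s,
#'   `slope` and `intercept` in nm^2/ps and nm^2, `n_points`
#' @export
fit_diffusion <- function(curve, t_min = 1, t_max = 10000) {
  stopifnot(inherits(curve, "msd_curve"))
  sel <- which(curve$lag >= t_min & curve$lag <= t_max & curve$lag > 0)
  if (length(sel) < 2L) stop("empty fit window: fewer than 2 lags inside")
  x <- curve$lag[sel]
  y <- curve$msd[sel]
  fit <- stats::lm(y ~ x)
  sl <- unname(stats::coef(fit)[2L])
  # suppress the "essentially perfect fit" warning for exact linear input
  se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit)))[2L]))
  conv <- 1e-2   # nm^2/ps -> cm^2/s
  structure(list(D = sl / 6 * conv, D_se = se / 6 * conv, slope = sl,
                 intercept = unname(stats::coef(fit)[1L]),
                 n_points = length(sel), window = c(t_min, t_max)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g cm^2/s (%d lags in [%g, %g] ps)\n",
              x$D, x$D_se, x$n_points, x$window[1L], x$window[2L]))
  invisible(x)
}

## ---- cation bridges and hydrogen bonds -----------------------------------

.ELECTRONEG_O <- c("carbonyl-O", "carboxylate-O", "sulfonate-O",
                   "ether-O", "hydroxyl-O")
.ACCEPTOR_ROLES <- c(.ELECTRONEG_O, "amide-N")
.DONOR_ROLES <- c("amide-N", "hydroxyl-O")

#' Cation bridge density along the polymer
#'
#' A bridging cation binds two electronegative polymer atoms at once: per
#' frame, the number of cations strictly within `cutoff` of at least two
#' tagged electronegative oxygens (carbonyl, carboxylate, sulfonate, ether,
#' hydroxyl), divided by the extended polymer length.  With
#' `count = "cations"` (default) a cation contacting more than two atoms
#' still counts once; `count = "pairs"` counts every bridged atom pair.
#'
#' @param traj a `trajectory` with a role-tagged topology
#' @param cutoff contact radius in nm (0.3)
#' @param L normalizing length in nm (defaults to the topology's)
#' @param count bridging count convention
#' @param n_blocks blocks for the standard error
#' @return an [analysis_result()] in 1/nm
#' @export
cation_bridges <- function(traj, cutoff = 0.3, L = NULL,
                           count = c("cations", "pairs"), n_blocks = 5L) {
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  count <- match.arg(count)
  topo <- traj$topology
  a <- topo$atoms
  tagged <- which(a$molecule == "polymer" & a$role %in% .ELECTRONEG_O)
  if (!length(tagged)) stop("no tagged electronegative atoms in topology")
  cations <- .cation_idx(topo)
  L <- .norm_length(L, topo)
  nf <- n_frames(traj)
  series <- numeric(nf)
  for (f in seq_len(nf)) {
    if (!length(cations)) next
    X <- traj$coords[, , f]
    dm <- dist_matrix(X[cations, , drop = FALSE], X[tagged, , drop = FALSE],
                      traj$box[f])
    k <- rowSums(dm < cutoff)
    series[f] <- if (count == "cations") sum(k >= 2L) else
      sum(choose(k[k >= 2L], 2L))
  }
  analysis_result(series / L, traj$times, units = "1/nm", n_blocks = n_blocks)
}

# neighbours within `depth` covalent bonds of each atom in `of`
.bonded_within <- function(bonds, of, n_atoms, depth = 2L) {
  adj <- vector("list", n_atoms)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1L]; j <- bonds[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(of, function(i) {
    seen <- i
    frontier <- i
    for (d in seq_len(depth)) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
    }
    seen
  })
}

#' Intramolecular hydrogen bond density along the polymer
#'
#' Distance-criterion hydrogen bonds within the polymer: pairs of
#' electronegative atoms (the tagged oxygens plus amide nitrogens) strictly
#' closer than `cutoff`, where at least one partner is a donor (carries a
#' covalently bound hydrogen).  Pairs separated by two or fewer covalent
#' bonds are excluded so directly bonded geometry is not counted.  Counts
#' are divided by the extended polymer length.
#'
#' @param traj a `trajectory` with a role-tagged, bonded topology
#' @param cutoff donor-acceptor heavy-atom distance in nm (0.30)
#' @param L normalizing length in nm (defaults to the topology's)
#' @param n_blocks blocks for the standard error
#' @return an [analysis_result()] in 1/nm
#' @export
hydrogen_bonds <- function(traj, cutoff = 0.30, L = NULL, n_blocks = 5L) {
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  topo <- traj$topology
  a <- topo$atoms
  acceptors <- which(a$molecule == "polymer" & a$role %in% .ACCEPTOR_ROLES)
  donors <- if (!is.null(topo$donors)) unique(topo$donors[, 1L]) else integer(0)
  if (!length(donors)) {
    # derive donors: role-tagged heavies with a bonded hydrogen
    if (!is.null(topo$bonds)) {
      hb <- topo$bonds
      is_h <- a$element == "H"
      heavy <- c(hb[is_h[hb[, 2L]], 1L], hb[is_h[hb[, 1L]], 2L])
      donors <- intersect(which(a$role %in% .DONOR_ROLES), heavy)
    }
  }
  if (!length(donors)) stop("no hydrogen-bond donors in topology")
  if (!length(acceptors)) stop("no hydrogen-bond acceptors in topology")
  if (is.null(topo$bonds)) stop("hydrogen_bonds requires topology bonds")
  L <- .norm_length(L, topo)
  excl <- .bonded_within(topo$bonds, donors, nrow(a), depth = 2L)
  names(excl) <- as.character(donors)
  nf <- n_frames(traj)
  series <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- traj$coords[, , f]
    dm <- dist_matrix(X[donors, , drop = FALSE], X[acceptors, , drop = FALSE],
                      traj$box[f])
    hit <- which(dm < cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      di <- donors[hit[, 1L]]
      ai <- acceptors[hit[, 2L]]
      ok <- mapply(function(d, ac) !(ac %in% excl[[as.character(d)]]),
                   di, ai)
      di <- di[ok]; ai <- ai[ok]
      # one hydrogen bond per unordered heavy-atom pair
      key <- paste(pmin(di, ai), pmax(di, ai))
      series[f] <- length(unique(key))
    }
  }
  analysis_result(series / L, traj$times, units = "1/nm", n_blocks = n_blocks)
}
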