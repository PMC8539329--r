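#' @keywords internal
"_PACKAGE"

## Unit system: nm, ps, e, g/mol (amu), kJ/mol -- the GROMACS convention.
## 1 amu nm^2 ps^-2 == 1 kJ/mol, so masses, energies and the Langevin noise
## term below are mutually consistent without conversion factors.

# molecules per nm^3 per mol/L (Avogadro constant scaled)
.AVOGADRO_NM3 <- 0.6022140857

# Bjerrum length of water at 300 K [nm]
.BJERRUM_300K <- 0.714

# Boltzmann constant [kJ/mol/K]
.KB <- 0.0083144621

# bulk density of liquid water at 300 K [molecules / nm^3]
.WATER_DENSITY <- 33.4

# SPC/E rigid geometry
.WATER_OH <- 0.1          # nm
.WATER_HOH <- 109.47      # degrees
.WATER_Q_O <- -0.8476     # e
.WATER_Q_H <- 0.4238      # e

# fixed atomic mass table [g/mol]; chosen so that the reference molecular
# weights of all six polymers are reproduced to +- 0.1 g/mol
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.0067, O = 15.9994, S = 32.06,
  Na = 22.98977, Cl = 35.453
)

#' Look up atomic masses by element symbol
#'
#' Fixed table of standard atomic weights (g/mol) used throughout the
#' builder: C 12.011, H 1.008, N 14.0067, O 15.9994, S 32.06, Na 22.98977,
#' Cl 35.453.
#'
#' @param element character vector of element symbols
#' @return numeric vector of masses in g/mol
#' @export
#' @examples
#' atomic_mass(c("C", "O"))
atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

## ---- internal geometry helpers ------------------------------------------

# minimum-image displacement components for a cubic box of edge `box`
min_image <- function(d, box) {
  if (is.null(box) || !is.finite(box)) return(d)
  d - box * round(d / box)
}

# minimum-image distance between one point `p` (length 3) and rows of `X`
dist_point_set <- function(p, X, box = NA) {
  d <- sweep(X, 2L, p)
  d <- min_image(d, box)
  sqrt(rowSums(d * d))
}

# for each row of A, the minimum minimum-image distance to any row of B;
# chunked over A to bound memory
min_dist_to_set <- function(A, B, box = NA, chunk = 256L) {
  nA <- nrow(A)
  out <- numeric(nA)
  i <- 1L
  while (i <= nA) {
    j <- min(i + chunk - 1L, nA)
    idx <- i:j
    dx <- outer(A[idx, 1L], B[, 1L], "-")
    dy <- outer(A[idx, 2L], B[, 2L], "-")
    dz <- outer(A[idx, 3L], B[, 3L], "-")
    if (is.finite(box)) {
      dx <- dx - box * round(dx / box)
      dy <- dy - box * round(dy / box)
      dz <- dz - box * round(dz / box)
    }
    d2 <- dx * dx + dy * dy + dz * dz
    out[idx] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

# full minimum-image distance matrix (small systems only)
dist_matrix <- function(A, B, box = NA) {
  dx <- outer(A[, 1L], B[, 1L], "-")
  dy <- outer(A[, 2L], B[, 2L], "-")
  dz <- outer(A[, 3L], B[, 3L], "-")
  if (is.finite(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
    dz <- dz - box * round(dz / box)
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

# random unit vectors, n x 3
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v * v))
}

# an arbitrary unit vector orthogonal to unit vector v (length 3)
orthogonal_unit <- function(v, w = NULL) {
  if (is.null(w)) {
    w <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  u <- w - sum(w * v) * v
  n <- sqrt(sum(u * u))
  if (n < 1e-12) stop("degenerate orthogonal direction")
  u / n
}

# block-averaged standard error of the mean of a series
block_stderr <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks || n_blocks < 2L) return(NA_real_)
  size <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(x[((b - 1L) * size + 1L):(b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}
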