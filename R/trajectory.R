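#' Construct a trajectory
#'
#' A trajectory binds an ordered set of coordinate frames (nm) to an
#' optional topology (a `polymer_system`), per-frame times (ps) and a cubic
#' box edge.  Frames may be given as a list of n x 3 matrices or as a
#' 3-dimensional array `[atom, xyz, frame]`.  A non-finite box means an
#' open (non-periodic) system; no minimum-image convention is applied.
#'
#' @param coords list of n x 3 matrices, or array with dim (n, 3, F)
#' @param times numeric vector of frame times in ps (strictly increasing)
#' @param box cubic box edge in nm; scalar or per-frame vector; NA for none
#' @param topology a `polymer_system` (or NULL)
#' @param wrapped logical: are coordinates wrapped into the box?
#' @param ground_truth optional list of known values encoded by a fixture
#' @return object of class `trajectory`
#' @export
trajectory <- function(coords, times = NULL, box = NA, topology = NULL,
                       wrapped = FALSE, ground_truth = NULL) {
  if (is.list(coords)) {
    n <- nrow(coords[[1L]])
    if (!all(vapply(coords, nrow, integer(1)) == n)) {
      stop("constant atom count required across frames")
    }
    arr <- array(NA_real_, c(n, 3L, length(coords)))
    for (f in seq_along(coords)) arr[, , f] <- coords[[f]]
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  nf <- dim(coords)[3L]
  if (nf < 1L) stop("at least one frame required")
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("times must match frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  box <- rep_len(as.numeric(box), nf)
  structure(list(coords = coords, times = times, box = box,
                 topology = topology, wrapped = wrapped,
                 ground_truth = ground_truth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d atoms, %d frames, t = [%g, %g] ps, box %s nm\n",
              d[1L], d[3L], x$times[1L], x$times[length(x$times)],
              if (is.finite(x$box[1L])) format(x$box[1L]) else "none"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`
#' @return integer
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Single- or repeated-frame trajectory of a built system
#'
#' @param system a `polymer_system`
#' @param n_frames number of (identical) frames
#' @param times frame times in ps
#' @return a `trajectory` with the system as topology
#' @export
system_trajectory <- function(system, n_frames = 1L, times = NULL) {
  arr <- array(rep(system$coords, n_frames),
               c(nrow(system$coords), 3L, n_frames))
  trajectory(arr, times = times, box = system$box, topology = system,
             wrapped = FALSE)
}

# rebuild a molecule across periodic boundaries by walking its bond graph:
# every atom is placed at its parent's position plus the minimum-image
# displacement.  `bonds` is a 2-column matrix of 1-based indices.
make_whole <- function(coords, bonds, box) {
  if (!is.finite(box) || is.null(bonds) || nrow(bonds) == 0L) return(coords)
  n <- nrow(coords)
  adj <- vector("list", n)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1L]; j <- bonds[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  out <- coords
  for (root in seq_len(n)) {
    if (seen[root] || is.null(adj[[root]])) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (nb in adj[[cur]]) {
        if (!seen[nb]) {
          seen[nb] <- TRUE
          out[nb, ] <- out[cur, ] + min_image(coords[nb, ] - coords[cur, ], box)
          queue <- c(queue, nb)
        }
      }
    }
  }
  out
}

#' Unwrap a trajectory by per-atom image tracking
#'
#' Accumulates minimum-image frame-to-frame displacements, producing
#' continuous coordinates suitable for mean-squared-displacement analysis.
#' Assumes no atom moves more than half a box edge between frames.
#'
#' @param traj a `trajectory` with a finite box
#' @return an unwrapped `trajectory` (box retained, `wrapped = FALSE`)
#' @export
unwrap_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.finite(traj$box[1L])) return(traj)
  arr <- traj$coords
  nf <- dim(arr)[3L]
  for (f in seq_len(nf)[-1L]) {
    d <- min_image(arr[, , f] - traj$coords[, , f - 1L], traj$box[f])
    arr[, , f] <- arr[, , f - 1L] + d
  }
  traj$coords <- arr
  traj$wrapped <- FALSE
  traj
}
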