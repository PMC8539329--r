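## Readers/writers for the plain-text formats the pipeline touches:
## GRO coordinates (nm, fixed columns), PDB (write-only, Angstrom),
## multi-frame XYZ with an extended comment line (time + box, nm), a JSON
## topology document, and tidy CSV/JSON result output.

.TOPOLOGY_SCHEMA <- "polysalt-topology/1"

#' Write a GRO coordinate file
#'
#' Fixed-column GROMACS GRO format, coordinates in nm to three decimals.
#'
#' @param system a `polymer_system`
#' @param path output file
#' @param title header line
#' @return `path`, invisibly
#' @export
write_gro <- function(system, path, title = "polysalt system") {
  a <- system$atoms
  n <- nrow(a)
  lines <- character(n + 3L)
  lines[1L] <- title
  lines[2L] <- sprintf("%5d", n)
  resid <- a$resid %% 100000L
  idx <- seq_len(n) %% 100000L
  lines[3L:(n + 2L)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                resid, substr(a$resname, 1L, 5L),
                                substr(a$name, 1L, 5L), idx,
                                system$coords[, 1L], system$coords[, 2L],
                                system$coords[, 3L])
  lines[n + 3L] <- sprintf("%10.5f%10.5f%10.5f", system$box, system$box,
                           system$box)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' @param path input file
#' @return list with `atoms` (resid, resname, name), `coords` (nm) and
#'   `box` (cubic edge, nm)
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n)) stop("malformed atom count line in ", path)
  if (length(lines) < n + 3L) {
    stop("GRO header declares ", n, " atoms but file has ",
         length(lines) - 3L, " records")
  }
  rec <- lines[3L:(n + 2L)]
  atoms <- data.frame(
    resid = as.integer(substr(rec, 1L, 5L)),
    resname = trimws(substr(rec, 6L, 10L)),
    name = trimws(substr(rec, 11L, 15L)),
    stringsAsFactors = FALSE)
  coords <- cbind(as.numeric(substr(rec, 21L, 28L)),
                  as.numeric(substr(rec, 29L, 36L)),
                  as.numeric(substr(rec, 37L, 44L)))
  if (anyNA(coords)) stop("malformed coordinate record in ", path)
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1L]])[1L]
  list(atoms = atoms, coords = coords, box = box)
}

#' Write a PDB coordinate file (write-only convenience)
#'
#' @param system a `polymer_system`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(system, path) {
  a <- system$atoms
  n <- nrow(a)
  xyz <- system$coords * 10   # nm -> Angstrom
  rec <- sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                 seq_len(n) %% 100000L, substr(a$name, 1L, 4L),
                 substr(a$resname, 1L, 4L), a$resid %% 10000L,
                 xyz[, 1L], xyz[, 2L], xyz[, 3L], a$element)
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       system$box * 10, system$box * 10, system$box * 10),
               rec, "END"), path)
  invisible(path)
}

#' Write a multi-frame XYZ trajectory
#'
#' Element + coordinates per atom; the comment line of every frame carries
#' the time in ps and the cubic box edge, with an explicit unit tag to
#' avoid the nm/Angstrom ambiguity of bare XYZ:
#' `t= <ps> box= <nm|none> units=nm`.
#'
#' @param traj a `trajectory` whose topology provides element symbols
#'   (plain "X" is used without topology)
#' @param path output file
#' @param digits coordinate precision
#' @return `path`, invisibly
#' @export
write_xyz_traj <- function(traj, path, digits = 6L) {
  n <- dim(traj$coords)[1L]
  el <- if (!is.null(traj$topology)) traj$topology$atoms$element else
    rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.6f box= %s units=nm", traj$times[f],
                       if (is.finite(traj$box[f]))
                         sprintf("%.6f", traj$box[f]) else "none"), con)
    writeLines(sprintf(fmt, el, traj$coords[, 1L, f], traj$coords[, 2L, f],
                       traj$coords[, 3L, f]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path input file
#' @param topology optional `polymer_system` to attach
#' @return a `trajectory`; frames lacking a `t=` stamp get their frame
#'   index as time, with a warning
#' @export
read_xyz_traj <- function(path, topology = NULL) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  boxes <- numeric(0)
  n_ref <- NA_integer_
  missing_time <- FALSE
  f <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    f <- f + 1L
    if (is.na(n)) stop("malformed atom count at frame ", f)
    if (is.na(n_ref)) n_ref <- n
    if (n != n_ref) {
      stop("inconsistent atom count at frame ", f, ": ", n, " vs ", n_ref)
    }
    if (pos + 1L + n > length(lines)) stop("truncated frame ", f)
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1L]]
    if (length(tm) == 2L) {
      times[f] <- as.numeric(tm[2L])
    } else {
      missing_time <- TRUE
      times[f] <- f - 1
    }
    bm <- regmatches(comment, regexec("box=\\s*([-0-9.eE+]+)", comment))[[1L]]
    boxes[f] <- if (length(bm) == 2L) as.numeric(bm[2L]) else NA_real_
    body <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    frames[[f]] <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    pos <- pos + 2L + n
  }
  if (missing_time) warning("missing time stamp(s): using frame index as time")
  if (!length(frames)) stop("no frames in ", path)
  trajectory(frames, times = times, box = boxes, topology = topology)
}

#' Write a topology document as JSON
#'
#' Serialises a `polymer_system` (atoms with element, mass, charge,
#' monomer assignment, molecule and role tags; bonds; donor pairs;
#' backbone; box; counts; provenance) under a versioned schema.  Indices
#' are 0-based in the document.
#'
#' @param system a `polymer_system`
#' @param path output file
#' @param coords logical: embed coordinates too (default TRUE, so a
#'   topology file round-trips to a complete static system)
#' @return `path`, invisibly
#' @export
write_topology <- function(system, path, coords = TRUE) {
  a <- system$atoms
  doc <- list(
    schema = .TOPOLOGY_SCHEMA,
    box = system$box,
    atoms = data.frame(index = seq_len(nrow(a)) - 1L, a,
                       stringsAsFactors = FALSE),
    bonds = if (!is.null(system$bonds)) unname(system$bonds - 1L) else
      matrix(integer(0), 0L, 2L),
    donors = if (!is.null(system$donors)) unname(system$donors - 1L) else
      matrix(integer(0), 0L, 2L),
    backbone = system$backbone - 1L,
    counts = list(counterion = system$counterion_count,
                  salt_na = system$salt_na, salt_cl = system$salt_cl,
                  water = system$water_count),
    length_nm = system$length_nm,
    provenance = list(
      package = "polysalt",
      version = as.character(utils::packageVersion("polysalt")),
      spec = if (!is.null(system$spec)) unclass(system$spec) else NULL)
  )
  if (coords) doc$coords <- unname(system$coords)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' Read a topology document
#'
#' @param path JSON file written by [write_topology()]
#' @return a `polymer_system`
#' @export
read_topology <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, .TOPOLOGY_SCHEMA)) {
    stop("unsupported topology schema: ", doc$schema)
  }
  a <- doc$atoms
  if (is.null(a$index) || !identical(as.integer(a$index),
                                     seq_len(nrow(a)) - 1L)) {
    stop("topology atom indices must be contiguous from 0")
  }
  a$index <- NULL
  a$monomer <- as.integer(a$monomer)
  a$resid <- as.integer(a$resid)
  to_mat <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    m <- matrix(as.integer(unlist(x)), ncol = 2L,
                byrow = !is.matrix(x))
    if (is.matrix(x)) m <- apply(x, 2L, as.integer)
    m + 1L
  }
  spec <- doc$provenance$spec
  if (!is.null(spec)) class(spec) <- "build_spec"
  coords <- NULL
  if (!is.null(doc$coords)) {
    coords <- if (is.matrix(doc$coords)) doc$coords else
      matrix(unlist(doc$coords), ncol = 3L, byrow = TRUE)
  }
  structure(list(
    atoms = a,
    coords = coords,
    bonds = to_mat(doc$bonds), donors = to_mat(doc$donors),
    backbone = as.integer(unlist(doc$backbone)) + 1L,
    box = doc$box, spec = spec,
    counterion_count = as.integer(doc$counts$counterion),
    salt_na = as.integer(doc$counts$salt_na),
    salt_cl = as.integer(doc$counts$salt_cl),
    water_count = as.integer(doc$counts$water),
    length_nm = if (is.null(doc$length_nm)) NA_real_ else doc$length_nm
  ), class = "polymer_system")
}

#' Write an analysis result as tidy CSV plus a JSON summary
#'
#' @param result an `analysis_result`, `orientation_histogram`,
#'   `msd_curve` or `diffusion_fit`
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`
#' @param params list of parameters to record in the summary
#' @return the two paths, invisibly
#' @export
write_results <- function(result, prefix, params = list()) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  if (inherits(result, "analysis_result")) {
    df <- data.frame(frame = seq_along(result$series),
                     time_ps = if (!is.null(result$times)) result$times else
                       seq_along(result$series) - 1,
                     value = result$series)
    summary <- list(mean = result$mean, stderr = result$stderr,
                    units = result$units, n_frames = length(result$series))
  } else if (inherits(result, "orientation_histogram")) {
    df <- data.frame(cos_phi = result$bin_mid, frequency = result$frequencies,
                     count = result$counts)
    summary <- list(n_samples = result$n_samples, n_bins = length(result$counts))
  } else if (inherits(result, "msd_curve")) {
    df <- data.frame(lag_ps = result$lag, msd_nm2 = result$msd,
                     n_origins = result$n_origins)
    summary <- list(n_lags = length(result$lag) - 1L,
                    max_lag_ps = max(result$lag))
  } else if (inherits(result, "diffusion_fit")) {
    df <- data.frame(D_cm2_s = result$D, D_se = result$D_se,
                     slope_nm2_ps = result$slope)
    summary <- unclass(result)
  } else stop("unsupported result type")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(c(summary, list(parameters = params)), js,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, js))
}
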