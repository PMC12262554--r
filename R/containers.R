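#' Build a molecular frame
#'
#' A frame is the basic substrate of all geometry operations: a table of
#' atoms with coordinates in Angstrom, residue identity, and flags marking
#' water oxygens, water hydrogens, and protein heavy atoms.
#'
#' @param atoms data.frame with columns `elety` (atom name), `elem`
#'   (element symbol), `resid` (integer residue number), `resname`,
#'   `x`, `y`, `z` (Angstrom). Optional logical columns `is_water_o`,
#'   `is_water_h`, `is_protein` are derived from `resname`/`elem` when
#'   absent (water residues: HOH, WAT, SOL, TIP3, TIP).
#' @param time_ps frame time in picoseconds.
#' @param validate check invariants (finite coordinates, two hydrogens per
#'   water oxygen).
#' @return object of class `md_frame` (a data.frame with a `time_ps`
#'   attribute).
#' @export
md_frame <- function(atoms, time_ps = 0, validate = TRUE) {
  need <- c("elety", "elem", "resid", "resname", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("md_frame: atoms table is missing column(s): ",
         paste(miss, collapse = ", "))
  water_res <- c("HOH", "WAT", "SOL", "TIP3", "TIP")
  if (is.null(atoms$is_water_o))
    atoms$is_water_o <- atoms$resname %in% water_res & atoms$elem == "O"
  if (is.null(atoms$is_water_h))
    atoms$is_water_h <- atoms$resname %in% water_res & atoms$elem == "H"
  if (is.null(atoms$is_protein))
    atoms$is_protein <- !(atoms$resname %in% water_res) & atoms$elem != "H"
  if (validate) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      stop("md_frame: non-finite coordinates")
    if (any(atoms$is_water_o)) {
      hn <- tapply(atoms$is_water_h, atoms$resid, sum)
      on <- tapply(atoms$is_water_o, atoms$resid, sum)
      bad <- names(on)[on == 1L & hn[names(on)] != 2L]
      if (length(bad) > 0L)
        stop("md_frame: water residue(s) without exactly 2 hydrogens: ",
             paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  structure(as.data.frame(atoms), time_ps = time_ps,
            class = c("md_frame", "data.frame"))
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms (%d water O, %d protein heavy), t = %g ps\n",
              nrow(x), sum(x$is_water_o), sum(x$is_protein),
              attr(x, "time_ps")))
  invisible(x)
}

#' Frame coordinates as a matrix
#' @param frame an `md_frame`.
#' @param sel optional logical or integer row selection.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
frame_coords <- function(frame, sel = NULL) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Build a trajectory
#'
#' Stores a fixed topology (an `md_frame` giving atom identities) plus a
#' coordinate array, one slice per frame.
#'
#' @param topology `md_frame` describing the atoms (its own coordinates are
#'   those of the first frame unless `coords` is given).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param times_ps numeric vector of frame times (ps).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, times_ps) {
  stopifnot(inherits(topology, "md_frame"))
  if (length(dim(coords)) != 3L || dim(coords)[1] != nrow(topology) ||
      dim(coords)[2] != 3L)
    stop("md_trajectory: coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[3] != length(times_ps))
    stop("md_trajectory: length(times_ps) must equal the number of frames")
  structure(list(topology = topology, coords = coords,
                 times_ps = as.numeric(times_ps)),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[3]
}

#' Extract one frame from a trajectory
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return `md_frame`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (i < 1L || i > n_frames(traj)) stop("traj_frame: index out of range")
  at <- traj$topology
  at$x <- traj$coords[, 1, i]
  at$y <- traj$coords[, 2, i]
  at$z <- traj$coords[, 3, i]
  md_frame(at, time_ps = traj$times_ps[i], validate = FALSE)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms x %d frames, t = [%g, %g] ps\n",
              nrow(x$topology), n_frames(x), min(x$times_ps),
              max(x$times_ps)))
  invisible(x)
}

# Coerce a single frame to a 1-frame trajectory (internal convenience).
.as_trajectory <- function(x) {
  if (inherits(x, "md_trajectory")) return(x)
  if (inherits(x, "md_frame")) {
    co <- array(frame_coords(x), dim = c(nrow(x), 3L, 1L))
    return(md_trajectory(x, co, attr(x, "time_ps")))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "md_frame"))) {
    co <- array(0, dim = c(nrow(x[[1]]), 3L, length(x)))
    for (i in seq_along(x)) co[, , i] <- frame_coords(x[[i]])
    return(md_trajectory(x[[1]], co,
                         vapply(x, attr, numeric(1), "time_ps")))
  }
  stop("expected an md_trajectory, an md_frame, or a list of md_frame")
}

#' Amplitude-versus-time curve
#'
#' Shared container for inversion-recovery curves (delay in ms), photocycle
#' absorbance recoveries (time in s), and water-population kinetics
#' (time in min).
#'
#' @param time numeric, non-negative times or delays.
#' @param amplitude numeric, same length.
#' @param time_unit one of "ms", "s", "min".
#' @return `recovery_curve` data.frame with columns `time`, `amplitude`.
#' @export
recovery_curve <- function(time, amplitude, time_unit = c("ms", "s", "min")) {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(amplitude))
    stop("recovery_curve: time and amplitude lengths differ")
  if (any(time < 0)) stop("recovery_curve: negative times")
  structure(data.frame(time = as.numeric(time),
                       amplitude = as.numeric(amplitude)),
            time_unit = time_unit,
            class = c("recovery_curve", "data.frame"))
}
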