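#' Read a PDB structure into a frame
#'
#' Parses ATOM/HETATM records (via bio3d) with residue numbers taken
#' verbatim -- no renumbering, so e.g. the AsLOV2 403-546 convention is
#' preserved. Water residues (HOH/WAT/SOL/TIP3/TIP) are flagged as water;
#' everything else heavy is protein.
#'
#' @param path PDB file.
#' @return an [md_frame()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  # crystallographic waters usually carry no hydrogens, so the
  # two-hydrogens-per-water invariant is not enforced here; operations that
  # need explicit water hydrogens (hydrogen-bond detection) raise their own
  # error when they are absent
  md_frame(data.frame(elety = at$elety, elem = elem, resid = at$resno,
                      resname = at$resid, x = at$x, y = at$y, z = at$z),
           validate = FALSE)
}

#' Write a frame as a PDB file
#'
#' @param frame an [md_frame()].
#' @param path output file.
#' @export
write_structure <- function(frame, path) {
  stopifnot(inherits(frame, "md_frame"))
  xyz <- as.numeric(t(frame_coords(frame)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = frame$resid,
                   resid = frame$resname, elety = frame$elety,
                   elesy = frame$elem)
  invisible(path)
}

#' Write a trajectory in the plain XYZ-block format
#'
#' One header line per frame (`FRAME <index> time_ps <t>`) followed by one
#' whitespace-delimited `x y z` line per atom, preceded by a two-line file
#' header giving the atom count. Atom identities live in the companion
#' topology (PDB).
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(traj$topology)
  writeLines(c("# xyz-block trajectory", paste("natoms", na)), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("FRAME %d time_ps %.6g", f, traj$times_ps[f]), con)
    m <- traj$coords[, , f]
    writeLines(sprintf("%.4f %.4f %.4f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ-block trajectory
#'
#' Adapter contract for other trajectory sources: anything that can hand
#' frames to [md_trajectory()] (topology + coordinate array) can feed the
#' pipeline; this reader implements the contract for the native plain-text
#' format of [write_trajectory()].
#'
#' @param path trajectory file.
#' @param topology an [md_frame()] (or path to a PDB) giving atom
#'   identities.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("read_trajectory: file not found: ", path)
  if (is.character(topology)) topology <- read_structure(topology)
  stopifnot(inherits(topology, "md_frame"))
  lines <- readLines(path)
  nat_line <- grep("^natoms ", lines)[1]
  if (is.na(nat_line))
    stop("read_trajectory: ", path, ": missing 'natoms' header line")
  na <- as.integer(sub("^natoms ", "", lines[nat_line]))
  if (na != nrow(topology))
    stop("read_trajectory: ", path, ": natoms (", na,
         ") does not match topology (", nrow(topology), " atoms)")
  hdr <- grep("^FRAME ", lines)
  if (length(hdr) == 0L) stop("read_trajectory: ", path, ": no FRAME records")
  nf <- length(hdr)
  coords <- array(0, dim = c(na, 3L, nf))
  times <- numeric(nf)
  for (i in seq_len(nf)) {
    parts <- strsplit(lines[hdr[i]], "\\s+")[[1]]
    times[i] <- as.numeric(parts[4])
    block <- lines[(hdr[i] + 1L):(hdr[i] + na)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(m) != na)
      stop("read_trajectory: ", path, ": frame ", i, " at line ", hdr[i],
           " has ", nrow(m), " coordinate rows, expected ", na)
    coords[, , i] <- m
  }
  md_trajectory(topology, coords, times)
}

#' Read and validate a CSV table
#'
#' @param path CSV file with a header row.
#' @param required_cols column names that must be present; a clear error
#'   names the file and the missing column otherwise.
#' @param numeric_cols columns checked to be numeric.
#' @return data.frame.
#' @export
read_table <- function(path, required_cols = character(0),
                       numeric_cols = character(0)) {
  if (!file.exists(path)) stop("read_table: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss) > 0L)
    stop("read_table: ", path, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v) & !is.na(df[[cc]])))
      stop("read_table: ", path, ": column '", cc, "' is not numeric")
    df[[cc]] <- v
  }
  df
}
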