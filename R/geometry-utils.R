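# Internal 3D vector helpers used by the synthetic geometry builder and the
# water-shell operators. All angles in degrees, lengths in Angstrom.

.unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

.crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vangle_deg <- function(u, v) {
  cc <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cc))) * 180 / pi
}

# Rodrigues rotation of vector v about unit axis by theta degrees.
.rotate_deg <- function(v, axis, theta_deg) {
  k <- .unitv(axis)
  th <- theta_deg * pi / 180
  v * cos(th) + .crossv(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# Any unit vector perpendicular to v.
.any_perp <- function(v) {
  v <- .unitv(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unitv(.crossv(v, ref))
}

# Rigid three-site water geometry (TIP3P-class): O-H 0.9572 A, H-O-H 104.52 deg.
.OH_LEN <- 0.9572
.HOH_DEG <- 104.52

# Place the two hydrogens of a water at oxygen position `o`.
# `donor_dirs`: list of 0-2 unit vectors along which the water must donate a
# hydrogen bond (H kept as close to the O->acceptor axis as the rigid H-O-H
# angle allows). `avoid_axes`: list of unit vectors (O->O axes of nearby
# non-partner oxygens); free hydrogens are steered away from them so no
# unintended hydrogen bond fires. `fallback_dir`: direction for the first
# hydrogen when there is no donation constraint.
.place_hydrogens <- function(o, donor_dirs = list(), avoid_axes = list(),
                             fallback_dir = c(0, 0, 1)) {
  nd <- length(donor_dirs)
  if (nd > 2L) stop("a water can donate at most two hydrogen bonds")
  cone_pick <- function(h1, n_cand = 72L) {
    # candidate H2 directions on the rigid-angle cone about h1; pick the one
    # farthest (in min-angle sense) from all axes to avoid
    p <- .any_perp(h1)
    best <- NULL; best_score <- -Inf
    for (az in seq(0, 360 - 360 / n_cand, by = 360 / n_cand)) {
      axis <- .rotate_deg(p, h1, az)
      cand <- .rotate_deg(h1, axis, .HOH_DEG)
      score <- if (length(avoid_axes) == 0L) 90 else
        min(vapply(avoid_axes, function(a) .vangle_deg(cand, a), numeric(1)))
      if (score > best_score) { best_score <- score; best <- cand }
    }
    best
  }
  if (nd == 2L) {
    d1 <- .unitv(donor_dirs[[1]]); d2 <- .unitv(donor_dirs[[2]])
    gamma <- .vangle_deg(d1, d2)
    if (gamma < 1e-9 || gamma > 179.999) {
      h1 <- d1; h2 <- cone_pick(h1)
    } else {
      nrm <- .unitv(.crossv(d1, d2))
      bis <- .unitv(d1 + d2)
      h1 <- .rotate_deg(bis, nrm, -.HOH_DEG / 2)
      h2 <- .rotate_deg(bis, nrm, .HOH_DEG / 2)
      # keep h1 paired with d1 (rotation sign convention check)
      if (.vangle_deg(h1, d1) > .vangle_deg(h1, d2)) { tmp <- h1; h1 <- h2; h2 <- tmp }
    }
  } else if (nd == 1L) {
    h1 <- .unitv(donor_dirs[[1]])
    h2 <- cone_pick(h1)
  } else {
    h1 <- .unitv(fallback_dir)
    h2 <- cone_pick(h1)
  }
  rbind(o + .OH_LEN * h1, o + .OH_LEN * h2)
}
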