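# Bondi van der Waals radii (Angstrom)
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Deterministic quasi-uniform sphere points (Fibonacci lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: for each heavy atom, the fraction of `n_points`
#' quasi-uniform points on a sphere of radius `r_vdw + probe` not buried
#' inside any other inflated atom, times the sphere area. Radii are Bondi;
#' unknown elements fall back to `default_radius` with a warning.
#'
#' @param frame an [md_frame()].
#' @param probe probe radius (Angstrom).
#' @param n_points test points per atom.
#' @param atoms optional logical/integer selection of rows to include;
#'   default: protein heavy atoms (all heavy non-water atoms when the frame
#'   has no protein).
#' @param default_radius fallback van der Waals radius (Angstrom).
#' @return list with `total` (Angstrom^2) and `per_atom` data.frame
#'   (`row`, `elem`, `area_A2`).
#' @export
sasa <- function(frame, probe = 1.4, n_points = 960, atoms = NULL,
                 default_radius = 1.70) {
  stopifnot(inherits(frame, "md_frame"))
  if (is.null(atoms)) {
    atoms <- which(frame$is_protein)
    if (length(atoms) == 0L)
      atoms <- which(!frame$is_water_h & toupper(frame$elem) != "H")
  } else if (is.logical(atoms)) atoms <- which(atoms)
  if (length(atoms) == 0L) stop("sasa: no atoms selected")
  el <- toupper(frame$elem[atoms])
  r <- .VDW_RADII[el]
  if (any(is.na(r))) {
    warning("sasa: unknown element(s) ",
            paste(unique(el[is.na(r)]), collapse = ", "),
            "; using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  R <- unname(r) + probe
  X <- frame_coords(frame, atoms)
  sp <- .sphere_points(n_points)
  n <- length(atoms)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(X, 2, X[i, ])^2))
    nbr <- which(d < R[i] + R & seq_len(n) != i)
    pts <- sweep(sp * R[i], 2, X[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      d2 <- (pts[, 1] - X[j, 1])^2 + (pts[, 2] - X[j, 2])^2 +
        (pts[, 3] - X[j, 3])^2
      acc <- acc & d2 > R[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  list(total = sum(area),
       per_atom = data.frame(row = atoms, elem = el, area_A2 = area))
}

#' SASA time series over a trajectory
#'
#' @param traj an [md_trajectory()] (or frame list).
#' @inheritParams sasa
#' @return data.frame: `frame`, `time_ps`, `sasa_A2`.
#' @export
sasa_series <- function(traj, probe = 1.4, n_points = 960, atoms = NULL) {
  traj <- .as_trajectory(traj)
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    sasa(traj_frame(traj, f), probe = probe, n_points = n_points,
         atoms = atoms)$total, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times_ps,
             sasa_A2 = vals)
}

# Within-segment squared-error cost from cumulative sums; segment a..b.
.seg_cost <- function(cs, cs2, a, b) {
  n <- b - a + 1
  s <- cs[b + 1] - cs[a]
  s2 <- cs2[b + 1] - cs2[a]
  s2 - s^2 / n
}

#' Penalized change-point detection (binary segmentation, L2 cost)
#'
#' Recursively splits the series at the point minimizing the within-segment
#' squared error, accepting a split when the cost reduction exceeds
#' `penalty`. Deterministic; a constant series yields no breakpoints for
#' any positive penalty.
#'
#' @param x numeric series (e.g. a SASA series).
#' @param penalty per-breakpoint penalty; default `2 * sigma2 * log(n)`
#'   with the noise variance estimated from first differences,
#'   `sigma2 = mean(diff(x)^2) / 2`.
#' @param min_size minimum segment length.
#' @return sorted integer breakpoints b, each meaning segments split as
#'   `1..b` and `b+1..n`.
#' @export
changepoints <- function(x, penalty = NULL, min_size = 2L) {
  n <- length(x)
  if (n < 2L * min_size) return(integer(0))
  if (is.null(penalty)) {
    sigma2 <- mean(diff(x)^2) / 2
    penalty <- 2 * sigma2 * log(n)
  }
  if (penalty < 0) stop("changepoints: penalty must be >= 0")
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  bps <- integer(0)
  recurse <- function(a, b) {
    if (b - a + 1 < 2L * min_size) return()
    full <- .seg_cost(cs, cs2, a, b)
    ks <- seq.int(a + min_size - 1L, b - min_size)
    costs <- vapply(ks, function(k)
      .seg_cost(cs, cs2, a, k) + .seg_cost(cs, cs2, k + 1L, b), numeric(1))
    k_best <- ks[which.min(costs)]
    if (full - min(costs) > penalty) {
      bps <<- c(bps, k_best)
      recurse(a, k_best)
      recurse(k_best + 1L, b)
    }
  }
  recurse(1L, n)
  sort(bps)
}

#' Heavy-atom RMSD between two frames
#'
#' Centroid-removed root-mean-square deviation; with `fit = TRUE` the
#' optimal rotation (Kabsch superposition via SVD, reflection-corrected)
#' is applied first.
#'
#' @param frame_a,frame_b [md_frame()]s with matching atom order.
#' @param fit superpose before computing the deviation.
#' @param atoms optional row selection (default: protein heavy atoms, or
#'   all heavy atoms when no protein present).
#' @return RMSD in nanometers.
#' @export
pairwise_rmsd <- function(frame_a, frame_b, fit = TRUE, atoms = NULL) {
  sel <- function(fr) {
    if (!is.null(atoms)) return(if (is.logical(atoms)) which(atoms) else atoms)
    p <- which(fr$is_protein)
    if (length(p) > 0L) p else which(toupper(fr$elem) != "H")
  }
  A <- frame_coords(frame_a, sel(frame_a))
  B <- frame_coords(frame_b, sel(frame_b))
  if (nrow(A) != nrow(B))
    stop("pairwise_rmsd: frames have different atom counts")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  if (fit) {
    s <- svd(crossprod(B, A))   # rotate B onto A
    d <- sign(det(s$u %*% t(s$v)))
    Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    B <- B %*% Rm
  }
  sqrt(mean(rowSums((A - B)^2))) / 10
}

#' Daura RMSD clustering of trajectory frames
#'
#' Greedy neighbor-count clustering: the frame with the most neighbors
#' within `cutoff` becomes a cluster center, it and its neighbors are
#' removed, and the procedure repeats. Ties are broken by the lowest frame
#' index. The output is a partition of all frames, and every center is a
#' member of its own cluster.
#'
#' @param frames an [md_trajectory()] or list of frames.
#' @param cutoff RMSD cutoff (nm).
#' @param fit superpose before each RMSD (see [pairwise_rmsd()]).
#' @return list of class `cluster_result`: `centers` (frame indices),
#'   `members` (list of integer vectors), `cutoff_nm`.
#' @export
daura_cluster <- function(frames, cutoff = 0.2, fit = TRUE) {
  traj <- .as_trajectory(frames)
  nf <- n_frames(traj)
  frs <- lapply(seq_len(nf), function(i) traj_frame(traj, i))
  D <- matrix(0, nf, nf)
  if (nf > 1L)
    for (i in seq_len(nf - 1L)) for (j in seq.int(i + 1L, nf)) {
      D[i, j] <- D[j, i] <- pairwise_rmsd(frs[[i]], frs[[j]], fit = fit)
    }
  remaining <- seq_len(nf)
  centers <- integer(0); members <- list()
  while (length(remaining) > 0L) {
    cnt <- vapply(remaining, function(i)
      sum(D[i, remaining] <= cutoff), numeric(1))  # includes self
    center <- remaining[which.max(cnt)]            # which.max -> lowest index
    grp <- remaining[D[center, remaining] <= cutoff]
    centers <- c(centers, center)
    members <- c(members, list(sort(grp)))
    remaining <- setdiff(remaining, grp)
  }
  structure(list(centers = centers, members = members, cutoff_nm = cutoff),
            class = "cluster_result")
}

#' Residue-wise displacement relative to a reference structure
#'
#' Both structures are translated to a common center of gravity (heavy-atom
#' centroid; translation only, no rotational fit unless `rotate = TRUE`),
#' then the Euclidean distance between per-residue heavy-atom centroids is
#' reported.
#'
#' @param frame,reference [md_frame()]s sharing residue numbering.
#' @param rotate additionally apply a Kabsch rotational fit.
#' @return data.frame: `residue`, `displacement_A` (>= 0).
#' @export
residue_displacement <- function(frame, reference, rotate = FALSE) {
  heavy <- function(fr) {
    p <- which(fr$is_protein)
    if (length(p) > 0L) p else which(toupper(fr$elem) != "H")
  }
  ia <- heavy(frame); ib <- heavy(reference)
  A <- frame_coords(frame, ia); B <- frame_coords(reference, ib)
  ra <- frame$resid[ia]; rb <- reference$resid[ib]
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  if (rotate) {
    if (nrow(A) != nrow(B))
      stop("residue_displacement: rotational fit needs matching atoms")
    s <- svd(crossprod(A, B))
    d <- sign(det(s$u %*% t(s$v)))
    A <- A %*% (s$u %*% diag(c(1, 1, d)) %*% t(s$v))
  }
  resids <- sort(intersect(unique(ra), unique(rb)))
  disp <- vapply(resids, function(r) {
    ca <- colMeans(A[ra == r, , drop = FALSE])
    cb <- colMeans(B[rb == r, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  data.frame(residue = resids, displacement_A = disp)
}
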