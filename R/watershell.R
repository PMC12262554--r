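#' Geometric hydrogen-bond criterion
#'
#' Two waters are hydrogen bonded when their O-O distance is at most
#' `max_oo` and at least one of them donates a hydrogen lying within
#' `max_angle_dev` degrees of its O-to-O axis. This is the standard
#' geometric definition for 3-site water models; both limits are
#' configurable.
#'
#' @param max_oo maximum O-O distance (Angstrom).
#' @param max_angle_dev maximum donor O-H off-axis angle (degrees, 0-90).
#' @export
hbond_criterion <- function(max_oo = 3.5, max_angle_dev = 30) {
  if (max_oo <= 0) stop("hbond_criterion: max_oo must be > 0")
  if (max_angle_dev < 0 || max_angle_dev > 90)
    stop("hbond_criterion: max_angle_dev must lie in [0, 90]")
  structure(list(max_oo = max_oo, max_angle_dev = max_angle_dev),
            class = "hbond_criterion")
}

#' Three-body-angle classification windows
#'
#' Angular windows (degrees) assigning each three-body angle to a water
#' structural archetype: tetrahedral "wrap" water (100-120), icosahedral
#' bulk-like water (50-70), and near-planar "bound" water (150-170).
#' Windows must be disjoint; angles outside every window are
#' "unclassified".
#'
#' @param wrap,icosahedral,bound numeric length-2 `[lo, hi]` windows.
#' @export
class_windows <- function(wrap = c(100, 120), icosahedral = c(50, 70),
                          bound = c(150, 170)) {
  w <- list(wrap = wrap, icosahedral = icosahedral, bound = bound)
  for (nm in names(w))
    if (length(w[[nm]]) != 2L || w[[nm]][1] >= w[[nm]][2])
      stop("class_windows: window '", nm, "' must be [lo, hi] with lo < hi")
  iv <- do.call(rbind, w)
  o <- order(iv[, 1])
  if (any(iv[o, 2][-nrow(iv)] >= iv[o, 1][-1]))
    stop("class_windows: windows must be disjoint")
  structure(w, class = "class_windows")
}

# Internal: water bookkeeping for a frame. Returns oxygen rows and a
# 2-column matrix of hydrogen rows per water.
.water_index <- function(frame) {
  o_rows <- which(frame$is_water_o)
  if (length(o_rows) == 0L)
    return(list(o_rows = integer(0), h_rows = matrix(0L, 0, 2)))
  h_rows <- matrix(0L, length(o_rows), 2)
  hs <- which(frame$is_water_h)
  hs_by_res <- split(hs, frame$resid[hs])
  for (i in seq_along(o_rows)) {
    hh <- hs_by_res[[as.character(frame$resid[o_rows[i]])]]
    if (is.null(hh) || length(hh) != 2L)
      stop("water oxygen in residue ", frame$resid[o_rows[i]],
           " lacks exactly 2 hydrogens")
    h_rows[i, ] <- hh
  }
  list(o_rows = o_rows, h_rows = h_rows)
}

#' Hydrogen-bonded neighbor list of water oxygens
#'
#' @param frame an [md_frame()].
#' @param crit an [hbond_criterion()].
#' @return list of integer vectors, one per water oxygen (indices into the
#'   water list), with attribute `o_rows` giving the frame row of each
#'   water oxygen. The relation is symmetric and irreflexive.
#' @export
find_hbond_neighbors <- function(frame, crit = hbond_criterion()) {
  stopifnot(inherits(frame, "md_frame"), inherits(crit, "hbond_criterion"))
  wi <- .water_index(frame)
  nw <- length(wi$o_rows)
  nb <- rep(list(integer(0)), nw)
  attr(nb, "o_rows") <- wi$o_rows
  class(nb) <- "hbond_neighbors"
  if (nw < 2L) return(nb)
  O <- frame_coords(frame, wi$o_rows)
  H1 <- frame_coords(frame, wi$h_rows[, 1])
  H2 <- frame_coords(frame, wi$h_rows[, 2])
  dmat <- as.matrix(stats::dist(O))
  cosmax <- cos(crit$max_angle_dev * pi / 180)
  donates <- function(i, j) {
    axis <- O[j, ] - O[i, ]
    dn <- sqrt(sum(axis^2))
    for (H in list(H1, H2)) {
      hv <- H[i, ] - O[i, ]
      cc <- sum(hv * axis) / (dn * sqrt(sum(hv^2)))
      if (cc >= cosmax) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(nw - 1L)) for (j in seq.int(i + 1L, nw)) {
    if (dmat[i, j] > crit$max_oo) next
    if (donates(i, j) || donates(j, i)) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  attr(nb, "o_rows") <- wi$o_rows
  class(nb) <- "hbond_neighbors"
  nb
}

#' Three-body angles at each water oxygen
#'
#' For every water oxygen with at least two hydrogen-bonded neighbors, the
#' angle subtended at the central oxygen by each unordered pair of neighbor
#' oxygens. Neighbor sets are capped at the `max_neighbors` nearest
#' oxygens (tetrahedral coordination bound).
#'
#' @param frame an [md_frame()].
#' @param neighbors output of [find_hbond_neighbors()].
#' @param max_neighbors cap on neighbors per central oxygen.
#' @return data.frame with columns `water` (index into the water list),
#'   `o_row` (frame row of the central oxygen), `angle_deg` in [0, 180].
#' @export
three_body_angles <- function(frame, neighbors, max_neighbors = 4L) {
  stopifnot(inherits(frame, "md_frame"), inherits(neighbors, "hbond_neighbors"))
  o_rows <- attr(neighbors, "o_rows")
  O <- frame_coords(frame, o_rows)
  out <- vector("list", length(neighbors))
  for (i in seq_along(neighbors)) {
    nbs <- neighbors[[i]]
    if (length(nbs) < 2L) next
    if (length(nbs) > max_neighbors) {
      dd <- sqrt(rowSums((O[nbs, , drop = FALSE] -
                            matrix(O[i, ], length(nbs), 3,
                                   byrow = TRUE))^2))
      nbs <- nbs[order(dd)][seq_len(max_neighbors)]
    }
    prs <- utils::combn(sort(nbs), 2L)
    ang <- apply(prs, 2, function(p)
      .vangle_deg(O[p[1], ] - O[i, ], O[p[2], ] - O[i, ]))
    out[[i]] <- data.frame(water = i, o_row = o_rows[i], angle_deg = ang)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(water = integer(0), o_row = integer(0),
                      angle_deg = numeric(0))
  rownames(res) <- NULL
  res
}

#' Classify three-body angles into structural windows
#'
#' @param angles data.frame from [three_body_angles()] (or any with an
#'   `angle_deg` column).
#' @param windows a [class_windows()].
#' @return data.frame with one row per class (wrap, icosahedral, bound,
#'   unclassified): `count` and `fraction`; attribute `assignment` is a
#'   factor giving each angle's class.
#' @export
classify_angles <- function(angles, windows = class_windows()) {
  stopifnot(inherits(windows, "class_windows"))
  a <- angles$angle_deg
  lev <- c(names(windows), "unclassified")
  asg <- rep("unclassified", length(a))
  for (nm in names(windows)) {
    w <- windows[[nm]]
    asg[a >= w[1] & a <= w[2]] <- nm
  }
  asg <- factor(asg, levels = lev)
  cnt <- table(asg)
  res <- data.frame(class = lev, count = as.integer(cnt),
                    fraction = if (length(a) > 0)
                      as.numeric(cnt) / length(a) else rep(0, length(lev)))
  attr(res, "assignment") <- asg
  res
}

#' Assign waters to per-residue hydration shells
#'
#' A water oxygen belongs to residue r's shell when it lies within `cutoff`
#' of any heavy atom of r. A water may belong to several shells.
#'
#' @param frame an [md_frame()].
#' @param cutoff shell cutoff (Angstrom).
#' @return named list: residue id -> integer vector of frame rows of
#'   in-shell water oxygens.
#' @export
shell_assign <- function(frame, cutoff = 4.5) {
  stopifnot(inherits(frame, "md_frame"))
  if (cutoff <= 0) stop("shell_assign: cutoff must be > 0")
  o_rows <- which(frame$is_water_o)
  prot <- which(frame$is_protein)
  resids <- sort(unique(frame$resid[prot]))
  out <- stats::setNames(rep(list(integer(0)), length(resids)),
                         as.character(resids))
  if (length(o_rows) == 0L || length(prot) == 0L) return(out)
  W <- frame_coords(frame, o_rows)
  for (r in resids) {
    P <- frame_coords(frame, prot[frame$resid[prot] == r])
    d2min <- rep(Inf, nrow(W))
    for (k in seq_len(nrow(P))) {
      d2 <- (W[, 1] - P[k, 1])^2 + (W[, 2] - P[k, 2])^2 +
        (W[, 3] - P[k, 3])^2
      d2min <- pmin(d2min, d2)
    }
    out[[as.character(r)]] <- o_rows[d2min <= cutoff^2]
  }
  out
}

#' Per-residue hydration-structure profile
#'
#' Averages, over the frames of a time window, the per-residue class makeup
#' of hydration-shell water: the fraction of three-body angles (or, in
#' water-majority mode, of central waters) falling in the wrap,
#' icosahedral, and bound windows. An angle counts toward residue r when
#' its central water lies in r's shell.
#'
#' @param traj an [md_trajectory()], an [md_frame()], or a list of frames.
#' @param windows a [class_windows()].
#' @param cutoff shell cutoff (Angstrom).
#' @param crit an [hbond_criterion()].
#' @param frames optional integer frame indices restricting the window.
#' @param mode "angle" counts one vote per three-body angle; "water"
#'   counts one vote per central water, classified by majority over its
#'   angles.
#' @return data.frame per residue: `shell_count` (mean waters in shell),
#'   `n_votes`, `frac_wrap`, `frac_icosahedral`, `frac_bound`,
#'   `frac_unclassified`, and `empty` (TRUE when no votes; fractions then
#'   reported as 0).
#' @export
hydration_profile <- function(traj, windows = class_windows(), cutoff = 4.5,
                              crit = hbond_criterion(), frames = NULL,
                              mode = c("angle", "water")) {
  mode <- match.arg(mode)
  traj <- .as_trajectory(traj)
  idx <- if (is.null(frames)) seq_len(n_frames(traj)) else frames
  resids <- sort(unique(traj$topology$resid[traj$topology$is_protein]))
  lev <- c(names(windows), "unclassified")
  counts <- matrix(0, length(resids), length(lev),
                   dimnames = list(as.character(resids), lev))
  shell_sum <- stats::setNames(rep(0, length(resids)), as.character(resids))
  for (f in idx) {
    fr <- traj_frame(traj, f)
    nb <- find_hbond_neighbors(fr, crit)
    ang <- three_body_angles(fr, nb)
    cls <- classify_angles(ang, windows)
    asg <- attr(cls, "assignment")
    shells <- shell_assign(fr, cutoff)
    for (r in names(shells)) {
      shell_sum[r] <- shell_sum[r] + length(shells[[r]])
      in_shell <- ang$o_row %in% shells[[r]]
      if (!any(in_shell)) next
      if (mode == "angle") {
        tt <- table(asg[in_shell])
        counts[r, ] <- counts[r, ] + as.numeric(tt[lev])
      } else {
        per_w <- split(as.character(asg[in_shell]), ang$water[in_shell])
        for (v in per_w) {
          tv <- table(factor(v, levels = lev))
          win <- lev[which.max(tv)]
          counts[r, win] <- counts[r, win] + 1
        }
      }
    }
  }
  n_votes <- rowSums(counts)
  frac <- counts / ifelse(n_votes > 0, n_votes, 1)
  frac[n_votes == 0, ] <- 0
  data.frame(residue = resids,
             shell_count = as.numeric(shell_sum) / length(idx),
             n_votes = as.numeric(n_votes),
             frac_wrap = frac[, "wrap"],
             frac_icosahedral = frac[, "icosahedral"],
             frac_bound = frac[, "bound"],
             frac_unclassified = frac[, "unclassified"],
             empty = n_votes == 0, row.names = NULL)
}

#' First-passage residence times of shell water
#'
#' For every water x residue pair, the duration of the water's first
#' continuous stay in the residue's shell: from first entry (a water
#' already in shell at the start of the trajectory counts from the first
#' frame) to first exit. Later re-entries of the same water are excluded,
#' as are visits still running when the trajectory ends. Duration is the
#' number of occupied frames times the frame spacing.
#'
#' @param traj an [md_trajectory()] with uniformly spaced frames (>= 2).
#' @param cutoff shell cutoff (Angstrom).
#' @return data.frame per residue: `mean_residence_ps` (NA when no
#'   completed visit), `n_visits`.
#' @export
residence_times <- function(traj, cutoff = 4.5) {
  traj <- .as_trajectory(traj)
  nf <- n_frames(traj)
  if (nf < 2L) stop("residence_times: need at least 2 frames")
  dts <- diff(traj$times_ps)
  if (any(abs(dts - dts[1]) > 1e-9 * max(dts[1], 1)))
    stop("residence_times: frames must be uniformly spaced")
  dt <- dts[1]
  topo <- traj$topology
  o_rows <- which(topo$is_water_o)
  resids <- sort(unique(topo$resid[topo$is_protein]))
  res <- data.frame(residue = resids, mean_residence_ps = NA_real_,
                    n_visits = 0L)
  if (length(o_rows) == 0L || length(resids) == 0L) return(res)
  # streaming scan over frames: occupancy computed directly on the
  # coordinate array (equivalent to shell_assign frame by frame), first
  # runs tracked online per water x residue pair
  prot <- which(topo$is_protein)
  res_rows <- split(prot, topo$resid[prot])[as.character(resids)]
  cutoff2 <- cutoff^2
  nw <- length(o_rows); nr <- length(resids)
  seen <- matrix(FALSE, nw, nr)      # first run has started
  finished <- matrix(FALSE, nw, nr)  # first run has completed
  runlen <- matrix(0L, nw, nr)
  IN <- matrix(FALSE, nw, nr)
  for (f in seq_len(nf)) {
    W <- matrix(traj$coords[o_rows, , f], ncol = 3)
    for (ri in seq_len(nr)) {
      P <- matrix(traj$coords[res_rows[[ri]], , f], ncol = 3)
      d2min <- rep(Inf, nw)
      for (k in seq_len(nrow(P)))
        d2min <- pmin(d2min, (W[, 1] - P[k, 1])^2 + (W[, 2] - P[k, 2])^2 +
                        (W[, 3] - P[k, 3])^2)
      IN[, ri] <- d2min <= cutoff2
    }
    newstart <- IN & !seen
    cont <- IN & seen & !finished & !newstart
    ended <- !IN & seen & !finished
    runlen[newstart] <- 1L
    runlen[cont] <- runlen[cont] + 1L
    seen[newstart] <- TRUE
    finished[ended] <- TRUE
  }
  # runs still open at the last frame are unterminated -> excluded
  for (ri in seq_len(nr)) {
    done <- finished[, ri]
    if (any(done)) {
      res$mean_residence_ps[ri] <- mean(runlen[done, ri]) * dt
      res$n_visits[ri] <- sum(done)
    }
  }
  res
}

#' Flag residues with a large wrap-water reduction
#'
#' A residue is flagged when its wrap-water fraction drops, between a
#' reference profile and a later profile, by more than half of the mean
#' reference wrap fraction across all residues.
#'
#' @param profile_ref,profile_t [hydration_profile()] outputs sharing
#'   residue ids.
#' @return data.frame per residue: `wrap_ref`, `wrap_t`, `delta`,
#'   `flagged`.
#' @export
wrap_change_flags <- function(profile_ref, profile_t) {
  m <- merge(profile_ref[, c("residue", "frac_wrap")],
             profile_t[, c("residue", "frac_wrap")],
             by = "residue", suffixes = c("_ref", "_t"))
  if (nrow(m) == 0L) stop("wrap_change_flags: no shared residues")
  thr <- 0.5 * mean(m$frac_wrap_ref)
  data.frame(residue = m$residue, wrap_ref = m$frac_wrap_ref,
             wrap_t = m$frac_wrap_t,
             delta = m$frac_wrap_ref - m$frac_wrap_t,
             flagged = (m$frac_wrap_ref - m$frac_wrap_t) > thr)
}
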