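#' Specification for synthetic water-geometry frames
#'
#' Describes a set of water clusters built so that the hydrogen-bonded
#' three-body angles (3BA) at each cluster's central oxygen sit exactly at a
#' chosen structural archetype before angular jitter is applied:
#' tetrahedral (109.47 deg, "wrap" water), icosahedral adjacent-vertex
#' (63.43 deg, bulk-like water), or planar (150-170 deg, "bound" water).
#'
#' @param class_label one of "tetrahedral", "icosahedral", "planar",
#'   "mixed".
#' @param n_waters total water budget. Clusters are emitted whole
#'   (tetrahedral: 5 waters, icosahedral: 13, planar: 3), so the realized
#'   count may be slightly below the budget; it is recorded in the output.
#' @param jitter_deg SD (degrees) of Gaussian angular noise applied to each
#'   neighbor direction.
#' @param box_edge nominal box edge (Angstrom); clusters are laid out on a
#'   lattice with 15 A spacing starting from this extent.
#' @param planar_angle_deg angle used for the planar class, in [150, 170].
#' @param mix_fractions named fractions over classes used when
#'   `class_label == "mixed"`; must sum to 1.
#' @param anchor_residues if TRUE, a carbon pseudo-atom (its own residue) is
#'   placed 3.3 A from each cluster's central water so shell-based
#'   operations (shell assignment, hydration profiles) can run on the frame.
#' @param seed integer RNG seed; identical specs give identical frames.
#' @export
geometry_spec <- function(class_label, n_waters, jitter_deg = 0,
                          box_edge = 40, planar_angle_deg = 160,
                          mix_fractions = c(tetrahedral = 0.5,
                                            icosahedral = 0.5),
                          anchor_residues = FALSE, seed = 1L) {
  class_label <- match.arg(class_label,
                           c("tetrahedral", "icosahedral", "planar", "mixed"))
  if (n_waters < 1) stop("geometry_spec: n_waters must be >= 1")
  if (jitter_deg < 0) stop("geometry_spec: jitter_deg must be >= 0")
  if (planar_angle_deg < 150 || planar_angle_deg > 170)
    stop("geometry_spec: planar_angle_deg must lie in [150, 170]")
  if (class_label == "mixed") {
    if (is.null(names(mix_fractions)) ||
        !all(names(mix_fractions) %in%
             c("tetrahedral", "icosahedral", "planar")))
      stop("geometry_spec: mix_fractions must be named by class")
    if (any(mix_fractions < 0) || abs(sum(mix_fractions) - 1) > 1e-8)
      stop("geometry_spec: mix_fractions must be non-negative and sum to 1")
  }
  structure(list(class_label = class_label, n_waters = as.integer(n_waters),
                 jitter_deg = jitter_deg, box_edge = box_edge,
                 planar_angle_deg = planar_angle_deg,
                 mix_fractions = mix_fractions,
                 anchor_residues = anchor_residues, seed = as.integer(seed)),
            class = "geometry_spec")
}

.UNIT_SIZE <- c(tetrahedral = 5L, icosahedral = 13L, planar = 3L)
.OO_HB <- 2.8  # O-O hydrogen-bond distance used in constructed clusters (A)

# Unit neighbor directions for one cluster; rows are unit vectors.
.ico_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

# Build one water cluster centered at `center`. Returns a list with the atom
# rows of the unit and the local index of the central oxygen row.
.build_unit <- function(class, center, jitter_deg, planar_angle_deg) {
  jit <- function(d) {
    if (jitter_deg <= 0) return(d)
    ax <- .rotate_deg(.any_perp(d), d, stats::runif(1, 0, 360))
    .rotate_deg(d, ax, stats::rnorm(1, 0, jitter_deg))
  }
  if (class == "tetrahedral") {
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    dirs <- t(apply(dirs, 1, jit))
    opos <- sweep(dirs * .OO_HB, 2, center, `+`)
    waters <- vector("list", 5L)
    # central donates to neighbors 1 and 2; neighbors 3 and 4 donate back
    cen_donors <- list(.unitv(opos[1, ] - center), .unitv(opos[2, ] - center))
    waters[[1]] <- list(o = center, donors = cen_donors, avoid = list(),
                        fallback = c(0, 0, 1))
    for (i in 1:4) {
      o <- opos[i, ]
      if (i <= 2)
        waters[[i + 1]] <- list(o = o, donors = list(),
                                avoid = list(.unitv(center - o)),
                                fallback = .unitv(o - center))
      else
        waters[[i + 1]] <- list(o = o, donors = list(.unitv(center - o)),
                                avoid = list(), fallback = .unitv(o - center))
    }
  } else if (class == "icosahedral") {
    dirs <- .ico_vertices()
    # pick a triangular face: vertex 1 and two mutually adjacent neighbors
    adj <- function(i, j) abs(sum(dirs[i, ] * dirs[j, ]) - 1 / sqrt(5)) < 1e-6
    nb1 <- which(vapply(1:12, function(j) j != 1 && adj(1, j), logical(1)))
    face <- NULL
    for (a in nb1) for (b in nb1) if (a < b && adj(a, b)) {
      face <- c(1L, a, b); break
    }
    dirs <- t(apply(dirs, 1, jit))
    opos <- sweep(dirs * .OO_HB, 2, center, `+`)
    waters <- vector("list", 13L)
    cen_donors <- list(.unitv(opos[face[1], ] - center),
                       .unitv(opos[face[2], ] - center))
    waters[[1]] <- list(o = center, donors = cen_donors, avoid = list(),
                        fallback = c(0, 0, 1))
    for (i in 1:12) {
      o <- opos[i, ]
      near <- which(vapply(1:12, function(j)
        j != i && sqrt(sum((opos[j, ] - o)^2)) < 3.6, logical(1)))
      avoid <- c(list(.unitv(center - o)),
                 lapply(near, function(j) .unitv(opos[j, ] - o)))
      if (i == face[3])
        waters[[i + 1]] <- list(o = o, donors = list(.unitv(center - o)),
                                avoid = avoid[-1], fallback = .unitv(o - center))
      else
        waters[[i + 1]] <- list(o = o, donors = list(), avoid = avoid,
                                fallback = .unitv(o - center))
    }
  } else { # planar
    d1 <- c(1, 0, 0)
    d2 <- .rotate_deg(d1, c(0, 0, 1), planar_angle_deg)
    d1 <- jit(d1); d2 <- jit(d2)
    o1 <- center + .OO_HB * d1
    o2 <- center + .OO_HB * d2
    bis <- .unitv(.unitv(o1 - center) + .unitv(o2 - center))
    waters <- list(
      list(o = center, donors = list(),
           avoid = list(.unitv(o1 - center), .unitv(o2 - center)),
           fallback = -bis),
      list(o = o1, donors = list(.unitv(center - o1)), avoid = list(),
           fallback = .unitv(o1 - center)),
      list(o = o2, donors = list(.unitv(center - o2)), avoid = list(),
           fallback = .unitv(o2 - center)))
  }
  rows <- do.call(rbind, lapply(waters, function(w) {
    h <- .place_hydrogens(w$o, w$donors, w$avoid, w$fallback)
    data.frame(elety = c("OW", "HW1", "HW2"), elem = c("O", "H", "H"),
               x = c(w$o[1], h[, 1]), y = c(w$o[2], h[, 2]),
               z = c(w$o[3], h[, 3]))
  }))
  list(rows = rows, central_local = 1L)
}

#' Generate a synthetic water frame with prescribed 3BA geometry
#'
#' Builds water clusters whose hydrogen-bonded three-body angles at the
#' central oxygen fall exactly at the class angle before jitter:
#' 109.47 deg (tetrahedral), 63.43 deg (icosahedral adjacent vertices,
#' arccos(1/sqrt(5))), or the configured planar angle. Hydrogens follow a
#' rigid 3-site water geometry and are oriented so the geometric
#' hydrogen-bond criterion fires exactly for the intended partners.
#'
#' @param spec a [geometry_spec()].
#' @return an [md_frame()] of waters (plus anchor pseudo-atoms if
#'   requested), with attributes `centers` (data.frame: frame row of each
#'   central oxygen, its class label, and its cluster/residue id) and
#'   `spec`.
#' @export
gen_water_geometry <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  withr::with_seed(spec$seed, {
    budget <- spec$n_waters
    classes <- character(0)
    if (spec$class_label == "mixed") {
      frac <- spec$mix_fractions[spec$mix_fractions > 0]
      repeat {
        fits <- names(frac)[.UNIT_SIZE[names(frac)] <= budget]
        if (length(fits) == 0L) break
        cl <- sample(names(frac), 1L, prob = frac)
        if (!(cl %in% fits)) cl <- sample(fits, 1L,
                                          prob = frac[fits] / sum(frac[fits]))
        classes <- c(classes, cl)
        budget <- budget - .UNIT_SIZE[[cl]]
      }
    } else {
      us <- .UNIT_SIZE[[spec$class_label]]
      if (spec$n_waters < us)
        stop(sprintf("gen_water_geometry: class '%s' needs >= %d waters",
                     spec$class_label, us))
      classes <- rep(spec$class_label, spec$n_waters %/% us)
    }
    n_units <- length(classes)
    spacing <- 15
    per_row <- max(1L, floor(spec$box_edge / spacing) + 1L)
    all_rows <- vector("list", n_units)
    centers <- data.frame(o_row = integer(n_units), class = classes,
                          unit = seq_len(n_units))
    row_count <- 0L
    for (u in seq_len(n_units)) {
      i <- (u - 1L) %% per_row
      j <- ((u - 1L) %/% per_row) %% per_row
      k <- (u - 1L) %/% (per_row * per_row)
      cen <- c(i, j, k) * spacing
      unit <- .build_unit(classes[u], cen, spec$jitter_deg,
                          spec$planar_angle_deg)
      ur <- unit$rows
      ur$unit <- u
      centers$o_row[u] <- row_count + unit$central_local
      row_count <- row_count + nrow(ur)
      all_rows[[u]] <- ur
    }
    at <- do.call(rbind, all_rows)
    nw <- nrow(at) %/% 3L
    at$resid <- rep(seq_len(nw), each = 3L)
    at$resname <- "HOH"
    if (spec$anchor_residues) {
      anchors <- do.call(rbind, lapply(seq_len(n_units), function(u) {
        crow <- centers$o_row[u]
        cen <- as.numeric(at[crow, c("x", "y", "z")])
        # place the anchor opposite the first neighbor direction so it does
        # not collide with cluster atoms
        nb1 <- as.numeric(at[crow + 3L, c("x", "y", "z")])
        d <- .unitv(cen - nb1)
        p <- cen + 3.3 * d
        data.frame(elety = "CA", elem = "C", x = p[1], y = p[2], z = p[3],
                   unit = u, resid = nw + u, resname = "GLY")
      }))
      at <- rbind(at, anchors)
    }
    at$unit <- NULL
    fr <- md_frame(at, time_ps = 0)
    attr(fr, "centers") <- centers
    attr(fr, "spec") <- spec
    fr
  })
}

#' Specification for a toy shell-occupancy trajectory
#'
#' Pseudo-residue beads fixed in space with waters that enter and leave each
#' bead's hydration shell as a two-state telegraph process with exponential
#' dwell times. The analytical mean in-shell dwell equals `mean_dwell`,
#' which is what a first-passage residence-time analysis should recover.
#'
#' @param n_residues number of pseudo-residue beads.
#' @param n_frames number of frames.
#' @param dt frame spacing (ps).
#' @param mean_dwell mean in-shell dwell time (ps).
#' @param occupancy expected number of waters in each shell at any time;
#'   0 gives empty shells in every frame.
#' @param seed integer RNG seed.
#' @export
shell_dynamics_spec <- function(n_residues, n_frames, dt = 1,
                                mean_dwell = 50, occupancy = 1, seed = 1L) {
  if (mean_dwell <= 0) stop("shell_dynamics_spec: mean_dwell must be > 0")
  if (dt <= 0) stop("shell_dynamics_spec: dt must be > 0")
  if (occupancy < 0) stop("shell_dynamics_spec: occupancy must be >= 0")
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames), dt = dt,
                 mean_dwell = mean_dwell, occupancy = occupancy,
                 seed = as.integer(seed)),
            class = "shell_dynamics_spec")
}

#' Generate a toy telegraph-process hydration trajectory
#'
#' @param spec a [shell_dynamics_spec()].
#' @return an [md_trajectory()]; waters jump between an in-shell position
#'   (3 A from their bead) and a far position (30 A away) according to the
#'   telegraph process. Residue beads are 60 A apart so shells never share
#'   waters.
#' @export
gen_toy_trajectory <- function(spec) {
  stopifnot(inherits(spec, "shell_dynamics_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$n_residues; nf <- spec$n_frames; dt <- spec$dt
    times <- (seq_len(nf) - 1L) * dt
    n_slots <- if (spec$occupancy == 0) 0L else
      max(1L, ceiling(2 * spec$occupancy))
    p_in <- if (n_slots > 0L) spec$occupancy / n_slots else 0
    if (p_in >= 1) { n_slots <- ceiling(spec$occupancy) + 1L
                     p_in <- spec$occupancy / n_slots }
    dwell_in <- spec$mean_dwell
    dwell_out <- if (p_in > 0) dwell_in * (1 - p_in) / p_in else Inf
    # topology: one bead per residue + water slots
    beads <- data.frame(elety = "CA", elem = "C",
                        resid = seq_len(nr), resname = "GLY",
                        x = 60 * (seq_len(nr) - 1L), y = 0, z = 0)
    waters <- NULL
    occ <- NULL  # matrix n_waters x n_frames
    if (n_slots > 0L) {
      wlist <- list(); olist <- list(); wid <- 0L
      for (r in seq_len(nr)) for (s in seq_len(n_slots)) {
        wid <- wid + 1L
        state <- stats::runif(1) < p_in
        o <- logical(nf); t <- 0; Tend <- nf * dt
        while (t < Tend) {
          dur <- stats::rexp(1, 1 / (if (state) dwell_in else dwell_out))
          if (state) o[times >= t & times < t + dur] <- TRUE
          t <- t + dur; state <- !state
        }
        olist[[wid]] <- o
        wlist[[wid]] <- data.frame(residue = r, slot = s)
      }
      occ <- do.call(rbind, olist)
      wmeta <- do.call(rbind, wlist)
      waters <- do.call(rbind, lapply(seq_len(nrow(wmeta)), function(i) {
        data.frame(elety = c("OW", "HW1", "HW2"), elem = c("O", "H", "H"),
                   resid = nr + i, resname = "HOH",
                   x = 0, y = 0, z = 0, residue = wmeta$residue[i],
                   slot = wmeta$slot[i])
      }))
    }
    topo_df <- if (is.null(waters)) beads else
      rbind(cbind(beads, residue = NA, slot = NA), waters)
    res_of <- topo_df$residue; slot_of <- topo_df$slot
    topo_df$residue <- NULL; topo_df$slot <- NULL
    na <- nrow(topo_df)
    coords <- array(0, dim = c(na, 3L, nf))
    coords[seq_len(nr), 1, ] <- 60 * (seq_len(nr) - 1L)  # beads fixed
    if (n_slots > 0L) {
      hoff <- rbind(c(0, 0, 0), c(0.59, 0.76, 0), c(0.59, -0.76, 0))
      for (w in seq_len(nrow(wmeta))) {
        rows <- nr + 3L * (w - 1L) + 1:3
        r <- wmeta$residue[w]; s <- wmeta$slot[w]
        ox <- 60 * (r - 1L) + ifelse(occ[w, ], 3.0, 30.0)
        oy <- 0.4 * (s - 1L)
        for (q in 1:3) {
          coords[rows[q], 1, ] <- ox + hoff[q, 1]
          coords[rows[q], 2, ] <- oy + hoff[q, 2]
          coords[rows[q], 3, ] <- hoff[q, 3]
        }
      }
    }
    topo_df$x <- coords[, 1, 1]
    topo_df$y <- coords[, 2, 1]
    topo_df$z <- coords[, 3, 1]
    topo <- md_frame(topo_df, time_ps = 0, validate = FALSE)
    traj <- md_trajectory(topo, coords, times)
    attr(traj, "spec") <- spec
    attr(traj, "occupancy_truth") <- occ
    traj
  })
}

#' Specification for a synthetic pressure--chemical-shift table
#'
#' @param n_residues number of residues.
#' @param pressures strictly increasing pressures (bar), at least 3 points.
#' @param frac_nonlinear fraction of residues given a nonzero quadratic
#'   coefficient (in all three nuclei).
#' @param coeff_scales named triple `c(a=, b=, c=)`: scales of the
#'   intercept (ppm), linear (ppm/bar) and quadratic (ppm/bar^2) terms.
#' @param noise_ppm SD of Gaussian shift noise (ppm).
#' @param seed integer RNG seed.
#' @export
shift_table_spec <- function(n_residues = 50,
                             pressures = seq(20, 2500, length.out = 11),
                             frac_nonlinear = 0.1,
                             coeff_scales = c(a = 8, b = 2e-4, c = 4e-8),
                             noise_ppm = 0.003, seed = 1L) {
  if (length(pressures) < 3 || any(diff(pressures) <= 0))
    stop("shift_table_spec: pressures must be strictly increasing, >= 3 points")
  if (frac_nonlinear < 0 || frac_nonlinear > 1)
    stop("shift_table_spec: frac_nonlinear must lie in [0, 1]")
  if (noise_ppm < 0) stop("shift_table_spec: noise_ppm must be >= 0")
  structure(list(n_residues = as.integer(n_residues),
                 pressures = as.numeric(pressures),
                 frac_nonlinear = frac_nonlinear,
                 coeff_scales = coeff_scales, noise_ppm = noise_ppm,
                 seed = as.integer(seed)),
            class = "shift_table_spec")
}

#' Generate a synthetic pressure-shift table
#'
#' Per residue and nucleus (H, N, CO), shifts follow
#' `delta(p) = a + b p + c p^2` with `c = 0` for the linear residues, plus
#' Gaussian noise. Ground-truth coefficients are kept as the `truth`
#' attribute for recovery tests.
#'
#' @param spec a [shift_table_spec()].
#' @return data.frame with columns `residue`, `nucleus`, `pressure_bar`,
#'   `shift_ppm`; attribute `truth` holds `residue`, `nucleus`, `a`, `b`,
#'   `c`, `nonlinear`.
#' @export
gen_shift_table <- function(spec) {
  stopifnot(inherits(spec, "shift_table_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$n_residues
    nuclei <- c("H", "N", "CO")
    n_nl <- round(spec$frac_nonlinear * nr)
    nl_res <- if (n_nl > 0) sort(sample(seq_len(nr), n_nl)) else integer(0)
    sc <- spec$coeff_scales
    truth <- do.call(rbind, lapply(nuclei, function(nuc) {
      data.frame(residue = seq_len(nr), nucleus = nuc,
                 a = stats::runif(nr, 0.5, 1.5) * sc[["a"]],
                 b = stats::rnorm(nr, 0, sc[["b"]]),
                 c = ifelse(seq_len(nr) %in% nl_res,
                            sample(c(-1, 1), nr, replace = TRUE) *
                              stats::runif(nr, 0.5, 1.5) * sc[["c"]],
                            0),
                 nonlinear = seq_len(nr) %in% nl_res)
    }))
    tab <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      p <- spec$pressures
      mu <- truth$a[i] + truth$b[i] * p + truth$c[i] * p^2
      data.frame(residue = truth$residue[i], nucleus = truth$nucleus[i],
                 pressure_bar = p,
                 shift_ppm = mu + stats::rnorm(length(p), 0, spec$noise_ppm))
    }))
    attr(tab, "truth") <- truth
    attr(tab, "spec") <- spec
    tab
  })
}

#' Specification for a synthetic inversion-recovery curve
#'
#' @param components data.frame with columns `T1_ms`, `amplitude`, `label`
#'   (e.g. wrap / bulk / bound).
#' @param delays inversion-recovery delays (ms), non-negative.
#' @param flip_deg read-pulse flip angle theta (degrees, in (0, 180]).
#' @param tr_ms repetition time (ms); `Inf` gives the single-shot limit.
#' @param inv_eff inversion efficiency f in (0.5, 1].
#' @param noise_frac SD of Gaussian noise relative to the summed component
#'   amplitudes.
#' @param seed integer RNG seed.
#' @export
relax_spec <- function(components, delays, flip_deg = 90, tr_ms = Inf,
                       inv_eff = 1, noise_frac = 0, seed = 1L) {
  components <- as.data.frame(components)
  if (!all(c("T1_ms", "amplitude", "label") %in% names(components)))
    stop("relax_spec: components needs columns T1_ms, amplitude, label")
  if (any(components$T1_ms <= 0)) stop("relax_spec: every T1 must be > 0")
  if (any(delays < 0)) stop("relax_spec: delays must be non-negative")
  if (inv_eff <= 0.5 || inv_eff > 1)
    stop("relax_spec: inv_eff must lie in (0.5, 1]")
  if (flip_deg <= 0 || flip_deg > 180)
    stop("relax_spec: flip_deg must lie in (0, 180]")
  structure(list(components = components, delays = as.numeric(delays),
                 flip_deg = flip_deg, tr_ms = tr_ms, inv_eff = inv_eff,
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "relax_spec")
}

#' Generate a multi-component inversion-recovery curve
#'
#' Sums, over components, the steady-state amplitude of the bulk-suppression
#' sequence (inversion with efficiency f, delay tau, read pulse theta,
#' recovery to TR) evaluated by [steady_state_amplitude()] at every delay,
#' plus optional noise.
#'
#' @param spec a [relax_spec()].
#' @return a [recovery_curve()] (time in ms) with attributes `truth` (the
#'   component table) and `settings`.
#' @export
gen_inversion_recovery <- function(spec) {
  stopifnot(inherits(spec, "relax_spec"))
  withr::with_seed(spec$seed, {
    clean <- vapply(spec$delays, function(tau) {
      st <- suppression_settings(tau_zc = tau, flip_deg = spec$flip_deg,
                                 tr_ms = spec$tr_ms, inv_eff = spec$inv_eff)
      sum(spec$components$amplitude *
            vapply(spec$components$T1_ms, steady_state_amplitude,
                   numeric(1), settings = st))
    }, numeric(1))
    sdn <- spec$noise_frac * sum(spec$components$amplitude)
    amp <- clean + if (sdn > 0) stats::rnorm(length(clean), 0, sdn) else 0
    cv <- recovery_curve(spec$delays, amp, "ms")
    attr(cv, "truth") <- spec$components
    attr(cv, "settings") <- list(flip_deg = spec$flip_deg,
                                 tr_ms = spec$tr_ms, inv_eff = spec$inv_eff)
    cv
  })
}

#' Specification for a synthetic DEER dipolar trace
#'
#' @param gauss_params matrix or data.frame with two rows and columns
#'   `mean_nm`, `width_nm`, `weight`; weights must be non-negative and sum
#'   to 1.
#' @param t_max_us trace length (microseconds).
#' @param n_t number of time points (from 0 to `t_max_us`).
#' @param mod_depth modulation depth lambda in [0, 1].
#' @param bg_rate background decay rate k (per microsecond).
#' @param noise_sd absolute SD of Gaussian noise on the normalized signal.
#' @param r_grid distance grid (nm) for rendering P(r).
#' @param seed integer RNG seed.
#' @export
deer_spec <- function(gauss_params, t_max_us = 3, n_t = 200, mod_depth = 0.3,
                      bg_rate = 0.05, noise_sd = 0,
                      r_grid = seq(1.5, 8, by = 0.05), seed = 1L) {
  gp <- as.data.frame(gauss_params)
  if (!all(c("mean_nm", "width_nm", "weight") %in% names(gp)) ||
      nrow(gp) != 2L)
    stop("deer_spec: gauss_params needs two rows of mean_nm, width_nm, weight")
  if (any(gp$weight < 0) || abs(sum(gp$weight) - 1) > 1e-8)
    stop("deer_spec: weights not normalized (must be >= 0 and sum to 1)")
  if (any(gp$mean_nm <= 0) || any(gp$width_nm <= 0))
    stop("deer_spec: means and widths must be > 0")
  if (mod_depth < 0 || mod_depth > 1)
    stop("deer_spec: mod_depth must lie in [0, 1]")
  structure(list(gauss_params = gp, t_max_us = t_max_us,
                 n_t = as.integer(n_t), mod_depth = mod_depth,
                 bg_rate = bg_rate, noise_sd = noise_sd,
                 r_grid = r_grid, seed = as.integer(seed)),
            class = "deer_spec")
}

#' Generate a synthetic DEER trace from a two-Gaussian distance model
#'
#' Renders P(r) through the dipolar kernel with modulation depth and
#' exponential background, then adds noise. Truth parameters are retained.
#'
#' @param spec a [deer_spec()].
#' @return a `dipolar_trace` (see [simulate_trace()]) with attribute
#'   `truth`.
#' @export
gen_deer_trace <- function(spec) {
  stopifnot(inherits(spec, "deer_spec"))
  withr::with_seed(spec$seed, {
    t_us <- seq(0, spec$t_max_us, length.out = spec$n_t)
    dist <- distance_distribution(spec$gauss_params$mean_nm,
                                  spec$gauss_params$width_nm,
                                  spec$gauss_params$weight,
                                  r_grid = spec$r_grid)
    tr <- simulate_trace(dist, mod_depth = spec$mod_depth,
                         bg_rate = spec$bg_rate, t_us = t_us)
    if (spec$noise_sd > 0)
      tr$signal <- tr$signal + stats::rnorm(nrow(tr), 0, spec$noise_sd)
    attr(tr, "truth") <- list(gauss_params = spec$gauss_params,
                              mod_depth = spec$mod_depth,
                              bg_rate = spec$bg_rate)
    tr
  })
}

#' Generate a single-exponential decay/recovery series
#'
#' `a_inf + (a0 - a_inf) * exp(-t / tau)` plus Gaussian noise.
#'
#' @param tau time constant (same unit as `times`).
#' @param a0 value at t = 0.
#' @param a_inf plateau value.
#' @param times sampling times.
#' @param noise_sd absolute noise SD.
#' @param seed integer RNG seed.
#' @param time_unit unit label for the curve ("s", "min", or "ms").
#' @return a [recovery_curve()] with attribute `truth`.
#' @export
gen_decay_series <- function(tau, a0, a_inf, times, noise_sd = 0, seed = 1L,
                             time_unit = "s") {
  if (tau <= 0) stop("gen_decay_series: tau must be > 0")
  withr::with_seed(as.integer(seed), {
    y <- a_inf + (a0 - a_inf) * exp(-times / tau)
    if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
    cv <- recovery_curve(times, y, time_unit)
    attr(cv, "truth") <- list(tau = tau, a0 = a0, a_inf = a_inf)
    cv
  })
}
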