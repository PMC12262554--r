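# Independent oracles and fixture builders. Everything here is written
# against the definitions, not against the package implementation, so
# module outputs can be checked route-independently.

# Build a frame from a list of waters; each water is list(o=, h1=, h2=).
make_water_frame <- function(waters, extra_atoms = NULL) {
  rows <- do.call(rbind, lapply(seq_along(waters), function(i) {
    w <- waters[[i]]
    data.frame(elety = c("OW", "HW1", "HW2"), elem = c("O", "H", "H"),
               resid = i, resname = "HOH",
               x = c(w$o[1], w$h1[1], w$h2[1]),
               y = c(w$o[2], w$h1[2], w$h2[2]),
               z = c(w$o[3], w$h1[3], w$h2[3]))
  }))
  if (!is.null(extra_atoms)) rows <- rbind(rows, extra_atoms)
  md_frame(rows)
}

# Water with both hydrogens pointing along given directions (unit vectors).
simple_water <- function(o, d1 = c(1, 0, 0), d2 = c(0, 1, 0)) {
  list(o = o, h1 = o + 0.9572 * d1 / sqrt(sum(d1^2)),
       h2 = o + 0.9572 * d2 / sqrt(sum(d2^2)))
}

# Brute-force hydrogen-bond pair oracle: all O pairs, direct angle math.
oracle_hbond_pairs <- function(frame, max_oo = 3.5, max_dev = 30) {
  o_rows <- which(frame$is_water_o)
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  hs <- which(frame$is_water_h)
  pairs <- NULL
  ang <- function(u, v) acos(min(1, max(-1, sum(u * v) /
                                          sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  for (i in seq_along(o_rows)) for (j in seq_along(o_rows)) {
    if (i >= j) next
    oi <- xyz[o_rows[i], ]; oj <- xyz[o_rows[j], ]
    if (sqrt(sum((oi - oj)^2)) > max_oo) next
    bonded <- FALSE
    for (k in hs[frame$resid[hs] == frame$resid[o_rows[i]]])
      if (ang(xyz[k, ] - oi, oj - oi) <= max_dev) bonded <- TRUE
    for (k in hs[frame$resid[hs] == frame$resid[o_rows[j]]])
      if (ang(xyz[k, ] - oj, oi - oj) <= max_dev) bonded <- TRUE
    if (bonded) pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

# Adjacent-vertex central angle of a regular icosahedron, from raw
# golden-ratio vertex coordinates (independent geometry route).
oracle_icosahedron_adjacent_angle <- function() {
  phi <- (1 + sqrt(5)) / 2
  a <- c(0, 1, phi); b <- c(0, -1, phi)   # two adjacent vertices
  acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
}

# Dense lat/long-grid SASA oracle for a set of spheres (centers X, inflated
# radii R): area of sphere i outside all others.
oracle_sasa_grid <- function(X, R, n_lat = 316) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    th <- (seq_len(n_lat) - 0.5) / n_lat * pi      # polar
    nph <- pmax(1L, round(2 * n_lat * sin(th)))
    acc_area <- 0
    for (a in seq_along(th)) {
      ph <- (seq_len(nph[a]) - 0.5) / nph[a] * 2 * pi
      pts <- cbind(R[i] * sin(th[a]) * cos(ph), R[i] * sin(th[a]) * sin(ph),
                   rep(R[i] * cos(th[a]), nph[a]))
      pts <- sweep(pts, 2, X[i, ], `+`)
      keep <- rep(TRUE, nrow(pts))
      for (j in seq_len(nrow(X))) {
        if (j == i) next
        d2 <- (pts[, 1] - X[j, 1])^2 + (pts[, 2] - X[j, 2])^2 +
          (pts[, 3] - X[j, 3])^2
        keep <- keep & d2 > R[j]^2
      }
      # weight of this latitude band
      band <- 2 * pi * R[i]^2 * (cos(th[a] - pi / (2 * n_lat)) -
                                   cos(th[a] + pi / (2 * n_lat)))
      acc_area <- acc_area + band * sum(keep) / nph[a]
    }
    total <- total + acc_area
  }
  total
}

# Exhaustive single-split least-squares oracle.
oracle_best_split <- function(x, min_size = 2L) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  ks <- seq.int(min_size, n - min_size)
  costs <- vapply(ks, function(k) sse(x[1:k]) + sse(x[(k + 1):n]), numeric(1))
  ks[which.min(costs)]
}

# Quaternion (Horn) superposition RMSD oracle, in nm.
oracle_rmsd_quaternion <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(B, A)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[3, 1] + M[1, 3]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0)) / 10
}

# Iterate the suppression sequence cycle by cycle to convergence.
oracle_steady_state_iter <- function(T1, tau_zc, flip_deg, tr_ms, f,
                                     n_cycles = 200) {
  th <- flip_deg * pi / 180
  Mz <- 1
  mzm <- NA
  for (i in seq_len(n_cycles)) {
    Mz <- (1 - 2 * f) * Mz                                   # inversion
    Mz <- 1 + (Mz - 1) * exp(-tau_zc / T1)                   # delay tau_zc
    mzm <- Mz
    Mz <- Mz * cos(th)                                       # read pulse
    trec <- tr_ms - tau_zc
    Mz <- if (is.infinite(trec)) 1 else 1 + (Mz - 1) * exp(-trec / T1)
  }
  sin(th) * mzm
}

# Dense-trapezoid DEER kernel oracle.
oracle_kernel_trap <- function(t_us, r_nm, n = 2^18 + 1) {
  u <- seq(0, 1, length.out = n)
  w <- rep(1, n); w[1] <- w[n] <- 0.5
  w <- w / (n - 1)
  D <- 52.04102  # MHz nm^3, frozen from independent constant computation
  vapply(r_nm, function(r) {
    wd <- 2 * pi * D / r^3
    vapply(t_us, function(t) sum(w * cos((1 - 3 * u^2) * wd * t)),
           numeric(1))
  }, numeric(length(t_us)))
}

# Apply a rigid-body transform to a frame.
rigid_transform <- function(frame, axis, angle_deg, shift) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  Kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  frame$x <- xyz[, 1] + shift[1]
  frame$y <- xyz[, 2] + shift[2]
  frame$z <- xyz[, 3] + shift[3]
  frame
}
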