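single_atom_frame <- function(elem = "S", x = 0) {
  md_frame(data.frame(elety = elem, elem = elem, resid = 1L, resname = "ALA",
                      x = x, y = 0, z = 0), validate = FALSE)
}

test_that("single-sphere SASA equals the closed-form sphere area", {
  # sulfur: r_vdw 1.80 + probe 1.4 -> 4 pi 3.2^2
  fr <- single_atom_frame("S")
  expect_equal(sasa(fr, probe = 1.4)$total, 4 * pi * 3.2^2, tolerance = 1e-9)
  # a 1.9 A radius atom (unknown element, default radius) with probe 1.4
  fr2 <- md_frame(data.frame(elety = "X", elem = "XX", resid = 1L,
                             resname = "ALA", x = 0, y = 0, z = 0),
                  validate = FALSE)
  expect_warning(out <- sasa(fr2, probe = 1.4, default_radius = 1.9),
                 "unknown element")
  expect_equal(out$total, 4 * pi * 3.3^2, tolerance = 1e-9)
})

test_that("well-separated atoms contribute independent areas", {
  fr <- md_frame(data.frame(elety = c("C", "C"), elem = c("C", "C"),
                            resid = 1:2, resname = "ALA",
                            x = c(0, 100), y = 0, z = 0), validate = FALSE)
  expect_equal(sasa(fr)$total, 2 * 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("overlapping spheres match a dense latitude-grid oracle within 1%", {
  fr <- md_frame(data.frame(elety = c("C", "N"), elem = c("C", "N"),
                            resid = 1:2, resname = "ALA",
                            x = c(0, 2.2), y = 0, z = 0), validate = FALSE)
  got <- sasa(fr, probe = 1.4, n_points = 960)$total
  want <- oracle_sasa_grid(X = rbind(c(0, 0, 0), c(2.2, 0, 0)),
                           R = c(1.70 + 1.4, 1.55 + 1.4))
  expect_lt(abs(got - want) / want, 0.01)
})

test_that("SASA converges: doubling the point count moves a buried pair by < 0.5%", {
  fr <- md_frame(data.frame(elety = c("C", "O"), elem = c("C", "O"),
                            resid = 1:2, resname = "ALA",
                            x = c(0, 1.8), y = 0, z = 0), validate = FALSE)
  a1 <- sasa(fr, n_points = 960)$total
  a2 <- sasa(fr, n_points = 1920)$total
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("change-point detection finds steps and stays silent on constants", {
  expect_identical(changepoints(rep(5, 300)), integer(0))
  for (pen in c(0.001, 1, 100))
    expect_identical(changepoints(rep(5, 300), penalty = pen), integer(0))
  x <- c(rep(0, 100), rep(10, 100))
  expect_identical(changepoints(x), 100L)
})

test_that("a noisy one-jump series splits where the exhaustive oracle splits", {
  withr::with_seed(21, {
    x <- c(rnorm(80, 0, 1), rnorm(120, 4, 1))
  })
  bp <- changepoints(x)
  expect_length(bp, 1)
  expect_identical(bp, oracle_best_split(x))
})

test_that("pairwise RMSD is zero for identical and rigidly rotated frames", {
  fr <- gen_water_geometry(geometry_spec("tetrahedral", 15,
                                         anchor_residues = TRUE, seed = 6))
  expect_equal(pairwise_rmsd(fr, fr), 0, tolerance = 1e-12)
  fr2 <- rigid_transform(fr, axis = c(0, 1, 1), angle_deg = 113,
                         shift = c(4, -2, 9))
  expect_lt(pairwise_rmsd(fr, fr2, fit = TRUE), 1e-9)
  expect_gt(pairwise_rmsd(fr, fr2, fit = FALSE), 0.01)
})

test_that("Kabsch RMSD matches the quaternion oracle on random frames", {
  withr::with_seed(31, {
    n <- 15
    A <- matrix(rnorm(n * 3, sd = 3), n, 3)
    B <- A + matrix(rnorm(n * 3, sd = 0.5), n, 3)
  })
  mk <- function(X) md_frame(data.frame(elety = "CA", elem = "C",
                                        resid = seq_len(nrow(X)),
                                        resname = "GLY", x = X[, 1],
                                        y = X[, 2], z = X[, 3]),
                             validate = FALSE)
  expect_equal(pairwise_rmsd(mk(A), mk(B), fit = TRUE),
               oracle_rmsd_quaternion(A, B), tolerance = 1e-10)
})

test_that("Daura clustering partitions frames and resolves constructed groups", {
  mk <- function(X) md_frame(data.frame(elety = "CA", elem = "C",
                                        resid = seq_len(nrow(X)),
                                        resname = "GLY", x = X[, 1],
                                        y = X[, 2], z = X[, 3]),
                             validate = FALSE)
  base <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 0, 0, 3, 3, 3, 0), 5, 3,
                 byrow = TRUE)
  # three groups: intra-group jitter << cutoff << inter-group displacement
  withr::with_seed(8, {
    frames <- list()
    truth <- integer(0)
    for (g in 1:3) for (m in 1:(g + 1)) {
      # groups differ in overall scale (not removable by superposition);
      # intra-group jitter 0.05 A << cutoff 0.2 nm << inter-group ~3 A
      X <- base * c(1, 2.5, 4)[g] + matrix(rnorm(15, 0, 0.05), 5, 3)
      frames <- c(frames, list(mk(X)))
      truth <- c(truth, g)
    }
  })
  cl <- daura_cluster(frames, cutoff = 0.2)
  expect_length(cl$centers, 3)
  got <- integer(length(frames))
  for (k in seq_along(cl$members)) got[cl$members[[k]]] <- k
  expect_equal(length(unique(paste(truth, got))), 3)  # exact refinement
  # partition: disjoint, covering, centers are members
  all_m <- unlist(cl$members)
  expect_equal(sort(all_m), seq_along(frames))
  for (k in seq_along(cl$centers))
    expect_true(cl$centers[k] %in% cl$members[[k]])
  # all identical frames -> one cluster; cutoff 0 -> singletons
  same <- rep(frames[1], 4)
  expect_length(daura_cluster(same, cutoff = 0.2)$centers, 1)
  expect_length(daura_cluster(frames, cutoff = 0)$centers, length(frames))
})

test_that("Daura clustering is invariant to frame order up to relabeling", {
  mk <- function(X) md_frame(data.frame(elety = "CA", elem = "C",
                                        resid = seq_len(nrow(X)),
                                        resname = "GLY", x = X[, 1],
                                        y = X[, 2], z = X[, 3]),
                             validate = FALSE)
  withr::with_seed(17, {
    frames <- lapply(1:8, function(i)
      mk(matrix(rnorm(15, sd = 2), 5, 3)))
  })
  cl1 <- daura_cluster(frames, cutoff = 0.35)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  cl2 <- daura_cluster(frames[perm], cutoff = 0.35)
  sets1 <- lapply(cl1$members, sort)
  sets2 <- lapply(cl2$members, function(m) sort(perm[m]))
  expect_setequal(lapply(sets1, paste, collapse = ","),
                  lapply(sets2, paste, collapse = ","))
})

test_that("residue displacement is zero under identity and pure translation", {
  fr <- gen_water_geometry(geometry_spec("tetrahedral", 20,
                                         anchor_residues = TRUE, seed = 9))
  d0 <- residue_displacement(fr, fr)
  expect_true(all(d0$displacement_A < 1e-12))
  shifted <- rigid_transform(fr, axis = c(1, 0, 0), angle_deg = 0,
                             shift = c(10, -4, 2))
  d1 <- residue_displacement(shifted, fr)
  expect_true(all(d1$displacement_A < 1e-9))
})

test_that("moving one residue registers only at that residue", {
  # residue 2 is a single atom moved 5 A; the other residues carry 30 atoms
  # each, so the center-of-gravity shift (5/91 A) is negligible against the
  # checked tolerance
  withr::with_seed(12, {
    rows <- do.call(rbind, lapply(c(1, 3, 4), function(r)
      data.frame(elety = "CA", elem = "C", resid = r, resname = "GLY",
                 x = 10 * r + rnorm(30), y = rnorm(30), z = rnorm(30))))
  })
  rows <- rbind(rows, data.frame(elety = "CA", elem = "C", resid = 2,
                                 resname = "GLY", x = 20, y = 15, z = 0))
  X <- md_frame(rows, validate = FALSE)
  rows2 <- rows
  rows2$x[rows2$resid == 2] <- rows2$x[rows2$resid == 2] + 5
  Y <- md_frame(rows2, validate = FALSE)
  d <- residue_displacement(Y, X)
  expect_equal(d$displacement_A[d$residue == 2], 5, tolerance = 0.03)
  expect_true(all(d$displacement_A[d$residue != 2] < 0.1))
})
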