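test_that("hydrogen-bond detection follows the geometric criterion", {
  # donor H on the O-O axis at 2.8 A: bonded
  w1 <- simple_water(c(0, 0, 0), d1 = c(1, 0, 0), d2 = c(0, 1, 0))
  w2 <- simple_water(c(2.8, 0, 0), d1 = c(1, 0, 0), d2 = c(0, 0, 1))
  fr <- make_water_frame(list(w1, w2))
  nb <- find_hbond_neighbors(fr)
  expect_identical(nb[[1]], 2L)
  expect_identical(nb[[2]], 1L)
  # beyond the distance cutoff: not bonded
  w3 <- simple_water(c(4.0, 0, 0))
  fr2 <- make_water_frame(list(w1, w3))
  nb2 <- find_hbond_neighbors(fr2)
  expect_length(nb2[[1]], 0)
  # within distance but no donor within the angular tolerance
  w4 <- simple_water(c(0, 0, 0), d1 = c(0, 1, 0), d2 = c(0, -1, 0))
  w5 <- simple_water(c(2.8, 0, 0), d1 = c(0, 1, 0), d2 = c(0, 0, 1))
  nb3 <- find_hbond_neighbors(make_water_frame(list(w4, w5)))
  expect_length(nb3[[1]], 0)
})

test_that("neighbor lists match a brute-force all-pairs oracle on random waters", {
  withr::with_seed(42, {
    waters <- lapply(1:100, function(i) {
      o <- runif(3, 0, 18)
      d1 <- rnorm(3); d2 <- rnorm(3)
      simple_water(o, d1, d2)
    })
  })
  fr <- make_water_frame(waters)
  nb <- find_hbond_neighbors(fr)
  got <- do.call(rbind, lapply(seq_along(nb), function(i)
    if (length(nb[[i]]) > 0)
      cbind(pmin(i, nb[[i]]), pmax(i, nb[[i]]))))
  got <- unique(got[order(got[, 1], got[, 2]), , drop = FALSE])
  want <- oracle_hbond_pairs(fr)
  expect_gt(nrow(want), 10)  # the fixture actually exercises the criterion
  expect_equal(got, want, ignore_attr = TRUE)
  # symmetry and irreflexivity
  for (i in seq_along(nb)) {
    expect_false(i %in% nb[[i]])
    for (j in nb[[i]]) expect_true(i %in% nb[[j]])
  }
})

test_that("three-body angles are the central-oxygen angles of neighbor pairs", {
  w0 <- simple_water(c(0, 0, 0), d1 = c(1, 0, 0), d2 = c(0, 1, 0))
  wx <- simple_water(c(2.8, 0, 0), d1 = c(0, 0, 1), d2 = c(0, 1, 0))
  wy <- simple_water(c(0, 2.8, 0), d1 = c(0, 0, 1), d2 = c(1, 0, 0))
  fr <- make_water_frame(list(w0, wx, wy))
  ang <- three_body_angles(fr, find_hbond_neighbors(fr))
  expect_equal(ang$angle_deg[ang$water == 1], 90, tolerance = 1e-9)
})

test_that("angle classification partitions angles into disjoint windows", {
  a <- data.frame(angle_deg = c(109.5, 60, 160, 85, 119.9, 50, 170, 0, 180))
  cls <- classify_angles(a)
  asg <- attr(cls, "assignment")
  expect_equal(as.character(asg[1:4]),
               c("wrap", "icosahedral", "bound", "unclassified"))
  expect_equal(sum(cls$count), nrow(a))      # partition: counts sum to total
  expect_equal(sum(cls$fraction), 1)
  expect_error(class_windows(wrap = c(100, 160)), "disjoint")
})

test_that("shell assignment matches a direct distance oracle and is monotone in cutoff", {
  bead <- data.frame(elety = "CA", elem = "C", resid = 99L, resname = "ALA",
                     x = 0, y = 0, z = 0)
  withr::with_seed(7, {
    waters <- lapply(1:40, function(i) simple_water(runif(3, -8, 8)))
  })
  fr <- make_water_frame(waters, extra_atoms = bead)
  o_rows <- which(fr$is_water_o)
  d <- sqrt(fr$x[o_rows]^2 + fr$y[o_rows]^2 + fr$z[o_rows]^2)
  for (cutoff in c(3, 4.5, 6)) {
    sh <- shell_assign(fr, cutoff)
    expect_setequal(sh[["99"]], o_rows[d <= cutoff])
  }
  counts <- vapply(c(2, 3, 4.5, 6, 8), function(cc)
    length(shell_assign(fr, cc)[["99"]]), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("angles, shells and residence tables are rigid-body invariant", {
  fr <- gen_water_geometry(geometry_spec("mixed", 70, jitter_deg = 3,
                                         anchor_residues = TRUE, seed = 11))
  ang1 <- three_body_angles(fr, find_hbond_neighbors(fr))
  sh1 <- shell_assign(fr, 4.5)
  fr2 <- rigid_transform(fr, axis = c(1, 2, 3), angle_deg = 77,
                         shift = c(-5, 12, 3))
  ang2 <- three_body_angles(fr2, find_hbond_neighbors(fr2))
  sh2 <- shell_assign(fr2, 4.5)
  expect_equal(ang1$angle_deg, ang2$angle_deg, tolerance = 1e-9)
  expect_identical(sh1, sh2)
})

test_that("pure-class shells give class fractions exactly {1, 0, 0}", {
  for (cls in c("tetrahedral", "icosahedral")) {
    fr <- gen_water_geometry(geometry_spec(cls, 26, jitter_deg = 0,
                                           anchor_residues = TRUE, seed = 2))
    pr <- hydration_profile(fr)
    col <- if (cls == "tetrahedral") "frac_wrap" else "frac_icosahedral"
    expect_true(all(pr[[col]][!pr$empty] == 1))
    others <- setdiff(c("frac_wrap", "frac_icosahedral", "frac_bound"), col)
    for (oc in others) expect_true(all(pr[[oc]] == 0))
  }
})

test_that("a residue with an empty shell is reported with zero fractions and a flag", {
  far_bead <- data.frame(elety = "CA", elem = "C", resid = 500L,
                         resname = "ALA", x = 500, y = 500, z = 500)
  fr <- gen_water_geometry(geometry_spec("tetrahedral", 10,
                                         anchor_residues = TRUE, seed = 3))
  fr2 <- md_frame(rbind(as.data.frame(fr)[, c("elety", "elem", "resid",
                                              "resname", "x", "y", "z")],
                        far_bead))
  pr <- hydration_profile(fr2)
  row <- pr[pr$residue == 500, ]
  expect_true(row$empty)
  expect_equal(row$shell_count, 0)
  expect_equal(row$frac_wrap + row$frac_icosahedral + row$frac_bound +
                 row$frac_unclassified, 0)
})

test_that("first-passage residence excludes re-entries and unterminated visits", {
  topo <- data.frame(elety = c("CA", "OW", "HW1", "HW2"),
                     elem = c("C", "O", "H", "H"), resid = c(1L, 2L, 2L, 2L),
                     resname = c("GLY", "HOH", "HOH", "HOH"),
                     x = 0, y = 0, z = 0)
  build <- function(ox) {
    nf <- length(ox)
    co <- array(0, dim = c(4, 3, nf))
    co[2, 1, ] <- ox
    co[3, 1, ] <- ox + 0.6; co[4, 1, ] <- ox - 0.6
    co[3, 2, ] <- 0.75; co[4, 2, ] <- -0.75
    md_trajectory(md_frame(topo, validate = FALSE), co, seq_len(nf) - 1)
  }
  # in shell for 10 frames (dt 1 ps), then exits -> 10 ps
  rt <- residence_times(build(c(30, rep(3, 10), rep(30, 4))), 4.5)
  expect_equal(rt$mean_residence_ps, 10)
  expect_equal(rt$n_visits, 1L)
  # re-enters for a long second visit -> still 10 ps
  rt2 <- residence_times(build(c(30, rep(3, 10), 30, rep(3, 50), rep(30, 3))),
                         4.5)
  expect_equal(rt2$mean_residence_ps, 10)
  expect_equal(rt2$n_visits, 1L)
  # visit running into the trajectory end is excluded
  rt3 <- residence_times(build(c(rep(30, 5), rep(3, 10))), 4.5)
  expect_true(is.na(rt3$mean_residence_ps))
  expect_equal(rt3$n_visits, 0L)
  # a water never entering contributes nothing
  rt4 <- residence_times(build(rep(30, 12)), 4.5)
  expect_equal(rt4$n_visits, 0L)
  expect_error(residence_times(build(30)), "2 frames")
})

test_that("wrap-change flags compare the drop against half the mean reference wrap", {
  prof <- function(wrap) data.frame(residue = seq_along(wrap),
                                    frac_wrap = wrap)
  # no change anywhere -> no flags
  p <- prof(c(0.4, 0.2, 0.1, 0.1))
  expect_false(any(wrap_change_flags(p, p)$flagged))
  # one residue drops 0.4 -> 0.0 with mean_ref 0.2: 0.4 > 0.1 -> flagged
  ref <- prof(c(0.4, 0.2, 0.1, 0.1))
  after <- prof(c(0.0, 0.2, 0.1, 0.1))
  fl <- wrap_change_flags(ref, after)
  expect_identical(fl$flagged, c(TRUE, FALSE, FALSE, FALSE))
  # uniform 10% relative drop with mean_ref 0.2 -> deltas 0.04..0.01 < 0.1
  ref2 <- prof(c(0.4, 0.2, 0.1, 0.1))
  after2 <- prof(c(0.36, 0.18, 0.09, 0.09))
  expect_false(any(wrap_change_flags(ref2, after2)$flagged))
})
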