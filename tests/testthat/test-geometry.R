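# Superposition, RMSD/RMSF, centres of mass, distances, helix axes.

test_that("centre of mass matches hand arithmetic and handles weighting", {
  fr <- mk_frame(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(fr, 1:2), c(1, 0, 0))
  expect_equal(center_of_mass(fr, 1), c(0, 0, 0))

  fr3 <- mk_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 3, 4)))
  expect_equal(center_of_mass(fr3, 1:3), c(1, 1, 4 / 3))
  expect_error(center_of_mass(fr3, integer(0)), "empty")

  # mass weighting shifts the COM towards the heavier atom
  fr_m <- mk_frame(rbind(c(0, 0, 0), c(1, 0, 0)), element = c("H", "S"))
  com <- center_of_mass(fr_m, 1:2, weighting = "mass")
  expect_gt(com[1], 0.9)
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(11)
  A <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)

  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  B <- sweep(A %*% t(Rz90), 2, c(5, 5, 5), `+`)
  tf <- kabsch_superpose(A, B)
  expect_lt(tf$rmsd, 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(tf, A) - B)), 1e-9)

  expect_error(kabsch_superpose(A, A[1:5, ]), "differ in length")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch RMSD is symmetric and invariant under pre-applied rigid motions", {
  set.seed(12)
  for (rep in 1:20) {
    A <- matrix(rnorm(21), ncol = 3)
    B <- matrix(rnorm(21), ncol = 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
                 tolerance = 1e-9)
    R <- random_rotation()
    A2 <- sweep(A %*% t(R), 2, rnorm(3, sd = 10), `+`)
    expect_equal(kabsch_superpose(A2, B)$rmsd, kabsch_superpose(A, B)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD agrees with the exhaustive-rotation oracle on planar sets", {
  sq <- cbind(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), 0)
  sq2 <- sq; sq2[3, 1] <- sq2[3, 1] + 0.1
  expect_equal(kabsch_superpose(sq, sq2)$rmsd, brute_rmsd_planar(sq, sq2),
               tolerance = 1e-4)
  set.seed(13)
  for (rep in 1:5) {
    A <- cbind(matrix(rnorm(12, sd = 2), ncol = 2), 0)
    B <- cbind(matrix(rnorm(12, sd = 2), ncol = 2), 0)
    expect_equal(kabsch_superpose(A, B)$rmsd, brute_rmsd_planar(A, B),
                 tolerance = 1e-4)
  }
})

test_that("Kabsch agrees with the bio3d least-squares fit", {
  skip_if_not_installed("bio3d")
  set.seed(14)
  A <- matrix(rnorm(45, sd = 3), ncol = 3)
  B <- matrix(rnorm(45, sd = 3), ncol = 3)
  ours <- kabsch_superpose(A, B)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
  theirs <- bio3d::rmsd(as.numeric(t(B)), fitted)
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("RMSD series aligns on one selection and measures on another", {
  ref <- mk_frame(rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0),
                        c(1.9, 1.1, 3.1), c(0, 5, 0), c(3.8, 5, 0)),
                  name = rep("CA", 6), resno = 1:6)
  # copies of the reference give zero everywhere
  tr <- new_trajectory(list(ref, ref, ref))
  ca <- selection(class = "CA_ONLY")
  expect_equal(rmsd_series(tr, align_sel = ca, measure_sel = ca)$value,
               rep(0, 3))

  # align on residues 1-4 (unchanged), measure residues 5-6 with one atom
  # displaced by 1 A: rmsd = sqrt(1/2)
  fr2 <- ref; fr2$xyz[5, ] <- fr2$xyz[5, ] + c(0, 0, 1)
  tr2 <- new_trajectory(list(ref, fr2))
  out <- rmsd_series(tr2, align_sel = selection(resno = 1:4, class = "CA_ONLY"),
                     measure_sel = selection(resno = 5:6, class = "CA_ONLY"))
  expect_equal(out$value, c(0, sqrt(0.5)), tolerance = 1e-9)

  # align_sel == measure_sel reduces to the per-frame Kabsch rmsd
  fr3 <- transform_frame(fr2, random_rotation(), c(4, -2, 1))
  tr3 <- new_trajectory(list(ref, fr3))
  out3 <- rmsd_series(tr3, align_sel = ca, measure_sel = ca)
  expect_equal(out3$value[2], kabsch_superpose(fr3$xyz, ref$xyz)$rmsd,
               tolerance = 1e-9)
})

test_that("RMSF is zero for static trajectories and exact for two-state motion", {
  set.seed(15)
  base <- mk_frame(matrix(rnorm(30, sd = 5), ncol = 3),
                   name = rep("CA", 10), resno = 1:10)
  tr <- new_trajectory(list(base, base, base))
  ca <- selection(class = "CA_ONLY")
  expect_equal(rmsf(tr, align_sel = ca)$value, rep(0, 10), tolerance = 1e-9)

  # atom 10 oscillates +-1 A along x; align only on the rigid atoms 1-9
  up <- base; up$xyz[10, 1] <- up$xyz[10, 1] + 1
  dn <- base; dn$xyz[10, 1] <- dn$xyz[10, 1] - 1
  tr2 <- new_trajectory(list(up, dn, up, dn))
  out <- rmsf(tr2, align_sel = selection(resno = 1:9, class = "CA_ONLY"))
  expect_equal(out$value[1:9], rep(0, 9), tolerance = 1e-9)
  expect_equal(out$value[10], 1, tolerance = 1e-9)

  # invariant when every frame is globally rotated
  R <- random_rotation()
  tr3 <- new_trajectory(lapply(list(up, dn, up, dn), transform_frame,
                               R = R, t = c(1, 2, 3)))
  expect_equal(rmsf(tr3, align_sel = selection(resno = 1:9, class = "CA_ONLY"))$value,
               out$value, tolerance = 1e-9)
  expect_error(rmsf(new_trajectory(list(base)), align_sel = ca), "two frames")
})

test_that("minimum pair distance equals the brute-force double loop", {
  fr <- mk_frame(rbind(c(0, 0, 0), c(3, 4, 0), c(1, 0, 0), c(9, 9, 9)))
  expect_equal(min_pair_distance(fr, 1, 2), 5)
  expect_equal(min_pair_distance(fr, 1, c(3, 4)), 1)
  expect_error(min_pair_distance(fr, integer(0), 1), "empty")
  expect_error(min_pair_distance(fr, 1:2, 2:3), "overlap")

  set.seed(16)
  for (rep in 1:10) {
    fr <- mk_frame(matrix(rnorm(30, sd = 4), ncol = 3))
    a <- 1:5; b <- 6:10
    brute <- min(vapply(a, function(i) {
      min(sqrt(colSums((t(fr$xyz[b, ]) - fr$xyz[i, ])^2)))
    }, numeric(1)))
    expect_equal(min_pair_distance(fr, a, b), brute, tolerance = 1e-12)
  }
})

test_that("helix axes align with construction and rotate equivariantly", {
  ca <- build_ideal_helix(20)
  fr <- mk_frame(ca, name = rep("CA", 20), resno = 1:20)
  ax <- helix_axis(fr, 1:20)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), cos(1 * pi / 180))
  expect_gt(ax$direction[3], 0)  # oriented N -> C

  aRx30 <- rot_mat_x30 <- matrix(c(1, 0, 0,
                                   0, cos(pi / 6), -sin(pi / 6),
                                   0, sin(pi / 6), cos(pi / 6)), 3, 3,
                                 byrow = TRUE)
  fr2 <- transform_frame(fr, rot_mat_x30)
  ax2 <- helix_axis(fr2, 1:20)
  expect_equal(as.numeric(ax2$direction),
               as.numeric(rot_mat_x30 %*% ax$direction), tolerance = 1e-6)
  expect_error(helix_axis(fr, 1:3), "at least 4")

  # noisy helices recover the generator axis within 5 degrees
  set.seed(17)
  for (rep in 1:50) {
    noisy <- ca + matrix(rnorm(60, sd = 0.3), ncol = 3)
    frn <- mk_frame(noisy, name = rep("CA", 20), resno = 1:20)
    axn <- helix_axis(frn, 1:20)
    expect_gt(abs(sum(axn$direction * c(0, 0, 1))), cos(5 * pi / 180))
  }
})

test_that("kink angle reproduces constructed tilts on [0, 90]", {
  ca <- build_ideal_helix(20)
  fr <- mk_frame(ca, name = rep("CA", 20), resno = 1:20)
  seg <- selection(class = "CA_ONLY")
  expect_lt(kink_angle(fr, seg, c(0, 0, 1)), 1)
  expect_gt(kink_angle(fr, seg, c(1, 0, 0)), 89)

  tilt45 <- matrix(c(cos(pi / 4), 0, sin(pi / 4), 0, 1, 0,
                     -sin(pi / 4), 0, cos(pi / 4)), 3, 3, byrow = TRUE)
  fr45 <- transform_frame(fr, tilt45)
  expect_equal(kink_angle(fr45, seg, c(0, 0, 1)), 45, tolerance = 1)
})
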