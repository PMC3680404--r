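# Scaffold-bundle distances, gates, ion displacement, contact occupancy.

test_that("terminal residues follow the third-and-fourth counting convention", {
  h <- list(first = 100L, last = 120L)
  expect_setequal(terminal_residues(h, "C_terminal"), c(118L, 117L))
  expect_setequal(terminal_residues(h, "N_terminal"), c(102L, 103L))
  expect_error(terminal_residues(list(first = 1L, last = 3L), "N_terminal"),
               "shorter")
})

test_that("scaffold-bundle distance matches constructed centres of mass", {
  # two 8-residue helices: scaffold-group C-alphas centred at origin, bundle
  # at (0, 10, 0)
  mk_helix_ca <- function(x0, y0) {
    t(vapply(1:8, function(i) c(x0, y0, 1.5 * (i - 1)), numeric(3)))
  }
  xyz <- rbind(mk_helix_ca(-1, 0), mk_helix_ca(1, 0),
               mk_helix_ca(-1, 10), mk_helix_ca(1, 10))
  fr <- mk_frame(xyz, name = rep("CA", 32), resno = 1:32)
  topo <- topology(
    chains = "A",
    helices = tibble::tibble(tm = c("TM3", "TM5", "TM1a", "TM7"), chain = "A",
                             first = c(1L, 9L, 17L, 25L),
                             last = c(8L, 16L, 24L, 32L)),
    groups = list(intracellular = list(
      scaffold = tibble::tibble(tm = c("TM3", "TM5"),
                                end = c("N_terminal", "N_terminal")),
      bundle = tibble::tibble(tm = c("TM1a", "TM7"),
                              end = c("N_terminal", "N_terminal")))))
  d <- scaffold_bundle_distance(fr, topo, "intracellular")
  expect_equal(d, 10, tolerance = 1e-12)

  # invariance under global rigid motion
  fr2 <- transform_frame(fr, random_rotation(), c(13, -4, 2))
  expect_equal(scaffold_bundle_distance(fr2, topo, "intracellular"), d,
               tolerance = 1e-9)
  expect_error(scaffold_bundle_distance(fr, topo, "extracellular"),
               "no extracellular groups")
})

test_that("the intracellular face opens while the extracellular face holds", {
  p <- synthetic_params(noise_sigma = 0, n_frames = 8, schedule = "linear_open")
  gen <- generate_trajectory(p)
  ic <- scaffold_bundle_series(gen$trajectory, gen$topology, "intracellular")
  ec <- scaffold_bundle_series(gen$trajectory, gen$topology, "extracellular")
  expect_true(all(diff(ic$value) > 0))
  d_ic <- ic$value[8] - ic$value[1]
  expect_gt(d_ic, 0)
  expect_lt(abs(ec$value[8] - ec$value[1]), 0.2 * d_ic)
  # zero-noise monotonicity: perfect rank correlation with the hinge angle
  expect_equal(cor(ic$value, gen$ground_truth$theta_deg, method = "spearman"), 1)
})

test_that("gate distances take the minimum over the selected atom pairs", {
  fr <- mk_residue_frame(list(
    list(resno = 350, resname = "TYR", atoms = list(OH = c(0, 0, 0)),
         elements = c(OH = "O")),
    list(resno = 444, resname = "GLU",
         atoms = list(OE1 = c(2.6, 0, 0), OE2 = c(5, 0, 0)),
         elements = c(OE1 = "O", OE2 = "O"))))
  g <- hsert_gates("A")$tyr350_glu444
  expect_equal(gate_distance(fr, g), 2.6, tolerance = 1e-12)

  tr <- new_trajectory(list(fr, fr, fr))
  s <- gate_distance_series(tr, g)
  expect_equal(s$value, rep(2.6, 3), tolerance = 1e-12)

  # gate distances are invariant under global rigid motion
  fr_rot <- transform_frame(fr, random_rotation(), c(-3, 8, 1))
  expect_equal(gate_distance(fr_rot, g), 2.6, tolerance = 1e-9)
})

test_that("in-band fraction counts frames within the contact band", {
  expect_equal(in_band_fraction(rep(3, 10)), 1)
  expect_equal(in_band_fraction(c(2.0, 3.0, 5.0, 3.5)), 0.5)
  x <- runif(50, 1, 6)
  expect_equal(in_band_fraction(x) +
                 mean(x < 2.5 | x > 4.0), 1)
  expect_error(in_band_fraction(1:3, low = 5, high = 2), "low > high")
})

test_that("ion displacement is measured in the protein frame of reference", {
  base <- mk_frame(rbind(build_ideal_helix(10), c(5, 5, 5)),
                   name = c(rep("CA", 10), "NA"),
                   resno = c(1:10, 900L),
                   element = c(rep("C", 10), "NA"),
                   is_hetero = c(rep(FALSE, 10), TRUE))
  ion <- selection(atoms = "NA", hetero = TRUE)
  ca <- selection(class = "CA_ONLY")
  tr <- new_trajectory(list(base, base))
  expect_equal(ion_z_displacement(tr, ion, ca)$value, c(0, 0), tolerance = 1e-9)

  # ion drops 6 A while the protein is unchanged
  dropped <- base; dropped$xyz[11, 3] <- dropped$xyz[11, 3] - 6
  tr2 <- new_trajectory(list(base, dropped))
  expect_equal(ion_z_displacement(tr2, ion, ca)$value[2], -6, tolerance = 1e-9)
  # with an inverted membrane normal the sign flips
  expect_equal(ion_z_displacement(tr2, ion, ca, membrane_normal = -1)$value[2],
               6, tolerance = 1e-9)

  # a whole-system translation is removed by the alignment
  shifted <- transform_frame(base, diag(3), c(10, -7, 3))
  tr3 <- new_trajectory(list(base, shifted))
  expect_equal(ion_z_displacement(tr3, ion, ca)$value[2], 0, tolerance = 1e-9)

  two_ions <- base; two_ions$atoms$name[10] <- "NA"
  expect_error(ion_z_displacement(new_trajectory(list(base)),
                                  selection(atoms = "ZZ"), ca), "0 atoms")
})

test_that("contact occupancy counts frames within the cutoff per residue", {
  mk <- function(d) {
    mk_residue_frame(list(
      list(resno = 1, resname = "LIG", chain = "A",
           atoms = list(C1 = c(0, 0, 0)), elements = c(C1 = "C")),
      list(resno = 438, resname = "SER", chain = "A",
           atoms = list(OG = c(d, 0, 0)), elements = c(OG = "O")),
      list(resno = 500, resname = "ALA", chain = "A",
           atoms = list(CB = c(20, 0, 0)), elements = c(CB = "C"))))
  }
  lig <- selection(resno = 1)
  partners <- tibble::tibble(chain = "A", resno = c(438L, 500L))

  tr <- new_trajectory(list(mk(2.8), mk(2.8)))
  occ <- contact_occupancy(tr, lig, partners)
  expect_equal(occ$occupancy, c(1, 0))
  expect_equal(occ$stable, c(TRUE, FALSE))

  tr2 <- new_trajectory(list(mk(3.0), mk(4.0), mk(3.0), mk(4.0)))
  occ2 <- contact_occupancy(tr2, lig, partners)
  expect_equal(occ2$occupancy[1], 0.5)
  expect_false(occ2$stable[1])
  expect_error(contact_occupancy(tr, lig, partners[0, ]), "empty partner")
})

test_that("the shipped hSERT gate presets name the published atom groups", {
  gates <- hsert_gates("B")
  expect_named(gates, c("tyr350_glu444", "glu136_gly340", "arg104_glu493",
                        "glu136_glu508"))
  expect_equal(gates$tyr350_glu444$selA$resno, 350L)
  expect_equal(gates$tyr350_glu444$selA$atoms, "OH")
  expect_setequal(gates$arg104_glu493$selA$atoms, c("NE", "NH1", "NH2"))
  expect_equal(gates$glu136_gly340$selB$atoms, "N")
  expect_equal(gates$glu136_glu508$selB$resno, 508L)
  expect_true(all(vapply(gates, function(g) g$selA$chain == "B", logical(1))))
})
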