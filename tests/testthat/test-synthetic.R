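# Synthetic toy-transporter generator and its ground truth.

test_that("ideal helices have the canonical alpha-helix geometry", {
  ca <- build_ideal_helix(20)
  expect_equal(diff(range(ca[, 3])), 28.5, tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  fr <- mk_frame(ca, name = rep("CA", 20), resno = 1:20)
  ax <- helix_axis(fr, 1:20)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), cos(pi / 180))
  # arbitrary axes are honoured
  ca2 <- build_ideal_helix(20, axis = c(1, 1, 0))
  fr2 <- mk_frame(ca2, name = rep("CA", 20), resno = 1:20)
  ax2 <- helix_axis(fr2, 1:20)
  expect_gt(abs(sum(ax2$direction * c(1, 1, 0) / sqrt(2))), cos(pi / 180))
  expect_error(build_ideal_helix(3), "at least 4")
})

test_that("toy conformations are deterministic with a localised TM1a swing", {
  p <- synthetic_params(noise_sigma = 0)
  expect_identical(build_toy_transporter(p, 10), build_toy_transporter(p, 10))
  fr0 <- build_toy_transporter(p, 0)
  fr_max <- build_toy_transporter(p, p$hinge_angle_max)

  tip <- resolve_selection(fr0, selection(resno = 1L, atoms = "CA"))
  expect_gt(sqrt(sum((fr_max$xyz[tip, ] - fr0$xyz[tip, ])^2)), 5)

  # scaffold helices TM3-TM5 and TM8-TM10 do not move at all
  h <- toy_helix_table(p)
  sc_tms <- c("TM3", "TM4", "TM5", "TM8", "TM9", "TM10")
  sc_res <- unlist(lapply(sc_tms, function(tm) {
    r <- h[h$tm == tm, ]; r$first:r$last
  }))
  si <- resolve_selection(fr0, selection(resno = sc_res, class = "CA_ONLY"))
  expect_lt(max(sqrt(rowSums((fr_max$xyz[si, ] - fr0$xyz[si, ])^2))), 0.5)

  expect_error(build_toy_transporter(p, p$hinge_angle_max + 1), "theta")
  expect_error(build_toy_transporter(p, -1), "theta")
})

test_that("toy frames survive the PDB round trip with their helix records", {
  p <- synthetic_params(noise_sigma = 0)
  fr <- build_toy_transporter(p, 20)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fr, f, header_lines = format_helix_records(toy_helix_table(p)))
  back <- read_pdb(f)
  expect_identical(back$atoms$name, fr$atoms$name)
  expect_identical(back$atoms$resno, fr$atoms$resno)
  expect_identical(back$atoms$is_hetero, fr$atoms$is_hetero)
  expect_lt(max(abs(back$coords[, , 1] - fr$xyz)), 1e-3 + 1e-9)

  hr <- helix_records(f)
  expect_equal(nrow(hr), 14L)
  ranges <- assign_tm_ranges(
    hr, tm_map = setNames(toupper(sub("^TM", "", toy_helix_table(p)$tm)),
                          toy_helix_table(p)$tm))
  expect_equal(ranges$first, toy_helix_table(p)$first)
  expect_equal(ranges$last, toy_helix_table(p)$last)
})

test_that("whole-helix records split at user-declared unwound centres", {
  helices <- tibble::tibble(tm = c("TM1", "TM6"), chain = "A",
                            first = c(11L, 241L), last = c(38L, 268L))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(format_helix_records(helices),
               pdb_line(1, "CA", "ALA", "A", 11, 0, 0, 0), "END"), f)
  hr <- helix_records(f)
  ranges <- assign_tm_ranges(hr, tm_map = c(TM1 = "1", TM6 = "6"),
                             splits = c(TM1 = 22L, TM6 = 252L))
  expect_equal(ranges$tm, c("TM1a", "TM1b", "TM6a", "TM6b"))
  expect_equal(ranges$first, c(11L, 23L, 241L, 253L))
  expect_equal(ranges$last, c(22L, 38L, 252L, 268L))
  expect_error(assign_tm_ranges(hr, tm_map = c(TM1 = "1")), "split")
  expect_error(assign_tm_ranges(hr, tm_map = c(TM2 = "9")), "no HELIX record")
})

test_that("trajectory schedules and seeding behave as declared", {
  # hold_closed at zero noise reproduces the closed conformation exactly
  p <- synthetic_params(noise_sigma = 0, n_frames = 3,
                        schedule = "hold_closed")
  gen <- generate_trajectory(p)
  fr0 <- build_toy_transporter(p, 0)
  for (k in 1:3) {
    expect_equal(gen$trajectory$coords[, , k], unname(fr0$xyz),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # identical seeds give bit-identical trajectories
  pn <- synthetic_params(noise_sigma = 0.3, n_frames = 4, seed = 99)
  g1 <- generate_trajectory(pn)
  g2 <- generate_trajectory(pn)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  g3 <- generate_trajectory(synthetic_params(noise_sigma = 0.3, n_frames = 4,
                                             seed = 100))
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))

  # two-state schedule holds closed then open
  pt <- synthetic_params(noise_sigma = 0, n_frames = 6, schedule = "two_state")
  expect_equal(generate_trajectory(pt)$ground_truth$theta_deg,
               c(0, 0, 0, 30, 30, 30))

  expect_error(synthetic_params(hinge_angle_max = 75), "hinge")
  expect_error(synthetic_params(noise_sigma = -1), "noise_sigma")
  expect_error(synthetic_params(n_res_per_helix = 7), "even")
})

test_that("the emitted topology validates against the emitted trajectory", {
  p <- synthetic_params(noise_sigma = 0.1, n_frames = 2)
  gen <- generate_trajectory(p)
  expect_true(validate_topology(gen$topology, get_frame(gen$trajectory, 1)))
})

test_that("the pseudo-ion descends 0.2 A per degree of hinge opening", {
  p <- synthetic_params(noise_sigma = 0, n_frames = 5, schedule = "linear_open")
  gen <- generate_trajectory(p)
  dz <- ion_z_displacement(gen$trajectory, gen$topology$ion,
                           selection(chain = "A", class = "CA_ONLY"))
  # the C-alpha superposition drifts slightly as TM1a swings; allow 0.2 A
  expect_equal(dz$value[5], -0.2 * p$hinge_angle_max, tolerance = 0.2 / 6)
  expect_true(all(diff(dz$value) < 0))
})

test_that("ground truth recovers from measured coordinates across seeds", {
  rho <- vapply(1:5, function(s) {
    p <- synthetic_params(noise_sigma = 0.1, n_frames = 25, seed = s,
                          schedule = "linear_open")
    gen <- generate_trajectory(p)
    ic <- scaffold_bundle_series(gen$trajectory, gen$topology, "intracellular")
    cor(ic$value, gen$ground_truth$theta_deg, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.95)
})
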