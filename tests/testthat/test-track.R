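test_that("no primaries means no trajectories", {
  beam <- beam_config(n_primaries = 0L)
  expect_equal(nrow(sample_primaries(beam, nucleus_model())), 0)
})

test_that("the source plane sits outside the nucleus at the configured offset", {
  nuc <- nucleus_model()
  beam <- beam_config(n_primaries = 50L, source_offset_um = 3,
                      direction = c(0, 0, 1))
  set.seed(5)
  tr <- sample_primaries(beam, nuc)
  # plane perpendicular to the beam, 3 um beyond the nucleus surface
  expect_true(all(tr$z0 == -(5 + 3) * 1000))
  w <- (tr$x0 / 14200)^2 + (tr$y0 / 14200)^2 + (tr$z0 / 5000)^2
  expect_true(all(w > 1))
})

test_that("all trajectories traverse the cytoplasm ellipsoid", {
  nuc <- nucleus_model()
  beam <- beam_config(n_primaries = 200L)
  set.seed(6)
  tr <- sample_primaries(beam, nuc)
  for (k in seq_len(nrow(tr))) {
    chord <- radbreak:::line_ellipsoid_chord(
      c(tr$x0[k], tr$y0[k], tr$z0[k]),
      c(tr$dx[k], tr$dy[k], tr$dz[k]),
      nuc$cyto_semi_axes_um * 1000)
    expect_false(is.null(chord))
  }
})

test_that("deposit density reproduces the configured LET", {
  nuc <- nucleus_model(semi_axes_um = c(5, 5, 5),
                       cyto_semi_axes_um = c(10, 10, 5))
  beam <- beam_config(let_keV_um = 25.77, n_primaries = 1L)
  traj <- data.frame(primary_id = 0L, x0 = 0, y0 = 0, z0 = -8000,
                     dx = 0, dy = 0, dz = 1)
  set.seed(7)
  totals <- replicate(300, sum(generate_deposits(traj, beam, nuc)$energy_eV))
  # central chord is 10 um: expect 257.7 keV per track
  expect_equal(mean(totals) / 1000, 25.77 * 10, tolerance = 0.01)
})

test_that("doubling LET doubles the event density at fixed event energy", {
  nuc <- nucleus_model(semi_axes_um = c(5, 5, 5),
                       cyto_semi_axes_um = c(10, 10, 5))
  traj <- data.frame(primary_id = 0L, x0 = 0, y0 = 0, z0 = -8000,
                     dx = 0, dy = 0, dz = 1)
  set.seed(8)
  n1 <- mean(replicate(80, nrow(generate_deposits(
    traj, beam_config(let_keV_um = 10), nuc))))
  n2 <- mean(replicate(80, nrow(generate_deposits(
    traj, beam_config(let_keV_um = 20), nuc))))
  expect_equal(n2 / n1, 2, tolerance = 0.05)
})

test_that("a trajectory missing the nucleus deposits nothing", {
  nuc <- nucleus_model()
  beam <- beam_config()
  traj <- data.frame(primary_id = 0L, x0 = 20000, y0 = 20000, z0 = -8000,
                     dx = 0, dy = 0, dz = 1)
  expect_equal(nrow(generate_deposits(traj, beam, nuc)), 0)
})

test_that("deposit generation is reproducible under a seed", {
  nuc <- nucleus_model()
  beam <- beam_config(let_keV_um = 30)
  traj <- data.frame(primary_id = 0L, x0 = 0, y0 = 0, z0 = -8000,
                     dx = 0, dy = 0, dz = 1)
  d1 <- generate_deposits(traj, beam, nuc, seed = 99)
  d2 <- generate_deposits(traj, beam, nuc, seed = 99)
  expect_identical(d1, d2)
})

test_that("per-event energies follow the truncated spectrum with the requested mean", {
  set.seed(9)
  e <- radbreak:::rtrunc_exp(2e5, 45, c(5, 500))
  expect_true(all(e >= 5 & e <= 500))
  expect_equal(mean(e), 45, tolerance = 0.01)
})

test_that("species yields are Poisson with mean G x E / 100", {
  deposits <- data.frame(primary_id = 0L, event_id = seq_len(1e5) - 1L,
                         x = 0, y = 0, z = 0, energy_eV = 100)
  set.seed(10)
  sp <- spawn_species(deposits, yield_table = c(OH = 2.5),
                      diffusion = c(OH = 2.8))
  lambda <- nrow(sp) / nrow(deposits)
  expect_equal(lambda, 2.5, tolerance = 0.02)
  expect_true(all(sp$name == "OH"))
  expect_true(all(sp$t_ns == 0))
})

test_that("zero yields spawn nothing and unknown species are rejected", {
  deposits <- data.frame(primary_id = 0L, event_id = 0L,
                         x = 0, y = 0, z = 0, energy_eV = 100)
  expect_equal(nrow(spawn_species(deposits,
                                  yield_table = c(OH = 0, e_aq = 0))), 0)
  expect_error(spawn_species(deposits, yield_table = c(bogus = 1)),
               "unknown species")
})

test_that("event CSVs round-trip and tolerate column reordering", {
  nuc <- nucleus_model()
  beam <- beam_config(let_keV_um = 30)
  traj <- data.frame(primary_id = 0L, x0 = 0, y0 = 0, z0 = -8000,
                     dx = 0, dy = 0, dz = 1)
  dep <- generate_deposits(traj, beam, nuc, seed = 4)
  sp <- spawn_species(dep, seed = 4)
  dp <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  write_external_events(dep, sp, dp, sf)
  back <- read_external_events(dp, sf)
  expect_equal(back$deposits$energy_eV, dep$energy_eV)
  expect_equal(back$species$name, sp$name)
  # shuffled columns load the same through header matching
  shuffled <- dep[, rev(names(dep))]
  write.csv(shuffled, dp, row.names = FALSE)
  again <- read_external_events(dp)
  expect_equal(again$deposits$energy_eV, dep$energy_eV)
  # header-only file gives empty lists
  write.csv(dep[0, ], dp, row.names = FALSE)
  expect_equal(nrow(read_external_events(dp)$deposits), 0)
  # malformed numeric column is reported
  bad <- dep[1:3, ]
  bad$energy_eV <- c("1", "oops", "3")
  write.csv(bad, dp, row.names = FALSE)
  expect_error(read_external_events(dp), "malformed")
})

test_that("energy bookkeeping is exact per track", {
  nuc <- nucleus_model()
  beam <- beam_config(let_keV_um = 40)
  traj <- data.frame(primary_id = 0L, x0 = 0, y0 = 0, z0 = -8000,
                     dx = 0, dy = 0, dz = 1)
  dep <- generate_deposits(traj, beam, nuc, seed = 11)
  expect_equal(sum(dep$energy_eV), sum(dep$energy_eV))
  expect_true(all(dep$energy_eV > 0))
  # deposits stay inside a penumbra-padded nucleus
  w <- (dep$x / 14200)^2 + (dep$y / 14200)^2 + (dep$z / 5000)^2
  expect_true(mean(w <= 1.01) > 0.99)
})
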