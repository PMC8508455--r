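test_that("a pair in contact reacts immediately and with certainty", {
  expect_equal(irt_sample_pair(0.5, R_eff = 0.5, D_rel = 2.8, u = 0.3), 0)
  expect_equal(irt_sample_pair(0.1, R_eff = 0.5, D_rel = 2.8, u = 0.99), 0)
})

test_that("the ultimate reaction probability is R_eff / r0", {
  set.seed(20)
  tt <- irt_sample_pair(rep(1.0, 1e5), R_eff = 0.5, D_rel = 2.8)
  expect_equal(mean(is.finite(tt)), 0.5, tolerance = 0.02)
  # distant pairs almost never react
  tt_far <- irt_sample_pair(rep(500, 1e4), R_eff = 0.5, D_rel = 2.8)
  expect_lt(mean(is.finite(tt_far)), 0.01)
})

test_that("sampled reaction times follow the diffusion closed form", {
  set.seed(21)
  r0 <- 1.0; R <- 0.5; D <- 2.8
  tt <- irt_sample_pair(rep(r0, 1e5), R_eff = R, D_rel = D)
  tt <- tt[is.finite(tt)]
  # conditional CDF: W(t)/W_inf = erfc((r0-R)/sqrt(4 D t))
  cdf <- function(t) 2 * pnorm((r0 - R) / sqrt(4 * D * t) * sqrt(2),
                               lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(tt, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("IRT ultimate probability matches a Brownian absorption oracle", {
  set.seed(22)
  for (cfg in list(c(0.5, 1.0), c(0.2, 1.0), c(0.3, 0.6))) {
    R <- cfg[1]; r0 <- cfg[2]
    p_wos <- wos_absorption(r0, R, n_walkers = 1e5)
    tt <- irt_sample_pair(rep(r0, 1e5), R_eff = R, D_rel = 2.8)
    p_irt <- mean(is.finite(tt))
    expect_equal(p_irt, p_wos, tolerance = 0.02)
  }
})

test_that("rate constants map to encounter radii through diffusion control", {
  # R_eff = k / (4 pi D_rel N_A): OH self-recombination at 5.5e9 M^-1 s^-1
  ch <- reaction_channel("OH", "OH", rate = 5.5e9, D_rel = 5.6)
  k_nm <- 5.5e9 * 1e24 / (6.02214076e23 * 1e9)
  expect_equal(ch$R_eff, k_nm / (4 * pi * 5.6))
  expect_error(reaction_channel("OH", "OH", R_eff = 0), "radius")
  expect_error(reaction_channel("OH", "OH", rate = 1e9), "D_rel")
})

test_that("the kill distance removes species strictly beyond it, surface-referenced", {
  mol <- mol_row("sugar", 0, 0, 0, radius = 0.228)
  sp <- rbind(species_row(x = 9.228, id = 0L),             # exactly d_kill
              species_row(x = 9.229, id = 1L),             # just beyond
              species_row(x = 5.228, id = 2L))
  out <- apply_kill_distance(sp, mol, d_kill = 9)
  expect_equal(sort(out$species_id), c(0L, 2L))
  expect_equal(attr(out, "killed"), 1L)
})

test_that("kill-distance diffusion time follows the 3-D MSD formula", {
  expect_equal(consistency_check_kill_time(9, 2.8), 9^2 / (6 * 2.8))
  expect_equal(consistency_check_kill_time(9, 2.8), 4.82, tolerance = 0.002)
  expect_equal(consistency_check_kill_time(0, 2.8), 0)
  expect_equal(consistency_check_kill_time(18, 2.8),
               4 * consistency_check_kill_time(9, 2.8))
  expect_warning(consistency_check_kill_time(30, 2.8, T_chem = 5),
                 "differs from T_chem")
  expect_silent(consistency_check_kill_time(9, 2.8, T_chem = 5))
})

test_that("no species means no chemistry events", {
  mol <- mol_row("sugar", 0, 0, 0, radius = 0.228)
  out <- evolve_chemistry(species_row()[0, ], mol)
  expect_equal(nrow(out$events), 0)
})

test_that("a hydroxyl radical beside a backbone group is forced to react", {
  mol <- mol_row("phosphate", 0, 0, 0, radius = 0.263, bp = 17L, strand = 1L)
  sp <- species_row(x = 1.0)
  channels <- list(reaction_channel("OH", "backbone", R_eff = 5))
  out <- evolve_chemistry(sp, mol, channels, T_chem = 5, dt_max = 0.5)
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$channel, "OH+backbone")
  expect_equal(out$events$bp, 17L)
  expect_equal(out$events$strand, 1L)
  expect_equal(nrow(out$survivors), 0)
  hits <- dna_hit_events(out$events)
  expect_equal(hits$bp, 17L)
})

test_that("the earliest reaction wins: contact recombination beats distant DNA", {
  mol <- mol_row("sugar", 50, 0, 0, radius = 0.228)
  sp <- rbind(species_row(x = 0, id = 0L, rng = 1L),
              species_row(x = 0.05, id = 1L, rng = 2L))
  channels <- list(reaction_channel("OH", "backbone", R_eff = 0.2),
                   reaction_channel("OH", "OH", R_eff = 0.1))
  out <- evolve_chemistry(sp, mol, channels, T_chem = 5, dt_max = 0.5)
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$channel, "OH+OH")
  expect_equal(nrow(out$survivors), 0)
})

test_that("histone contact scavenges without producing a DNA hit", {
  mol <- mol_row("histone", 0, 0, 0, radius = 2.4, strand = NA_integer_)
  sp <- species_row(x = 1.0)   # inside the histone contact radius
  out <- evolve_chemistry(sp, mol, default_channels())
  expect_equal(out$events$channel, "OH+histone")
  expect_equal(nrow(dna_hit_events(out$events)), 0)
})

test_that("every species ends up reacted, killed at birth, or surviving", {
  model <- small_model(it = 2L, bp = 2200L)
  mol <- radbreak:::materialize_voxels(model, model$chromosome_map[1:2, ])
  center <- c(mean(mol$x), mean(mol$y), mean(mol$z))
  set.seed(23)
  n0 <- 400
  sp <- data.frame(species_id = seq_len(n0) - 1L, name = "OH",
                   x = center[1] + rnorm(n0, 0, 30),
                   y = center[2] + rnorm(n0, 0, 30),
                   z = center[3] + rnorm(n0, 0, 30),
                   t_ns = 0, D = 2.8, primary_id = 0L,
                   rng = sample.int(1e6, n0))
  surv0 <- apply_kill_distance(sp, mol, d_kill = 9)
  killed <- attr(surv0, "killed")
  out <- evolve_chemistry(surv0, mol, default_channels())
  expect_equal(killed + nrow(out$events) + nrow(out$survivors), n0)
  expect_true(all(out$events$time_ns >= 0 & out$events$time_ns <= 5))
  expect_lte(nrow(dna_hit_events(out$events)), n0)
})

test_that("chemistry rejects non-positive stage or window durations", {
  mol <- mol_row("sugar", 0, 0, 0, radius = 0.228)
  sp <- species_row()
  expect_error(evolve_chemistry(sp, mol, T_chem = 0), "T_chem")
  expect_error(evolve_chemistry(sp, mol, dt_max = -1), "dt_max")
})

test_that("widening the kill distance never loses DNA-hit events at fixed seed", {
  cfg <- tiny_config(let = 80, n_primaries = 8L)
  model <- config_genome(cfg)
  hits_at <- function(dk) {
    cfg$damage$d_kill_nm <- dk
    res <- run_damage(model, cfg, seed = 3)
    sum(res$per_primary$n_hits)
  }
  h <- vapply(c(3, 6, 9, 14), hits_at, numeric(1))
  expect_true(all(diff(h) >= 0))
  expect_gt(h[4], 0)
})
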