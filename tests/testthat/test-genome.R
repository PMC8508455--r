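test_that("nucleus mask retains centre voxels and drops voxels beyond the surface", {
  nuc <- nucleus_model(semi_axes_um = c(14.2, 14.2, 5))
  lay <- build_hilbert_path(3, anisotropic_scale = nuc$semi_axes_um * 1000)
  lay <- apply_nucleus_mask(lay, nuc)
  ctr <- layout_centers(lay)
  w <- sweep(ctr, 2, nuc$semi_axes_um * 1000, "/")
  inside <- rowSums(w^2) <= 1
  expect_equal(lay$retained, inside)
  # the voxel closest to the origin is retained; corner voxels are not
  expect_true(lay$retained[which.min(rowSums(ctr^2))])
  expect_false(lay$retained[which.max(rowSums(w^2))])
})

test_that("a sphere mask with equal semi-axes matches the ellipsoid mask", {
  lay1 <- build_hilbert_path(3, anisotropic_scale = rep(5000, 3))
  sph <- nucleus_model(semi_axes_um = c(5, 5, 5), mask_shape = "sphere")
  ell <- nucleus_model(semi_axes_um = c(5, 5, 5), mask_shape = "ellipsoid")
  expect_equal(apply_nucleus_mask(lay1, sph)$retained,
               apply_nucleus_mask(lay1, ell)$retained)
})

test_that("masked path splits into contiguous grid-adjacent runs", {
  model <- small_model(it = 3L)
  lay <- model$layout
  idx <- which(lay$retained)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  for (run in runs) {
    if (length(run) < 2) next
    steps <- diff(lay$cells[run, , drop = FALSE])
    expect_true(all(rowSums(abs(steps)) == 1))
  }
})

test_that("genome bp counting is lazy arithmetic over retained voxels", {
  model <- small_model(it = 2L, bp = 200L)
  n_ret <- sum(model$layout$retained)
  expect_equal(count_genome_bp(model), n_ret * 200)
  # empty mask: a nucleus far smaller than one voxel retains nothing
  nuc0 <- nucleus_model(semi_axes_um = c(1e-4, 1e-4, 1e-4))
  lay0 <- build_hilbert_path(2, anisotropic_scale = c(450, 450, 160))
  lay0 <- apply_nucleus_mask(lay0, nuc0)
  model0 <- model
  model0$layout <- lay0
  expect_equal(count_genome_bp(model0), 0)
})

test_that("lazy count equals the bp of fully materialised molecules", {
  model <- small_model(it = 2L, bp = 60L)
  semi <- model$nucleus$semi_axes_um * 1000
  mol <- materialize_region(model, rbind(-semi, semi))
  sug0 <- mol[mol$kind == "sugar" & mol$strand == 0L, ]
  expect_equal(nrow(sug0), count_genome_bp(model))
  # per bp and strand: exactly one sugar, phosphate and base
  for (kind in c("sugar", "phosphate", "base")) {
    sub <- mol[mol$kind == kind, ]
    expect_equal(nrow(sub), 2 * count_genome_bp(model))
    expect_equal(as.numeric(table(sub$strand)),
                 rep(count_genome_bp(model), 2))
  }
})

test_that("chromosome partition is contiguous with human-proportional sizes", {
  model <- genome_model(nucleus_model(), hilbert_iteration = 4L,
                        bp_per_voxel = 1000L)
  map <- model$chromosome_map
  expect_equal(sort(unique(map$chromosome)), 1:46)
  # contiguity in path order
  expect_true(all(diff(map$chromosome) >= 0))
  # block sizes roughly proportional to chromosome lengths (coarse: voxels
  # quantise the boundaries)
  lens <- human_chromosome_lengths()
  w <- rep(c(lens[1:22], lens["chrX"]), 2)
  expected <- w / sum(w) * nrow(map)
  observed <- as.numeric(table(map$chromosome))
  expect_true(all(abs(observed - expected) <= pmax(2, 0.25 * expected)))
  # bp indices restart at 0 and advance by bp_per_voxel within a chromosome
  for (cc in c(1, 24, 46)) {
    sub <- map[map$chromosome == cc, ]
    expect_equal(sub$bp_start, (seq_len(nrow(sub)) - 1L) * 1000L)
  }
})

test_that("materialisation is consistent, monotone in the region and empty off-model", {
  model <- small_model(it = 2L, bp = 120L)
  roi1 <- rbind(c(-460, -460, -170), c(0, 0, 0))
  roi2 <- rbind(c(-460, -460, -170), c(460, 460, 170))
  m1 <- materialize_region(model, roi1)
  m2 <- materialize_region(model, roi2)
  m1b <- materialize_region(model, roi1)
  expect_identical(m1, m1b)
  # union contains the smaller region's voxels with identical coordinates
  key <- function(m) paste(m$kind, m$chromosome, m$strand, m$bp)
  expect_true(all(key(m1) %in% key(m2)))
  far <- rbind(c(1e6, 1e6, 1e6), c(2e6, 2e6, 2e6))
  expect_equal(nrow(materialize_region(model, far)), 0)
})

test_that("non-bonded same-strand backbone volumes never overlap", {
  model <- small_model(it = 2L, bp = 2200L)
  map <- model$chromosome_map[1:2, ]
  mol <- radbreak:::materialize_voxels(model, map)
  bb <- mol[mol$kind %in% c("sugar", "phosphate") & mol$strand == 0L, ]
  bb <- bb[order(bb$bp), ]
  tr <- build_octree(bb)
  expect_gt(nrow(bb), 1000)
  # smallest allowed gap: 0.9 x the sum of the two radii
  min_gap <- 0.9 * 2 * max(bb$radius)
  for (i in sample(nrow(bb), 200)) {
    near <- query_radius(tr, c(bb$x[i], bb$y[i], bb$z[i]), min_gap)
    near <- setdiff(near, i)
    # bonded neighbours (adjacent bp on the same strand) are exempt
    non_bonded <- near[abs(bb$bp[near] - bb$bp[i]) > 1 |
                         bb$kind[near] == bb$kind[i]]
    non_bonded <- non_bonded[!(abs(bb$bp[non_bonded] - bb$bp[i]) <= 1)]
    if (length(non_bonded)) {
      d <- sqrt((bb$x[non_bonded] - bb$x[i])^2 +
                  (bb$y[non_bonded] - bb$y[i])^2 +
                  (bb$z[non_bonded] - bb$z[i])^2)
      expect_true(all(d >= 0.9 * (bb$radius[non_bonded] + bb$radius[i])))
    }
  }
})

test_that("segment definition files round-trip", {
  model <- small_model(it = 2L, bp = 50L)
  tpl <- segment_template(model, "turned", 50L)
  path <- withr::local_tempfile(fileext = ".seg")
  write_segment_file(tpl, "turned", 50L, path)
  back <- read_segment_file(path)
  expect_equal(back$segment_type, "turned")
  expect_equal(back$bp_count, 50L)
  expect_equal(nrow(back$molecules), nrow(tpl))
  expect_equal(back$molecules$x, tpl$x, tolerance = 1e-5)
  expect_equal(back$molecules$kind, tpl$kind)
})

test_that("nominal genomic density reproduces the literature figure", {
  expect_equal(nominal_bp_density(), 0.012)
  expect_equal(nominal_bp_density(6.4e9, 500), 0.0128)
})
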