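test_that("textbook configurations classify as expected", {
  p <- damage_params()
  # opposite strands within d_DSB: one DSB
  t1 <- classify_event(rbind(brk(0, 100), brk(1, 105)), p)
  expect_equal(unname(t1$counts[["DSB"]]), 1)
  expect_equal(sum(t1$counts), 1)
  # opposite strands beyond d_DSB but within d_s: one 2SSB cluster
  t2 <- classify_event(rbind(brk(0, 100), brk(1, 150)), p)
  expect_equal(unname(t2$counts[["2SSB"]]), 1)
  expect_equal(sum(t2$counts), 1)
  # same strand within d_s: SSB+
  t3 <- classify_event(rbind(brk(0, 100), brk(0, 150)), p)
  expect_equal(unname(t3$counts[["SSB+"]]), 1)
  # DSB core plus an extra break within d_DSB: DSB+
  t4 <- classify_event(rbind(brk(0, 100), brk(1, 105), brk(0, 108)), p)
  expect_equal(unname(t4$counts[["DSB+"]]), 1)
  expect_equal(sum(t4$counts), 1)
  # two DSBs within d_s: one DSB++ cluster
  t5 <- classify_event(rbind(brk(0, 100), brk(1, 101),
                             brk(0, 180), brk(1, 181)), p)
  expect_equal(unname(t5$counts[["DSB++"]]), 1)
  expect_equal(sum(t5$counts), 1)
  expect_equal(nrow(t5$dsb_positions), 2)
  # no breaks at all
  t0 <- classify_event(brk(0, 1)[0, ], p)
  expect_equal(sum(t0$counts), 0)
  expect_equal(t0$total_breaks, 0)
})

test_that("breaks on different chromosomes never cluster", {
  p <- damage_params()
  t1 <- classify_event(rbind(brk(0, 100, chromosome = 1L),
                             brk(1, 101, chromosome = 2L)), p)
  expect_equal(unname(t1$counts[["SSB"]]), 2)
  expect_equal(unname(t1$counts[["DSB"]]), 0)
})

test_that("source labels follow the core/accessory rules", {
  p <- damage_params()
  lab <- function(t) names(which(t$sources[4:7] > 0))
  expect_equal(lab(classify_event(rbind(brk(0, 10, "direct"),
                                        brk(1, 12, "direct")), p)), "DSB_d")
  expect_equal(lab(classify_event(rbind(brk(0, 10, "indirect"),
                                        brk(1, 12, "indirect")), p)), "DSB_i")
  expect_equal(lab(classify_event(rbind(brk(0, 10, "direct"),
                                        brk(1, 12, "indirect")), p)), "DSB_m")
  # indirect core with a direct accessory break: hybrid
  expect_equal(lab(classify_event(rbind(brk(0, 10, "indirect"),
                                        brk(1, 12, "indirect"),
                                        brk(0, 15, "direct")), p)), "DSB_hyb")
  # indirect core with indirect accessory stays indirect
  expect_equal(lab(classify_event(rbind(brk(0, 10, "indirect"),
                                        brk(1, 12, "indirect"),
                                        brk(0, 15, "indirect")), p)), "DSB_i")
  ssb <- classify_event(rbind(brk(0, 10, "direct"), brk(0, 40, "indirect")), p)
  expect_equal(unname(ssb$sources[["SSB_m"]]), 1)
})

test_that("classification matches the exhaustive oracle on boundary-covering configurations", {
  p <- damage_params()
  # positions chosen to exercise every distance boundary (d_DSB = 10,
  # d_s = 100) on a 400-bp duplex
  positions <- c(0, 9, 10, 11, 20, 99, 100, 101, 110, 200, 399)
  sites <- expand.grid(strand = 0:1, bp = positions)
  ns <- nrow(sites)
  combos <- c(utils::combn(ns, 1, simplify = FALSE),
              utils::combn(ns, 2, simplify = FALSE),
              utils::combn(ns, 3, simplify = FALSE),
              utils::combn(ns, 4, simplify = FALSE))
  srcs <- c("direct", "indirect")
  mismatches <- 0
  first_bad <- NULL
  for (cmb in combos) {
    b <- data.frame(chromosome = 1L, strand = sites$strand[cmb],
                    bp = sites$bp[cmb],
                    source = srcs[1 + (cmb %% 2)],
                    primary_id = 0L)
    got <- tally_vector(classify_event(b, p))
    want <- oracle_classify(b, p$d_DSB_bp, p$d_s_bp)
    if (!identical(unname(as.integer(got)), unname(as.integer(want)))) {
      mismatches <- mismatches + 1
      if (is.null(first_bad)) first_bad <- b
    }
  }
  expect_equal(mismatches, 0,
               info = if (!is.null(first_bad))
                 paste(capture.output(print(first_bad)), collapse = "\n"))
})

test_that("classification matches the oracle on random dense configurations", {
  p <- damage_params()
  set.seed(40)
  for (rep in 1:400) {
    n <- sample(2:7, 1)
    b <- data.frame(chromosome = 1L,
                    strand = sample(0:1, n, replace = TRUE),
                    bp = sample(0:399, n),
                    source = sample(c("direct", "indirect"), n,
                                    replace = TRUE),
                    primary_id = 0L)
    b <- b[!duplicated(b[, c("strand", "bp")]), ]
    got <- tally_vector(classify_event(b, p))
    want <- oracle_classify(b, p$d_DSB_bp, p$d_s_bp)
    expect_equal(unname(got), unname(as.integer(want)),
                 info = paste(capture.output(print(b)), collapse = "\n"))
  }
})

test_that("adding a break never decreases the break or DSB totals", {
  p <- damage_params()
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    b <- data.frame(chromosome = 1L,
                    strand = sample(0:1, n, replace = TRUE),
                    bp = sample(0:399, n),
                    source = "direct", primary_id = 0L)
    b <- b[!duplicated(b[, c("strand", "bp")]), ]
    extra <- data.frame(chromosome = 1L, strand = sample(0:1, 1),
                        bp = sample(0:399, 1), source = "direct",
                        primary_id = 0L)
    b2 <- merge_breaks(b, extra)
    t1 <- classify_event(b, p)
    t2 <- classify_event(b2, p)
    expect_gte(t2$total_breaks, t1$total_breaks)
    expect_gte(nrow(t2$dsb_positions), nrow(t1$dsb_positions))
  }
})

test_that("cluster break multiplicities account for every break", {
  p <- damage_params()
  set.seed(42)
  for (rep in 1:80) {
    n <- sample(1:8, 1)
    b <- data.frame(chromosome = 1L,
                    strand = sample(0:1, n, replace = TRUE),
                    bp = sample(0:399, n),
                    source = sample(c("direct", "indirect"), n, TRUE),
                    primary_id = 0L)
    b <- b[!duplicated(b[, c("strand", "bp")]), ]
    t1 <- classify_event(b, p)
    expect_equal(sum(t1$clusters$n_breaks), nrow(b))
    expect_equal(t1$total_breaks, nrow(b))
    expect_equal(sum(t1$clusters$n_direct),
                 sum(b$source == "direct"))
  }
})

test_that("tally merging is associative bookkeeping", {
  p <- damage_params()
  t1 <- classify_event(rbind(brk(0, 100), brk(1, 105)), p)
  t2 <- classify_event(rbind(brk(0, 300, "indirect")), p)
  m <- merge_tallies(t1, t2)
  expect_equal(unname(m$counts[["DSB"]]), 1)
  expect_equal(unname(m$counts[["SSB"]]), 1)
  expect_equal(m$total_breaks, 3)
  m2 <- merge_tallies(list(t2, t1))
  expect_equal(m$counts, m2$counts)
})

test_that("fragment lengths partition each chromosome", {
  expect_equal(sort(fragment_lengths(c(300, 700), 1000)),
               sort(c(300, 400, 300)))
  expect_equal(fragment_lengths(numeric(0), 1000), 1000)
  dsb <- data.frame(chromosome = c(1L, 1L, 2L), pos = c(300, 700, 100))
  fl <- fragment_lengths(dsb, c("1" = 1000, "2" = 500))
  expect_equal(sum(fl), 1500)
  expect_length(fl, 5)
})

test_that("uniformly placed DSBs give order-statistics fragment spacings", {
  set.seed(43)
  L <- 1e6; n <- 5
  firsts <- replicate(1000, {
    pos <- sort(runif(n, 0, L))
    fragment_lengths(pos, L)[1]
  })
  # first fragment ~ Beta(1, n) scaled to L: P(X <= x) = 1 - (1 - x/L)^n
  ks <- stats::ks.test(firsts, function(x) 1 - (1 - x / L)^n)
  expect_gt(ks$p.value, 0.01)
})

test_that("distant DSBs merge below the detectability threshold", {
  expect_equal(distant_dsb_count(c(0, 5000, 50000)), 2L)
  expect_equal(distant_dsb_count(c(0, 10000, 50000)), 3L)  # >= 10 kbp apart
  expect_equal(distant_dsb_count(42), 1L)
  expect_equal(distant_dsb_count(numeric(0)), 0L)
  two <- data.frame(chromosome = c(1L, 2L), pos = c(0, 0))
  expect_equal(distant_dsb_count(two), 2L)
})

test_that("the scavengeable fraction is the indirect share of DSBs", {
  fake <- function(d, i, m, hyb) {
    cl <- data.frame(
      class = rep("DSB", d + i + m + hyb),
      start_bp = 0L, end_bp = 1L, n_breaks = 2L, n_direct = 0L,
      n_indirect = 0L,
      source = rep(c("d", "i", "m", "hyb"), c(d, i, m, hyb)))
    damage_tally(cl, total_breaks = 2 * nrow(cl))
  }
  expect_equal(scavengeable_fraction(fake(7, 3, 0, 0)), 0.3)
  expect_equal(scavengeable_fraction(fake(5, 0, 0, 0)), 0)
  expect_equal(scavengeable_fraction(fake(0, 4, 0, 0)), 1)
  expect_equal(scavengeable_fraction(fake(0, 2, 0, 2)), 1)
  expect_equal(scavengeable_fraction(fake(0, 2, 0, 2), include_hyb = FALSE),
               0.5)
  expect_true(is.na(scavengeable_fraction(damage_tally())))
})
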