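# Independent oracles the implementation is checked against. These are
# deliberately naive: brute-force scans, exhaustive enumeration, and a
# walk-on-spheres Brownian simulation, sharing no code with the package
# internals they test.

# brute-force fixed-radius neighbour scan
brute_radius <- function(pts, center, r) {
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2
  which(d2 <= r^2)
}

brute_nearest <- function(pts, center) {
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2
  i <- which.min(d2)
  list(id = i, dist = sqrt(d2[i]))
}

# Walk-on-spheres estimate of the probability that Brownian motion
# started at distance r0 hits the absorbing sphere of radius R before
# escaping far away. Each step jumps uniformly on the sphere of radius
# (r - R) around the walker (the exact harmonic measure for Laplace),
# absorbing within eps of the target and killing beyond R_out.
wos_absorption <- function(r0, R, n_walkers = 1e5, R_out = 500 * r0,
                           eps_frac = 1e-4, max_steps = 2000) {
  eps <- eps_frac * R
  pos <- matrix(rep(c(r0, 0, 0), each = n_walkers), ncol = 3)
  absorbed <- 0L
  steps <- 0
  while (nrow(pos) > 0 && steps < max_steps) {
    steps <- steps + 1
    r <- sqrt(rowSums(pos^2))
    hit <- r - R < eps
    gone <- r > R_out
    absorbed <- absorbed + sum(hit)
    keep <- !hit & !gone
    pos <- pos[keep, , drop = FALSE]
    if (nrow(pos) == 0) break
    r <- r[keep]
    g <- matrix(rnorm(3 * nrow(pos)), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    pos <- pos + (r - R) * g
  }
  absorbed / n_walkers
}

# ---- exhaustive damage-classification oracle -----------------------------
# Enumerates every matching of opposite-strand break pairs within d_dsb,
# keeps the maximum-size matchings, picks the lexicographically smallest
# (leftmost) one, then applies the published clustering rules in
# straight-line code. Returns a named count vector comparable across
# implementations.

oracle_classify <- function(breaks, d_dsb = 10, d_s = 100) {
  ord <- order(breaks$bp, breaks$strand)
  b <- breaks[ord, , drop = FALSE]
  n <- nrow(b)
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (b$strand[i] != b$strand[j] && abs(b$bp[i] - b$bp[j]) <= d_dsb)
          pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  best <- list(size = -1L, key = NULL, sel = integer())
  rec <- function(k, used, chosen) {
    if (k > length(pairs)) {
      size <- length(chosen)
      key <- if (size) unlist(lapply(chosen, function(ci) pairs[[ci]]))
      else integer()
      if (size > best$size ||
          (size == best$size && size > 0 &&
           lex_less(key, best$key))) {
        best <<- list(size = size, key = key, sel = chosen)
      }
      return()
    }
    pr <- pairs[[k]]
    if (!used[pr[1]] && !used[pr[2]]) {
      used2 <- used
      used2[pr] <- TRUE
      rec(k + 1, used2, c(chosen, k))
    }
    rec(k + 1, used, chosen)
  }
  rec(1L, rep(FALSE, n), integer())
  sel <- best$sel
  dsb <- do.call(rbind, lapply(sel, function(ci) pairs[[ci]]))
  # order DSBs by midpoint
  if (!is.null(dsb)) {
    pos <- floor((b$bp[dsb[, 1]] + b$bp[dsb[, 2]]) / 2)
    o <- order(pos, b$bp[dsb[, 1]])
    dsb <- dsb[o, , drop = FALSE]
    pos <- pos[o]
  } else pos <- numeric()
  in_core <- rep(FALSE, n)
  if (!is.null(dsb)) in_core[as.vector(dsb)] <- TRUE
  free <- which(!in_core)
  # accessory attachment
  acc_of <- rep(NA_integer_, n)
  if (!is.null(dsb)) {
    for (u in free) {
      dd <- sapply(seq_len(nrow(dsb)), function(k)
        min(abs(b$bp[u] - b$bp[dsb[k, 1]]), abs(b$bp[u] - b$bp[dsb[k, 2]])))
      ok <- which(dd <= d_dsb)
      if (length(ok)) acc_of[u] <- ok[which.min(dd[ok])]
    }
  }
  free <- free[is.na(acc_of[free])]
  counts <- c("SSB" = 0L, "SSB+" = 0L, "2SSB" = 0L,
              "DSB" = 0L, "DSB+" = 0L, "DSB++" = 0L)
  src <- c(SSB_d = 0L, SSB_i = 0L, SSB_m = 0L,
           DSB_d = 0L, DSB_i = 0L, DSB_m = 0L, DSB_hyb = 0L)
  label_of <- function(all_src, core_src, dsb_kind) {
    if (all(all_src == "direct")) "d"
    else if (all(all_src == "indirect")) "i"
    else if (dsb_kind && all(core_src == "indirect")) "hyb"
    else "m"
  }
  nd <- if (is.null(dsb)) 0L else nrow(dsb)
  k <- 1L
  while (k <= nd) {
    if (k < nd && pos[k + 1] - pos[k] <= d_s) { members <- c(k, k + 1); cls <- "DSB++" }
    else { members <- k; cls <- NA }
    core_idx <- as.vector(dsb[members, , drop = FALSE])
    acc_idx <- which(!is.na(acc_of) & acc_of %in% members)
    if (is.na(cls)) cls <- if (length(acc_idx)) "DSB+" else "DSB"
    counts[cls] <- counts[cls] + 1L
    lab <- label_of(b$source[c(core_idx, acc_idx)], b$source[core_idx], TRUE)
    src[paste0("DSB_", lab)] <- src[paste0("DSB_", lab)] + 1L
    k <- k + length(members)
  }
  free <- free[order(b$bp[free])]
  m <- length(free)
  k <- 1L
  while (k <= m) {
    if (k < m && b$bp[free[k + 1]] - b$bp[free[k]] <= d_s) {
      two <- free[c(k, k + 1)]
      cls <- if (b$strand[two[1]] == b$strand[two[2]]) "SSB+" else "2SSB"
      counts[cls] <- counts[cls] + 1L
      lab <- label_of(b$source[two], b$source[two], FALSE)
      src[paste0("SSB_", lab)] <- src[paste0("SSB_", lab)] + 1L
      k <- k + 2L
    } else {
      counts["SSB"] <- counts["SSB"] + 1L
      lab <- label_of(b$source[free[k]], b$source[free[k]], FALSE)
      src[paste0("SSB_", lab)] <- src[paste0("SSB_", lab)] + 1L
      k <- k + 1L
    }
  }
  c(counts, src)
}

lex_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (i in seq_len(min(la, lb))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}

# package tally -> the oracle's comparable vector
tally_vector <- function(tally) {
  c(tally$counts, tally$sources)
}
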