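# SSB/DSB complexity classification.
#
# Complexity taxonomy: a DSB is two opposite-strand breaks within d_DSB bp
# of each other; a DSB plus at least one more break within d_DSB is a
# DSB+; two DSBs within the fragment gap d_s form one DSB++ cluster. Of
# the breaks that end up in no DSB, two on the same strand within d_s are
# an SSB+, two on opposite strands (necessarily farther than d_DSB apart)
# within d_s are a 2SSB, and isolated breaks are plain SSBs. Every cluster
# also carries a source label: d (all direct), i (all indirect), m
# (mixed); a DSB whose core pair is purely indirect but which carries
# direct accessory breaks is the hybrid class DSB_hyb.

#' Classify the strand breaks of one primary particle
#'
#' Runs the canonical per-chromosome classification: (1) opposite-strand
#' breaks within `d_DSB` are paired into the maximal number of DSBs,
#' leftmost-first among optima (greedy earliest-partner matching, which is
#' optimal for this interval structure); (2) leftover breaks within
#' `d_DSB` of a DSB attach to it as accessory damage; (3) DSBs within
#' `d_s` of each other pair into DSB++ clusters, remaining DSBs become
#' DSB+ (with accessories) or DSB; (4) the still-unassigned breaks are
#' clustered pairwise into SSB+ / 2SSB within `d_s`, the rest are SSBs.
#' Breaks on different chromosomes are never clustered together.
#'
#' @param breaks strand-break data frame (`chromosome`, `strand`, `bp`,
#'   `source`); normally the merged direct + indirect breaks of a single
#'   primary.
#' @param params a [damage_params()].
#' @return a `damage_tally`; see [damage_tally()].
#' @export
classify_event <- function(breaks, params = damage_params()) {
  breaks <- merge_breaks(breaks)
  clusters <- list()
  dsb_pos <- list()
  for (chrom in sort(unique(breaks$chromosome))) {
    b <- breaks[breaks$chromosome == chrom, , drop = FALSE]
    res <- classify_chromosome(b, params$d_DSB_bp, params$d_s_bp)
    if (nrow(res$clusters)) {
      res$clusters$chromosome <- chrom
      clusters[[length(clusters) + 1]] <- res$clusters
    }
    if (length(res$dsb_pos))
      dsb_pos[[length(dsb_pos) + 1]] <-
        data.frame(chromosome = chrom, pos = res$dsb_pos)
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else NULL
  dp <- if (length(dsb_pos)) do.call(rbind, dsb_pos) else
    data.frame(chromosome = integer(), pos = numeric())
  damage_tally(cl, total_breaks = nrow(breaks), dsb_positions = dp)
}

classify_chromosome <- function(b, d_dsb, d_s) {
  ord <- order(b$bp, b$strand)
  b <- b[ord, , drop = FALSE]
  n <- nrow(b)
  matched <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(matched[i])) next
    cand <- which(is.na(matched) & b$strand != b$strand[i] &
                    abs(b$bp - b$bp[i]) <= d_dsb)
    cand <- cand[cand != i]
    if (length(cand)) {
      j <- cand[1]
      matched[i] <- j
      matched[j] <- i
    }
  }
  cores <- which(!is.na(matched) & seq_len(n) < matched)
  dsbs <- data.frame(i = cores, j = matched[cores])
  if (nrow(dsbs)) {
    dsbs$lo <- b$bp[dsbs$i]
    dsbs$hi <- b$bp[dsbs$j]
    dsbs$pos <- floor((dsbs$lo + dsbs$hi) / 2)
    dsbs <- dsbs[order(dsbs$pos, dsbs$lo), , drop = FALSE]
  }
  free <- which(is.na(matched))
  # accessory attachment: free breaks within d_dsb of a DSB core
  accessory <- rep(NA_integer_, n)   # index into dsbs rows
  if (nrow(dsbs)) {
    for (u in free) {
      dd <- pmin(abs(b$bp[u] - dsbs$lo), abs(b$bp[u] - dsbs$hi))
      k <- which(dd <= d_dsb)
      if (length(k)) accessory[u] <- k[which.min(dd[k])]
    }
  }
  free <- free[is.na(accessory[free])]
  # DSB++ pairing among DSBs, greedy leftmost
  nd <- nrow(dsbs)
  dsb_cluster <- integer(nd)
  cl_list <- list()
  k <- 1L
  while (k <= nd) {
    if (k < nd && (dsbs$pos[k + 1] - dsbs$pos[k]) <= d_s) {
      cl_list[[length(cl_list) + 1]] <- list(kind = "DSB++", dsb = c(k, k + 1))
      k <- k + 2L
    } else {
      cl_list[[length(cl_list) + 1]] <- list(kind = "single", dsb = k)
      k <- k + 1L
    }
  }
  rows <- list()
  for (cl in cl_list) {
    core_idx <- unlist(dsbs[cl$dsb, c("i", "j")])
    acc_idx <- which(accessory %in% cl$dsb)
    cls <- if (identical(cl$kind, "DSB++")) "DSB++" else
      if (length(acc_idx)) "DSB+" else "DSB"
    rows[[length(rows) + 1]] <- cluster_row(b, core_idx, acc_idx, cls)
  }
  # SSB-kind clustering of remaining free breaks (pairwise, leftmost)
  free <- free[order(b$bp[free])]
  m <- length(free)
  k <- 1L
  while (k <= m) {
    if (k < m && (b$bp[free[k + 1]] - b$bp[free[k]]) <= d_s) {
      pair <- free[c(k, k + 1)]
      cls <- if (b$strand[pair[1]] == b$strand[pair[2]]) "SSB+" else "2SSB"
      rows[[length(rows) + 1]] <- cluster_row(b, pair, integer(), cls)
      k <- k + 2L
    } else {
      rows[[length(rows) + 1]] <- cluster_row(b, free[k], integer(), "SSB")
      k <- k + 1L
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), start_bp = integer(),
               end_bp = integer(), n_breaks = integer(),
               n_direct = integer(), n_indirect = integer(),
               source = character())
  list(clusters = clusters, dsb_pos = if (nrow(dsbs)) dsbs$pos else numeric())
}

cluster_row <- function(b, core_idx, acc_idx, cls) {
  all_idx <- c(core_idx, acc_idx)
  src <- b$source[all_idx]
  core_src <- b$source[core_idx]
  label <- if (all(src == "direct")) "d"
  else if (all(src == "indirect")) "i"
  else if (cls %in% c("DSB", "DSB+", "DSB++") &&
           all(core_src == "indirect")) "hyb"
  else "m"
  data.frame(class = cls,
             start_bp = min(b$bp[all_idx]),
             end_bp = max(b$bp[all_idx]),
             n_breaks = length(all_idx),
             n_direct = sum(src == "direct"),
             n_indirect = sum(src == "indirect"),
             source = label)
}

#' Damage tally
#'
#' Aggregated per-event damage bookkeeping: counts per complexity class,
#' source-split counts, total break count and the genomic positions of all
#' individual DSBs (a DSB++ cluster contributes two).
#'
#' @param clusters cluster data frame from the classifier (or `NULL`).
#' @param total_breaks total number of (deduplicated) strand breaks.
#' @param dsb_positions data frame `chromosome`, `pos`.
#' @return a `damage_tally` with elements `counts` (named: SSB, SSB+,
#'   2SSB, DSB, DSB+, DSB++), `sources` (named: SSB_d/i/m, DSB_d/i/m/hyb),
#'   `total_breaks`, `dsb_positions`, `clusters`.
#' @export
damage_tally <- function(clusters = NULL, total_breaks = 0,
                         dsb_positions = data.frame(chromosome = integer(),
                                                    pos = numeric())) {
  classes <- c("SSB", "SSB+", "2SSB", "DSB", "DSB+", "DSB++")
  counts <- setNames(integer(6), classes)
  sources <- setNames(integer(7), c("SSB_d", "SSB_i", "SSB_m",
                                    "DSB_d", "DSB_i", "DSB_m", "DSB_hyb"))
  if (!is.null(clusters) && nrow(clusters)) {
    tb <- table(factor(clusters$class, levels = classes))
    counts[] <- as.integer(tb)
    ssb_kind <- clusters$class %in% c("SSB", "SSB+", "2SSB")
    for (lab in c("d", "i", "m"))
      sources[paste0("SSB_", lab)] <-
        sum(ssb_kind & clusters$source == lab)
    for (lab in c("d", "i", "m", "hyb"))
      sources[paste0("DSB_", lab)] <-
        sum(!ssb_kind & clusters$source == lab)
  }
  structure(list(counts = counts, sources = sources,
                 total_breaks = as.integer(total_breaks),
                 dsb_positions = dsb_positions,
                 clusters = clusters %||%
                   data.frame(class = character(), start_bp = integer(),
                              end_bp = integer(), n_breaks = integer(),
                              n_direct = integer(), n_indirect = integer(),
                              source = character(),
                              chromosome = integer())),
            class = "damage_tally")
}

#' Sum damage tallies
#'
#' Aggregates per-primary tallies into run totals; associative and
#' order-independent.
#'
#' @param ... `damage_tally` objects or a single list of them.
#' @return the aggregate `damage_tally`.
#' @export
merge_tallies <- function(...) {
  ts <- list(...)
  if (length(ts) == 1 && !inherits(ts[[1]], "damage_tally")) ts <- ts[[1]]
  stopifnot(length(ts) > 0)
  out <- ts[[1]]
  for (t2 in ts[-1]) {
    out$counts <- out$counts + t2$counts
    out$sources <- out$sources + t2$sources
    out$total_breaks <- out$total_breaks + t2$total_breaks
    out$dsb_positions <- rbind(out$dsb_positions, t2$dsb_positions)
    out$clusters <- rbind(out$clusters, t2$clusters)
  }
  out
}

#' @export
print.damage_tally <- function(x, ...) {
  cat("<damage_tally>", x$total_breaks, "strand breaks\n")
  print(x$counts)
  cat("sources:\n")
  print(x$sources)
  invisible(x)
}

#' Fragment lengths between DSBs
#'
#' The sorted DSB positions of each chromosome partition `[0, L)`;
#' fragment lengths are the successive differences including both end
#' fragments. A chromosome with no DSB contributes one fragment of its
#' full length.
#'
#' @param dsb_positions data frame `chromosome`, `pos` (bp), or a bare
#'   numeric vector of positions for a single chromosome.
#' @param chromosome_lengths numeric vector of chromosome lengths (bp),
#'   indexed (or named) by chromosome id; a single value when
#'   `dsb_positions` is a bare vector.
#' @return numeric vector of fragment lengths, bp.
#' @export
fragment_lengths <- function(dsb_positions, chromosome_lengths) {
  if (!is.data.frame(dsb_positions))
    dsb_positions <- data.frame(chromosome = rep(1L, length(dsb_positions)),
                                pos = dsb_positions)
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- seq_along(chromosome_lengths)
  out <- numeric(0)
  for (ch in names(chromosome_lengths)) {
    L <- chromosome_lengths[[ch]]
    pos <- sort(dsb_positions$pos[dsb_positions$chromosome == as.integer(ch)])
    out <- c(out, diff(c(0, pos, L)))
  }
  out
}

#' Count distant (detectable) DSB clusters
#'
#' DSBs separated from their predecessor by less than the threshold merge
#' into the same detectable cluster, mimicking the resolution limit of
#' gel-electrophoresis fragment counting; clusters whose members are "at
#' least `threshold` apart" stay distinct.
#'
#' @param dsb_positions data frame `chromosome`, `pos`, or a numeric
#'   vector for one chromosome.
#' @param threshold_bp merging threshold, bp (default 10 kbp).
#' @return integer cluster count.
#' @export
distant_dsb_count <- function(dsb_positions, threshold_bp = 10000) {
  if (!is.data.frame(dsb_positions))
    dsb_positions <- data.frame(chromosome = rep(1L, length(dsb_positions)),
                                pos = dsb_positions)
  if (nrow(dsb_positions) == 0) return(0L)
  total <- 0L
  for (ch in unique(dsb_positions$chromosome)) {
    pos <- sort(dsb_positions$pos[dsb_positions$chromosome == ch])
    total <- total + 1L + sum(diff(pos) >= threshold_bp)
  }
  total
}

#' Scavengeable (protectable) damage fraction
#'
#' Share of DSB-kind clusters attributable to indirect action, i.e. the
#' damage an OH scavenger could prevent:
#' `(DSB_i + DSB_hyb) / (DSB_d + DSB_i + DSB_m + DSB_hyb)`. Hybrid DSBs
#' have an indirect core pair, so they count as protectable by default.
#'
#' @param tally a `damage_tally`.
#' @param include_hyb count DSB_hyb in the numerator.
#' @return fraction in `[0, 1]`, or `NA` when the tally holds no DSBs.
#' @export
scavengeable_fraction <- function(tally, include_hyb = TRUE) {
  s <- tally$sources
  denom <- s[["DSB_d"]] + s[["DSB_i"]] + s[["DSB_m"]] + s[["DSB_hyb"]]
  if (denom == 0) return(NA_real_)
  num <- s[["DSB_i"]] + if (include_hyb) s[["DSB_hyb"]] else 0
  num / denom
}
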