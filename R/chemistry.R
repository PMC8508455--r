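#' Diffusion-controlled reaction channel
#'
#' Channels are treated as fully diffusion-controlled: a rate constant k
#' (M^-1 s^-1) maps to an encounter radius
#' `R_eff = k / (4 pi D_rel N_A)` (in consistent units), and a pair at
#' separation `r0` reacts with ultimate probability `R_eff / r0`. Either
#' the rate or the encounter radius can be given directly.
#'
#' Reactants are species names, or for species-DNA channels the moiety
#' targets `"backbone"` (sugar + phosphate) and `"histone"`.
#'
#' @param a,b reactant names.
#' @param rate rate constant, M^-1 s^-1 (used when `R_eff` is `NULL`).
#' @param R_eff encounter radius, nm.
#' @param D_rel relative diffusion coefficient, nm^2/ns (needed to derive
#'   `R_eff` from `rate`).
#' @param products product species names (informational; products are not
#'   propagated further).
#' @param enabled logical; disabled channels are skipped by the engine.
#' @return a `reaction_channel`.
#' @export
reaction_channel <- function(a, b, rate = NULL, R_eff = NULL, D_rel = NULL,
                             products = character(), enabled = TRUE) {
  if (is.null(R_eff)) {
    if (is.null(rate) || is.null(D_rel))
      stop("give either R_eff, or rate plus D_rel")
    # (M^-1 s^-1) -> nm^3/ns per molecule pair: 1e24 / (N_A * 1e9)
    k_nm <- rate * 1e24 / (6.02214076e23 * 1e9)
    R_eff <- k_nm / (4 * pi * D_rel)
  }
  if (R_eff <= 0) stop("encounter radius must be > 0")
  structure(list(a = a, b = b, rate = rate, R_eff = R_eff,
                 products = products, enabled = enabled),
            class = "reaction_channel")
}

#' Default reaction channel table
#'
#' The hydroxyl-radical attack on the sugar-phosphate backbone is the only
#' channel enabled by default (encounter radius 0.2 nm, a configurable
#' surrogate); histone scavenging removes any species on contact with a
#' histone sphere; radical-radical recombination channels with standard
#' aqueous rate constants are included but disabled by default.
#'
#' @param diffusion named diffusion table, nm^2/ns.
#' @param radical_radical enable the species-species recombination
#'   channels.
#' @param histone_radius_nm contact radius for histone scavenging.
#' @return list of [reaction_channel()]s.
#' @export
default_channels <- function(diffusion = default_diffusion_table(),
                             radical_radical = FALSE,
                             histone_radius_nm = 2.4) {
  ch <- list(
    reaction_channel("OH", "backbone", R_eff = 0.2),
    reaction_channel("OH", "histone", R_eff = histone_radius_nm),
    reaction_channel("e_aq", "histone", R_eff = histone_radius_nm),
    reaction_channel("H", "histone", R_eff = histone_radius_nm))
  rr <- list(
    reaction_channel("OH", "OH", rate = 5.5e9,
                     D_rel = 2 * diffusion[["OH"]],
                     products = "H2O2", enabled = radical_radical),
    reaction_channel("OH", "e_aq", rate = 3.0e10,
                     D_rel = diffusion[["OH"]] + diffusion[["e_aq"]],
                     products = "OHm", enabled = radical_radical),
    reaction_channel("OH", "H", rate = 7.0e9,
                     D_rel = diffusion[["OH"]] + diffusion[["H"]],
                     products = character(), enabled = radical_radical),
    reaction_channel("e_aq", "e_aq", rate = 5.5e9,
                     D_rel = 2 * diffusion[["e_aq"]],
                     products = c("H2", "OHm"), enabled = radical_radical),
    reaction_channel("e_aq", "H3O", rate = 2.3e10,
                     D_rel = diffusion[["e_aq"]] + diffusion[["H3O"]],
                     products = "H", enabled = radical_radical))
  c(ch, rr)
}

#' Sample an independent reaction time for one pair
#'
#' Implements the IRT primitive: for a pair at separation `r0` with
#' encounter radius `R_eff` and relative diffusion `D_rel`, the ultimate
#' reaction probability is `W_inf = R_eff / r0` and, conditional on
#' reacting, the time is obtained by inverting
#' `W(t) = (R_eff/r0) * erfc((r0 - R_eff) / sqrt(4 D_rel t))`
#' at the uniform deviate `u`. Pairs already in contact (`r0 <= R_eff`)
#' react at t = 0.
#'
#' @param r0 initial separations, nm (vectorised).
#' @param R_eff encounter radius, nm.
#' @param D_rel relative diffusion coefficient, nm^2/ns.
#' @param u uniform(0,1) deviates, one per pair; drawn internally when
#'   `NULL`.
#' @return reaction times in ns; `Inf` marks "no reaction, ever".
#' @export
irt_sample_pair <- function(r0, R_eff, D_rel, u = NULL) {
  stopifnot(all(R_eff > 0), all(D_rel > 0))
  n <- length(r0)
  R_eff <- rep_len(R_eff, n)
  D_rel <- rep_len(D_rel, n)
  if (is.null(u)) u <- runif(n)
  t_out <- rep(Inf, n)
  contact <- r0 <= R_eff
  t_out[contact] <- 0
  react <- !contact & u < R_eff / r0
  if (any(react)) {
    z <- erfcinv(u[react] * r0[react] / R_eff[react])
    t_out[react] <- ((r0[react] - R_eff[react]) /
                       (2 * sqrt(D_rel[react]) * z))^2
  }
  t_out
}

#' Remove species born beyond the radical kill distance
#'
#' Any species whose distance to the nearest DNA molecular volume
#' (surface distance: centre distance minus the volume's physical radius)
#' strictly exceeds `d_kill` is considered scavenged by the bulk medium
#' and removed at birth. A species exactly at `d_kill` is retained.
#'
#' @param species species data frame (see [spawn_species()]).
#' @param molecules DNA molecular volumes ([materialize_region()]); sugar,
#'   phosphate and base spheres are used as the reference surface.
#' @param d_kill kill distance, nm (Table-calibrated default 9 nm lives in
#'   [damage_params()]).
#' @return the surviving subset of `species`, with a `killed` attribute
#'   giving the removed count.
#' @export
apply_kill_distance <- function(species, molecules, d_kill, tree = NULL) {
  sel <- molecules$kind %in% c("sugar", "phosphate", "base")
  dna <- molecules[sel, ]
  if (nrow(species) == 0 || nrow(dna) == 0) {
    attr(species, "killed") <- 0L
    return(species)
  }
  if (is.null(tree)) tree <- build_octree(dna)
  near <- query_nearest(tree, species)
  surf <- near$dist - dna$radius[near$id]
  keep <- surf <= d_kill
  out <- species[keep, , drop = FALSE]
  attr(out, "killed") <- sum(!keep)
  out
}

#' Evolve radiolysis species with the IRT method
#'
#' The chemical stage runs from 0 to `T_chem` in synchronisation windows
#' of length at most `dt_max`. Within each window, candidate pairs are
#' collected through octree queries (species vs DNA moieties) and pairwise
#' distances (species vs species); an independent reaction time is sampled
#' for every pair, and events earlier than the window end are processed
#' earliest-first, consuming their species. Survivors are moved by
#' Gaussian diffusion (variance `2 D dt` per axis) at the window boundary
#' and the next window re-samples from the new positions.
#'
#' @param species surviving species after [apply_kill_distance()].
#' @param molecules DNA molecular volumes for the region.
#' @param channels list of [reaction_channel()]s.
#' @param T_chem end of the chemical stage, ns.
#' @param dt_max maximum synchronisation window, ns.
#' @param search_factor octree search radius is
#'   `R_eff + search_factor * sqrt(D_rel * dt)`; beyond it the in-window
#'   reaction probability is negligible.
#' @param moiety_index optional precomputed [build_moiety_index()] over
#'   `molecules`.
#'
#' @details Every species owns a private RNG substream (seeded at spawn
#' time) from which its pair deviates and diffusion steps are drawn in a
#' canonical order. Because DNA and histones are static, a species'
#' chemistry is then independent of which *other* species survived the
#' kill distance, so enlarging `d_kill` can only add DNA-hit events at a
#' fixed master seed (as long as species-species channels stay disabled).
#' @return a list: `events` (data frame: `time_ns`, `channel`, `species_id`,
#'   `name`, `kind`, `chromosome`, `strand`, `bp`, `x`, `y`, `z`) and
#'   `survivors` (species data frame at `T_chem`).
#' @export
evolve_chemistry <- function(species, molecules, channels = default_channels(),
                             T_chem = 5, dt_max = 0.5, search_factor = 8,
                             moiety_index = NULL) {
  if (T_chem <= 0 || dt_max <= 0) stop("T_chem and dt_max must be > 0")
  channels <- Filter(function(ch) isTRUE(ch$enabled), channels)
  empty_ev <- data.frame(time_ns = numeric(), channel = character(),
                         species_id = integer(), name = character(),
                         kind = character(), chromosome = integer(),
                         strand = integer(), bp = integer(),
                         x = numeric(), y = numeric(), z = numeric())
  if (nrow(species) == 0 || length(channels) == 0)
    return(list(events = empty_ev, survivors = species))
  is_dna_target <- function(b) b %in% c("backbone", "histone")
  if (is.null(moiety_index)) moiety_index <- build_moiety_index(molecules)
  moiety_rows <- moiety_index$rows
  trees <- moiety_index$trees
  alive <- species
  if (!"rng" %in% names(alive))
    alive$rng <- sample.int(2147483646L, nrow(alive), replace = TRUE)
  events <- list()
  t_now <- 0
  window <- 0L
  while (t_now < T_chem && nrow(alive) > 0) {
    window <- window + 1L
    dt <- min(dt_max, T_chem - t_now)
    cand <- list()
    for (ci in seq_along(channels)) {
      ch <- channels[[ci]]
      if (is_dna_target(ch$b)) {
        if (is.null(trees[[ch$b]])) next
        rows_a <- which(alive$name == ch$a)
        if (length(rows_a) == 0) next
        D_rel <- alive$D[rows_a][1]
        r_search <- ch$R_eff + search_factor * sqrt(D_rel * dt)
        hits <- query_radius(trees[[ch$b]],
                             as.matrix(alive[rows_a, c("x", "y", "z")]),
                             r_search)
        na <- lengths(hits)
        if (sum(na) == 0) next
        ai <- rep(rows_a, na)
        mi <- moiety_rows[[ch$b]][unlist(hits)]
        r0 <- sqrt((alive$x[ai] - molecules$x[mi])^2 +
                     (alive$y[ai] - molecules$y[mi])^2 +
                     (alive$z[ai] - molecules$z[mi])^2)
        cand[[length(cand) + 1]] <- data.frame(
          channel = ci, i = ai, j = NA_integer_, mol = mi,
          r0 = r0, R_eff = ch$R_eff, D_rel = D_rel)
      } else {
        rows_a <- which(alive$name == ch$a)
        rows_b <- which(alive$name == ch$b)
        if (length(rows_a) == 0 || length(rows_b) == 0) next
        D_rel <- alive$D[rows_a][1] + alive$D[rows_b][1]
        r_search <- ch$R_eff + search_factor * sqrt(D_rel * dt)
        prs <- close_pairs(alive, rows_a, rows_b, r_search)
        if (nrow(prs) == 0) next
        r0 <- sqrt((alive$x[prs$i] - alive$x[prs$j])^2 +
                     (alive$y[prs$i] - alive$y[prs$j])^2 +
                     (alive$z[prs$i] - alive$z[prs$j])^2)
        cand[[length(cand) + 1]] <- data.frame(
          channel = ci, i = prs$i, j = prs$j, mol = NA_integer_,
          r0 = r0, R_eff = ch$R_eff, D_rel = D_rel)
      }
    }
    cand <- if (length(cand)) do.call(rbind, cand) else NULL
    # draw uniforms and diffusion steps from each species' own stream,
    # pairs taken in canonical order
    if (!is.null(cand))
      cand <- cand[order(cand$i, cand$channel, cand$mol, cand$j), ,
                   drop = FALSE]
    n_alive <- nrow(alive)
    diff_step <- matrix(0, n_alive, 3)
    u <- if (!is.null(cand)) numeric(nrow(cand)) else numeric(0)
    cand_of <- if (!is.null(cand))
      split(seq_len(nrow(cand)), factor(cand$i, levels = seq_len(n_alive)))
    for (i in seq_len(n_alive)) {
      set.seed(as.integer((as.double(alive$rng[i]) * 69069 + window) %%
                            2147483629))
      ki <- cand_of[[i]]
      if (length(ki)) u[ki] <- runif(length(ki))
      diff_step[i, ] <- rnorm(3)
    }
    if (!is.null(cand)) {
      cand$t <- irt_sample_pair(cand$r0, cand$R_eff, cand$D_rel, u)
      cand <- cand[cand$t <= dt, , drop = FALSE]
    }
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- cand[order(cand$t), , drop = FALSE]
      consumed <- rep(FALSE, nrow(alive))
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (consumed[i]) next
        if (!is.na(j) && consumed[j]) next
        consumed[i] <- TRUE
        if (!is.na(j)) consumed[j] <- TRUE
        ch <- channels[[cand$channel[k]]]
        mi <- cand$mol[k]
        events[[length(events) + 1]] <- data.frame(
          time_ns = t_now + cand$t[k],
          channel = paste(ch$a, ch$b, sep = "+"),
          species_id = alive$species_id[i],
          name = alive$name[i],
          kind = if (!is.na(mi)) molecules$kind[mi] else alive$name[j],
          chromosome = if (!is.na(mi)) molecules$chromosome[mi] else NA_integer_,
          strand = if (!is.na(mi)) molecules$strand[mi] else NA_integer_,
          bp = if (!is.na(mi)) molecules$bp[mi] else NA_integer_,
          x = alive$x[i], y = alive$y[i], z = alive$z[i])
      }
      keep <- !consumed
      alive <- alive[keep, , drop = FALSE]
      diff_step <- diff_step[keep, , drop = FALSE]
    }
    if (nrow(alive) > 0) {             # diffuse survivors to window end
      sdv <- sqrt(2 * alive$D * dt)
      alive$x <- alive$x + diff_step[, 1] * sdv
      alive$y <- alive$y + diff_step[, 2] * sdv
      alive$z <- alive$z + diff_step[, 3] * sdv
    }
    t_now <- t_now + dt
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_ev
  ev <- ev[order(ev$time_ns), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, survivors = alive)
}

#' Spatial index over the reactive DNA moieties
#'
#' Precomputes the row sets and octrees used by [evolve_chemistry()]
#' (backbone = sugar + phosphate; histone) and by
#' [apply_kill_distance()] (`dna` tree over sugar/phosphate/base), so
#' repeated chemistry runs over the same molecules share one index.
#'
#' @param molecules molecular-volume data frame.
#' @return list with `rows` (row indices per moiety) and `trees`.
#' @export
build_moiety_index <- function(molecules) {
  rows <- list(
    backbone = which(molecules$kind %in% c("sugar", "phosphate")),
    histone = which(molecules$kind == "histone"),
    dna = which(molecules$kind %in% c("sugar", "phosphate", "base")))
  trees <- list()
  for (m in names(rows))
    if (length(rows[[m]]) > 0)
      trees[[m]] <- build_octree(molecules[rows[[m]], ])
  list(rows = rows, trees = trees)
}

# unordered close pairs between two index sets (brute force; species
# populations per primary are small)
close_pairs <- function(alive, rows_a, rows_b, r_max) {
  same <- identical(rows_a, rows_b)
  ij <- expand.grid(i = rows_a, j = rows_b)
  ij <- ij[ij$i != ij$j, , drop = FALSE]
  if (same) ij <- ij[ij$i < ij$j, , drop = FALSE]
  if (nrow(ij) == 0) return(data.frame(i = integer(), j = integer()))
  d2 <- (alive$x[ij$i] - alive$x[ij$j])^2 +
    (alive$y[ij$i] - alive$y[ij$j])^2 +
    (alive$z[ij$i] - alive$z[ij$j])^2
  ij[d2 <= r_max^2, , drop = FALSE]
}

#' Extract hydroxyl-radical backbone hits
#'
#' Filters a chemistry event log down to the OH + sugar-phosphate
#' reactions, the only channel that can induce indirect strand breaks,
#' keeping the genomic address of the attacked backbone group.
#'
#' @param events the `events` element of [evolve_chemistry()].
#' @return data frame: `chromosome`, `strand`, `bp`, `time_ns`.
#' @export
dna_hit_events <- function(events) {
  sel <- events$channel == "OH+backbone" &
    events$kind %in% c("sugar", "phosphate")
  out <- events[sel, c("chromosome", "strand", "bp", "time_ns")]
  rownames(out) <- NULL
  out
}

#' Diffusion time to the kill distance
#'
#' The kill distance and the chemical-stage end time are linked by the
#' time an OH radical needs to diffuse `d_kill`: by the 3-D mean-squared
#' displacement, `t = d_kill^2 / (6 D_OH)`. A warning is emitted when this
#' differs from `T_chem` by more than 50%, signalling an inconsistent
#' parameter pair.
#'
#' @param d_kill kill distance, nm.
#' @param D_OH OH diffusion coefficient, nm^2/ns.
#' @param T_chem chemical-stage end time to check against, ns (`NULL`
#'   skips the check).
#' @return the diffusion time, ns.
#' @export
consistency_check_kill_time <- function(d_kill, D_OH = 2.8, T_chem = NULL) {
  t_diff <- d_kill^2 / (6 * D_OH)
  if (!is.null(T_chem) && T_chem > 0) {
    if (abs(t_diff - T_chem) / T_chem > 0.5)
      warning(sprintf(
        "kill-distance diffusion time %.2f ns differs from T_chem %.2f ns by more than 50%%",
        t_diff, T_chem))
  }
  t_diff
}
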