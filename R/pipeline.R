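# Run orchestration: per-primary seeding, the damage chain for one
# primary, whole-run aggregation, file-based stages and split merging.

#' Per-primary random seed
#'
#' Every primary particle owns an RNG stream seeded deterministically from
#' the master seed and the primary id, so a run split into k jobs
#' reproduces exactly the tallies of the unsplit run.
#'
#' @param master_seed integer master seed.
#' @param primary_id 0-based primary index.
#' @return integer seed below 2^31.
#' @export
primary_seed <- function(master_seed, primary_id) {
  as.integer((as.double(master_seed %% 94906249L) * 22695477 +
                as.double(primary_id) * 1103515245) %% 2147483647)
}

#' Simulate the full damage chain for one primary particle
#'
#' Under the primary's own RNG stream: samples the entry point, generates
#' energy deposits along the nucleus chord, spawns radiolysis species,
#' applies the kill distance, evolves the IRT chemistry, scores direct and
#' indirect breaks, and classifies them. DNA is materialised only in the
#' corridor of voxels around the track, which keeps memory flat in the
#' number of primaries.
#'
#' @param model a [genome_model()].
#' @param beam a [beam_config()].
#' @param cfg configuration list ([default_config()] shape).
#' @param primary_id 0-based id.
#' @param master_seed master seed.
#' @param cache optional environment used to memoise voxel
#'   materialisation across primaries of one run.
#' @return list: `tally` (a `damage_tally`), `breaks`, `n_deposits`,
#'   `n_species`, `n_hits`, `energy_eV`.
#' @export
simulate_primary <- function(model, beam, cfg, primary_id, master_seed,
                             cache = NULL) {
  set.seed(primary_seed(master_seed, primary_id))
  params <- config_damage_params(cfg)
  nucleus <- model$nucleus
  traj <- sample_primaries(modifyList(beam, list(n_primaries = 1L)), nucleus)
  traj$primary_id <- primary_id
  deposits <- generate_deposits(traj[1, ], beam, nucleus)
  out_empty <- list(tally = damage_tally(),
                    breaks = merge_breaks(),
                    n_deposits = nrow(deposits), n_species = 0L,
                    n_hits = 0L, energy_eV = sum(deposits$energy_eV))
  if (nrow(deposits) == 0) return(out_empty)
  molecules <- materialize_track_corridor(model, deposits, cfg, cache)
  midx <- corridor_moiety_index(molecules, cache)
  species <- spawn_species(deposits,
                           yield_table = unlist(cfg$chemistry$yield_table),
                           sigma_nm = cfg$chemistry$species_jitter_nm,
                           diffusion = unlist(cfg$chemistry$diffusion))
  hits <- data.frame(chromosome = integer(), strand = integer(),
                     bp = integer(), time_ns = numeric())
  if (nrow(molecules) > 0 && nrow(species) > 0) {
    survivors <- apply_kill_distance(species, molecules, params$d_kill_nm,
                                     tree = midx$trees$dna)
    chem <- evolve_chemistry(survivors, molecules,
                             channels = config_channels(cfg),
                             T_chem = params$T_chem_ns,
                             dt_max = params$dt_max_ns,
                             search_factor = cfg$chemistry$search_factor,
                             moiety_index = midx)
    hits <- dna_hit_events(chem$events)
  }
  direct <- score_direct(deposits, molecules, params, moiety_index = midx)
  indirect <- score_indirect(hits, params, primary_id = primary_id)
  breaks <- merge_breaks(direct, indirect)
  if (nrow(breaks)) breaks$primary_id <- primary_id
  list(tally = classify_event(breaks, params),
       breaks = breaks,
       n_deposits = nrow(deposits),
       n_species = nrow(species),
       n_hits = nrow(hits),
       energy_eV = sum(deposits$energy_eV))
}

# voxels within reach of any deposit of the track: kill distance +
# direct radius + diffusion margin
materialize_track_corridor <- function(model, deposits, cfg,
                                       cache = NULL) {
  margin <- cfg$damage$d_kill_nm + cfg$damage$R_direct_nm +
    3 * sqrt(2 * max(unlist(cfg$chemistry$diffusion)) * cfg$damage$T_chem_ns) +
    3 * cfg$chemistry$species_jitter_nm
  roi <- rbind(apply(deposits[, c("x", "y", "z")], 2, min) - margin,
               apply(deposits[, c("x", "y", "z")], 2, max) + margin)
  sel <- voxels_in_box(model, roi)
  if (nrow(sel) > 1) {
    # prune to voxels actually near a deposit (box distance test)
    lay <- model$layout
    ctr <- sweep((lay$cells[sel$path_index, , drop = FALSE] + 0.5) /
                   lay$n_side * 2 - 1, 2, lay$anisotropic_scale, "*")
    h <- voxel_half_extents(lay)
    dep <- as.matrix(deposits[, c("x", "y", "z")])
    tr <- build_octree(dep)
    near <- query_nearest(tr, ctr)
    reach <- margin + sqrt(sum((h)^2))
    sel <- sel[near$dist <= reach, , drop = FALSE]
  }
  mol <- materialize_voxels(model, sel, cache)
  attr(mol, "voxel_key") <- paste(sel$path_index, collapse = ",")
  mol
}

# memoise the moiety spatial index per corridor voxel set
corridor_moiety_index <- function(molecules, cache = NULL) {
  key <- attr(molecules, "voxel_key")
  if (is.null(cache) || is.null(key))
    return(build_moiety_index(molecules))
  store <- cache[["__moiety__"]]
  if (is.null(store)) {
    store <- new.env(parent = emptyenv())
    cache[["__moiety__"]] <- store
  }
  if (is.null(store[[key]])) store[[key]] <- build_moiety_index(molecules)
  store[[key]]
}

#' Run the damage chain for a whole beam
#'
#' Loops [simulate_primary()] over all primaries of the beam (damage is
#' classified per primary: breaks from different particles are never
#' clustered together) and aggregates the tallies.
#'
#' @param model a [genome_model()].
#' @param cfg configuration list.
#' @param seed master seed.
#' @param primary_ids which primaries to run (0-based); defaults to all
#'   `beam$n_primaries`, subsets are used for run splitting.
#' @return list: `tally` aggregate, `breaks` (all primaries), `per_primary`
#'   summary data frame.
#' @export
run_damage <- function(model, cfg, seed = 1L,
                       primary_ids = NULL) {
  beam <- config_beam(cfg)
  if (is.null(primary_ids)) primary_ids <- seq_len(beam$n_primaries) - 1L
  tallies <- list()
  brks <- list()
  summ <- list()
  cache <- new.env(parent = emptyenv())
  for (pid in primary_ids) {
    res <- simulate_primary(model, beam, cfg, pid, seed, cache = cache)
    tallies[[length(tallies) + 1]] <- res$tally
    brks[[length(brks) + 1]] <- res$breaks
    summ[[length(summ) + 1]] <- data.frame(
      primary_id = pid, n_deposits = res$n_deposits,
      n_species = res$n_species, n_hits = res$n_hits,
      energy_eV = res$energy_eV, n_breaks = nrow(res$breaks))
  }
  tally <- if (length(tallies)) merge_tallies(tallies) else damage_tally()
  breaks <- if (length(brks)) do.call(rbind, brks) else merge_breaks()
  list(tally = tally, breaks = breaks,
       per_primary = if (length(summ)) do.call(rbind, summ) else NULL)
}

#' Tally report as a plain list
#'
#' Per-class counts plus per-Gbp and per-Gy normalisations and the
#' SSB/DSB ratio, ready for JSON serialisation.
#'
#' @param tally a `damage_tally`.
#' @param genome_gbp genome size, Gbp.
#' @param dose_Gy dose, Gy (`NULL` skips per-Gy columns).
#' @return nested list.
#' @export
tally_report <- function(tally, genome_gbp = NULL, dose_Gy = NULL) {
  n_dsb <- nrow(tally$dsb_positions)
  n_ssb_breaks <- tally$total_breaks - 2L * n_dsb
  rep <- list(counts = as.list(tally$counts),
              sources = as.list(tally$sources),
              total_breaks = tally$total_breaks,
              n_dsb = n_dsb,
              ssb_dsb_ratio = if (n_dsb > 0) n_ssb_breaks / n_dsb else NA,
              scavengeable_fraction = scavengeable_fraction(tally),
              irreparable_yield = irreparable_yield(tally))
  if (!is.null(genome_gbp)) rep$dsb_per_gbp <- n_dsb / genome_gbp
  if (!is.null(dose_Gy) && dose_Gy > 0) rep$dsb_per_gy <- n_dsb / dose_Gy
  rep
}

#' Drive the staged pipeline on disk
#'
#' File-based stages chainable from intermediate artifacts:
#' `build-geometry` (geometry summary), `irradiate` (deposit events),
#' `chemistry` + `classify` (break records, tally report, SDD file) and
#' `repair` (time series). Every stage writes a manifest carrying the
#' master seed, primary count and configuration hash.
#'
#' @param cfg configuration list.
#' @param stage one of `"build-geometry"`, `"irradiate"`, `"classify"`,
#'   `"repair"`, `"report"`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param primary_ids optional subset for split runs.
#' @return the stage's main artifact, invisibly.
#' @export
run_pipeline <- function(cfg, stage, out_dir, seed = 1L,
                         primary_ids = NULL) {
  stage <- match.arg(stage, c("build-geometry", "irradiate", "classify",
                              "repair", "report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, config_hash = config_hash(cfg),
                   n_primaries = cfg$beam$n_primaries,
                   primary_ids = primary_ids,
                   package_version = as.character(utils::packageVersion("radbreak")))
  if (stage == "build-geometry") {
    model <- config_genome(cfg)
    out <- list(total_bp = count_genome_bp(model),
                retained_voxels = sum(model$layout$retained),
                chromosomes = model$nucleus$chromosomes)
    jsonlite::write_json(out, file.path(out_dir, "geometry.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(manifest, out_dir, stage)
    return(invisible(out))
  }
  if (stage == "irradiate") {
    model <- config_genome(cfg)
    beam <- config_beam(cfg)
    nucleus <- model$nucleus
    ids <- primary_ids %||% (seq_len(beam$n_primaries) - 1L)
    deps <- list()
    for (pid in ids) {
      set.seed(primary_seed(seed, pid))
      traj <- sample_primaries(modifyList(beam, list(n_primaries = 1L)),
                               nucleus)
      traj$primary_id <- pid
      deps[[length(deps) + 1]] <- generate_deposits(traj[1, ], beam, nucleus)
    }
    deposits <- do.call(rbind, deps)
    write.csv(deposits, file.path(out_dir, "deposits.csv"),
              row.names = FALSE)
    write_manifest(manifest, out_dir, stage)
    return(invisible(deposits))
  }
  if (stage == "classify") {
    model <- config_genome(cfg)
    res <- run_damage(model, cfg, seed = seed, primary_ids = primary_ids)
    write.csv(res$breaks, file.path(out_dir, "breaks.csv"),
              row.names = FALSE)
    saveRDS_free_tally(res$tally, out_dir)
    rep <- tally_report(res$tally,
                        genome_gbp = count_genome_bp(model) / 1e9,
                        dose_Gy = cfg$repair$dose_Gy)
    jsonlite::write_json(rep, file.path(out_dir, "tally.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    write_sdd(res$tally, sdd_header_info(cfg, model),
              file.path(out_dir, "damage.sdd"))
    write_manifest(manifest, out_dir, stage)
    return(invisible(res$tally))
  }
  if (stage == "repair") {
    tally <- read_tally_csv(out_dir)
    rp <- config_repair_params(cfg, N_ir = irreparable_yield(tally))
    state <- solve_repair(rp, t_end_h = cfg$repair$t_end_h,
                          dt_h = cfg$repair$dt_h)
    foci <- gamma_h2ax_curve(state)
    out <- cbind(state, foci_scaled = foci$foci)
    write.csv(out, file.path(out_dir, "repair.csv"), row.names = FALSE)
    write_manifest(manifest, out_dir, stage)
    return(invisible(out))
  }
  if (stage == "report") {
    tally <- read_tally_csv(out_dir)
    rep <- tally_report(tally, dose_Gy = cfg$repair$dose_Gy)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    write_manifest(manifest, out_dir, stage)
    return(invisible(rep))
  }
}

write_manifest <- function(manifest, out_dir, stage) {
  manifest$stage <- stage
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"),
                      simplifyVector = TRUE)
}

# tallies travel between stages as the break + cluster CSV pair
saveRDS_free_tally <- function(tally, out_dir) {
  write.csv(tally$clusters, file.path(out_dir, "clusters.csv"),
            row.names = FALSE)
  write.csv(tally$dsb_positions, file.path(out_dir, "dsb_positions.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

read_tally_csv <- function(out_dir) {
  cl_path <- file.path(out_dir, "clusters.csv")
  if (!file.exists(cl_path))
    stop("missing upstream artifact for stage: run 'classify' first ",
         "(no clusters.csv in ", out_dir, ")")
  clusters <- read.csv(cl_path, stringsAsFactors = FALSE)
  dsb <- read.csv(file.path(out_dir, "dsb_positions.csv"),
                  stringsAsFactors = FALSE)
  brk <- read.csv(file.path(out_dir, "breaks.csv"), stringsAsFactors = FALSE)
  damage_tally(if (nrow(clusters)) clusters else NULL,
               total_breaks = nrow(brk), dsb_positions = dsb)
}

#' Merge the outputs of split runs
#'
#' Splits must share a configuration (hash equality is enforced).
#' Aggregate counts are the sums of the split counts and break records are
#' concatenated with their stable per-primary ids, so merging is
#' associative and order-independent.
#'
#' @param dirs character vector of split output directories (each written
#'   by [run_pipeline()] stage `"classify"`).
#' @return list `tally`, `breaks`.
#' @export
merge_splits <- function(dirs) {
  if (length(dirs) == 0) stop("no split outputs to merge")
  mans <- lapply(dirs, read_manifest)
  hashes <- vapply(mans, `[[`, "", "config_hash")
  if (length(unique(hashes)) != 1)
    stop("refusing to merge splits with different configuration hashes")
  tallies <- lapply(dirs, read_tally_csv)
  brks <- lapply(dirs, function(d)
    read.csv(file.path(d, "breaks.csv"), stringsAsFactors = FALSE))
  list(tally = merge_tallies(tallies),
       breaks = do.call(rbind, brks))
}

#' @importFrom utils modifyList
NULL
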