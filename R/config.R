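#' Default run configuration
#'
#' One nested list with five sections (geometry, beam, chemistry, damage,
#' repair). The damage section carries the calibrated damage-parameter
#' defaults; every value can be overridden from a YAML file.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(
      hilbert_iteration = 7L,
      bp_per_voxel = 5823L,
      nucleus_semi_axes_um = c(14.2, 14.2, 5),
      cytoplasm_semi_axes_um = c(28, 28, 5),
      mask_shape = "ellipsoid",
      chromosomes = 46L,
      chromosome_partition = "human",
      fiber_radius_nm = 12.5,
      histone_spacing_bp = 200L,
      histone_radius_nm = 2.4),
    beam = list(
      particle = "proton",
      energy_MeV = 1,
      let_keV_um = 25.8,
      n_primaries = 10L,
      source_offset_um = 3,
      direction = c(0, 0, 1),
      mean_deposit_eV = 45,
      deposit_range_eV = c(5, 500),
      penumbra_nm = 2),
    chemistry = list(
      yield_table = as.list(default_yield_table()),
      diffusion = as.list(default_diffusion_table()),
      species_jitter_nm = 1,
      radical_radical = FALSE,
      backbone_R_eff_nm = 0.2,
      search_factor = 8),
    damage = list(
      R_direct_nm = 0.35,
      E_lower_eV = 5,
      E_higher_eV = 37.5,
      P_OH = 0.405,
      d_kill_nm = 9,
      T_chem_ns = 5,
      dt_max_ns = 0.5,
      d_DSB_bp = 10L,
      d_s_bp = 100L,
      distant_DSB_bp = 10000L),
    repair = list(
      alpha = 25.9,
      dose_Gy = 1,
      N_ir = 0,
      k_on_foci = 8,
      k_off_foci = 0.4,
      foci_floor = 0,
      t_end_h = 25,
      dt_h = 0.05,
      pathway_names = c("NHEJ", "HR", "SSA", "micro-SSA", "Alt-NHEJ"),
      pathway_fractions = c(0.75, 0.12, 0.06, 0.03, 0.04),
      pathway_half_lives_h = c(0.3, 4, 4, 8, 8)))
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()] (an empty file
#' yields the full defaults), rejects unknown keys by name, and validates
#' value ranges.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional nested list applied on top (used by the CLI).
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user, "")
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- coerce_like(base[[key]], user[[key]], full)
    }
  }
  base
}

coerce_like <- function(template, value, key) {
  if (is.numeric(template)) {
    v <- suppressWarnings(as.numeric(unlist(value)))
    if (anyNA(v)) stop("configuration key ", key, " must be numeric")
    if (is.integer(template)) v <- as.integer(round(v))
    return(v)
  }
  unlist(value)
}

validate_config <- function(cfg) {
  dmg <- cfg$damage
  if (dmg$d_kill_nm < 0) stop("damage.d_kill_nm must be >= 0")
  if (dmg$P_OH < 0 || dmg$P_OH > 1) stop("damage.P_OH must be in [0, 1]")
  if (dmg$E_lower_eV >= dmg$E_higher_eV)
    stop("damage.E_lower_eV must be below damage.E_higher_eV")
  if (dmg$T_chem_ns <= 0 || dmg$dt_max_ns <= 0)
    stop("damage.T_chem_ns and damage.dt_max_ns must be > 0")
  if (dmg$d_DSB_bp >= dmg$d_s_bp)
    stop("damage.d_DSB_bp must be below damage.d_s_bp")
  if (cfg$beam$let_keV_um <= 0) stop("beam.let_keV_um must be > 0")
  if (cfg$beam$n_primaries < 0) stop("beam.n_primaries must be >= 0")
  if (cfg$geometry$hilbert_iteration < 1)
    stop("geometry.hilbert_iteration must be >= 1")
  if (any(unlist(cfg$chemistry$diffusion) < 0))
    stop("chemistry.diffusion coefficients must be >= 0")
  fr <- cfg$repair$pathway_fractions
  if (abs(sum(fr) - 1) > 1e-8)
    stop("repair.pathway_fractions must sum to 1")
  invisible(cfg)
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Configuration hash
#'
#' Stable digest used to refuse merging run splits that were produced
#' under different configurations.
#'
#' @param cfg configuration list.
#' @return md5 string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

#' Build model objects from a configuration
#'
#' Convenience constructors mapping the relevant configuration section to
#' the corresponding model object.
#'
#' @param cfg a validated configuration list ([load_config()] /
#'   [default_config()]).
#' @return `config_nucleus()` a [nucleus_model()]; `config_genome()` a
#'   [genome_model()]; `config_beam()` a [beam_config()];
#'   `config_damage_params()` a [damage_params()]; `config_channels()` a
#'   channel list; `config_repair_params()` a [repair_params()].
#' @name config_constructors
NULL

#' @rdname config_constructors
#' @export
config_nucleus <- function(cfg) {
  g <- cfg$geometry
  nucleus_model(semi_axes_um = g$nucleus_semi_axes_um,
                cyto_semi_axes_um = g$cytoplasm_semi_axes_um,
                mask_shape = g$mask_shape,
                chromosomes = g$chromosomes,
                chromosome_partition = g$chromosome_partition)
}

#' @rdname config_constructors
#' @export
config_genome <- function(cfg) {
  g <- cfg$geometry
  genome_model(nucleus = config_nucleus(cfg),
               hilbert_iteration = g$hilbert_iteration,
               bp_per_voxel = g$bp_per_voxel,
               fiber_radius_nm = g$fiber_radius_nm,
               histone_spacing_bp = g$histone_spacing_bp,
               histone_radius_nm = g$histone_radius_nm)
}

#' @rdname config_constructors
#' @export
config_beam <- function(cfg) {
  b <- cfg$beam
  beam_config(particle = b$particle, energy_MeV = b$energy_MeV,
              let_keV_um = b$let_keV_um, n_primaries = b$n_primaries,
              source_offset_um = b$source_offset_um,
              direction = b$direction,
              mean_deposit_eV = b$mean_deposit_eV,
              deposit_range_eV = b$deposit_range_eV,
              penumbra_nm = b$penumbra_nm)
}

#' @rdname config_constructors
#' @export
config_damage_params <- function(cfg) {
  d <- cfg$damage
  damage_params(R_direct_nm = d$R_direct_nm, E_lower_eV = d$E_lower_eV,
                E_higher_eV = d$E_higher_eV, P_OH = d$P_OH,
                d_kill_nm = d$d_kill_nm, T_chem_ns = d$T_chem_ns,
                dt_max_ns = d$dt_max_ns, d_DSB_bp = d$d_DSB_bp,
                d_s_bp = d$d_s_bp, distant_DSB_bp = d$distant_DSB_bp)
}

#' @rdname config_constructors
#' @export
config_channels <- function(cfg) {
  ch <- cfg$chemistry
  chans <- default_channels(diffusion = unlist(ch$diffusion),
                            radical_radical = ch$radical_radical,
                            histone_radius_nm = cfg$geometry$histone_radius_nm)
  chans[[1]]$R_eff <- ch$backbone_R_eff_nm
  chans
}

#' @rdname config_constructors
#' @param N_ir,alpha optional overrides for the repair parameters.
#' @export
config_repair_params <- function(cfg, N_ir = NULL, alpha = NULL) {
  r <- cfg$repair
  repair_params(alpha = alpha %||% r$alpha, dose = r$dose_Gy,
                N_ir = N_ir %||% r$N_ir,
                pathways = data.frame(name = r$pathway_names,
                                      fraction = r$pathway_fractions,
                                      half_life_h = r$pathway_half_lives_h),
                k_on_foci = r$k_on_foci, k_off_foci = r$k_off_foci,
                foci_floor = r$foci_floor)
}
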