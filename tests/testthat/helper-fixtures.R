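# Shared fixtures: small genome configurations and hand-built molecule /
# species tables used across the unit tests.

# tiny chromatin model: iteration-1 Hilbert cube in a flat ellipsoid,
# chromatin density of the same order as the fibroblast model
tiny_config <- function(bp_per_voxel = 6600L, let = 80, n_primaries = 10L) {
  cfg <- default_config()
  cfg$geometry$hilbert_iteration <- 1L
  cfg$geometry$nucleus_semi_axes_um <- c(0.22, 0.22, 0.1)
  cfg$geometry$cytoplasm_semi_axes_um <- c(0.44, 0.44, 0.1)
  cfg$geometry$bp_per_voxel <- bp_per_voxel
  cfg$beam$n_primaries <- as.integer(n_primaries)
  cfg$beam$let_keV_um <- let
  cfg
}

small_model <- function(it = 2L, bp = 400L, semi = c(0.45, 0.45, 0.16)) {
  genome_model(nucleus_model(semi_axes_um = semi,
                             cyto_semi_axes_um = semi * c(2, 2, 1)),
               hilbert_iteration = it, bp_per_voxel = bp)
}

# one molecule row
mol_row <- function(kind, x, y, z, radius, chromosome = 1L, strand = 0L,
                    bp = 0L) {
  data.frame(kind = kind, chromosome = chromosome, strand = strand,
             bp = bp, x = x, y = y, z = z, radius = radius)
}

# one species row with a fixed private RNG stream
species_row <- function(name = "OH", x = 0, y = 0, z = 0, D = 2.8,
                        id = 0L, rng = 42L) {
  data.frame(species_id = id, name = name, x = x, y = y, z = z,
             t_ns = 0, D = D, primary_id = 0L, rng = rng)
}

# break record shorthand
brk <- function(strand, bp, source = "direct", chromosome = 1L,
                primary_id = 0L) {
  data.frame(chromosome = chromosome, strand = strand, bp = bp,
             source = source, primary_id = primary_id)
}
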