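#' Ellipsoidal fibroblast nucleus description
#'
#' The default geometry is a flat ellipsoidal nucleus with semi-axes
#' 14.2 x 14.2 x 5 um inside an ellipsoidal cytoplasm of 28 x 28 x 5 um,
#' the simplified human fibroblast used throughout the package.
#'
#' @param semi_axes_um nucleus semi-axes (a, b, c), micrometres.
#' @param cyto_semi_axes_um cytoplasm semi-axes, micrometres.
#' @param mask_shape `"ellipsoid"` or `"sphere"`; the sphere option uses
#'   `min(semi_axes_um)` as radius.
#' @param chromosomes number of chromosome territories the masked path is
#'   cut into (46 for a diploid human cell).
#' @param chromosome_partition `"human"` for blocks proportional to human
#'   chromosome lengths (diploid, XX), `"equal"` for equal bp blocks.
#' @return a `nucleus_model`.
#' @export
nucleus_model <- function(semi_axes_um = c(14.2, 14.2, 5),
                          cyto_semi_axes_um = c(28, 28, 5),
                          mask_shape = c("ellipsoid", "sphere"),
                          chromosomes = 46L,
                          chromosome_partition = c("human", "equal")) {
  mask_shape <- match.arg(mask_shape)
  chromosome_partition <- match.arg(chromosome_partition)
  stopifnot(length(semi_axes_um) == 3, all(semi_axes_um > 0),
            length(cyto_semi_axes_um) == 3, all(cyto_semi_axes_um > 0))
  structure(list(semi_axes_um = as.numeric(semi_axes_um),
                 cyto_semi_axes_um = as.numeric(cyto_semi_axes_um),
                 mask_shape = mask_shape,
                 chromosomes = as.integer(chromosomes),
                 chromosome_partition = chromosome_partition),
            class = "nucleus_model")
}

#' Mask a voxel path with the nucleus
#'
#' Retains the voxels whose centres lie inside the nucleus (centre-in test)
#' and splits the path into maximal contiguous runs. The layout must
#' already be scaled: its `anisotropic_scale` gives the half-extents of the
#' box the Hilbert cube was stretched into, normally the nucleus bounding
#' box, so the flat ellipsoid can hold the full cube path.
#'
#' @param layout a `fractal_layout`.
#' @param nucleus a [nucleus_model()].
#' @return the layout with `retained` (logical per path cell), `runs`
#'   (an [rle()] over `retained`) and `segment_types` filled in.
#' @export
apply_nucleus_mask <- function(layout, nucleus) {
  stopifnot(inherits(layout, "fractal_layout"), inherits(nucleus, "nucleus_model"))
  ctr <- layout_centers(layout)                       # nm
  semi <- nucleus$semi_axes_um * 1000                 # nm
  if (nucleus$mask_shape == "sphere") semi <- rep(min(semi), 3)
  w <- sweep(ctr, 2, semi, "/")
  layout$retained <- rowSums(w * w) <= 1
  layout$runs <- rle(layout$retained)
  layout$segment_types <- assign_segment_types(layout)
  layout
}

#' Human chromosome lengths
#'
#' Approximate GRCh38 sequence lengths in Mbp for chr1-22 and X, used to
#' partition the masked chromatin path into 46 territories (diploid, XX)
#' proportional to physical chromosome size.
#'
#' @return named numeric vector, Mbp.
#' @export
human_chromosome_lengths <- function() {
  c(chr1 = 248.96, chr2 = 242.19, chr3 = 198.30, chr4 = 190.21,
    chr5 = 181.54, chr6 = 170.81, chr7 = 159.35, chr8 = 145.14,
    chr9 = 138.39, chr10 = 133.80, chr11 = 135.09, chr12 = 133.28,
    chr13 = 114.36, chr14 = 107.04, chr15 = 101.99, chr16 = 90.34,
    chr17 = 83.26, chr18 = 80.37, chr19 = 58.62, chr20 = 64.44,
    chr21 = 46.71, chr22 = 50.82, chrX = 156.04)
}

#' Assemble the full-genome chromatin model
#'
#' Builds the Hilbert path at the requested iteration, stretches it over
#' the nucleus bounding box, applies the nucleus mask, assigns segment
#' types, and cuts the retained path into contiguous chromosome
#' territories. The default calibration (iteration 7, 5823 bp per voxel)
#' places 6.40 Gbp in the default fibroblast nucleus. No molecular volumes
#' are materialised here; use [materialize_region()] for that.
#'
#' @param nucleus a [nucleus_model()].
#' @param hilbert_iteration Hilbert depth; default 7.
#' @param bp_per_voxel base pairs hosted by one voxel's chromatin segment.
#'   The same count is used for straight and turned segments.
#' @param fiber_radius_nm solenoid radius of the chromatin fiber centreline
#'   inside a voxel.
#' @param histone_spacing_bp one histone scavenging sphere is placed on the
#'   fiber centreline per this many bp.
#' @param histone_radius_nm histone sphere radius.
#' @return a `genome_model`.
#' @export
genome_model <- function(nucleus = nucleus_model(),
                         hilbert_iteration = 7L,
                         bp_per_voxel = 5823L,
                         fiber_radius_nm = 12.5,
                         histone_spacing_bp = 200L,
                         histone_radius_nm = 2.4) {
  semi_nm <- nucleus$semi_axes_um * 1000
  layout <- build_hilbert_path(hilbert_iteration, anisotropic_scale = semi_nm)
  layout <- apply_nucleus_mask(layout, nucleus)
  model <- structure(list(
    nucleus = nucleus,
    layout = layout,
    bp_per_voxel = as.integer(bp_per_voxel),
    fiber_radius_nm = fiber_radius_nm,
    histone_spacing_bp = as.integer(histone_spacing_bp),
    histone_radius_nm = histone_radius_nm,
    segment_library = default_segment_library()
  ), class = "genome_model")
  model$chromosome_map <- partition_chromosomes(model)
  model
}

# Cut the retained path (in path order) into contiguous chromosome blocks
# with bp proportional to chromosome length. Returns a data frame with one
# row per retained voxel: path index, chromosome id, bp offset of the voxel
# start within its chromosome.
partition_chromosomes <- function(model) {
  lay <- model$layout
  idx <- which(lay$retained)
  nvox <- length(idx)
  if (nvox == 0)
    return(data.frame(path_index = integer(), chromosome = integer(),
                      bp_start = integer()))
  nuc <- model$nucleus
  n_chrom <- nuc$chromosomes
  if (nuc$chromosome_partition == "human" && n_chrom == 46L) {
    lens <- human_chromosome_lengths()
    w <- rep(c(lens[1:22], lens["chrX"]), 2)        # diploid, XX
  } else {
    w <- rep(1, n_chrom)
  }
  w <- w / sum(w)
  total_bp <- nvox * as.numeric(model$bp_per_voxel)
  # chromosome boundaries in cumulative bp, mapped to voxel boundaries
  cum_bp <- cumsum(w) * total_bp
  vox_end_bp <- seq_len(nvox) * as.numeric(model$bp_per_voxel)
  chrom <- findInterval(vox_end_bp - 1, c(0, cum_bp[-n_chrom]))
  chrom <- pmin(pmax(chrom, 1L), n_chrom)
  bp_start <- integer(nvox)
  off <- 0L
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    bp_start[sel] <- (seq_len(sum(sel)) - 1L) * model$bp_per_voxel
  }
  data.frame(path_index = idx, chromosome = as.integer(chrom),
             bp_start = bp_start)
}

#' Count the base pairs of the modeled genome
#'
#' Sums the bp content of all retained voxels lazily, without materialising
#' a single molecular volume, so the full 6.4 Gbp fibroblast genome can be
#' counted in seconds.
#'
#' @param model a [genome_model()].
#' @return total base pairs (double, to hold >2^31).
#' @export
count_genome_bp <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  sum(model$layout$retained) * as.numeric(model$bp_per_voxel)
}

#' Nominal genomic base-pair density
#'
#' The textbook mammalian figure: a ~6 Gbp genome packed into a ~500 um^3
#' nucleus, i.e. 0.012 bp/nm^3. This literature-derived nominal density is
#' distinct from the density of the flat modelled ellipsoid, whose volume
#' (~4200 um^3) is much larger than the 500 um^3 literature nucleus.
#'
#' @param genome_bp genome size in bp.
#' @param nucleus_volume_um3 nucleus volume in um^3.
#' @return density in bp/nm^3.
#' @export
nominal_bp_density <- function(genome_bp = 6e9, nucleus_volume_um3 = 500) {
  genome_bp / (nucleus_volume_um3 * 1e9)
}

#' @export
print.genome_model <- function(x, ...) {
  n_ret <- sum(x$layout$retained)
  cat("<genome_model>\n")
  cat("  nucleus semi-axes:", paste(x$nucleus$semi_axes_um, collapse = " x "),
      "um (", x$nucleus$mask_shape, ")\n")
  cat("  Hilbert iteration:", x$layout$iteration, "->", n_ret,
      "retained voxels of", nrow(x$layout$cells), "\n")
  cat("  genome:", format(count_genome_bp(x), big.mark = ","), "bp in",
      x$nucleus$chromosomes, "chromosomes\n")
  invisible(x)
}
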