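# Chromatin segment construction.
#
# Each voxel of the masked Hilbert path hosts one chromatin segment whose
# fiber centreline runs from the entry face centre to the exit face centre:
# a straight line for "straight" segments, a quarter (elliptical) arc for
# "turned" and "turned-twisted" segments. The DNA double helix is wound as
# a solenoid around that centreline so that the helical contour length
# matches bp_count x 0.34 nm (canonical B-DNA rise) even though the voxel
# is only a few hundred nm across. Sugar and phosphate spheres sit on the
# two backbone strands (36 degrees twist per bp, 10 bp/turn), bases sit
# near the helix axis, and one histone sphere per nucleosome-scale bp
# window sits on the fiber path as a scavenging target.

B_DNA <- list(
  rise_nm = 0.34,
  bp_per_turn = 10,
  sugar_radius_nm = 0.228,      # van der Waals radii
  phosphate_radius_nm = 0.263,
  base_radius_nm = 0.3,
  sugar_helix_radius_nm = 0.75,
  phosphate_helix_radius_nm = 1.05,
  phosphate_lead_rad = 0.3,     # angular offset of phosphate vs sugar
  base_helix_radius_nm = 0.25
)

vnormalize <- function(m) m / sqrt(rowSums(m * m))

# Molecular volumes of one voxel's chromatin segment, in nucleus frame.
# path_row: one row of model$chromosome_map.
build_voxel_molecules <- function(model, path_row) {
  lay <- model$layout
  i <- path_row$path_index
  ctr <- ((lay$cells[i, ] + 0.5) / lay$n_side * 2 - 1) * lay$anisotropic_scale
  h <- voxel_half_extents(lay)
  n <- nrow(lay$cells)
  d_in <- if (i > 1) lay$cells[i, ] - lay$cells[i - 1, ] else
    lay$cells[2, ] - lay$cells[1, ]
  d_out <- if (i < n) lay$cells[i + 1, ] - lay$cells[i, ] else d_in
  seg_type <- lay$segment_types[i]
  bp_n <- model$bp_per_voxel
  mol <- segment_molecules_local(
    bp_n, seg_type, d_in, d_out, h,
    fiber_radius = model$fiber_radius_nm,
    histone_spacing = model$histone_spacing_bp,
    histone_radius = model$histone_radius_nm,
    bp_global_start = path_row$bp_start)
  mol$x <- mol$x + ctr[1]
  mol$y <- mol$y + ctr[2]
  mol$z <- mol$z + ctr[3]
  mol$chromosome <- path_row$chromosome
  mol$bp <- mol$bp + path_row$bp_start
  mol[, c("kind", "chromosome", "strand", "bp", "x", "y", "z", "radius")]
}

# Segment geometry in the voxel-local frame (voxel centre at origin).
segment_molecules_local <- function(bp_n, seg_type, d_in, d_out, half,
                                    fiber_radius, histone_spacing,
                                    histone_radius, bp_global_start = 0) {
  s <- (seq_len(bp_n) - 0.5) / bp_n
  axis_in <- which(d_in != 0)
  axis_out <- which(d_out != 0)
  h_in <- half[axis_in]
  h_out <- half[axis_out]
  if (seg_type == "straight") {
    entry <- -h_in * d_in
    exit <- h_out * d_out
    A <- outer(1 - s, entry) + outer(s, exit)
    Tn <- matrix(d_in, bp_n, 3, byrow = TRUE)
    L_axis <- h_in + h_out
  } else {
    # quarter-ellipse arc pivoting on the shared edge
    O <- h_out * d_out - h_in * d_in
    phi <- s * pi / 2
    A <- matrix(O, bp_n, 3, byrow = TRUE) -
      outer(cos(phi) * h_out, d_out) + outer(sin(phi) * h_in, d_in)
    Tn <- vnormalize(outer(sin(phi) * h_out, d_out) +
                       outer(cos(phi) * h_in, d_in))
    # quarter-ellipse length (Simpson on 64 panels)
    pp <- seq(0, pi / 2, length.out = 129)
    f <- sqrt(h_out^2 * sin(pp)^2 + h_in^2 * cos(pp)^2)
    wts <- c(1, rep(c(4, 2), 63), 4, 1)
    L_axis <- sum(wts * f) * (pp[2] - pp[1]) / 3
  }
  # solenoid winding so the fiber contour carries bp_n x rise of DNA
  contour <- bp_n * B_DNA$rise_nm
  n_turns <- sqrt(max(contour^2 - L_axis^2, 0)) / (2 * pi * fiber_radius)
  phi_sol <- 2 * pi * n_turns * s
  # transverse frame of the centreline
  if (seg_type == "straight") {
    N1 <- perpendicular_axis(d_in)
    N1 <- matrix(N1, bp_n, 3, byrow = TRUE)
    N2 <- rowwise_cross(Tn, N1)
  } else {
    B <- cross3(d_in, d_out)                  # turn-plane normal
    N2 <- matrix(B, bp_n, 3, byrow = TRUE)
    N1 <- vnormalize(rowwise_cross(N2, Tn))
  }
  radial <- cos(phi_sol) * N1 + sin(phi_sol) * N2
  Fp <- A + fiber_radius * radial
  # fiber tangent: centreline advance + azimuthal winding advance
  dphi <- 2 * pi * n_turns                     # d phi_sol / ds
  Tf <- vnormalize(L_axis * Tn +
                     fiber_radius * dphi * (-sin(phi_sol) * N1 +
                                              cos(phi_sol) * N2))
  # local DNA frame perpendicular to the fiber tangent
  e1 <- vnormalize(radial - rowSums(radial * Tf) * Tf)
  e2 <- rowwise_cross(Tf, e1)
  bp_idx <- bp_global_start + seq_len(bp_n) - 1
  psi <- 2 * pi * bp_idx / B_DNA$bp_per_turn
  if (seg_type == "turned-twisted") psi <- psi + s * pi / 2
  place <- function(r, ang) Fp + r * (cos(ang) * e1 + sin(ang) * e2)
  lead <- B_DNA$phosphate_lead_rad
  mk <- function(kind, strand, pos, radius)
    data.frame(kind = kind, strand = strand, bp = seq_len(bp_n) - 1L,
               x = pos[, 1], y = pos[, 2], z = pos[, 3], radius = radius)
  out <- rbind(
    mk("sugar", 0L, place(B_DNA$sugar_helix_radius_nm, psi),
       B_DNA$sugar_radius_nm),
    mk("phosphate", 0L, place(B_DNA$phosphate_helix_radius_nm, psi + lead),
       B_DNA$phosphate_radius_nm),
    mk("base", 0L, place(B_DNA$base_helix_radius_nm, psi),
       B_DNA$base_radius_nm),
    mk("sugar", 1L, place(B_DNA$sugar_helix_radius_nm, psi + pi),
       B_DNA$sugar_radius_nm),
    mk("phosphate", 1L, place(B_DNA$phosphate_helix_radius_nm, psi + pi + lead),
       B_DNA$phosphate_radius_nm),
    mk("base", 1L, place(B_DNA$base_helix_radius_nm, psi + pi),
       B_DNA$base_radius_nm))
  n_hist <- bp_n %/% histone_spacing
  if (n_hist > 0) {
    hmid <- (seq_len(n_hist) - 0.5) * histone_spacing
    hsel <- pmin(pmax(round(hmid), 1), bp_n)
    out <- rbind(out, data.frame(
      kind = "histone", strand = NA_integer_, bp = as.integer(hsel - 1L),
      x = Fp[hsel, 1], y = Fp[hsel, 2], z = Fp[hsel, 3],
      radius = histone_radius))
  }
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rowwise_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# deterministic unit vector perpendicular to a grid axis direction
perpendicular_axis <- function(d) {
  ax <- which(d != 0)
  switch(ax, c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
}

default_segment_library <- function() {
  list(types = c("straight", "turned", "turned-twisted"),
       b_dna = B_DNA)
}

#' Materialise molecular volumes inside a region of interest
#'
#' Instantiates sugar, phosphate, base and histone spheres only for the
#' chromatin voxels intersecting an axis-aligned box, so damage scoring for
#' one particle track touches a corridor of voxels rather than the full
#' 6.4 Gbp genome. Repeated calls are consistent: a voxel always
#' materialises to the same coordinates.
#'
#' @param model a [genome_model()].
#' @param roi either a 2 x 3 matrix (rows: lower, upper corner, nm) or a
#'   list with `lower` and `upper` length-3 vectors.
#' @return data frame of molecular volumes: `kind`, `chromosome`, `strand`
#'   (0/1, `NA` for histones), `bp` (0-based within chromosome), `x`, `y`,
#'   `z` (nm), `radius` (nm). Empty when the box misses all voxels.
#' @export
materialize_region <- function(model, roi) {
  stopifnot(inherits(model, "genome_model"))
  roi <- as_roi(roi)
  sel <- voxels_in_box(model, roi)
  materialize_voxels(model, sel)
}

as_roi <- function(roi) {
  if (is.list(roi) && !is.data.frame(roi)) roi <- rbind(roi$lower, roi$upper)
  roi <- as.matrix(roi)
  stopifnot(nrow(roi) == 2, ncol(roi) == 3)
  roi
}

# rows of chromosome_map whose voxel boxes intersect the roi
voxels_in_box <- function(model, roi) {
  map <- model$chromosome_map
  if (nrow(map) == 0) return(map)
  lay <- model$layout
  ctr <- sweep((lay$cells[map$path_index, , drop = FALSE] + 0.5) /
                 lay$n_side * 2 - 1, 2, lay$anisotropic_scale, "*")
  h <- voxel_half_extents(model$layout)
  keep <- rep(TRUE, nrow(map))
  for (d in 1:3)
    keep <- keep & (ctr[, d] + h[d] >= roi[1, d]) &
      (ctr[, d] - h[d] <= roi[2, d])
  map[keep, , drop = FALSE]
}

materialize_voxels <- function(model, map_rows, cache = NULL) {
  if (nrow(map_rows) == 0)
    return(data.frame(kind = character(), chromosome = integer(),
                      strand = integer(), bp = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric()))
  one <- function(r) {
    if (is.null(cache))
      return(build_voxel_molecules(model, map_rows[r, ]))
    key <- as.character(map_rows$path_index[r])
    if (is.null(cache[[key]]))
      cache[[key]] <- build_voxel_molecules(model, map_rows[r, ])
    cache[[key]]
  }
  parts <- lapply(seq_len(nrow(map_rows)), one)
  do.call(rbind, parts)
}

#' Write / read a chromatin segment definition file
#'
#' Plain-text exchange format for one segment template: header lines give
#' the segment type and bp count, then one molecule per line with kind,
#' strand, bp offset, local coordinates (nm) and radius (nm),
#' whitespace-separated.
#'
#' @param molecules data frame as produced by [segment_template()].
#' @param segment_type one of `"straight"`, `"turned"`, `"turned-twisted"`.
#' @param bp_count base pairs in the segment.
#' @param path file path.
#' @return `write_segment_file()` returns `path` invisibly;
#'   `read_segment_file()` returns a list with `segment_type`, `bp_count`
#'   and `molecules`.
#' @export
write_segment_file <- function(molecules, segment_type, bp_count, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("segment_type", segment_type),
               paste("bp_count", bp_count),
               "kind strand bp_offset x y z radius"), con)
  strand <- ifelse(is.na(molecules$strand), "-", molecules$strand)
  writeLines(sprintf("%s %s %d %.6f %.6f %.6f %.4f",
                     molecules$kind, strand, molecules$bp,
                     molecules$x, molecules$y, molecules$z,
                     molecules$radius), con)
  invisible(path)
}

#' @rdname write_segment_file
#' @export
read_segment_file <- function(path) {
  lines <- readLines(path)
  seg_type <- strsplit(lines[1], "[ ,]+")[[1]][2]
  bp_count <- as.integer(strsplit(lines[2], "[ ,]+")[[1]][2])
  body <- lines[-(1:3)]
  if (length(body) == 0) {
    mol <- data.frame(kind = character(), strand = integer(), bp = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric())
  } else {
    fields <- strsplit(body, "[ ,]+")
    bad <- which(lengths(fields) != 7)
    if (length(bad))
      stop("malformed segment line ", bad[1] + 3, " in ", path)
    m <- do.call(rbind, fields)
    mol <- data.frame(kind = m[, 1],
                      strand = suppressWarnings(as.integer(m[, 2])),
                      bp = as.integer(m[, 3]),
                      x = as.numeric(m[, 4]), y = as.numeric(m[, 5]),
                      z = as.numeric(m[, 6]), radius = as.numeric(m[, 7]))
  }
  list(segment_type = seg_type, bp_count = bp_count, molecules = mol)
}

#' Segment template in the voxel-local frame
#'
#' Builds one segment of each requested type with the voxel centred at the
#' origin, mainly to export segment definition files.
#'
#' @param model a [genome_model()].
#' @param segment_type segment flavour.
#' @param bp_count base pairs; defaults to the model's per-voxel count.
#' @return molecule data frame in local coordinates.
#' @export
segment_template <- function(model, segment_type = "straight",
                             bp_count = model$bp_per_voxel) {
  h <- voxel_half_extents(model$layout)
  d_in <- c(1, 0, 0)
  d_out <- if (segment_type == "straight") c(1, 0, 0) else c(0, 1, 0)
  segment_molecules_local(bp_count, segment_type, d_in, d_out, h,
                          fiber_radius = model$fiber_radius_nm,
                          histone_spacing = model$histone_spacing_bp,
                          histone_radius = model$histone_radius_nm)
}
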