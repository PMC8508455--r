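#' Build the 3-D Hilbert curve voxel path
#'
#' Generates the continuous space-filling path that threads the chromatin
#' fiber through the nucleus volume. Iteration `k` produces a path over the
#' `(2^k)^3` voxel grid in which consecutive voxels are always face
#' neighbours, so the chromatin fiber never jumps. The construction is the
#' transpose/Gray-code formulation of the Hilbert curve (Skilling's
#' algorithm), vectorised over all cells, and is fully deterministic.
#'
#' @param iteration Hilbert iteration depth (>= 1). The grid has
#'   `2^iteration` cells per side and the path visits `8^iteration` cells.
#' @param voxel_side_nm nominal voxel side before anisotropic scaling, nm.
#' @param anisotropic_scale per-axis half-extents of the box the unit cube
#'   is stretched into, nm. `NULL` leaves the cube isotropic with side
#'   `voxel_side_nm * 2^iteration`.
#' @return a `fractal_layout`: the ordered integer cell path (0-based),
#'   grid size, per-axis scale, and (after masking) the retained runs.
#' @examples
#' lay <- build_hilbert_path(2)
#' nrow(lay$cells)  # 64
#' @export
build_hilbert_path <- function(iteration, voxel_side_nm = NULL,
                               anisotropic_scale = NULL) {
  if (!is.numeric(iteration) || length(iteration) != 1 ||
      is.na(iteration) || iteration < 1 || iteration != round(iteration))
    stop("iteration must be an integer >= 1")
  b <- as.integer(iteration)
  n_side <- 2L^b
  cells <- hilbert_transpose_to_axes(b)
  if (is.null(anisotropic_scale)) {
    side <- voxel_side_nm %||% 1
    anisotropic_scale <- rep(side * n_side / 2, 3)
  }
  if (is.null(voxel_side_nm)) voxel_side_nm <- 2 * max(anisotropic_scale) / n_side
  structure(list(
    iteration = b,
    n_side = n_side,
    cells = cells,                   # 8^b x 3 integer, path order, 0-based
    voxel_side_nm = voxel_side_nm,
    anisotropic_scale = as.numeric(anisotropic_scale),
    retained = NULL,                 # set by apply_nucleus_mask()
    runs = NULL,
    segment_types = NULL
  ), class = "fractal_layout")
}

# Skilling transpose-to-axes: map Hilbert indices 0..8^b-1 to grid
# coordinates, vectorised over the whole path.
hilbert_transpose_to_axes <- function(b) {
  npts <- 8L^b
  d <- seq_len(npts) - 1L
  X <- matrix(0L, npts, 3L)
  for (q in seq_len(b)) {                    # distribute interleaved bits
    for (i in 1:3) {
      bitpos <- 3L * (b - q) + (3L - i)
      bit <- bitwAnd(bitwShiftR(d, bitpos), 1L)
      X[, i] <- bitwOr(X[, i], bitwShiftL(bit, b - q))
    }
  }
  N <- bitwShiftL(2L, b - 1L)
  t0 <- bitwShiftR(X[, 3L], 1L)              # Gray decode
  for (i in 3:2) X[, i] <- bitwXor(X[, i], X[, i - 1L])
  X[, 1L] <- bitwXor(X[, 1L], t0)
  Q <- 2L
  while (Q != N) {                           # undo excess work
    P <- Q - 1L
    for (i in 3:1) {
      hi <- bitwAnd(X[, i], Q) != 0L
      X[hi, 1L] <- bitwXor(X[hi, 1L], P)
      tt <- bitwAnd(bitwXor(X[!hi, 1L], X[!hi, i]), P)
      X[!hi, 1L] <- bitwXor(X[!hi, 1L], tt)
      X[!hi, i] <- bitwXor(X[!hi, i], tt)
    }
    Q <- bitwShiftL(Q, 1L)
  }
  colnames(X) <- c("i", "j", "k")
  X
}

#' Voxel centres of a layout in nm
#'
#' Cell centres are mapped from the unit grid into the box spanned by the
#' per-axis `anisotropic_scale` half-extents, centred on the origin.
#'
#' @param layout a `fractal_layout`.
#' @return numeric matrix of centres, one row per path cell, nm.
#' @export
layout_centers <- function(layout) {
  stopifnot(inherits(layout, "fractal_layout"))
  u <- (layout$cells + 0.5) / layout$n_side * 2 - 1
  sweep(u, 2, layout$anisotropic_scale, "*")
}

# Per-axis half extents of one voxel, nm.
voxel_half_extents <- function(layout) layout$anisotropic_scale / layout$n_side

#' Classify each voxel of the path as a chromatin segment type
#'
#' A voxel whose incoming and outgoing path directions are collinear hosts a
#' "straight" chromatin segment; a voxel where the path turns by ninety
#' degrees hosts a "turned" or "turned-twisted" segment. Turn-type voxels
#' alternate between the two so the accumulated twist of the fiber frame
#' cancels along the path. End voxels reuse their single neighbour
#' direction and are "straight".
#'
#' @param layout a `fractal_layout` with a continuous path.
#' @return character vector, one of `"straight"`, `"turned"`,
#'   `"turned-twisted"` per path voxel.
#' @export
assign_segment_types <- function(layout) {
  stopifnot(inherits(layout, "fractal_layout"))
  cells <- layout$cells
  n <- nrow(cells)
  if (n == 1) return("straight")
  steps <- diff(cells)
  if (any(rowSums(abs(steps)) != 1L))
    stop("path is discontinuous: consecutive cells must be grid neighbours")
  d_in <- rbind(steps[1, , drop = FALSE], steps)    # direction entering cell i
  d_out <- rbind(steps, steps[n - 1, , drop = FALSE])
  turns <- rowSums(d_in * d_out) == 0L
  types <- rep("straight", n)
  # alternate turn flavours to cancel net twist along the fiber
  types[turns] <- rep_len(c("turned", "turned-twisted"), sum(turns))
  types
}

# Entry/exit unit directions per voxel (matrices n x 3).
path_directions <- function(layout) {
  cells <- layout$cells
  n <- nrow(cells)
  if (n == 1) {
    d <- matrix(c(1, 0, 0), 1, 3)
    return(list(d_in = d, d_out = d))
  }
  steps <- diff(cells)
  list(d_in = rbind(steps[1, , drop = FALSE], steps),
       d_out = rbind(steps, steps[n - 1, , drop = FALSE]))
}

#' @export
print.fractal_layout <- function(x, ...) {
  cat("<fractal_layout> iteration", x$iteration, "-", nrow(x$cells),
      "cells on a", x$n_side, "^3 grid\n")
  if (!is.null(x$retained))
    cat("  masked:", sum(x$retained), "voxels retained in",
        length(x$runs$lengths[x$runs$values]), "contiguous runs\n")
  invisible(x)
}
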