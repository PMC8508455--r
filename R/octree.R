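#' Build an octree over 3-D points
#'
#' Constructs a spatial index for fast fixed-radius and nearest-neighbour
#' queries. An octree recursively divides a cubic cell into eight octants
#' until each leaf holds at most `leaf_capacity` points; queries then prune
#' whole octants by their distance to the query centre. The chemistry engine
#' uses one octree over DNA molecular-volume centres to find reaction
#' partners for every diffusing radical.
#'
#' @param points numeric matrix with three columns (coordinates in nm) or a
#'   data frame with columns `x`, `y`, `z`.
#' @param leaf_capacity maximum number of points per leaf node.
#' @return an object of class `octree`.
#' @examples
#' pts <- matrix(runif(300), ncol = 3)
#' tr <- build_octree(pts)
#' query_radius(tr, c(0.5, 0.5, 0.5), 0.2)
#' @export
build_octree <- function(points, leaf_capacity = 16L) {
  pts <- as_point_matrix(points)
  obj <- list(ptr = .octree_build(pts, as.integer(leaf_capacity)),
              n = nrow(pts))
  class(obj) <- "octree"
  obj
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (!is.matrix(points)) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must have three columns")
  points
}

#' Fixed-radius neighbour query
#'
#' Returns the (1-based) ids of all indexed points whose Euclidean distance
#' to `center` is less than or equal to `r`. The boundary is inclusive: a
#' point exactly at distance `r` is returned.
#'
#' @param tree an [build_octree()] index.
#' @param center numeric length-3 centre, or an n x 3 matrix of centres for
#'   a batched query.
#' @param r query radius (same units as the indexed coordinates); must be
#'   non-negative.
#' @return an integer vector of ids, or a list of such vectors when
#'   `center` is a matrix.
#' @export
query_radius <- function(tree, center, r) {
  stopifnot(inherits(tree, "octree"))
  if (length(r) != 1 || is.na(r) || r < 0) stop("query radius must be non-negative")
  if (is.matrix(center) || is.data.frame(center)) {
    .octree_query_many(tree$ptr, as_point_matrix(center), r)
  } else {
    .octree_query(tree$ptr, as.numeric(center), r)
  }
}

#' Nearest indexed point
#'
#' @param tree an [build_octree()] index.
#' @param center a length-3 centre or an n x 3 matrix of centres.
#' @return a list with `id` (1-based, `NA` for an empty tree) and `dist`.
#' @export
query_nearest <- function(tree, center) {
  stopifnot(inherits(tree, "octree"))
  if (!is.matrix(center) && !is.data.frame(center))
    center <- matrix(as.numeric(center), ncol = 3)
  res <- .octree_nearest_many(tree$ptr, as_point_matrix(center))
  res
}

#' @export
print.octree <- function(x, ...) {
  cat("<octree> over", x$n, "points\n")
  invisible(x)
}
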