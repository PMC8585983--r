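#' Decimate points for element-size uniformity
#'
#' Greedy retention in descending priority (detection contrast; ties broken
#' by point order): a point is retained iff no previously retained point
#' lies within `radius`. All pairwise distances among retained points
#' therefore exceed `radius` exactly.
#'
#' @param points n x d matrix of physical coordinates (micrometres).
#' @param priority numeric priority scores (higher first); defaults to
#'   input order.
#' @param radius exclusion radius, micrometres (>= 0).
#' @return Integer indices (into `points`) of the retained subset, in
#'   retention order.
#' @export
decimate_points <- function(points, priority = NULL, radius = 0) {
  points <- rbind(points)
  n <- nrow(points)
  if (radius < 0) stopf("radius must be >= 0")
  if (n == 0L) return(integer(0))
  if (is.null(priority)) priority <- rev(seq_len(n))
  ord <- order(-priority, seq_len(n))
  if (radius == 0) return(ord)
  kept <- integer(0)
  r2 <- radius^2
  for (i in ord) {
    if (length(kept)) {
      d2 <- rowSums(sweep(points[kept, , drop = FALSE], 2, points[i, ])^2)
      if (any(d2 <= r2)) next
    }
    kept <- c(kept, i)
  }
  kept
}

#' Delaunay triangulation of a node set
#'
#' Builds the simplex element list for a point cloud: triangles in 2-D,
#' tetrahedra in 3-D, with positively oriented elements. Co-spherical
#' degeneracies are resolved by a deterministic symbolic jitter of 1e-6 um
#' (fixed seed), so the mesh is reproducible for a fixed input ordering.
#'
#' @param nodes n x 2 or n x 3 matrix of physical coordinates (micrometres).
#' @param mode `"2d"` or `"3d"`.
#' @return Integer element matrix (m x 3 or m x 4) of 1-based node indices.
#' @export
triangulate_points <- function(nodes, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  nodes <- rbind(nodes)
  d <- if (mode == "2d") 2L else 3L
  if (nrow(nodes) < d + 1L)
    stopf("need at least %d nodes for %s triangulation", d + 1L, mode)
  P <- nodes[, seq_len(d), drop = FALSE]
  jit <- with_seed(76543L, matrix(runif(length(P), -1e-6, 1e-6), nrow(P)))
  Pj <- P + jit
  el <- if (d == 2L) cpp_delaunay2(Pj) else cpp_delaunay3(Pj)
  if (nrow(el) == 0L) {
    if (d == 3L)
      stopf("nodes are coplanar or collinear: no tetrahedra produced; consider 2-D mode")
    stopf("nodes are collinear: no triangles produced")
  }
  el
}

# signed measures of simplices (area in 2-D using first two coordinates,
# volume in 3-D)
element_measures <- function(nodes, elements) {
  d <- ncol(elements) - 1L
  if (d == 2L) {
    a <- nodes[elements[, 1], 1:2, drop = FALSE]
    b <- nodes[elements[, 2], 1:2, drop = FALSE]
    c_ <- nodes[elements[, 3], 1:2, drop = FALSE]
    0.5 * ((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  } else {
    a <- nodes[elements[, 1], , drop = FALSE]
    v1 <- nodes[elements[, 2], , drop = FALSE] - a
    v2 <- nodes[elements[, 3], , drop = FALSE] - a
    v3 <- nodes[elements[, 4], , drop = FALSE] - a
    (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
     v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
     v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  }
}

# normalized aspect quality in (0, 1]: ratio of inradius to circumradius,
# scaled so the regular simplex scores 1
element_quality <- function(nodes, elements) {
  d <- ncol(elements) - 1L
  m <- nrow(elements)
  q <- numeric(m)
  for (e in seq_len(m)) {
    v <- nodes[elements[e, ], , drop = FALSE]
    if (d == 2L) {
      l <- c(sqrt(sum((v[2, ] - v[1, ])^2)), sqrt(sum((v[3, ] - v[2, ])^2)),
             sqrt(sum((v[1, ] - v[3, ])^2)))
      s <- sum(l) / 2
      area <- sqrt(max(s * prod(s - l), 0))
      if (area <= 0) { q[e] <- 0; next }
      rin <- area / s
      rcirc <- prod(l) / (4 * area)
      q[e] <- 2 * rin / rcirc
    } else {
      vol <- abs(element_measures(nodes, elements[e, , drop = FALSE]))
      faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
      fa <- apply(faces, 1, function(f) {
        u <- v[f[2], ] - v[f[1], ]; w <- v[f[3], ] - v[f[1], ]
        cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
                u[1] * w[2] - u[2] * w[1])
        0.5 * sqrt(sum(cr^2))
      })
      if (vol <= 0 || any(fa <= 0)) { q[e] <- 0; next }
      rin <- 3 * vol / sum(fa)
      # circumradius via circumcenter solve
      A <- 2 * (v[2:4, , drop = FALSE] - matrix(v[1, ], 3, 3, byrow = TRUE))
      rhs <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
      cc <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(cc)) { q[e] <- 0; next }
      rcirc <- sqrt(sum((v[1, ] - cc)^2))
      q[e] <- 3 * rin / rcirc
    }
  }
  pmin(q, 1)
}

#' Build a strain mesh from tracked trajectories
#'
#' Converts the accepted trajectories of a [track_series] run into a finite
#' element mesh: reference voxel indices become physical node coordinates
#' (index x spacing), points are decimated for element-size uniformity,
#' nodes are connected by Delaunay triangulation, and per-frame nodal
#' displacements are attached. Sliver elements are pruned (see
#' [prune_mesh]).
#'
#' @param trajectories a `trajectory_set` from [track_series].
#' @param decimate_radius decimation radius, micrometres; one point is
#'   retained within any area of this radius (choose 30-300 um depending on
#'   the image size).
#' @param mode `"3d"` or `"2d"` (defaults to the tracking mode).
#' @param quality_floor sliver-pruning quality threshold passed to
#'   [prune_mesh].
#' @param node_label optional per-trajectory structure labels (e.g. which
#'   vein a point belongs to), carried onto the nodes.
#' @return An object of class `strain_mesh` with fields `nodes` (n x 3, um),
#'   `elements`, `ref_measure` (um^2 or um^3), `displacements`
#'   (frames x n x 3, um), `node_ids`, `node_label`, `mode`.
#' @export
build_strain_mesh <- function(trajectories, decimate_radius = 30,
                              mode = NULL, quality_floor = 0.05,
                              node_label = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  mode <- mode %||% trajectories$mode
  acc <- accepted_trajectories(trajectories)
  if (!length(acc)) stopf("no accepted trajectories to mesh")
  sp <- trajectories$spacing
  nf <- trajectories$n_frames
  ref_i <- trajectories$reference_index
  ref_loc <- t(vapply(acc, function(t) t$loc[ref_i, ], numeric(3)))
  pts <- sweep(ref_loc, 2, sp, "*")
  contrast <- vapply(acc, function(t) t$contrast %||% 0, 0)
  keep <- decimate_points(pts, contrast, decimate_radius)
  keep <- sort(keep)
  acc <- acc[keep]
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  el <- triangulate_points(pts, mode = mode)
  disp <- array(0, c(nf, n, 3))
  for (i in seq_len(n)) {
    li <- acc[[i]]$loc
    disp[, i, ] <- sweep(sweep(li, 2, li[ref_i, ]), 2, sp, "*")
  }
  meas <- element_measures(pts, el)
  mesh <- structure(list(
    nodes = pts,
    node_ids = vapply(acc, function(t) t$point_id, 0L),
    node_label = if (is.null(node_label)) rep(NA_character_, n)
                 else node_label[keep],
    elements = el,
    ref_measure = abs(meas),
    displacements = disp,
    mode = mode,
    spacing = sp,
    reference_index = ref_i),
    class = "strain_mesh")
  prune_mesh(mesh, quality_floor = quality_floor)
}

#' Construct a strain mesh directly from nodes and displacements
#'
#' Lower-level companion of [build_strain_mesh] for meshes whose nodes do
#' not come from tracking (ground-truth injection, the inter-vein sclera
#' mesh, tests).
#'
#' @param nodes n x 3 physical coordinates (micrometres; third column 0 for
#'   2-D).
#' @param displacements frames x n x 3 array of nodal displacements (um).
#' @param mode `"3d"` or `"2d"`.
#' @param node_label optional per-node structure labels.
#' @param quality_floor sliver-pruning threshold ([prune_mesh]).
#' @return A `strain_mesh`.
#' @export
strain_mesh_from_points <- function(nodes, displacements, mode = c("3d", "2d"),
                                    node_label = NULL, quality_floor = 0) {
  mode <- match.arg(mode)
  nodes <- rbind(nodes)
  if (ncol(nodes) == 2L) nodes <- cbind(nodes, 0)
  n <- nrow(nodes)
  if (length(dim(displacements)) != 3L || dim(displacements)[2] != n)
    stopf("displacements must be a frames x nodes x 3 array")
  el <- triangulate_points(nodes, mode = mode)
  mesh <- structure(list(
    nodes = nodes,
    node_ids = seq_len(n) - 1L,
    node_label = if (is.null(node_label)) rep(NA_character_, n) else node_label,
    elements = el,
    ref_measure = abs(element_measures(nodes, el)),
    displacements = displacements,
    mode = mode,
    spacing = c(1, 1, 1),
    reference_index = 1L),
    class = "strain_mesh")
  if (quality_floor > 0) prune_mesh(mesh, quality_floor) else mesh
}

#' Remove sliver elements from a mesh
#'
#' Drops elements whose normalized aspect quality (inradius/circumradius,
#' scaled so a regular simplex scores 1) falls below `quality_floor` or
#' whose reference measure is below an absolute floor, then drops orphaned
#' nodes. Constant-strain elements with near-zero measure amplify tracking
#' noise into unbounded strain, so they are excluded before strain
#' computation.
#'
#' @param mesh a `strain_mesh`.
#' @param quality_floor quality threshold in `[0, 1)`.
#' @param measure_floor absolute element measure floor (um^2 / um^3).
#' @return The pruned `strain_mesh`; attribute `removed` reports the number
#'   of elements removed.
#' @export
prune_mesh <- function(mesh, quality_floor = 0.05, measure_floor = 1e-9) {
  stopifnot(inherits(mesh, "strain_mesh"))
  if (quality_floor < 0 || quality_floor >= 1) stopf("quality_floor must be in [0, 1)")
  q <- element_quality(mesh$nodes, mesh$elements)
  keep <- q >= quality_floor & mesh$ref_measure > measure_floor
  removed <- sum(!keep)
  if (all(!keep)) stopf("pruning removed every element (quality_floor too high?)")
  el <- mesh$elements[keep, , drop = FALSE]
  used <- sort(unique(as.vector(el)))
  remap <- match(seq_len(nrow(mesh$nodes)), used)
  el[] <- remap[el]
  mesh$elements <- el
  mesh$ref_measure <- mesh$ref_measure[keep]
  mesh$nodes <- mesh$nodes[used, , drop = FALSE]
  mesh$node_ids <- mesh$node_ids[used]
  mesh$node_label <- mesh$node_label[used]
  mesh$displacements <- mesh$displacements[, used, , drop = FALSE]
  attr(mesh, "removed") <- removed
  mesh
}

#' @export
print.strain_mesh <- function(x, ...) {
  cat(sprintf("<strain_mesh> %d nodes, %d %s elements, %d frames\n",
              nrow(x$nodes), nrow(x$elements),
              if (x$mode == "2d") "triangle" else "tetrahedral",
              dim(x$displacements)[1]))
  invisible(x)
}
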