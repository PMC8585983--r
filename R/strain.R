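#' Deformation gradient of one constant-strain element
#'
#' For a simplex element the deformation gradient is constant:
#' `F = D_def %*% solve(D_ref)` where the columns of `D_ref`/`D_def` are
#' the reference and deformed edge vectors from vertex 1. Exact for affine
#' motions.
#'
#' @param ref_coords (d+1) x d matrix of reference vertex coordinates.
#' @param def_coords (d+1) x d matrix of deformed vertex coordinates.
#' @return The d x d deformation-gradient matrix.
#' @export
element_F <- function(ref_coords, def_coords) {
  ref_coords <- rbind(ref_coords); def_coords <- rbind(def_coords)
  d <- ncol(ref_coords)
  if (!identical(dim(ref_coords), dim(def_coords)) || nrow(ref_coords) != d + 1L)
    stopf("expected (d+1) x d vertex matrices of matching shape")
  Dref <- t(ref_coords[-1, , drop = FALSE] -
              matrix(ref_coords[1, ], d, d, byrow = TRUE))
  Ddef <- t(def_coords[-1, , drop = FALSE] -
              matrix(def_coords[1, ], d, d, byrow = TRUE))
  det_ref <- det(Dref)
  if (abs(det_ref) < 1e-14 * max(abs(Dref))^d)
    stopf("degenerate reference element (singular edge matrix)")
  Ddef %*% solve(Dref)
}

#' Strain tensor from a deformation gradient
#'
#' Logarithmic (true) strain: `eps = ln U` with `F = R U` the polar
#' decomposition, computed from the eigendecomposition of `C = F'F`
#' (`U = C^(1/2)`, `ln U = V diag(ln(lambda)/2) V'`); invariant to rigid
#' rotation. Small strain: `eps = (F + F')/2 - I`, the linearised measure,
#' which picks up spurious strain under finite rotations.
#'
#' @param F d x d deformation gradient with `det F > 0`.
#' @param measure `"log"` (default) or `"small"`.
#' @return Symmetric d x d strain tensor.
#' @export
strain_from_F <- function(F, measure = c("log", "small")) {
  measure <- match.arg(measure)
  F <- as.matrix(F)
  if (det(F) <= 0) stopf("deformation gradient must have det F > 0")
  if (measure == "small") {
    return((F + t(F)) / 2 - diag(ncol(F)))
  }
  C <- crossprod(F)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(0.5 * log(lam), ncol(F)) %*% t(e$vectors)
}

# pack a symmetric d x d tensor to components XX YY ZZ XY YZ XZ (3-D) or
# XX YY XY (2-D)
tensor_components <- function(mode) {
  if (mode == "2d") c("XX", "YY", "XY") else c("XX", "YY", "ZZ", "XY", "YZ", "XZ")
}

pack_tensor <- function(eps, mode) {
  if (mode == "2d") c(eps[1, 1], eps[2, 2], eps[1, 2])
  else c(eps[1, 1], eps[2, 2], eps[3, 3], eps[1, 2], eps[2, 3], eps[1, 3])
}

unpack_tensor <- function(v, mode) {
  if (mode == "2d") matrix(c(v[1], v[3], v[3], v[2]), 2)
  else matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3)
}

#' Per-element strain field at one frame
#'
#' Applies [element_F] and [strain_from_F] to every element of the mesh
#' using the nodal displacements of the requested frame. The reference
#' frame yields the zero field.
#'
#' @param mesh a `strain_mesh`.
#' @param frame frame index (1-based into the series) to evaluate.
#' @param measure strain measure, `"log"` (default) or `"small"`.
#' @return An object of class `element_strain_field`: a list with `eps`
#'   (m x k component matrix, columns XX, YY, ZZ, XY, YZ, XZ in 3-D),
#'   `frame`, `measure`, `mode`.
#' @export
field_strain <- function(mesh, frame, measure = c("log", "small")) {
  stopifnot(inherits(mesh, "strain_mesh"))
  measure <- match.arg(measure)
  nf <- dim(mesh$displacements)[1]
  if (frame < 1 || frame > nf) stopf("frame %d outside 1..%d", frame, nf)
  d <- if (mesh$mode == "2d") 2L else 3L
  comps <- tensor_components(mesh$mode)
  m <- nrow(mesh$elements)
  eps <- matrix(0, m, length(comps), dimnames = list(NULL, comps))
  if (frame != mesh$reference_index) {
    u <- mesh$displacements[frame, , , drop = TRUE]
    if (is.null(dim(u))) u <- matrix(u, ncol = 3)
    def <- mesh$nodes + u
    bad <- integer(0)
    for (e in seq_len(m)) {
      vi <- mesh$elements[e, ]
      Fm <- element_F(mesh$nodes[vi, seq_len(d), drop = FALSE],
                      def[vi, seq_len(d), drop = FALSE])
      if (det(Fm) <= 0) { bad <- c(bad, e); next }
      eps[e, ] <- pack_tensor(strain_from_F(Fm, measure), mesh$mode)
    }
    if (length(bad))
      stopf("inverted elements (det F <= 0) at frame %d: %s", frame,
            paste(bad, collapse = ", "))
  }
  structure(list(eps = eps, frame = frame, measure = measure, mode = mesh$mode),
            class = "element_strain_field")
}

#' Nodal strain averages
#'
#' Each node receives the unweighted mean of the strain tensors of the
#' elements containing it, for interpolation and visualization of the
#' spatial strain distribution.
#'
#' @param mesh a `strain_mesh`.
#' @param field an `element_strain_field` computed on `mesh`.
#' @return n x k matrix of nodal tensor components.
#' @export
nodal_strains <- function(mesh, field) {
  stopifnot(inherits(mesh, "strain_mesh"), inherits(field, "element_strain_field"))
  if (nrow(field$eps) != nrow(mesh$elements))
    stopf("field has %d elements, mesh has %d", nrow(field$eps), nrow(mesh$elements))
  n <- nrow(mesh$nodes)
  acc <- matrix(0, n, ncol(field$eps), dimnames = list(NULL, colnames(field$eps)))
  cnt <- numeric(n)
  for (e in seq_len(nrow(mesh$elements))) {
    vi <- mesh$elements[e, ]
    acc[vi, ] <- acc[vi, , drop = FALSE] +
      matrix(field$eps[e, ], length(vi), ncol(acc), byrow = TRUE)
    cnt[vi] <- cnt[vi] + 1
  }
  acc / pmax(cnt, 1)
}

#' Rotate a strain tensor into another coordinate frame
#'
#' `eps' = R eps R'` for an orthonormal rotation `R` mapping acquisition
#' axes to analysis axes (e.g. producing a Z' axis aligned with the
#' observed outward tissue motion).
#'
#' @param eps symmetric strain tensor (matrix) or packed component vector.
#' @param rotation 3x3 (or 2x2) rotation matrix, `det = +1`.
#' @param mode `"3d"` or `"2d"` (needed when `eps` is packed).
#' @return Rotated tensor, in the same representation as the input.
#' @export
rotate_strain <- function(eps, rotation, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  R <- as.matrix(rotation)
  if (max(abs(crossprod(R) - diag(ncol(R)))) > 1e-8 || det(R) < 0)
    stopf("rotation must be orthonormal with det = +1")
  packed <- is.null(dim(eps))
  M <- if (packed) unpack_tensor(eps, mode) else as.matrix(eps)
  out <- R %*% M %*% t(R)
  if (packed) pack_tensor(out, mode) else out
}

#' Rotation taking the acquisition z-axis towards an observed direction
#'
#' Convenience constructor for the coordinate transformation about the
#' X-axis that produces a Z' axis at angle `theta` from z towards y (the
#' direction of the observed outward motion of tracked points).
#'
#' @param theta rotation angle about the X-axis, radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_x <- function(theta) {
  rbind(c(1, 0, 0),
        c(0, cos(theta), -sin(theta)),
        c(0, sin(theta), cos(theta)))
}

#' Measure-weighted average strain
#'
#' The region-average strain: the mean of element strain components
#' weighted by the initial (undeformed) element area or volume,
#' `eps_bar = sum(eps_e m_e) / sum(m_e)`.
#'
#' @param field an `element_strain_field`.
#' @param mesh the `strain_mesh` the field was computed on.
#' @return Named numeric vector of weighted-average components; attribute
#'   `weighting` records whether areas or volumes were used.
#' @export
weighted_average_strain <- function(field, mesh) {
  stopifnot(inherits(field, "element_strain_field"), inherits(mesh, "strain_mesh"))
  if (nrow(field$eps) != length(mesh$ref_measure))
    stopf("field/mesh element counts differ")
  w <- mesh$ref_measure
  tot <- sum(w)
  if (tot <= 0) stopf("zero total reference measure")
  out <- colSums(field$eps * w) / tot
  attr(out, "weighting") <- if (mesh$mode == "2d") "area" else "volume"
  out
}

#' Strain of the tissue between two tracked structures
#'
#' Runs the constant-strain machinery on a mesh whose nodes come from two
#' bounding structures (e.g. the walls of two neighbouring veins), giving
#' the strain of the tissue spanned between them. The estimate assumes the
#' deformation of the bounding walls themselves is negligible relative to
#' the tissue in between.
#'
#' @param mesh a `strain_mesh` whose `node_label` identifies the source
#'   structure of each node; at least two distinct labels are required.
#' @param frames frame indices to evaluate (default: all).
#' @param measure strain measure.
#' @return List of `element_strain_field`s, one per requested frame.
#' @export
inter_vein_strain <- function(mesh, frames = NULL, measure = c("log", "small")) {
  stopifnot(inherits(mesh, "strain_mesh"))
  measure <- match.arg(measure)
  labs <- unique(mesh$node_label[!is.na(mesh$node_label)])
  if (length(labs) < 2)
    stopf("nodes from at least two structures required (found: %s)",
          if (length(labs)) paste(labs, collapse = ", ") else "none")
  frames <- frames %||% seq_len(dim(mesh$displacements)[1])
  lapply(frames, function(f) field_strain(mesh, f, measure))
}
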