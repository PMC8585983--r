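#' Deformation models with analytic gradients
#'
#' A deformation model is a smooth mapping `phi` of reference physical
#' coordinates (micrometres) to deformed coordinates together with its
#' deformation gradient `F(p) = d phi / d p` and an inverse mapping, used by
#' the phantom module to warp volumes and to provide ground-truth strain.
#'
#' `deformation_affine()` builds `phi(p) = F (p - origin) + origin + shift`
#' with a spatially constant gradient; `deformation_radial()` expands points
#' radially away from a line (axis point + direction) by a factor
#' `1 + rate`; `deformation_sinusoidal()` adds a smoothly varying
#' displacement `amplitude * sin(2 pi <p, k>/wavelength)` along `direction`,
#' inverted by fixed-point iteration.
#'
#' @param F 3x3 deformation-gradient matrix (det > 0).
#' @param shift translation vector, micrometres.
#' @param origin fixed point of the affine map, micrometres.
#' @return An object of class `deformation_model` with fields
#'   `kind`, `parameters`, and functions `evaluate(p)`, `gradient(p)`,
#'   `inverse(p)` operating on n x 3 matrices of physical points.
#' @export
deformation_affine <- function(F, shift = c(0, 0, 0), origin = c(0, 0, 0)) {
  F <- as.matrix(F)
  if (!identical(dim(F), c(3L, 3L))) stopf("`F` must be 3x3")
  if (det(F) <= 0) stopf("deformation gradient must have positive determinant")
  Finv <- solve(F)
  origin <- as.numeric(origin); shift <- as.numeric(shift)
  ev <- function(p) sweep(sweep(p, 2, origin) %*% t(F), 2, origin + shift, "+")
  inv <- function(p) sweep(sweep(p, 2, origin + shift) %*% t(Finv), 2, origin, "+")
  structure(list(
    kind = "affine",
    parameters = list(F = F, shift = shift, origin = origin),
    evaluate = ev,
    gradient = function(p) rep(list(F), nrow(p)),
    inverse = inv), class = "deformation_model")
}

#' @rdname deformation_affine
#' @param axis_point,axis_dir a point on the expansion axis and its (unit)
#'   direction, micrometres.
#' @param rate radial expansion fraction (> -1); radius maps to
#'   `radius * (1 + rate)`.
#' @export
deformation_radial <- function(axis_point, axis_dir, rate) {
  if (rate <= -1) stopf("rate must exceed -1")
  a <- as.numeric(axis_point)
  u <- as.numeric(axis_dir); u <- u / sqrt(sum(u^2))
  lam <- 1 + rate
  radial_part <- function(p) {
    rel <- sweep(p, 2, a)
    ax <- drop(rel %*% u)
    rel - outer(ax, u)
  }
  ev <- function(p) p + rate * radial_part(p)
  inv <- function(p) p - (rate / lam) * radial_part(p)
  gr <- function(p) {
    Pu <- diag(3) - outer(u, u)
    G <- diag(3) + rate * Pu
    rep(list(G), nrow(p))
  }
  structure(list(
    kind = "radial_expansion",
    parameters = list(axis_point = a, axis_dir = u, rate = rate),
    evaluate = ev, gradient = gr, inverse = inv), class = "deformation_model")
}

#' @rdname deformation_affine
#' @param amplitude displacement amplitude, micrometres.
#' @param wavelength spatial period of the modulation, micrometres.
#' @param direction direction of the displacement (unit vector).
#' @param normal direction along which the displacement is modulated.
#' @export
deformation_sinusoidal <- function(amplitude, wavelength,
                                   direction = c(1, 0, 0),
                                   normal = c(0, 1, 0)) {
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  m <- as.numeric(normal); m <- m / sqrt(sum(m^2))
  k <- 2 * pi / wavelength
  # det F = 1 + A k cos(.) (d.m): folding iff |A k (d.m)| >= 1
  if (abs(amplitude) * k * abs(sum(d * m)) >= 1)
    stopf("amplitude too large: mapping would fold")
  ev <- function(p) p + outer(amplitude * sin(k * drop(p %*% m)), d)
  gr <- function(p) {
    ph <- amplitude * k * cos(k * drop(p %*% m))
    lapply(ph, function(s) diag(3) + s * outer(d, m))
  }
  inv <- function(p) {
    q <- p
    for (it in 1:60) {
      q_new <- p - outer(amplitude * sin(k * drop(q %*% m)), d)
      if (max(abs(q_new - q)) < 1e-10) { q <- q_new; break }
      q <- q_new
    }
    q
  }
  structure(list(
    kind = "spatially_varying",
    parameters = list(amplitude = amplitude, wavelength = wavelength,
                      direction = d, normal = m),
    evaluate = ev, gradient = gr, inverse = inv), class = "deformation_model")
}

#' Compose two deformation models (apply `first`, then `second`)
#'
#' @param first,second `deformation_model` objects.
#' @return A `deformation_model` representing `second(first(p))`.
#' @export
deformation_compose <- function(first, second) {
  ev <- function(p) second$evaluate(first$evaluate(p))
  gr <- function(p) {
    G1 <- first$gradient(p)
    G2 <- second$gradient(first$evaluate(p))
    Map(function(a, b) b %*% a, G1, G2)
  }
  inv <- function(p) first$inverse(second$inverse(p))
  structure(list(
    kind = "composed",
    parameters = list(first = first, second = second),
    evaluate = ev, gradient = gr, inverse = inv), class = "deformation_model")
}

#' Analytic strain of a deformation model at given points
#'
#' The phantom-side oracle: evaluates the exact strain tensor implied by a
#' deformation model, against which pipeline-recovered strains are compared.
#' Under the logarithmic (true) measure the strain is `ln U` where
#' `F = R U` is the polar decomposition of the deformation gradient; under
#' the small-strain measure it is the symmetric displacement gradient
#' `(F + F^T)/2 - I`.
#'
#' @param model a `deformation_model`.
#' @param points n x 3 matrix of reference physical points (micrometres).
#' @param measure `"log"` (default) or `"small"`.
#' @return List of n symmetric 3x3 strain matrices.
#' @export
ground_truth_strain <- function(model, points, measure = c("log", "small")) {
  measure <- match.arg(measure)
  points <- rbind(points)
  lapply(model$gradient(points), strain_from_F, measure = measure)
}
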