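#' Specification of a synthetic stained-vein phantom
#'
#' Describes a photoacoustic-like volume of a contrast-stained vessel wall:
#' bright speckle features confined to a tubular shell around a centerline,
#' blurred by the anisotropic imaging point-spread (lateral resolution much
#' finer than axial), over a near-zero background. The phantom emulates the
#' image statistics relevant to feature tracking, not the acoustics or
#' optics of the imaging process.
#'
#' @param shape integer voxel counts per axis (length 3; use a third entry
#'   of 1 for a planar, 2-D phantom).
#' @param spacing micrometres per voxel per axis (lateral, lateral, axial).
#' @param vein_centerline k x 3 matrix of physical points (micrometres)
#'   traced by the vessel axis; defaults to a straight line along X through
#'   the volume centre.
#' @param vein_radius vessel radius, micrometres. Stained vessels of the
#'   kind this emulates have diameters on the order of 150-200 um.
#' @param wall_thickness radial extent of the stained wall shell, micrometres.
#' @param speckle_density features per 100 x 100 um^2 of wall-shell area.
#'   Each feature is one PSF-blurred bright blob occupying tens of voxels, so
#'   the default of 6 features per patch yields on the order of a hundred
#'   trackable supra-threshold pixels per patch.
#' @param blur_sigma Gaussian blur per axis, micrometres; defaults match a
#'   lateral/axial resolution of 4.1 and 37 um.
#' @param noise_sd additive Gaussian background noise level (intensity units,
#'   relative to a unit peak feature amplitude).
#' @param amplitude_range feature amplitudes are drawn uniformly from this
#'   range (the amplitude statistics of real stained veins are not
#'   characterised; see the methods vignette).
#' @param seed integer RNG seed; the phantom is bit-reproducible for a fixed
#'   spec and seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(240L, 240L, 80L),
                         spacing = c(4, 4, 13),
                         vein_centerline = NULL,
                         vein_radius = 87.5,
                         wall_thickness = 20,
                         speckle_density = 6,
                         blur_sigma = c(4.1, 4.1, 37),
                         noise_sd = 0.01,
                         amplitude_range = c(0.5, 1),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("`shape` must be 3 positive counts")
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("`spacing` must be positive")
  if (!(vein_radius > wall_thickness) || wall_thickness <= 0)
    stopf("need vein_radius > wall_thickness > 0")
  extent <- (shape - 1) * spacing
  if (is.null(vein_centerline)) {
    if (shape[3] == 1L) {
      vein_centerline <- rbind(c(0, extent[2] / 2, 0), c(extent[1], extent[2] / 2, 0))
    } else {
      vein_centerline <- rbind(c(0, extent[2] / 2, extent[3] / 2),
                               c(extent[1], extent[2] / 2, extent[3] / 2))
    }
  }
  vein_centerline <- rbind(vein_centerline)
  if (ncol(vein_centerline) != 3L || nrow(vein_centerline) < 2L)
    stopf("`vein_centerline` must be a polyline of >= 2 physical points (n x 3)")
  # the wall shell must fit the volume in the directions perpendicular to the
  # local vessel axis (a vein may run out through the end faces)
  margin <- vein_radius + wall_thickness / 2
  ax <- if (shape[3] == 1L) 1:2 else 1:3
  nseg <- nrow(vein_centerline) - 1L
  for (r in seq_len(nrow(vein_centerline))) {
    p <- vein_centerline[r, ]
    s <- min(max(r - 1L, 1L), nseg)
    u <- vein_centerline[s + 1L, ] - vein_centerline[s, ]
    u <- u / sqrt(sum(u^2))
    marg_ax <- margin * sqrt(pmax(1 - u[ax]^2, 0))
    if (any(p[ax] - marg_ax < -1e-9) || any(p[ax] + marg_ax > extent[ax] + 1e-9))
      stopf("vein exits the volume bounds at centerline point %d (%s) um",
            r, paste(signif(p, 5), collapse = ", "))
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 vein_centerline = vein_centerline,
                 vein_radius = vein_radius, wall_thickness = wall_thickness,
                 speckle_density = speckle_density,
                 blur_sigma = as.numeric(blur_sigma),
                 noise_sd = noise_sd,
                 amplitude_range = as.numeric(amplitude_range),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# distance from physical points (n x 3) to the centerline polyline, plus the
# arc-length coordinate of the closest point
centerline_distance <- function(points, centerline, two_d = FALSE) {
  points <- rbind(points)
  if (two_d) { points <- points; points[, 3] <- 0; centerline[, 3] <- 0 }
  n <- nrow(points)
  best <- rep(Inf, n)
  for (s in seq_len(nrow(centerline) - 1)) {
    a <- centerline[s, ]; b <- centerline[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- (sweep(points, 2, a) %*% ab) / len2
    t <- pmin(pmax(drop(t), 0), 1)
    proj <- sweep(outer(t, ab), 2, a, "+")
    d <- sqrt(rowSums((points - proj)^2))
    best <- pmin(best, d)
  }
  best
}

polyline_length <- function(cl) sum(sqrt(rowSums(diff(cl)^2)))

# Draw speckle feature centres on the wall shell: dart throwing with a
# minimum separation derived from the target density (Poisson-disc-like).
sample_shell_points <- function(spec) {
  cl <- spec$vein_centerline
  two_d <- spec$shape[3] == 1L
  len <- polyline_length(cl)
  # in 2-D (a maximum-amplitude projection) the stained wall fills the
  # projected silhouette of the tube, not just two thin lines
  shell_area <- if (two_d) 2 * spec$vein_radius * len else 2 * pi * spec$vein_radius * len
  # features per um^2
  dens <- spec$speckle_density / 1e4
  target <- max(1L, round(shell_area * dens))
  min_sep <- 0.6 * sqrt(1 / dens)
  seg <- diff(cl)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(NA_real_, target, 3)
  amps <- numeric(target)
  got <- 0L
  attempts <- 0L
  max_attempts <- 60L * target
  while (got < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    s <- runif(1, 0, len)
    k <- findInterval(s, cum, rightmost.closed = TRUE)
    k <- min(k, nrow(seg))
    a <- cl[k, ]; u <- seg[k, ] / seg_len[k]
    base <- a + (s - cum[k]) * u
    if (two_d) {
      nrm <- c(-u[2], u[1], 0)
      nrm <- nrm / sqrt(sum(nrm^2))
      p <- base + runif(1, -spec$vein_radius, spec$vein_radius) * nrm
      p[3] <- 0
    } else {
      rad <- spec$vein_radius + runif(1, -0.5, 0.5) * spec$wall_thickness
      # orthonormal frame around u
      ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      th <- runif(1, 0, 2 * pi)
      p <- base + rad * (cos(th) * e1 + sin(th) * e2)
    }
    ext <- (spec$shape - 1) * spec$spacing
    ax <- if (two_d) 1:2 else 1:3
    if (any(p[ax] < 0) || any(p[ax] > ext[ax])) next
    if (got > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
    amps[got] <- runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
  }
  list(points = pts[seq_len(got), , drop = FALSE], amplitudes = amps[seq_len(got)])
}

#' Generate a synthetic stained-vein volume
#'
#' Renders the phantom described by a [phantom_spec]: speckle features are
#' placed on the vessel-wall shell by minimum-separation dart throwing,
#' rendered as anisotropic Gaussian blobs (the point-spread of the imaging
#' system), and additive Gaussian noise is clipped at zero. Deterministic
#' for a fixed spec and seed.
#'
#' @param spec a [phantom_spec].
#' @param noise logical; add per-acquisition sensor noise (default). The
#'   speckle signal depends only on `spec$seed`; the noise of frame
#'   `frame_id` is drawn from a seed derived from `(seed, frame_id)`, so a
#'   frame series carries independent noise per frame over a common
#'   underlying structure, as repeated acquisitions do.
#' @param frame_id frame index used to seed the noise draw.
#' @return An [image_volume]; attributes `features` (n x 3 physical feature
#'   positions, micrometres) and `amplitudes` carry the ground-truth speckle.
#' @export
generate_phantom <- function(spec, noise = TRUE, frame_id = 0L) {
  out <- phantom_signal(spec)
  if (noise) out <- add_frame_noise(out, spec, frame_id)
  out
}

# noise-free speckle rendering, deterministic in spec$seed
phantom_signal <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    two_d <- spec$shape[3] == 1L
    vol <- array(0, spec$shape)
    sp <- spec$spacing
    if (spec$speckle_density > 0) {
      sh <- sample_shell_points(spec)
      sig_vox <- spec$blur_sigma / sp
      half <- pmax(1, ceiling(4 * sig_vox))
      if (two_d) half[3] <- 0
      for (b in seq_len(nrow(sh$points))) {
        c_vox <- sh$points[b, ] / sp           # 0-based voxel coords
        lo <- pmax(0, floor(c_vox - half))
        hi <- pmin(spec$shape - 1, ceiling(c_vox + half))
        if (any(lo > hi)) next
        ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
        gx <- exp(-((ii - c_vox[1])^2) / (2 * sig_vox[1]^2))
        gy <- exp(-((jj - c_vox[2])^2) / (2 * sig_vox[2]^2))
        gz <- if (two_d) 1 else exp(-((kk - c_vox[3])^2) / (2 * sig_vox[3]^2))
        blob <- sh$amplitudes[b] * outer(outer(gx, gy), gz)
        blob <- array(blob, c(length(ii), length(jj), length(kk)))
        vol[ii + 1, jj + 1, kk + 1] <-
          array(vol[ii + 1, jj + 1, kk + 1], dim(blob)) + blob
      }
    } else {
      sh <- list(points = matrix(0, 0, 3), amplitudes = numeric(0))
    }
    out <- image_volume(vol, sp, iop = NA_real_, frame_id = 0L)
    attr(out, "features") <- sh$points
    attr(out, "amplitudes") <- sh$amplitudes
    out
  })
}

# independent sensor noise per acquisition frame
add_frame_noise <- function(vol, spec, frame_id) {
  if (spec$noise_sd <= 0) return(vol)
  seed <- (abs(spec$seed) * 131L + as.integer(frame_id) * 7919L) %% 2147483629L
  msk <- attr(vol, "mask")
  with_seed(seed, {
    vol$data <- pmax(vol$data +
                       array(rnorm(length(vol$data), 0, spec$noise_sd),
                             dim(vol$data)), 0)
  })
  attr(vol, "mask") <- msk
  vol$frame_id <- as.integer(frame_id)
  vol
}

#' Warp a volume by a deformation model (backward mapping)
#'
#' The output intensity at deformed-grid position `x` is the input intensity
#' at `model$inverse(x)`, resampled by cubic (Catmull-Rom, default) or
#' linear interpolation; positions mapping outside the input are zero-filled
#' and flagged in the exported validity mask (attribute `mask`, which also
#' excludes a 1-voxel border where the interpolation support is truncated).
#'
#' @param image an [image_volume].
#' @param model a `deformation_model`; must be orientation-preserving
#'   (det F > 0) over the volume.
#' @param interpolation `"cubic"` (default) or `"linear"`.
#' @return The warped [image_volume] with a logical `mask` attribute.
#' @export
deform_volume <- function(image, model, interpolation = c("cubic", "linear")) {
  stopifnot(inherits(image, "image_volume"), inherits(model, "deformation_model"))
  interpolation <- match.arg(interpolation)
  cubic <- interpolation == "cubic"
  d <- vol_dim(image); sp <- image$spacing
  # sample det(F) over a coarse grid to reject folding maps
  gr_pts <- as.matrix(expand.grid(
    seq(0, (d[1] - 1) * sp[1], length.out = min(d[1], 5)),
    seq(0, (d[2] - 1) * sp[2], length.out = min(d[2], 5)),
    seq(0, (d[3] - 1) * sp[3], length.out = min(d[3], 5))))
  dets <- vapply(model$gradient(gr_pts), det, 0)
  if (any(dets <= 0))
    stopf("deformation model is not invertible over the volume (det F <= 0 sampled)")

  if (model$kind == "affine") {
    # inverse map in voxel units: x_in_vox = S^-1 (Finv (S x_out - o - t) + o)
    F <- model$parameters$F
    o <- model$parameters$origin; t <- model$parameters$shift
    Finv <- solve(F)
    S <- diag(sp); Sinv <- diag(1 / sp)
    A <- Sinv %*% Finv %*% S
    b <- drop(Sinv %*% (Finv %*% (-(o + t)) + o))
    res <- cpp_warp_affine(image$data, A, b, cubic)
  } else {
    # generic path: evaluate the inverse map on the full grid, slab by slab
    out <- array(0, d)
    msk <- array(FALSE, d)
    xi <- (seq_len(d[1]) - 1) * sp[1]
    yj <- (seq_len(d[2]) - 1) * sp[2]
    for (k in seq_len(d[3])) {
      g <- cbind(rep(xi, times = d[2]), rep(yj, each = d[1]), (k - 1) * sp[3])
      src <- model$inverse(g)
      src_vox <- sweep(src, 2, sp, "/")
      r <- cpp_interp_points(image$data, src_vox, cubic)
      out[, , k] <- r$data
      msk[, , k] <- r$mask
    }
    res <- list(data = out, mask = msk)
  }
  vout <- image_volume(res$data, sp, iop = image$iop, frame_id = image$frame_id)
  attr(vout, "mask") <- res$mask
  vout
}

#' Generate a loaded frame series with known strain law
#'
#' Builds the reference phantom and, for each subsequent load, warps it by a
#' uniaxial affine stretch along X whose longitudinal strain (relative to
#' the reference, in the chosen measure) follows the logarithmic pressure
#' law `a * ln(IOP) + b`. The exact per-frame models and strains are stored
#' as ground truth for end-to-end validation.
#'
#' @param spec a [phantom_spec].
#' @param iops strictly increasing loads, mmHg; the first is the reference.
#' @param strain_law numeric `c(a, b)` of the law `eps = a * ln(IOP) + b`.
#' @param measure strain measure in which the law is interpreted
#'   (`"log"` default, or `"small"`).
#' @param stretch_origin fixed point of the stretch (micrometres); defaults
#'   to the volume origin so that per-step feature displacements grow along
#'   the vessel as they do in a pressurised globe.
#' @return A [frame_series]; attribute `ground_truth` holds per-frame
#'   strains, stretches and `deformation_model`s.
#' @export
generate_series <- function(spec, iops, strain_law, measure = c("log", "small"),
                            stretch_origin = c(0, 0, 0)) {
  measure <- match.arg(measure)
  iops <- as.numeric(iops)
  if (length(iops) < 1 || any(diff(iops) <= 0)) stopf("`iops` must be strictly increasing")
  if (any(iops <= 0)) stopf("IOP values must be positive")
  a <- strain_law[1]; b <- strain_law[2]
  eps_rel <- a * log(iops) + b - (a * log(iops[1]) + b)
  stretch <- if (measure == "log") exp(eps_rel) else 1 + eps_rel
  if (any(stretch <= 0)) stopf("strain law yields non-positive stretch")
  # warp the noise-free signal, then add independent sensor noise per frame
  sig <- phantom_signal(spec)
  frames <- vector("list", length(iops))
  models <- vector("list", length(iops))
  models[[1]] <- deformation_affine(diag(3), origin = stretch_origin)
  frames[[1]] <- add_frame_noise(sig, spec, 0L)
  frames[[1]]$iop <- iops[1]
  for (i in seq_along(iops)[-1]) {
    F <- diag(c(stretch[i], 1, 1))
    models[[i]] <- deformation_affine(F, origin = stretch_origin)
    fr <- add_frame_noise(deform_volume(sig, models[[i]]), spec, i - 1L)
    fr$iop <- iops[i]
    frames[[i]] <- fr
  }
  ref <- frames[[1]]
  series <- frame_series(frames, reference_index = 1L, iops = iops)
  attr(series, "ground_truth") <- list(
    strain = eps_rel, stretch = stretch, measure = measure,
    models = models, law = c(a = a, b = b),
    features = attr(ref, "features"))
  series
}
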