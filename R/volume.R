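#' Scalar image volume with anisotropic voxel spacing
#'
#' The basic container for one photoacoustic frame: a 2-D or 3-D grid of
#' non-negative intensities plus the physical voxel spacing and, optionally,
#' the load (intraocular pressure) at which the frame was acquired. Voxel
#' indices are 0-based and the physical coordinate of voxel `(i, j, k)` is
#' `(i, j, k) * spacing` micrometres (voxel-corner origin); this single
#' convention is used everywhere downstream so that anisotropic spacing
#' enters strain computation exactly once.
#'
#' @param data numeric matrix or 3-D array of intensities (finite, >= 0).
#'   A matrix is stored with a singleton third axis and treated as 2-D.
#' @param spacing numeric length-3 (or length-2 for a matrix), micrometres
#'   per voxel along each axis.
#' @param iop scalar load value in mmHg, or `NA` if unknown.
#' @param frame_id integer identifier of the frame within a series.
#' @return An object of class `image_volume` with fields `data` (3-D array),
#'   `spacing`, `iop` and `frame_id`.
#' @export
image_volume <- function(data, spacing, iop = NA_real_, frame_id = 0L) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a matrix or 3-D array")
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be positive and finite (micrometres per voxel)")
  if (any(!is.finite(data)) || any(data < 0))
    stopf("intensities must be finite and non-negative")
  structure(
    list(data = data, spacing = as.numeric(spacing), iop = as.numeric(iop)[1],
         frame_id = as.integer(frame_id)),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%g, %g, %g) um%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.finite(x$iop)) sprintf(", IOP %g mmHg", x$iop) else ""))
  invisible(x)
}

is_2d <- function(vol) dim(vol$data)[3] == 1L

vol_dim <- function(vol) dim(vol$data)

#' Ordered series of frames under increasing load
#'
#' Bundles the frames of one perfusion experiment. The reference frame is the
#' near-zero-strain state: strains at every other load are computed relative
#' to it, so it must carry the lowest IOP of the series.
#'
#' @param frames list of [image_volume] objects sharing shape and spacing.
#' @param reference_index index (1-based) of the reference frame; default 1.
#' @param iops optional numeric vector of per-frame loads (mmHg); if missing,
#'   taken from the frames themselves.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, reference_index = 1L, iops = NULL) {
  if (!length(frames)) stopf("empty frame list")
  if (!all(vapply(frames, inherits, TRUE, "image_volume")))
    stopf("all frames must be image_volume objects")
  d0 <- vol_dim(frames[[1]]); s0 <- frames[[1]]$spacing
  for (f in frames) {
    if (!identical(vol_dim(f), d0)) stopf("frames differ in shape")
    if (max(abs(f$spacing - s0)) > 1e-9) stopf("frames differ in spacing")
  }
  if (is.null(iops)) iops <- vapply(frames, function(f) f$iop, 0)
  iops <- as.numeric(iops)
  if (length(iops) != length(frames)) stopf("one IOP per frame required")
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(frames))
    stopf("reference_index out of range")
  if (all(is.finite(iops)) && any(iops < iops[reference_index]))
    stopf("the reference frame must have the lowest IOP (near-zero strain state)")
  for (i in seq_along(frames)) frames[[i]]$frame_id <- i - 1L
  structure(list(frames = frames, reference_index = reference_index, iops = iops),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames, reference #%d, IOP [%s] mmHg\n",
              length(x$frames), x$reference_index,
              paste(signif(x$iops, 4), collapse = ", ")))
  invisible(x)
}
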