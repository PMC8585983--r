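#' Tracker configuration
#'
#' Settings of the multi-window correlation tracker. High-contrast voxels in
#' the reference frame are tracked frame-to-frame by scanning a search
#' region with sliding correlation windows of three sizes; a point is kept
#' at a step only if the three window sizes agree on its new location to
#' within `agreement_tol` voxels per axis (consensus rule).
#'
#' Defaults follow the published protocol this package implements: a 55%
#' neighbour-contrast detection threshold, lateral windows of 21/31/41
#' voxels with axial extents of 71/101/133 (about 3.3x the lateral extent,
#' reflecting the coarser axial resolution), a 61 x 61 x 101-voxel search
#' space, and a 2-voxel agreement range. When the axial voxel pitch differs
#' from the acquisition these numbers assume, scale the axial extents so
#' the windows cover the same physical distances (see the methods vignette).
#'
#' @param contrast_threshold minimum fractional contrast of a candidate over
#'   at least one neighbour, `(I_p - I_n)/I_n`.
#' @param lateral_windows odd lateral window extents, voxels.
#' @param axial_windows odd axial window extents, voxels; if `NULL`, derived
#'   as `odd(round(lateral_windows * axial_scale))`.
#' @param axial_scale ratio of axial to lateral window extent used when
#'   `axial_windows` is `NULL`.
#' @param search_lateral,search_axial odd search extents, voxels.
#' @param agreement_tol per-axis (Chebyshev) agreement range between the
#'   window sizes, voxels.
#' @param mode `"3d"` or `"2d"`; 2-D mode uses the lateral windows and
#'   search only.
#' @param dedup_radius if positive, candidate de-duplication radius in
#'   micrometres: among candidate pixels closer than this, only the highest
#'   contrast one is tracked (a blurred feature yields many contiguous
#'   supra-threshold pixels that carry no independent information).
#' @param subvoxel logical; refine the correlation peak to sub-voxel
#'   precision by parabolic interpolation. Off by default: the published
#'   protocol rounds tracked locations to the nearest pixel.
#' @param window_policy `"reference"` (default) correlates windows extracted
#'   from the original reference frame at the original candidate location,
#'   with only the search centre advancing frame to frame, so voxel-rounding
#'   errors do not accumulate across steps; `"incremental"` re-extracts the
#'   windows from the previous frame at each step, which tolerates stronger
#'   appearance drift at the cost of accumulating quantization error (see
#'   the methods vignette for the comparison).
#' @param eps_floor_frac fraction of the frame maximum used as the contrast
#'   denominator floor for near-zero background neighbours.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(contrast_threshold = 0.55,
                           lateral_windows = c(21L, 31L, 41L),
                           axial_windows = NULL,
                           axial_scale = 3.3,
                           search_lateral = 61L,
                           search_axial = 101L,
                           agreement_tol = 2,
                           mode = c("3d", "2d"),
                           dedup_radius = 0,
                           subvoxel = FALSE,
                           window_policy = c("reference", "incremental"),
                           eps_floor_frac = 0.05) {
  mode <- match.arg(mode)
  window_policy <- match.arg(window_policy)
  lateral_windows <- as.integer(lateral_windows)
  if (is.null(axial_windows)) {
    if (identical(lateral_windows, c(21L, 31L, 41L)) && axial_scale == 3.3) {
      axial_windows <- c(71L, 101L, 133L)
    } else {
      axial_windows <- as.integer(round(lateral_windows * axial_scale))
      axial_windows <- axial_windows + (1L - axial_windows %% 2L)
    }
  }
  axial_windows <- as.integer(axial_windows)
  ext <- c(lateral_windows, search_lateral,
           if (mode == "3d") c(axial_windows, search_axial))
  if (any(!is_odd(ext)) || any(ext < 3))
    stopf("window and search extents must be odd and >= 3")
  if (length(axial_windows) != length(lateral_windows))
    stopf("one axial extent per lateral window required")
  if (agreement_tol < 0) stopf("agreement_tol must be >= 0")
  structure(list(contrast_threshold = contrast_threshold,
                 lateral_windows = lateral_windows,
                 axial_windows = axial_windows,
                 axial_scale = axial_scale,
                 search_lateral = as.integer(search_lateral),
                 search_axial = as.integer(search_axial),
                 agreement_tol = agreement_tol,
                 mode = mode,
                 dedup_radius = dedup_radius,
                 subvoxel = subvoxel,
                 window_policy = window_policy,
                 eps_floor_frac = eps_floor_frac),
            class = "tracker_config")
}

# window extents as a k x 3 matrix of voxel counts; 2-D mode has extent 1
# along the third axis
window_matrix <- function(config, two_d) {
  k <- length(config$lateral_windows)
  cbind(config$lateral_windows, config$lateral_windows,
        if (two_d || config$mode == "2d") rep(1L, k) else config$axial_windows)
}

search_vector <- function(config, two_d) {
  c(config$search_lateral, config$search_lateral,
    if (two_d || config$mode == "2d") 1L else config$search_axial)
}

#' Detect high-contrast candidate voxels in a reference frame
#'
#' A voxel qualifies if its intensity exceeds at least one neighbour (full
#' 8-neighbourhood in 2-D, 26-neighbourhood in 3-D) by the configured
#' fractional contrast, `(I_p - I_n) / max(I_n, floor) >= threshold`, where
#' the denominator floor guards against near-zero background neighbours.
#' Voxels whose largest correlation window would leave the volume are
#' excluded. If `config$dedup_radius > 0`, candidates closer than that
#' radius (physical distance) are reduced to the locally strongest one.
#'
#' @param reference an [image_volume] (the near-zero-strain frame).
#' @param config a [tracker_config].
#' @return Integer matrix (n x 3) of 0-based voxel indices, with attribute
#'   `contrast` giving each candidate's detection contrast.
#' @export
detect_candidates <- function(reference, config) {
  stopifnot(inherits(reference, "image_volume"), inherits(config, "tracker_config"))
  d <- vol_dim(reference)
  two_d <- is_2d(reference)
  eps_floor <- config$eps_floor_frac * max(reference$data)
  if (eps_floor <= 0) eps_floor <- .Machine$double.eps
  cmax <- cpp_contrast_max(reference$data, eps_floor)
  wins <- window_matrix(config, two_d)
  hmax <- (apply(wins, 2, max) - 1L) / 2L
  # sensor noise alone shows 55% neighbour jumps but no trackable texture:
  # candidates must also clear the background noise level, estimated
  # robustly from the 90th percentile of deviations from the median
  med <- stats::median(reference$data)
  noise_scale <- unname(stats::quantile(abs(reference$data - med), 0.9)) / 1.2816
  keep <- cmax >= config$contrast_threshold &
    reference$data >= med + 7 * noise_scale
  # exclude voxels whose largest window would leave the volume
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(structure(matrix(integer(0), 0, 3), contrast = numeric(0)))
  idx0 <- idx - 1L  # 0-based
  ok <- idx0[, 1] >= hmax[1] & idx0[, 1] <= d[1] - 1 - hmax[1] &
        idx0[, 2] >= hmax[2] & idx0[, 2] <= d[2] - 1 - hmax[2] &
        idx0[, 3] >= hmax[3] & idx0[, 3] <= d[3] - 1 - hmax[3]
  idx0 <- idx0[ok, , drop = FALSE]
  contrast <- cmax[idx[ok, , drop = FALSE]]
  if (config$dedup_radius > 0 && nrow(idx0) > 1) {
    pts <- sweep(idx0, 2, reference$spacing, "*")
    keep_i <- decimate_points(pts, contrast, config$dedup_radius)
    idx0 <- idx0[keep_i, , drop = FALSE]
    contrast <- contrast[keep_i]
  }
  storage.mode(idx0) <- "integer"
  dimnames(idx0) <- NULL
  structure(idx0, contrast = contrast)
}

#' Zero-normalized cross-correlation of two intensity blocks
#'
#' The Pearson correlation of the flattened blocks: the match score used by
#' the tracker. Defined as 0 (with a `degenerate` attribute) when both
#' blocks are constant.
#'
#' @param a,b numeric arrays of identical shape.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
zncc <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stopf("blocks must have identical shape")
  av <- as.numeric(a) - mean(a)
  bv <- as.numeric(b) - mean(b)
  sa <- sum(av^2); sb <- sum(bv^2)
  if (sa <= 1e-24 || sb <= 1e-24) {
    return(structure(0, degenerate = TRUE))
  }
  max(-1, min(1, sum(av * bv) / sqrt(sa * sb)))
}

#' Find the best correlation match for one window around a location
#'
#' Scans the search region of `next_frame` centred on `loc` with a sliding
#' window and returns the location maximizing the zero-normalized
#' cross-correlation with the window extracted from `ref_frame` at `loc`.
#' The search region is clipped to the volume bounds; ties break by the
#' smallest displacement magnitude, then lexicographic displacement order.
#'
#' @param ref_frame,next_frame [image_volume]s of identical shape.
#' @param loc length-3 integer 0-based voxel index (the window centre).
#' @param window length-3 odd window extents (voxels).
#' @param search length-3 odd search extents (voxels).
#' @param subvoxel logical, parabolic sub-voxel refinement of the peak.
#' @return List with `loc` (matched location, 0-based), `displacement`,
#'   `corr`, and `status` (`"ok"`, `"degenerate"` or `"bounds"`).
#' @export
search_best_match <- function(ref_frame, next_frame, loc, window, search,
                              subvoxel = FALSE) {
  stopifnot(inherits(ref_frame, "image_volume"))
  loc <- as.integer(loc)
  window <- as.integer(window); search <- as.integer(search)
  if (length(loc) == 2L) loc <- c(loc, 0L)
  if (length(window) == 2L) window <- c(window, 1L)
  if (length(search) == 2L) search <- c(search, 1L)
  m <- cpp_match_windows(ref_frame$data, next_frame$data,
                         matrix(loc, 1), matrix(loc, 1),
                         matrix(window, 1), search, subvoxel)
  status <- c("ok", "degenerate", "bounds")[m[1, 5] + 1]
  if (status != "ok")
    return(list(loc = NULL, displacement = NULL, corr = NA_real_, status = status))
  disp <- m[1, 1:3]
  list(loc = loc + disp, displacement = disp, corr = m[1, 4], status = "ok")
}

# consensus across window sizes for a batch of candidate locations
# locs: n x 3 integer search centres (0-based); tlocs: template centres in
# prev_frame (defaults to locs). Returns list(loc = n x 3 (numeric), ok,
# reason, corr = n x k matrix).
track_step_batch <- function(prev_frame, next_frame, locs, config, tlocs = locs) {
  two_d <- is_2d(prev_frame)
  wins <- window_matrix(config, two_d)
  search <- search_vector(config, two_d)
  m <- cpp_match_windows(prev_frame$data, next_frame$data, locs, tlocs,
                         wins, search, config$subvoxel)
  k <- nrow(wins)
  n <- nrow(locs)
  status <- m[, 5 * seq_len(k), drop = FALSE]
  corr <- m[, 5 * seq_len(k) - 1, drop = FALSE]
  new_loc <- matrix(NA_real_, n, 3)
  ok <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  d1 <- m[, 5 * (seq_len(k) - 1) + 1, drop = FALSE]
  d2 <- m[, 5 * (seq_len(k) - 1) + 2, drop = FALSE]
  d3 <- m[, 5 * (seq_len(k) - 1) + 3, drop = FALSE]
  for (i in seq_len(n)) {
    st <- status[i, ]
    if (any(st == 2)) { reason[i] <- "bounds"; next }
    if (any(st == 1)) { reason[i] <- "degenerate"; next }
    cand <- rbind(d1[i, ], d2[i, ], d3[i, ])  # 3 x k displacements
    spread <- apply(cand, 1, function(x) diff(range(x)))
    if (any(spread > config$agreement_tol)) { reason[i] <- "consensus"; next }
    mean_disp <- rowMeans(cand)
    nl <- locs[i, ] + mean_disp
    if (!config$subvoxel) nl <- round_half_away(nl)
    new_loc[i, ] <- nl
    ok[i] <- TRUE
  }
  list(loc = new_loc, ok = ok, reason = reason, corr = corr)
}

#' Track one point through one frame step
#'
#' Runs [search_best_match] with each configured window size. If the
#' per-axis spread of the resulting locations is within the agreement
#' range, the new location is their mean rounded to the nearest voxel
#' (half away from zero); otherwise the point is rejected.
#'
#' @param prev_frame,next_frame consecutive [image_volume]s.
#' @param loc length-3 integer 0-based location of the point in `prev_frame`.
#' @param config a [tracker_config].
#' @return List with `loc` (new 0-based location or `NULL`), `accepted`,
#'   `reason` (`NA`, `"consensus"`, `"bounds"` or `"degenerate"`), and the
#'   per-window correlation coefficients.
#' @export
track_step <- function(prev_frame, next_frame, loc, config) {
  loc <- as.integer(loc)
  if (length(loc) == 2L) loc <- c(loc, 0L)
  r <- track_step_batch(prev_frame, next_frame, matrix(loc, 1), config)
  list(loc = if (r$ok[1]) drop(r$loc[1, ]) else NULL,
       accepted = r$ok[1], reason = r$reason[1], corr = drop(r$corr[1, ]))
}

#' Track all detected candidates through a frame series
#'
#' Candidates are detected in the reference frame and followed
#' frame-to-frame; a point rejected at any step (consensus failure, window
#' leaving the volume, or degenerate texture) is excluded from meshing but
#' retained in the output with its rejection record. With the default
#' incremental window policy, correlation windows are re-extracted from the
#' previous frame at each step while the search stays centred on the
#' current location.
#'
#' @param series a [frame_series] with at least 2 frames.
#' @param config a [tracker_config].
#' @return An object of class `trajectory_set`: a list of trajectories with
#'   fields `point_id`, `loc` (frames x 3, 0-based voxel indices), `status`
#'   (`"accepted"`/`"rejected"`), `reject_frame`, `reject_reason`, `corr`
#'   and detection `contrast`.
#' @export
track_series <- function(series, config) {
  stopifnot(inherits(series, "frame_series"), inherits(config, "tracker_config"))
  nf <- length(series$frames)
  if (nf < 2) stopf("need at least 2 frames")
  ref_i <- series$reference_index
  ref <- series$frames[[ref_i]]
  cand <- detect_candidates(ref, config)
  n <- nrow(cand)
  if (n == 0L)
    stopf(paste("no trackable candidates in the reference frame;",
                "increase phantom speckle density or lower the contrast threshold"))
  order_frames <- c(ref_i, setdiff(seq_len(nf), ref_i))  # reference first
  # locations per frame (frame-major), in series frame order
  locs <- array(NA_real_, c(nf, n, 3))
  locs[ref_i, , ] <- cand
  alive <- rep(TRUE, n)
  reject_frame <- rep(NA_integer_, n)
  reject_reason <- rep(NA_character_, n)
  corr <- array(NA_real_, c(nf, n, length(config$lateral_windows)))
  cur <- cand
  prev_frame <- ref
  for (step in seq_along(order_frames)[-1]) {
    fi <- order_frames[step]
    next_frame <- series$frames[[fi]]
    live_idx <- which(alive)
    if (!length(live_idx)) break
    cur_int <- matrix(as.integer(round_half_away(cur[live_idx, , drop = FALSE])),
                      ncol = 3)
    if (config$window_policy == "incremental") {
      r <- track_step_batch(prev_frame, next_frame, cur_int, config)
    } else {
      # windows always come from the original reference frame at the
      # original candidate location; only the search centre advances
      tl <- matrix(as.integer(cand[live_idx, , drop = FALSE]), ncol = 3)
      r <- track_step_batch(ref, next_frame, cur_int, config, tlocs = tl)
    }
    for (j in seq_along(live_idx)) {
      i <- live_idx[j]
      corr[fi, i, ] <- r$corr[j, ]
      if (r$ok[j]) {
        locs[fi, i, ] <- r$loc[j, ]
      } else {
        alive[i] <- FALSE
        reject_frame[i] <- fi - 1L   # 0-based frame id
        reject_reason[i] <- r$reason[j]
      }
    }
    cur[live_idx[r$ok], ] <- r$loc[r$ok, , drop = FALSE]
    prev_frame <- next_frame
  }
  trajectories <- lapply(seq_len(n), function(i) {
    list(point_id = i - 1L,
         loc = locs[, i, , drop = TRUE],
         status = if (alive[i]) "accepted" else "rejected",
         reject_frame = reject_frame[i],
         reject_reason = reject_reason[i],
         corr = corr[, i, , drop = TRUE],
         contrast = attr(cand, "contrast")[i])
  })
  out <- structure(list(trajectories = trajectories, n_frames = nf,
                        mode = config$mode,
                        spacing = ref$spacing,
                        reference_index = ref_i),
                   class = "trajectory_set")
  if (!any(alive))
    stopf(paste("no trajectory survived tracking;",
                "increase phantom speckle density or relax the tracker settings"))
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- length(x$trajectories)
  acc <- sum(vapply(x$trajectories, function(t) t$status == "accepted", TRUE))
  cat(sprintf("<trajectory_set> %d points over %d frames (%d accepted, %d rejected)\n",
              n, x$n_frames, acc, n - acc))
  invisible(x)
}

accepted_trajectories <- function(ts) {
  Filter(function(t) t$status == "accepted", ts$trajectories)
}
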