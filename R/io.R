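#' Read and write image volumes (NRRD, TIFF)
#'
#' NRRD files round-trip volumes exactly: the payload is raw little-endian
#' double with spacing, load and frame id in the header. TIFF files store
#' one page per axial slice with 32-bit samples (values must lie in
#' `[0, 1]`; intensities quantize at 2^-32). TIFF carries no spacing
#' metadata here, so reading a TIFF requires an explicit `spacing`
#' override. A 2-D TIFF yields a volume with a singleton third axis,
#' switching the pipeline to 2-D mode.
#'
#' @param path file path; format chosen by extension (`.nrrd`, `.tif`,
#'   `.tiff`).
#' @param spacing voxel spacing override (micrometres per axis), required
#'   for TIFF input.
#' @return `read_volume()` returns an [image_volume]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") return(read_nrrd(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing))
      stopf("TIFF carries no spacing metadata: pass `spacing` explicitly")
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    return(image_volume(arr, spacing))
  }
  stopf("unsupported volume extension '.%s' (use .nrrd or .tif)", ext)
}

#' @rdname read_volume
#' @param image an [image_volume] to write.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "image_volume"))
  if (!dir.exists(dirname(path))) stopf("directory does not exist: %s", dirname(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    write_nrrd(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (min(image$data) < 0 || max(image$data) > 1)
      stopf("TIFF output stores 32-bit float in [0, 1]; rescale the volume first")
    d <- vol_dim(image)
    pages <- lapply(seq_len(d[3]), function(k) image$data[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    stopf("unsupported volume extension '.%s' (use .nrrd or .tif)", ext)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stopf("not an NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stopf("NRRD header missing required field '%s'", f)
    fields[[f]]
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- need("encoding")
  if (enc != "raw") stopf("only raw NRRD encoding is supported")
  spacing <- as.numeric(strsplit(need("spacings"), "\\s+")[[1]])
  endian <- fields[["endian"]] %||% "little"
  n <- prod(sizes)
  what <- switch(type,
    "double" = "double", "float" = "double",
    stopf("unsupported NRRD type '%s'", type))
  size <- if (type == "double") 8L else 4L
  data <- readBin(con, "double", n = n, size = size,
                  endian = if (endian == "big") "big" else "little")
  if (length(data) != n) stopf("truncated NRRD payload in %s", path)
  arr <- array(data, if (length(sizes) == 2L) c(sizes, 1L) else sizes)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  iop <- as.numeric(fields[["iop"]] %||% NA)
  frame_id <- as.integer(fields[["frame"]] %||% 0)
  image_volume(arr, spacing, iop = iop, frame_id = frame_id)
}

write_nrrd <- function(image, path) {
  d <- vol_dim(image)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# veinstrain volume",
           "type: double",
           sprintf("dimension: %d", 3L),
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g",
                   image$spacing[1], image$spacing[2], image$spacing[3]),
           "encoding: raw",
           "endian: little",
           if (is.finite(image$iop)) sprintf("iop:=%.17g", image$iop),
           sprintf("frame:=%d", image$frame_id),
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(image$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Export a mesh with tensor fields as legacy VTK
#'
#' Writes an ASCII legacy-VTK unstructured grid (triangle or tetrahedral
#' cells) with tensor components stored as named scalar arrays
#' (`<name>_XX`, `_YY`, `_ZZ`, `_XY`, `_YZ`, `_XZ`), readable by standard
#' viewers. Element reference measures are always included as a cell array.
#'
#' @param mesh a `strain_mesh`.
#' @param fields named list of per-element (rows = elements) or per-node
#'   (rows = nodes) component matrices, e.g. from [field_strain] or
#'   [nodal_strains].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, fields = list(), path) {
  stopifnot(inherits(mesh, "strain_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  for (nm in names(fields)) {
    r <- nrow(rbind(fields[[nm]]))
    if (!r %in% c(n, m))
      stopf("field '%s' has %d rows; expected %d (elements) or %d (nodes)",
            nm, r, m, n)
  }
  k <- ncol(mesh$elements)
  lines <- c("# vtk DataFile Version 3.0",
             "veinstrain mesh", "ASCII", "DATASET UNSTRUCTURED_GRID",
             sprintf("POINTS %d double", n))
  lines <- c(lines, apply(mesh$nodes, 1, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])))
  lines <- c(lines, sprintf("CELLS %d %d", m, m * (k + 1)))
  lines <- c(lines, apply(mesh$elements, 1, function(e)
    paste(c(k, e - 1L), collapse = " ")))
  cell_type <- if (k == 3L) 5L else 10L
  lines <- c(lines, sprintf("CELL_TYPES %d", m), rep(as.character(cell_type), m))

  fmt_scalars <- function(name, v)
    c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default",
      sprintf("%.9g", v))
  cell_fields <- Filter(function(f) nrow(rbind(f)) == m, fields)
  node_fields <- Filter(function(f) nrow(rbind(f)) == n && m != n, fields)
  lines <- c(lines, sprintf("CELL_DATA %d", m),
             fmt_scalars(if (mesh$mode == "2d") "ref_area" else "ref_volume",
                         mesh$ref_measure))
  for (nm in names(cell_fields)) {
    f <- rbind(cell_fields[[nm]])
    cn <- colnames(f) %||% paste0("c", seq_len(ncol(f)))
    for (j in seq_len(ncol(f)))
      lines <- c(lines, fmt_scalars(paste0(nm, "_", cn[j]), f[, j]))
  }
  if (length(node_fields)) {
    lines <- c(lines, sprintf("POINT_DATA %d", n))
    for (nm in names(node_fields)) {
      f <- rbind(node_fields[[nm]])
      cn <- colnames(f) %||% paste0("c", seq_len(ncol(f)))
      for (j in seq_len(ncol(f)))
        lines <- c(lines, fmt_scalars(paste0(nm, "_", cn[j]), f[, j]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Minimal legacy-VTK unstructured grid reader
#'
#' Reads files produced by [write_mesh_vtk] (round-trip checks, viewers are
#' the primary consumers of the format).
#'
#' @param path a legacy ASCII VTK file.
#' @return List with `points`, `elements`, `cell_type`, and `cell_data` /
#'   `point_data` (named lists of numeric vectors).
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  i <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  pts <- matrix(scan(text = lines[(i + 1):(i + n)], quiet = TRUE), n, 3, byrow = TRUE)
  i <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  raw <- lapply(lines[(i + 1):(i + m)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  k <- raw[[1]][1]
  el <- t(vapply(raw, function(r) r[-1] + 1L, integer(k)))
  i <- grep("^CELL_TYPES", lines)[1]
  ct <- as.integer(lines[i + 1])
  parse_scalars <- function(start, count) {
    out <- list()
    j <- start
    while (j <= length(lines) && grepl("^SCALARS", lines[j])) {
      nm <- strsplit(lines[j], "\\s+")[[1]][2]
      vals <- as.numeric(lines[(j + 2):(j + 1 + count)])
      out[[nm]] <- vals
      j <- j + 2 + count
    }
    out
  }
  cd <- list(); pd <- list()
  i <- grep("^CELL_DATA", lines)
  if (length(i)) cd <- parse_scalars(i[1] + 1, m)
  i <- grep("^POINT_DATA", lines)
  if (length(i)) pd <- parse_scalars(i[1] + 1, n)
  list(points = pts, elements = el, cell_type = ct,
       cell_data = cd, point_data = pd)
}

#' Write and read tracked trajectories as CSV
#'
#' One row per tracked frame per point with columns `point_id`, `frame`
#' (0-based), `i`, `j`, `k` (0-based voxel indices) and `status`
#' (`"accepted"` or `"rejected:<reason>@<frame>"`). Voxel indices, not
#' physical coordinates, are stored; conversion to micrometres happens at
#' meshing.
#'
#' @param trajectories a `trajectory_set`.
#' @param path CSV path.
#' @return `path` invisibly; `read_trajectories()` returns a
#'   `trajectory_set`.
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  rows <- lapply(trajectories$trajectories, function(t) {
    loc <- rbind(t$loc)
    tracked <- which(apply(is.finite(loc), 1, all))
    if (t$status == "accepted" && length(tracked) != trajectories$n_frames)
      stopf("ragged trajectory %d: accepted but only %d of %d frames tracked",
            t$point_id, length(tracked), trajectories$n_frames)
    status <- if (t$status == "accepted") "accepted"
              else sprintf("rejected:%s@%d", t$reject_reason, t$reject_frame)
    data.frame(point_id = t$point_id, frame = tracked - 1L,
               i = loc[tracked, 1], j = loc[tracked, 2], k = loc[tracked, 3],
               status = status)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(point_id = integer(0), frame = integer(0),
                        i = numeric(0), j = numeric(0), k = numeric(0),
                        status = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param n_frames total frame count of the originating series (inferred
#'   from accepted trajectories when omitted).
#' @param spacing voxel spacing of the originating series (micrometres).
#' @export
read_trajectories <- function(path, n_frames = NULL, spacing = c(1, 1, 1)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(structure(list(trajectories = list(), n_frames = n_frames %||% 0L,
                          mode = "3d", spacing = spacing, reference_index = 1L),
                     class = "trajectory_set"))
  }
  nf <- n_frames %||% (max(df$frame) + 1L)
  split_df <- split(df, df$point_id)
  trajectories <- lapply(split_df, function(g) {
    loc <- matrix(NA_real_, nf, 3)
    loc[g$frame + 1L, ] <- as.matrix(g[, c("i", "j", "k")])
    st <- g$status[1]
    if (st == "accepted") {
      list(point_id = g$point_id[1], loc = loc, status = "accepted",
           reject_frame = NA_integer_, reject_reason = NA_character_,
           corr = NULL, contrast = NA_real_)
    } else {
      mm <- regmatches(st, regexec("^rejected:([^@]+)@(\\d+)$", st))[[1]]
      list(point_id = g$point_id[1], loc = loc, status = "rejected",
           reject_frame = as.integer(mm[3]), reject_reason = mm[2],
           corr = NULL, contrast = NA_real_)
    }
  })
  names(trajectories) <- NULL
  trajectories <- trajectories[order(vapply(trajectories, `[[`, 0L, "point_id"))]
  structure(list(trajectories = trajectories, n_frames = nf, mode = "3d",
                 spacing = spacing, reference_index = 1L),
            class = "trajectory_set")
}

#' Serialize a run configuration
#'
#' A run configuration bundles every tunable of the pipeline (tracker
#' settings, decimation radius, strain measure, coordinate rotation, seed,
#' output paths) and round-trips through JSON unchanged.
#'
#' @param config a list as produced by [default_run_config()].
#' @param path JSON path.
#' @return `path` invisibly; `read_run_config()` returns the configuration
#'   list.
#' @export
write_run_config <- function(config, path) {
  config <- unclass(config)
  config <- lapply(config, function(x) if (is.object(x)) unclass(x) else x)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tc <- cfg$tracker
  cfg$tracker <- tracker_config(
    contrast_threshold = tc$contrast_threshold,
    lateral_windows = tc$lateral_windows,
    axial_windows = tc$axial_windows,
    axial_scale = tc$axial_scale,
    search_lateral = tc$search_lateral,
    search_axial = tc$search_axial,
    agreement_tol = tc$agreement_tol,
    mode = tc$mode,
    dedup_radius = tc$dedup_radius,
    subvoxel = tc$subvoxel,
    window_policy = tc$window_policy,
    eps_floor_frac = tc$eps_floor_frac)
  structure(cfg, class = "run_config")
}

#' Default pipeline run configuration
#'
#' @param mode `"3d"` or `"2d"`.
#' @param seed integer seed for all stochastic stages.
#' @param ... overrides for individual fields (`tracker`,
#'   `decimate_radius`, `quality_floor`, `measure`, `rotation`, `out_dir`).
#' @return A `run_config` list.
#' @export
default_run_config <- function(mode = "3d", seed = 1L, ...) {
  cfg <- list(
    tracker = tracker_config(mode = mode, dedup_radius = 12),
    decimate_radius = 30,
    quality_floor = 0.05,
    measure = "log",
    rotation = NULL,
    out_dir = NULL,
    seed = as.integer(seed))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}
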