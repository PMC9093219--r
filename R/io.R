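#' Write a volume as MetaImage MHD + RAW
#'
#' Plain-text MHD header plus little-endian float64 raw payload; the round
#' trip through [read_mhd()] is lossless (bitwise-equal values, identical
#' spacing).
#'
#' @param volume A [ct_volume()].
#' @param path Path to the `.mhd` header; the `.raw` payload is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  g <- volume$grid
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g",
            grid_corner(g)[1], grid_corner(g)[2], grid_corner(g)[3]),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            g$voxel_size[1], g$voxel_size[2], g$voxel_size[3]),
    sprintf("DimSize = %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(volume$values), con, size = 8, endian = "little")
  invisible(path)
}

parse_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

mhd_field <- function(kv, name) {
  if (is.null(kv[[name]]))
    stop(sprintf("malformed MHD header: missing field '%s'", name))
  kv[[name]]
}

#' Read a MetaImage MHD + RAW volume
#'
#' Supports 3D `MET_DOUBLE`, `MET_FLOAT`, `MET_SHORT`, `MET_USHORT` and
#' `MET_UCHAR` payloads, little-endian unless the header says otherwise.
#' Malformed headers and truncated payloads raise errors naming the
#' offending field or the expected vs actual byte count.
#'
#' @param path Path to the `.mhd` header.
#' @return A [ct_volume()] (grid centred so that the header `Offset` is the
#'   min corner).
#' @export
read_mhd <- function(path) {
  kv <- parse_mhd_header(path)
  ndims <- as.integer(mhd_field(kv, "NDims"))
  if (!identical(ndims, 3L))
    stop(sprintf("malformed MHD header: NDims = %d (only 3 supported)", ndims))
  dims <- as.integer(strsplit(mhd_field(kv, "DimSize"), "\\s+")[[1]])
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1))
    stop("malformed MHD header: DimSize must be three positive integers")
  spacing <- as.numeric(strsplit(mhd_field(kv, "ElementSpacing"), "\\s+")[[1]])
  if (length(spacing) != 3 || any(is.na(spacing)) || any(spacing <= 0))
    stop("malformed MHD header: ElementSpacing must be three positive numbers")
  offset <- rep(0, 3)
  if (!is.null(kv[["Offset"]]))
    offset <- as.numeric(strsplit(kv[["Offset"]], "\\s+")[[1]])
  etype <- mhd_field(kv, "ElementType")
  esize <- switch(etype, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                  MET_USHORT = 2L, MET_UCHAR = 1L,
                  stop(sprintf("malformed MHD header: ElementType '%s' not supported",
                               etype)))
  endian <- if (identical(kv[["BinaryDataByteOrderMSB"]], "True"))
    "big" else "little"
  raw_path <- file.path(dirname(path), mhd_field(kv, "ElementDataFile"))
  if (!file.exists(raw_path))
    stop(sprintf("raw payload '%s' not found", raw_path))
  n <- prod(dims)
  expect_bytes <- n * esize
  actual_bytes <- file.size(raw_path)
  if (actual_bytes < expect_bytes)
    stop(sprintf("truncated RAW payload: expected %d bytes, found %d",
                 expect_bytes, actual_bytes))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(etype,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = endian),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = endian),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                        endian = endian),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = endian),
    MET_UCHAR = as.numeric(readBin(con, "raw", n = n)))
  grid <- volume_grid(dims, spacing,
                      origin = offset + dims * spacing / 2)
  ct_volume(grid, array(as.numeric(vals), dim = dims))
}

#' Write / read a volume as NIfTI
#'
#' Stored as 64-bit float with the grid spacing in `pixdim`; lossless round
#' trip of values and spacing.
#'
#' @param volume A [ct_volume()].
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `write_nifti`: `path` invisibly; `read_nifti`: a [ct_volume()].
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(structure(volume$values,
                                   pixdim = volume$grid$voxel_size),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3) stop("expected a 3D NIfTI volume")
  spacing <- RNifti::pixdim(img)[1:3]
  ct_volume(volume_grid(dim(vals), spacing),
            array(as.numeric(vals), dim = dim(vals)))
}

geometry_to_list <- function(geometry) {
  list(dist_source_detector = geometry$dist_source_detector,
       dist_source_origin = geometry$dist_source_origin,
       view_angles = as.numeric(geometry$view_angles),
       detector_shape = as.integer(geometry$detector_shape),
       detector_pixel = as.numeric(geometry$detector_pixel),
       detector_offset = as.numeric(geometry$detector_offset))
}

geometry_from_list <- function(lst) {
  cone_beam_geometry(dist_source_detector = lst$dist_source_detector,
                     dist_source_origin = lst$dist_source_origin,
                     view_angles = as.numeric(lst$view_angles),
                     detector_shape = lst$detector_shape,
                     detector_pixel = lst$detector_pixel,
                     detector_offset = if (is.null(lst$detector_offset))
                       c(0, 0) else lst$detector_offset)
}

#' Write / read projection stacks
#'
#' Frames are stored as one 32-bit float TIFF page per view angle plus a
#' YAML sidecar (`<path>.yaml`) carrying the geometry block and the
#' intensity range used to map line integrals onto the TIFF unit scale.
#' The round trip restores line integrals to single precision (relative
#' about 1e-7), the native precision of flat-panel projection interchange.
#'
#' @param projections A [projection_set()].
#' @param path Path to a `.tif`/`.tiff` file.
#' @return `write_projections`: `path` invisibly; `read_projections`: a
#'   [projection_set()].
#' @export
write_projections <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  lo <- min(projections$frames)
  span <- max(projections$frames) - lo
  if (span == 0) span <- 1
  pages <- lapply(seq_len(dim(projections$frames)[3]), function(v) {
    (projections$frames[, , v, drop = TRUE] - lo) / span
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(geometry = geometry_to_list(projections$geometry),
                        intensity = list(offset = lo, scale = span)),
                   paste0(path, ".yaml"), precision = 17)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop(sprintf("geometry sidecar '%s' not found", sidecar))
  meta <- yaml::read_yaml(sidecar)
  geom <- geometry_from_list(meta$geometry)
  lo <- if (is.null(meta$intensity)) 0 else meta$intensity$offset
  span <- if (is.null(meta$intensity)) 1 else meta$intensity$scale
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != geom$n_views)
    stop(sprintf("projection stack has %d pages but geometry lists %d views",
                 length(pages), geom$n_views))
  frames <- array(0, dim = c(geom$detector_shape, geom$n_views))
  for (v in seq_along(pages)) {
    pg <- pages[[v]]
    if (!identical(as.integer(dim(pg)[1:2]), geom$detector_shape))
      stop(sprintf("page %d shape %dx%d does not match detector %dx%d",
                   v, nrow(pg), ncol(pg),
                   geom$detector_shape[1], geom$detector_shape[2]))
    frames[, , v] <- pg * span + lo
  }
  projection_set(geom, frames)
}

#' Run configuration
#'
#' Assembles (and validates) the geometry, grid, algorithm choice,
#' per-algorithm parameter blocks, noise model and seed of a reconstruction
#' or comparison run; [read_run_config()] builds one from a YAML file with
#' blocks `geometry`, `grid`, and optional `algorithm`, `sart`, `tpv`,
#' `baseline`, `tpv_gif`, `gif`, `noise`, `seed`.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param grid A [volume_grid()].
#' @param algorithm One of `"sart"`, `"sart-tv"`, `"asd-pocs"`, `"tpv"`,
#'   `"tpv-gif"`.
#' @param sart,tpv,baseline,tpv_gif Parameter objects (defaults: the
#'   published operating points).
#' @param noise,photons_per_ray,seed Simulation noise model (see
#'   [simulation_config()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry, grid, algorithm = "tpv-gif",
                       sart = sart_params(), tpv = tpv_params(),
                       baseline = tv_baseline_params(),
                       tpv_gif = tpv_gif_params(sart = sart, tpv = tpv),
                       noise = "none", photons_per_ray = 1e5, seed = 1L) {
  algorithm <- match.arg(algorithm,
                         c("sart", "sart-tv", "asd-pocs", "tpv", "tpv-gif"))
  stopifnot(inherits(geometry, "cone_beam_geometry"),
            inherits(grid, "volume_grid"))
  structure(list(geometry = geometry, grid = grid, algorithm = algorithm,
                 sart = sart, tpv = tpv, baseline = baseline,
                 tpv_gif = tpv_gif, noise = noise,
                 photons_per_ray = photons_per_ray, seed = as.integer(seed)),
            class = "run_config")
}

#' @param path Path to a YAML configuration file.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry)) stop("config must contain a geometry block")
  if (is.null(cfg$grid)) stop("config must contain a grid block")
  geom <- if (!is.null(cfg$geometry$view_angles)) {
    geometry_from_list(cfg$geometry)
  } else {
    cone_beam_geometry(
      dist_source_detector = cfg$geometry$dist_source_detector,
      dist_source_origin = cfg$geometry$dist_source_origin,
      n_views = cfg$geometry$n_views,
      detector_shape = cfg$geometry$detector_shape,
      detector_pixel = cfg$geometry$detector_pixel,
      detector_offset = if (is.null(cfg$geometry$detector_offset)) c(0, 0)
        else cfg$geometry$detector_offset)
  }
  grid <- volume_grid(cfg$grid$shape,
                      if (is.null(cfg$grid$voxel_size)) c(1, 1, 1)
                        else cfg$grid$voxel_size,
                      if (is.null(cfg$grid$origin)) c(0, 0, 0)
                        else cfg$grid$origin)
  args <- list(geometry = geom, grid = grid)
  if (!is.null(cfg$algorithm)) args$algorithm <- cfg$algorithm
  if (!is.null(cfg$sart)) args$sart <- do.call(sart_params, cfg$sart)
  if (!is.null(cfg$tpv)) args$tpv <- do.call(tpv_params, cfg$tpv)
  if (!is.null(cfg$baseline))
    args$baseline <- do.call(tv_baseline_params, cfg$baseline)
  gif <- if (!is.null(cfg$gif)) do.call(guided_filter_params, cfg$gif)
    else guided_filter_params()
  tg <- cfg$tpv_gif
  args$tpv_gif <- tpv_gif_params(
    n_outer = if (is.null(tg$n_outer)) 20L else tg$n_outer,
    sart = if (is.null(args$sart)) sart_params() else args$sart,
    tpv = if (is.null(args$tpv)) tpv_params() else args$tpv,
    gif = gif)
  if (!is.null(cfg$noise)) args$noise <- cfg$noise
  if (!is.null(cfg$photons_per_ray)) args$photons_per_ray <- cfg$photons_per_ray
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(run_config, args)
}
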