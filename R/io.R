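#' Write channel data to an HDF5 container
#'
#' Layout: dataset `/channel_data` (N x M, float32) with attributes
#' `sampling_rate_hz`, `sound_speed_mps`, `t0_s`; group `/geometry` with
#' dataset `positions` (N x dim, float64, meters), attributes `label` and,
#' when the array has one, `radius`.
#'
#' @param data a `pa_channel_data`.
#' @param path output `.h5` file (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_channel_data <- function(data, path) {
  stopifnot(inherits(data, "pa_channel_data"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "channel_data", dims = dim(data$traces),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(data$traces, path, "channel_data")
  rhdf5::h5createGroup(path, "geometry")
  rhdf5::h5write(data$geometry$positions, path, "geometry/positions")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, "channel_data")
  rhdf5::h5writeAttribute(data$params$sampling_rate, did, "sampling_rate_hz")
  rhdf5::h5writeAttribute(data$params$sound_speed, did, "sound_speed_mps")
  rhdf5::h5writeAttribute(data$params$t0, did, "t0_s")
  rhdf5::H5Dclose(did)
  gid <- rhdf5::H5Gopen(fid, "geometry")
  rhdf5::h5writeAttribute(data$geometry$label, gid, "label")
  if (!is.null(data$geometry$radius))
    rhdf5::h5writeAttribute(data$geometry$radius, gid, "radius")
  rhdf5::H5Gclose(gid)
  invisible(path)
}

#' Read channel data from an HDF5 container
#'
#' Accepts the layout written by [write_channel_data()] (also the
#' interchange point for user-supplied measured data).
#'
#' @param path an `.h5` file.
#' @return A `pa_channel_data`.
#' @export
read_channel_data <- function(path) {
  traces <- rhdf5::h5read(path, "channel_data")
  pos <- rhdf5::h5read(path, "geometry/positions")
  a <- rhdf5::h5readAttributes(path, "channel_data")
  ga <- rhdf5::h5readAttributes(path, "geometry")
  geom <- new_pa_array(pos, as.character(ga$label %||% "imported"))
  if (!is.null(ga$radius)) geom$radius <- as.numeric(ga$radius)
  params <- pa_acquisition(sound_speed = as.numeric(a$sound_speed_mps),
                           sampling_rate = as.numeric(a$sampling_rate_hz),
                           n_samples = ncol(traces),
                           t0 = as.numeric(a$t0_s))
  new_channel_data(traces, geom, params)
}

#' Write an image to TIFF (2D) or NIfTI (3D)
#'
#' 2D images go to float32 TIFF with the pixel size recorded in a JSON
#' sidecar (`<path>.json`, spacing in meters); 3D volumes go to
#' uncompressed NIfTI-1 with the spacing in `pixdim` (mm). The file type
#' follows the extension (`.tif`/`.tiff` or `.nii`).
#'
#' @param image a `pa_recon`, `pa_phantom`, `pa_prior` (writes `Pnorm`),
#'   or numeric array.
#' @param path output file.
#' @param grid required when `image` is a bare array.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, grid = NULL) {
  if (inherits(image, "pa_prior")) {
    grid <- image$grid; vals <- image$Pnorm
  } else if (inherits(image, c("pa_recon", "pa_phantom"))) {
    grid <- image$grid; vals <- image$values
  } else {
    vals <- as.array(image)
    if (is.null(grid)) grid <- pa_grid(dim(vals), 1)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (length(dim(vals)) != 2L)
      stop("TIFF output requires a 2D image; use .nii for volumes")
    tiff::writeTIFF(vals, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(list(spacing_m = grid$spacing),
                         paste0(path, ".json"), digits = NA)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- grid$spacing * 1e3
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read a TIFF or NIfTI image written by [write_image()]
#'
#' @param path a `.tif`/`.tiff` or `.nii` file.
#' @return A numeric array (2D matrix or 3D array).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    unclass(tiff::readTIFF(path, as.is = FALSE))
  } else if (ext == "nii") {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  } else {
    stop("unsupported image extension: ", ext)
  }
}

#' Persist a subset plan as JSON (provenance)
#'
#' @param plan a `pa_subset_plan`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_subset_plan <- function(plan, path) {
  stopifnot(inherits(plan, "pa_subset_plan"))
  jsonlite::write_json(
    list(n_elements = plan$n_elements, s = plan$s, k = plan$k,
         seed = plan$seed, method = plan$method,
         index_base = 1L, subsets = plan$subsets),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
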