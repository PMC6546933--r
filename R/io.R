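#' Read and write volumetric images (NIfTI)
#'
#' Thin wrappers around RNifti carrying the voxel size. Arrays are stored
#' voxelwise with the voxel dimensions recorded in the NIfTI header.
#'
#' @param x 3D or 4D numeric/logical array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions, mm (length 3).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   the array with a `voxel_size_mm` attribute.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  out
}

#' Write / read a vessel-encoded series with its sidecar
#'
#' The 4D data is written as NIfTI; the sidecar YAML records the
#' acquisition protocol, the volume schedule (so permuted series decode
#' identically when the sidecar matches) and the encoding matrix.
#'
#' @param series An `asl_series`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.yaml`.
#' @return `write_series` returns `prefix` invisibly; `read_series`
#'   returns an `asl_series`.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "asl_series"))
  write_volume(series$data, paste0(prefix, ".nii.gz"),
               series$voxel_size_mm)
  sidecar <- list(
    protocol = unclass(series$protocol),
    schedule = as.list(series$schedule),
    encoding = list(
      cycles = rownames(series$matrix$weights),
      arteries = colnames(series$matrix$weights),
      weights = apply(series$matrix$weights, 1, as.numeric,
                      simplify = FALSE)
    ),
    noise_sd = series$noise_sd,
    voxel_size_mm = series$voxel_size_mm
  )
  yaml::write_yaml(sidecar, paste0(prefix, ".yaml"), precision = 15L)
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  data <- read_volume(paste0(prefix, ".nii.gz"))
  sc <- yaml::read_yaml(paste0(prefix, ".yaml"))
  protocol <- do.call(asl_protocol, sc$protocol)
  w <- do.call(rbind, lapply(sc$encoding$weights, as.numeric))
  rownames(w) <- sc$encoding$cycles
  colnames(w) <- sc$encoding$arteries
  matrix <- structure(
    list(weights = w,
         cycle_descriptions = paste("from sidecar", rownames(w))),
    class = "encoding_matrix"
  )
  schedule <- as.data.frame(sc$schedule, stringsAsFactors = FALSE)
  vox <- as.numeric(sc$voxel_size_mm)
  structure(
    list(data = array(data, dim = dim(data)), schedule = schedule,
         protocol = protocol, matrix = matrix,
         noise_sd = sc$noise_sd, voxel_size_mm = vox),
    class = "asl_series"
  )
}
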