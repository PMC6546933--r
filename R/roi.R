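#' Ischemic core from an ADC map
#'
#' Thresholds the apparent diffusion coefficient map at the externally
#' validated cutoff of 620e-6 mm^2/s (voxels strictly below the threshold)
#' and keeps the largest 6-connected component, a deterministic stand-in
#' for semi-automated delineation. An optional editing mask restricts the
#' result further (mimicking manual cleanup).
#'
#' @param adc 3D array of ADC values, mm^2/s, positive.
#' @param threshold ADC cutoff, mm^2/s.
#' @param largest_component Keep only the largest connected component?
#' @param edit_mask Optional logical array intersected with the result.
#' @return Logical 3D array.
#' @export
core_from_adc <- function(adc, threshold = 620e-6,
                          largest_component = TRUE, edit_mask = NULL) {
  stopifnot(all(adc > 0))
  mask <- adc < threshold
  if (!is.null(edit_mask)) mask <- mask & edit_mask
  if (largest_component && any(mask)) {
    mask <- largest_component_3d(mask)
  }
  mask
}

# Label 6-connected components with breadth-first flood fill and return
# the largest.
largest_component_3d <- function(mask) {
  shape <- dim(mask)
  labels <- array(0L, dim = shape)
  nxt <- 0L
  idx_all <- which(mask)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  coords <- arrayInd(idx_all, shape)
  rownames(coords) <- as.character(idx_all)
  sizes <- integer(0)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    count <- 0L
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      count <- count + length(cur)
      cc <- arrayInd(cur, shape)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(cc, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
        if (!any(ok)) next
        nbi <- nb[ok, , drop = FALSE]
        lin <- nbi[, 1] + (nbi[, 2] - 1L) * shape[1] +
          (nbi[, 3] - 1L) * prod(shape[1:2])
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new) > 0L) {
          labels[new] <- nxt
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
    sizes[nxt] <- count
  }
  labels == which.max(sizes)
}

#' Spherical-shell region of interest
#'
#' Dilates a binary mask with a spherical kernel of physical radius
#' `radius_mm` (all voxel offsets whose center-to-center distance is at
#' most the radius, honoring anisotropic voxel sizes) and subtracts the
#' original mask, leaving the surrounding shell. This is the construction
#' used for the Surviving-Tissue ROI (final infarct, 10 mm) and the
#' Peri-Core ROI (ischemic core, 20 mm).
#'
#' @param mask Logical 3D array.
#' @param radius_mm Kernel radius, mm, positive.
#' @param voxel_size_mm Numeric length-3 voxel dimensions, mm.
#' @return Logical 3D array; disjoint from `mask` by construction.
#' @export
shell_roi <- function(mask, radius_mm, voxel_size_mm) {
  if (radius_mm <= 0) stop("radius must be positive", call. = FALSE)
  dilated <- dilate_mm(mask, radius_mm, voxel_size_mm)
  dilated & !mask
}

# Morphological dilation with a physical-distance spherical kernel.
dilate_mm <- function(mask, radius_mm, voxel_size_mm) {
  shape <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(mask)
  reach <- floor(radius_mm / voxel_size_mm)
  og <- expand.grid(
    dx = -reach[1]:reach[1],
    dy = -reach[2]:reach[2],
    dz = -reach[3]:reach[3]
  )
  dist <- sqrt((og$dx * voxel_size_mm[1])^2 +
                 (og$dy * voxel_size_mm[2])^2 +
                 (og$dz * voxel_size_mm[3])^2)
  og <- og[dist <= radius_mm, , drop = FALSE]
  coords <- arrayInd(idx, shape)
  out <- array(FALSE, dim = shape)
  for (o in seq_len(nrow(og))) {
    nb <- cbind(coords[, 1] + og$dx[o],
                coords[, 2] + og$dy[o],
                coords[, 3] + og$dz[o])
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (!any(ok)) next
    nbi <- nb[ok, , drop = FALSE]
    out[nbi[, 1] + (nbi[, 2] - 1L) * shape[1] +
          (nbi[, 3] - 1L) * prod(shape[1:2])] <- TRUE
  }
  out
}

#' Mirror a mask across the sagittal midline
#'
#' Reflects voxel x-indices across `midline` (in voxel coordinates along
#' the first array dimension, possibly fractional) with nearest-voxel
#' rounding; reflections landing outside the volume are dropped.
#'
#' @param mask Logical 3D array.
#' @param midline Sagittal plane x-coordinate, voxel units (1-based).
#' @return Logical 3D array.
#' @export
mirror_mask <- function(mask, midline) {
  shape <- dim(mask)
  if (midline < 1 || midline > shape[1]) {
    stop("midline outside the volume", call. = FALSE)
  }
  idx <- which(mask)
  out <- array(FALSE, dim = shape)
  if (length(idx) == 0L) return(out)
  cc <- arrayInd(idx, shape)
  xr <- round(2 * midline - cc[, 1])
  ok <- xr >= 1 & xr <= shape[1]
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message(sprintf("mirror_mask: %d reflected voxels fell outside the volume",
                    n_drop))
  }
  keep <- which(ok)
  out[xr[keep] + (cc[keep, 2] - 1L) * shape[1] +
        (cc[keep, 3] - 1L) * prod(shape[1:2])] <- TRUE
  out
}

#' Restrict a mask to gray matter
#'
#' Keeps voxels whose gray-matter partial volume is strictly greater than
#' the threshold (default 0.5).
#'
#' @param mask Logical 3D array.
#' @param gm_pv Gray-matter partial-volume map, same shape.
#' @param threshold Partial-volume threshold (strict inequality).
#' @return Logical 3D array.
#' @export
restrict_to_gm <- function(mask, gm_pv, threshold = 0.5) {
  if (!identical(dim(mask), dim(gm_pv))) {
    stop("mask and gray-matter map shapes differ", call. = FALSE)
  }
  mask & (gm_pv > threshold)
}

#' Build the full stroke ROI set
#'
#' From the ischemic core, the final infarct and the gray-matter map,
#' constructs: the Surviving-Tissue ROI (10 mm shell around the infarct),
#' the Peri-Core ROI (20 mm shell around the core), and their
#' contralateral equivalents built from mirrored core/infarct masks. All
#' ROIs are restricted to gray matter and clipped to their own hemisphere
#' (an automatic replacement for manual checking that no opposite-
#' hemisphere voxels are included); clipped voxel counts are reported via
#' `message()`. Masks are mirrored first and GM-restricted afterwards.
#'
#' @param core Logical 3D array: ischemic core.
#' @param infarct Logical 3D array: final infarct.
#' @param gm_pv Gray-matter partial-volume map.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param midline Sagittal midline in voxel coordinates; defaults to the
#'   volume center.
#' @param surviving_radius_mm,peri_core_radius_mm Shell radii, mm.
#' @param gm_threshold GM partial-volume threshold.
#' @return An object of class `roi_set`: logical arrays
#'   `ischemic_core`, `final_infarct`, `surviving_tissue`, `peri_core`,
#'   `surviving_tissue_contra`, `peri_core_contra`, `gray_matter`.
#' @export
build_roi_set <- function(core, infarct, gm_pv, voxel_size_mm,
                          midline = (dim(core)[1] + 1) / 2,
                          surviving_radius_mm = 10,
                          peri_core_radius_mm = 20,
                          gm_threshold = 0.5) {
  if (!identical(dim(core), dim(infarct)) ||
      !identical(dim(core), dim(gm_pv))) {
    stop("core, infarct and gray-matter maps must share one grid",
         call. = FALSE)
  }
  shape <- dim(core)
  xs <- slice.index(array(0, shape), 1)
  lesion_side <- hemisphere_of(core | infarct, midline)
  ipsi <- if (lesion_side < 0) xs < midline else xs > midline
  contra <- if (lesion_side < 0) xs > midline else xs < midline

  clip <- function(mask, hemi, label) {
    n_out <- sum(mask & !hemi)
    if (n_out > 0) {
      message(sprintf("build_roi_set: clipped %d opposite-hemisphere voxels from %s",
                      n_out, label))
    }
    mask & hemi
  }

  gm <- gm_pv > gm_threshold
  surviving <- shell_roi(infarct, surviving_radius_mm, voxel_size_mm)
  peri <- shell_roi(core, peri_core_radius_mm, voxel_size_mm)
  core_m <- mirror_mask(core, midline)
  infarct_m <- mirror_mask(infarct, midline)
  surviving_c <- shell_roi(infarct_m, surviving_radius_mm, voxel_size_mm)
  peri_c <- shell_roi(core_m, peri_core_radius_mm, voxel_size_mm)

  structure(
    list(
      ischemic_core = core,
      final_infarct = infarct,
      surviving_tissue = clip(surviving & gm, ipsi, "surviving_tissue"),
      peri_core = clip(peri & gm, ipsi, "peri_core"),
      surviving_tissue_contra = clip(surviving_c & gm, contra,
                                     "surviving_tissue_contra"),
      peri_core_contra = clip(peri_c & gm, contra, "peri_core_contra"),
      gray_matter = gm
    ),
    class = "roi_set"
  )
}

# Which side of the midline holds most of the mask: -1 = below (right by
# radiological x convention in this package's phantom), +1 = above.
hemisphere_of <- function(mask, midline) {
  xs <- slice.index(array(0, dim(mask)), 1)
  n_lo <- sum(mask & xs < midline)
  n_hi <- sum(mask & xs > midline)
  if (n_lo >= n_hi) -1 else 1
}

#' @export
print.roi_set <- function(x, ...) {
  cat("Stroke ROI set (voxel counts)\n")
  for (nm in c("ischemic_core", "final_infarct", "surviving_tissue",
               "peri_core", "surviving_tissue_contra", "peri_core_contra")) {
    cat(sprintf("  %-24s %d\n", nm, sum(x[[nm]])))
  }
  invisible(x)
}
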