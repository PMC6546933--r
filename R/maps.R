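#' CBF-weighted arterial transit time map
#'
#' The per-voxel average of the per-artery transit times weighted by each
#' artery's CBF: `sum_a CBF_a * ATT_a / sum_a CBF_a`. In a voxel supplied
#' by a single artery this equals that artery's ATT; in mixed voxels it is
#' the flow-weighted average. Voxels with zero total flow are undefined
#' (NA).
#'
#' @param per_artery A `per_artery_maps` object, or a list with `cbf` and
#'   `att` 4D arrays (last dimension = artery).
#' @return 3D numeric array (seconds), NA where total CBF is zero.
#' @export
weighted_att <- function(per_artery) {
  cbf <- per_artery$cbf
  att <- per_artery$att
  if (!identical(dim(cbf), dim(att))) {
    stop("CBF and ATT map shapes differ", call. = FALSE)
  }
  shape <- dim(cbf)[1:3]
  n_art <- dim(cbf)[4]
  num <- array(0, dim = shape)
  den <- array(0, dim = shape)
  for (a in seq_len(n_art)) {
    w <- array(cbf[, , , a], dim = shape)
    t <- array(att[, , , a], dim = shape)
    contrib <- w * t
    contrib[w == 0] <- 0  # undefined ATT is irrelevant at zero flow
    num <- num + contrib
    den <- den + w
  }
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Direct, Indirect and total CBF maps
#'
#' Direct CBF is the flow a voxel receives from its hemisphere's
#' (ipsilateral) internal carotid artery; Indirect CBF is the summed flow
#' from every other encoded artery — the collateral-perfusion measure.
#' Total CBF is their sum.
#'
#' @param per_artery A `per_artery_maps` object (or compatible list with
#'   `cbf` and `artery_ids`).
#' @param ipsilateral Artery id of the ipsilateral ICA (e.g. `"RICA"`).
#' @return An object of class `derived_maps`: 3D arrays `total_cbf`,
#'   `direct_cbf`, `indirect_cbf`, `weighted_att`, plus
#'   `ipsilateral_artery_id`.
#' @export
direct_indirect <- function(per_artery, ipsilateral) {
  ids <- per_artery$artery_ids
  if (!(ipsilateral %in% ids)) {
    stop("unknown ipsilateral artery id: ", ipsilateral, call. = FALSE)
  }
  cbf <- per_artery$cbf
  shape <- dim(cbf)[1:3]
  direct <- array(cbf[, , , ipsilateral], dim = shape)
  indirect <- array(0, dim = shape)
  for (a in setdiff(ids, ipsilateral)) {
    indirect <- indirect + array(cbf[, , , a], dim = shape)
  }
  structure(
    list(total_cbf = direct + indirect,
         direct_cbf = direct,
         indirect_cbf = indirect,
         weighted_att = if (!is.null(per_artery$att)) {
           weighted_att(per_artery)
         } else NULL,
         ipsilateral_artery_id = ipsilateral),
    class = "derived_maps"
  )
}
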