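#' Artery geometry in the labeling plane
#'
#' Positions of the brain-feeding arteries in the VEPCASL labeling plane,
#' in millimetres along the right-left (x, right negative) and
#' anterior-posterior (y, posterior negative) axes. The default geometry is
#' a plausible neck configuration for the right and left internal carotid
#' arteries (RICA, LICA) and right and left vertebral arteries (RVA, LVA);
#' it is a phantom default, not a patient measurement.
#'
#' @param artery_ids Character vector of artery labels.
#' @param positions_mm Matrix (n_arteries x 2) of (x, y) positions, mm.
#' @return An object of class `artery_geometry`.
#' @export
artery_geometry <- function(artery_ids = c("RICA", "LICA", "RVA", "LVA"),
                            positions_mm = default_artery_positions()) {
  positions_mm <- as.matrix(positions_mm)
  stopifnot(
    length(artery_ids) >= 2L,
    nrow(positions_mm) == length(artery_ids),
    ncol(positions_mm) == 2L,
    !anyDuplicated(artery_ids)
  )
  if (anyDuplicated(positions_mm, MARGIN = 1)) {
    stop("artery positions must be pairwise distinct", call. = FALSE)
  }
  rownames(positions_mm) <- artery_ids
  colnames(positions_mm) <- c("x_mm", "y_mm")
  structure(
    list(artery_ids = as.character(artery_ids), positions_mm = positions_mm),
    class = "artery_geometry"
  )
}

default_artery_positions <- function() {
  rbind(
    RICA = c(-30, 0),
    LICA = c(+30, 0),
    RVA  = c(-8, -20),
    LVA  = c(+8, -20)
  )
}

#' Default vessel-encoding cycle scheme
#'
#' Eight cycles: non-selective control and label, then three selective
#' pairs (left-right, anterior-posterior, diagonal). Each selective cycle
#' modulates labeling efficiency sinusoidally along a unit direction in the
#' labeling plane; the spatial offset and half-period of each cycle are
#' chosen so the cycle's two target arteries sit exactly at efficiencies
#' -1 (fully labeled) and +1 (control). The two cycles of a pair swap which
#' target is labeled. The diagonal pair runs along the (1, 1)/sqrt(2) axis
#' and targets RICA vs LVA by default; its orientation is configurable
#' because it is a sequence-design choice, not a fixed convention.
#'
#' @param geometry An `artery_geometry`.
#' @param lr_targets,ap_targets,diag_targets Length-2 character vectors
#'   naming each pair's two target arteries (first is labeled in cycle 1).
#'   For the AP pair the two "targets" are group representatives: any
#'   artery at the same projection gets the same weight.
#' @return A list of cycle specs consumed by [build_encoding_matrix()].
#' @export
default_encoding_scheme <- function(geometry = artery_geometry(),
                                    lr_targets = c("RICA", "LICA"),
                                    ap_targets = c("RICA", "RVA"),
                                    diag_targets = c("RICA", "LVA")) {
  pair <- function(name, direction, targets) {
    direction <- direction / sqrt(sum(direction^2))
    list(
      list(name = paste0(name, "_1"), type = "selective",
           direction = direction, targets = targets),
      list(name = paste0(name, "_2"), type = "selective",
           direction = direction, targets = rev(targets))
    )
  }
  c(
    list(list(name = "control", type = "control"),
         list(name = "label", type = "label")),
    pair("LR", c(1, 0), lr_targets),
    pair("AP", c(0, 1), ap_targets),
    pair("DIAG", c(1, 1), diag_targets)
  )
}

#' Build the vessel-encoding matrix
#'
#' Constructs the (n_encodings x n_arteries) matrix of labeling
#' efficiencies `w[e, a]` in `[-1, +1]` (-1 = fully labeled/inverted,
#' +1 = control). Non-selective rows are constant -1 (label) or +1
#' (control). A selective cycle with unit direction `d`, offset `o` and
#' half-period `L` gives artery `a` at in-plane position `p_a` the weight
#' `-cos(pi * (p_a . d - o) / L)`; `o` and `L` are set from the cycle's two
#' target arteries so they land at -1 and +1 exactly.
#'
#' @param geometry An `artery_geometry`.
#' @param scheme Cycle scheme, e.g. [default_encoding_scheme()].
#' @return An object of class `encoding_matrix`: list with `weights`
#'   (matrix, rows named by cycle, columns by artery) and
#'   `cycle_descriptions`.
#' @export
build_encoding_matrix <- function(geometry = artery_geometry(),
                                  scheme = default_encoding_scheme(geometry)) {
  stopifnot(inherits(geometry, "artery_geometry"))
  ids <- geometry$artery_ids
  pos <- geometry$positions_mm
  rows <- lapply(scheme, function(cyc) {
    switch(cyc$type,
      control = rep(+1, length(ids)),
      label = rep(-1, length(ids)),
      selective = {
        if (!all(cyc$targets %in% ids)) {
          stop("unknown target artery in cycle ", cyc$name, call. = FALSE)
        }
        proj <- as.numeric(pos %*% cyc$direction)
        names(proj) <- ids
        o <- proj[cyc$targets[1]]
        L <- proj[cyc$targets[2]] - o
        if (abs(L) < sqrt(.Machine$double.eps)) {
          stop("ill-conditioned encoding scheme: targets of cycle ",
               cyc$name, " project to the same position", call. = FALSE)
        }
        pmin(pmax(-cos(pi * (proj - o) / L), -1), 1)
      },
      stop("unknown cycle type: ", cyc$type, call. = FALSE)
    )
  })
  weights <- do.call(rbind, rows)
  rownames(weights) <- vapply(scheme, `[[`, character(1), "name")
  colnames(weights) <- ids
  descriptions <- vapply(scheme, function(cyc) {
    if (cyc$type == "selective") {
      sprintf("selective [%s] label %s / control %s",
              paste(format(cyc$direction, digits = 3), collapse = ","),
              cyc$targets[1], cyc$targets[2])
    } else paste("non-selective", cyc$type)
  }, character(1))
  structure(
    list(weights = weights, cycle_descriptions = descriptions),
    class = "encoding_matrix"
  )
}

#' Ideal (+1/-1/0) encoding matrix
#'
#' A simplified matrix in which each selective cycle labels one target
#' fully (-1), leaves its partner in the control condition (+1) and gives
#' every other artery weight 0. Useful for exactly identifiable test cases.
#'
#' @inheritParams build_encoding_matrix
#' @return An `encoding_matrix`.
#' @export
ideal_encoding_matrix <- function(geometry = artery_geometry(),
                                  scheme = default_encoding_scheme(geometry)) {
  ids <- geometry$artery_ids
  rows <- lapply(scheme, function(cyc) {
    switch(cyc$type,
      control = rep(+1, length(ids)),
      label = rep(-1, length(ids)),
      selective = {
        w <- rep(0, length(ids))
        w[match(cyc$targets[1], ids)] <- -1
        w[match(cyc$targets[2], ids)] <- +1
        w
      }
    )
  })
  weights <- do.call(rbind, rows)
  rownames(weights) <- vapply(scheme, `[[`, character(1), "name")
  colnames(weights) <- ids
  structure(
    list(weights = weights,
         cycle_descriptions = paste("ideal", rownames(weights))),
    class = "encoding_matrix"
  )
}

#' @export
print.encoding_matrix <- function(x, ...) {
  cat("Vessel-encoding matrix (rows = cycles, columns = arteries)\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Numerical rank of the encoding matrix augmented with a static column
#'
#' The decoder solves for per-artery signals plus a static-tissue term; the
#' design is identifiable when `[W | 1]` has full column rank.
#'
#' @param matrix An `encoding_matrix`.
#' @param tol Singular-value tolerance relative to the largest.
#' @return Integer rank.
#' @export
encoding_rank <- function(matrix, tol = 1e-8) {
  stopifnot(inherits(matrix, "encoding_matrix"))
  aug <- cbind(matrix$weights, static = 1)
  sv <- svd(aug)$d
  sum(sv > tol * sv[1])
}

#' Export / import the encoding matrix as CSV
#'
#' CSV with a header row of artery IDs and one row per encoding cycle
#' (cycle names in the first column).
#'
#' @param matrix An `encoding_matrix`.
#' @param path File path.
#' @export
write_encoding_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "encoding_matrix"))
  df <- data.frame(cycle = rownames(matrix$weights), matrix$weights,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encoding_matrix
#' @export
read_encoding_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df$cycle
  structure(
    list(weights = w, cycle_descriptions = paste("imported", df$cycle)),
    class = "encoding_matrix"
  )
}
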