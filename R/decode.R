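#' Candidate artery-support classes
#'
#' The decoder assumes each voxel is fed by a small subset of the encoded
#' arteries: by default the empty set, every singleton and every pair
#' (11 classes for four arteries). Larger supports are excluded by default
#' because a voxel fed by three or more major arteries is physiologically
#' rare and poorly determined from eight encodings.
#'
#' @param artery_ids Character vector of artery labels.
#' @param max_support Largest subset size to consider.
#' @return Named list of integer index vectors (the empty class first).
#' @export
decode_classes <- function(artery_ids, max_support = 2L) {
  n <- length(artery_ids)
  stopifnot(max_support >= 0L, max_support <= n)
  classes <- list(integer(0))
  for (k in seq_len(max_support)) {
    classes <- c(classes,
                 utils::combn(n, k, simplify = FALSE))
  }
  names(classes) <- vapply(classes, function(idx) {
    if (length(idx) == 0L) "empty" else paste(artery_ids[idx], collapse = "+")
  }, character(1))
  classes
}

# Design matrix for one class: encoding columns of its arteries plus a
# static-tissue column of ones.
class_design <- function(weights, idx) {
  cbind(weights[, idx, drop = FALSE], static = 1)
}

# Orthonormal basis of the complement of the constant vector: the static
# tissue term carries a flat prior and is marginalized analytically by
# projecting data and design onto this (n - 1)-dimensional subspace.
static_complement <- function(n) {
  qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
}

# Per-class quantities reused across voxels: eigen-decomposition of the
# projected prior covariance A^2 Xq Xq' for the marginal likelihood, and
# the OLS pseudo-inverse of the full design for point estimates.
class_precompute <- function(weights, classes, amplitude_prior_sd) {
  Q <- static_complement(nrow(weights))
  lapply(classes, function(idx) {
    X <- class_design(weights, idx)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) {
      return(NULL)  # singular restricted system: class skipped
    }
    Xq <- crossprod(Q, weights[, idx, drop = FALSE])
    M <- amplitude_prior_sd^2 * tcrossprod(Xq)
    eig <- eigen(M, symmetric = TRUE)
    list(idx = idx, X = X, Q = Q,
         evec = eig$vectors, eval = pmax(eig$values, 0),
         proj = Q %*% eig$vectors,
         pinv = solve(XtX, t(X)))
  })
}

# Gaussian log marginal likelihood of one projected encoding vector under
# one class: yq ~ N(0, sigma^2 I + A^2 Xq Xq'), via the spectrum.
class_log_evidence <- function(pre, y, sigma2) {
  b <- drop(crossprod(pre$proj, y))
  d <- sigma2 + pre$eval
  -0.5 * (length(b) * log(2 * pi) + sum(log(d)) + sum(b^2 / d))
}

#' Decode the per-artery signals of a single voxel at one delay
#'
#' Maximum a posteriori vessel decoding: for every candidate artery-support
#' class the encoding vector is explained as
#' `y = X_C theta + noise`, where `X_C` holds the encoding-matrix columns
#' of the class's arteries plus a static-tissue column. Classes are scored
#' by the Gaussian marginal likelihood (zero-mean Gaussian priors on the
#' per-artery amplitudes, so that richer classes pay an automatic
#' complexity penalty; the static term carries a flat prior and is
#' marginalized by projection) times the class prior; the MAP class's
#' coefficients are
#' estimated by ordinary least squares restricted to that class, with
#' negative per-artery amplitudes clipped to zero.
#'
#' @param signals Numeric vector: one value per encoding cycle at one PLD.
#' @param matrix An `encoding_matrix`.
#' @param classes Candidate classes from [decode_classes()].
#' @param prior Class prior weights (recycled/normalized); `NULL` = flat.
#' @param noise_sd Noise standard deviation of `signals`.
#' @param amplitude_prior_sd Prior sd of the per-artery amplitudes;
#'   defaults to 10 x the spread of the demeaned signals (floored at
#'   10 x `noise_sd`).
#' @return A list: `class` (artery ids; `character(0)` for the empty
#'   class), `dm` (named per-artery amplitudes, zero outside the class),
#'   `static`, `residual_variance`, `log_posterior` (per class).
#' @export
decode_voxel <- function(signals, matrix, classes = NULL, prior = NULL,
                         noise_sd, amplitude_prior_sd = NULL) {
  stopifnot(inherits(matrix, "encoding_matrix"))
  w <- matrix$weights
  ids <- colnames(w)
  if (length(signals) != nrow(w)) {
    stop("signal vector length does not match the number of encodings",
         call. = FALSE)
  }
  if (is.null(classes)) classes <- decode_classes(ids)
  if (max(lengths(classes)) + 1L > length(signals)) {
    stop("more unknowns than encodings for the largest class",
         call. = FALSE)
  }
  if (is.null(amplitude_prior_sd)) {
    amplitude_prior_sd <- max(10 * stats::sd(signals), 10 * noise_sd,
                              .Machine$double.eps)
  }
  sigma2 <- max(noise_sd^2, 1e-12 * amplitude_prior_sd^2)
  log_prior <- normalize_class_prior(prior, length(classes), names(classes))
  pre <- class_precompute(w, classes, amplitude_prior_sd)
  log_post <- vapply(seq_along(classes), function(i) {
    if (is.null(pre[[i]])) return(-Inf)
    class_log_evidence(pre[[i]], signals, sigma2) + log_prior[i]
  }, numeric(1))
  if (all(!is.finite(log_post))) {
    stop("all candidate classes are singular for this encoding matrix",
         call. = FALSE)
  }
  best <- which.max(log_post)
  pb <- pre[[best]]
  theta <- drop(pb$pinv %*% signals)
  k <- length(pb$idx)
  dm <- stats::setNames(numeric(length(ids)), ids)
  if (k > 0) dm[pb$idx] <- pmax(theta[seq_len(k)], 0)
  static <- unname(theta[k + 1L])
  resid <- signals - pb$X %*% theta
  structure(
    list(class = ids[pb$idx], dm = dm, static = static,
         residual_variance = mean(resid^2),
         log_posterior = stats::setNames(log_post, names(classes))),
    class = "voxel_decode_result"
  )
}

normalize_class_prior <- function(prior, n, class_names) {
  if (is.null(prior)) return(rep(0, n))
  if (!is.null(names(prior))) prior <- prior[class_names]
  if (length(prior) != n || any(is.na(prior)) || any(prior < 0)) {
    stop("class prior must be a non-negative weight per class",
         call. = FALSE)
  }
  log(prior / sum(prior))
}

#' Decode a full vessel-encoded series
#'
#' Averages the repetitions of each encoding at each PLD, estimates the
#' noise level per voxel from paired-repetition differences (floored at a
#' global robust estimate), and decodes every voxel with a single
#' artery-support class shared across PLDs: class log evidences are summed
#' over PLDs before maximization, because a voxel's feeding arteries do
#' not change with delay. Per-artery amplitudes are then estimated per PLD
#' by least squares restricted to the selected class and clipped at zero.
#'
#' @param series An `asl_series` (data + schedule + protocol + matrix), as
#'   produced by [synthesize_series()] or [read_series()].
#' @param classes Candidate classes; default [decode_classes()] on the
#'   matrix's arteries.
#' @param prior Class prior weights; `NULL` = flat.
#' @param mask Optional logical 3D array restricting decoding (default:
#'   all voxels).
#' @return An object of class `decoded_series`: `dm` array
#'   (nx x ny x nz x n_arteries x n_plds), `class_map` (integer 3D array
#'   indexing `classes`, 1 = empty), `classes`, `static`, `noise_sd` (3D,
#'   per averaged volume), `residual_variance`, `artery_ids`, `protocol`,
#'   `voxel_size_mm`.
#' @export
decode_series <- function(series, classes = NULL, prior = NULL,
                          mask = NULL) {
  stopifnot(inherits(series, "asl_series"))
  protocol <- series$protocol
  sched <- series$schedule
  data <- series$data
  shape <- dim(data)[1:3]
  n_vol <- dim(data)[4]
  if (n_vol != nrow(sched)) {
    stop(sprintf("series has %d volumes but the schedule lists %d",
                 n_vol, nrow(sched)), call. = FALSE)
  }
  w <- series$matrix$weights
  ids <- colnames(w)
  n_enc <- nrow(w)
  n_pld <- length(protocol$nominal_plds_s)
  n_rep <- protocol$n_repeats
  if (is.null(classes)) classes <- decode_classes(ids)
  nvox <- prod(shape)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  vox_idx <- which(as.logical(mask))
  nv <- length(vox_idx)

  dim(data) <- c(nvox, n_vol)
  # Average repeats and accumulate squared repeat differences for the
  # noise estimate. enc_mean: nv x n_enc x n_pld.
  enc_mean <- array(0, dim = c(nv, n_enc, n_pld))
  ss_diff <- numeric(nv)
  n_pairs <- 0L
  for (p in seq_len(n_pld)) {
    for (e in seq_len(n_enc)) {
      vols <- sched$volume[sched$pld_index == p & sched$cycle_index == e]
      reps <- data[vox_idx, vols, drop = FALSE]
      enc_mean[, e, p] <- rowMeans(reps)
      if (length(vols) >= 2L) {
        ss_diff <- ss_diff + (reps[, 1] - reps[, 2])^2
        n_pairs <- n_pairs + 1L
      }
    }
  }
  # Noise variance of the *averaged* encodings: Var(r1 - r2) = 2 sigma^2
  # and averaging n_rep repeats divides the variance by n_rep.
  if (n_pairs > 0) {
    sigma2_vox <- ss_diff / n_pairs / 2 / n_rep
  } else {
    sigma2_vox <- numeric(nv)
  }
  scale2 <- mean(enc_mean^2)
  floor2 <- max(stats::median(sigma2_vox), 1e-12 * max(scale2, 1))
  sigma2_vox <- pmax(sigma2_vox, floor2)

  # Global amplitude prior from the non-selective (control - label) / 2
  # difference signal.
  ctrl <- which.max(rowMeans(w))
  labl <- which.min(rowMeans(w))
  d_ns <- (enc_mean[, ctrl, ] - enc_mean[, labl, ]) / 2
  amplitude_prior_sd <- max(10 * stats::quantile(abs(d_ns), 0.99),
                            10 * sqrt(floor2))

  pre <- class_precompute(w, classes, amplitude_prior_sd)
  log_prior <- normalize_class_prior(prior, length(classes), names(classes))

  # Joint class log evidence, summed over PLDs, vectorized over voxels.
  # The static term is marginalized: evidence lives in the (n_enc - 1)-
  # dimensional complement of the constant vector.
  log_post <- matrix(-Inf, nrow = nv, ncol = length(classes))
  const <- -0.5 * (n_enc - 1) * log(2 * pi) * n_pld
  for (ci in seq_along(classes)) {
    pc <- pre[[ci]]
    if (is.null(pc)) next
    acc <- rep(const + log_prior[ci], nv)
    logdet <- numeric(nv)
    for (i in seq_len(n_enc - 1L)) {
      logdet <- logdet + log(sigma2_vox + pc$eval[i])
    }
    acc <- acc - 0.5 * n_pld * logdet
    for (p in seq_len(n_pld)) {
      b <- enc_mean[, , p] %*% pc$proj        # nv x (n_enc - 1)
      quad <- numeric(nv)
      for (i in seq_len(n_enc - 1L)) {
        quad <- quad + b[, i]^2 / (sigma2_vox + pc$eval[i])
      }
      acc <- acc - 0.5 * quad
    }
    log_post[, ci] <- acc
  }
  class_of <- max.col(log_post, ties.method = "first")

  # Point estimates per selected class, per PLD.
  dm <- array(0, dim = c(nv, length(ids), n_pld))
  static <- numeric(nv)
  resid_var <- numeric(nv)
  for (ci in seq_along(classes)) {
    pc <- pre[[ci]]
    if (is.null(pc)) next
    sel <- which(class_of == ci)
    if (length(sel) == 0L) next
    k <- length(pc$idx)
    rss <- numeric(length(sel))
    st <- numeric(length(sel))
    for (p in seq_len(n_pld)) {
      y <- enc_mean[sel, , p, drop = FALSE]
      dim(y) <- c(length(sel), n_enc)
      theta <- y %*% t(pc$pinv)               # nsel x (k + 1)
      if (k > 0) dm[sel, pc$idx, p] <- pmax(theta[, seq_len(k)], 0)
      st <- st + theta[, k + 1L]
      fit <- theta %*% t(pc$X)
      rss <- rss + rowSums((y - fit)^2)
    }
    static[sel] <- st / n_pld
    resid_var[sel] <- rss / (n_pld * n_enc)
  }

  embed3 <- function(v) {
    out <- array(NA_real_, dim = shape)
    out[vox_idx] <- v
    out
  }
  dm_full <- array(0, dim = c(shape, length(ids), n_pld),
                   dimnames = list(NULL, NULL, NULL, ids, NULL))
  for (a in seq_along(ids)) {
    for (p in seq_len(n_pld)) {
      sl <- array(0, dim = shape)
      sl[vox_idx] <- dm[, a, p]
      dm_full[, , , a, p] <- sl
    }
  }
  cm <- array(NA_integer_, dim = shape)
  cm[vox_idx] <- class_of
  structure(
    list(dm = dm_full, class_map = cm, classes = classes,
         static = embed3(static), noise_sd = embed3(sqrt(sigma2_vox)),
         residual_variance = embed3(resid_var),
         artery_ids = ids, protocol = protocol,
         voxel_size_mm = series$voxel_size_mm),
    class = "decoded_series"
  )
}

#' @export
print.decoded_series <- function(x, ...) {
  tab <- table(factor(names(x$classes)[x$class_map],
                      levels = names(x$classes)))
  cat("Decoded vessel-encoded series\n")
  cat(sprintf("  grid %s, arteries: %s\n",
              paste(dim(x$class_map), collapse = "x"),
              paste(x$artery_ids, collapse = ", ")))
  cat("  class counts:\n")
  print(tab[tab > 0])
  invisible(x)
}
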