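# Independent oracles and small fixture builders shared across tests.

# Small phantom used by unit tests: same structure as the default study
# phantom, scaled to a 16x16x4 grid.
tiny_spec <- function(scenario = "inter-hemispheric", seed = 7L, ...) {
  args <- list(grid_shape = c(16L, 16L, 4L), voxel_size_mm = c(3.4, 3.4, 5),
               scenario = scenario,
               lesion_center_mm = c(-12, 5, 0), lesion_radius_mm = 9,
               core_radius_mm = 3, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Normalized Helmert basis of the complement of the constant vector — a
# deliberately different complement basis from the implementation's;
# the marginal likelihood is invariant to this choice.
helmert_basis <- function(n) {
  H <- stats::contr.helmert(n)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

# Gaussian log marginal likelihood of a projected encoding vector under
# one artery-support class, via the matrix determinant lemma and the
# Woodbury identity (k x k solves) — an algebraic route independent of
# the eigen-decomposition path used by the decoder. The static term is
# marginalized by projecting onto the Helmert complement of the constant.
oracle_log_evidence <- function(y, Xarteries, amplitude_prior_sd, sigma2) {
  H <- helmert_basis(length(y))
  yq <- drop(crossprod(H, y))
  n <- length(yq)
  if (ncol(Xarteries) == 0L) {
    return(-0.5 * (n * log(2 * pi) + n * log(sigma2) + sum(yq^2) / sigma2))
  }
  Xq <- crossprod(H, Xarteries)
  k <- ncol(Xq)
  A <- crossprod(Xq) + sigma2 * diag(1 / amplitude_prior_sd^2, k)
  logdet <- n * log(sigma2) +
    as.numeric(determinant(diag(k) + (amplitude_prior_sd^2 / sigma2) *
                             crossprod(Xq),
                           logarithm = TRUE)$modulus)
  Xty <- crossprod(Xq, yq)
  quad <- (sum(yq^2) - drop(t(Xty) %*% solve(A, Xty))) / sigma2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

# Exhaustive enumeration over all candidate classes; returns the winning
# class index and its OLS amplitudes.
oracle_decode <- function(y, matrix, classes, noise_sd, amplitude_prior_sd) {
  w <- matrix$weights
  sigma2 <- max(noise_sd^2, 1e-12 * amplitude_prior_sd^2)
  scores <- vapply(classes, function(idx) {
    oracle_log_evidence(y, w[, idx, drop = FALSE], amplitude_prior_sd,
                        sigma2)
  }, numeric(1))
  best <- which.max(scores)
  idx <- classes[[best]]
  X <- cbind(w[, idx, drop = FALSE], 1)
  theta <- drop(qr.solve(X, y))
  dm <- setNames(numeric(ncol(w)), colnames(w))
  if (length(idx) > 0) dm[idx] <- pmax(theta[seq_along(idx)], 0)
  list(best = best, scores = scores, dm = dm)
}

# Brute-force spherical dilation: mark every voxel whose physical distance
# to some mask voxel is within the radius (O(n * m) pairwise distances).
brute_dilate <- function(mask, radius_mm, voxel_size_mm) {
  shape <- dim(mask)
  src <- arrayInd(which(mask), shape)
  out <- array(FALSE, dim = shape)
  if (nrow(src) == 0) return(out)
  all_idx <- arrayInd(seq_len(prod(shape)), shape)
  for (v in seq_len(nrow(all_idx))) {
    d2 <- ((all_idx[v, 1] - src[, 1]) * voxel_size_mm[1])^2 +
      ((all_idx[v, 2] - src[, 2]) * voxel_size_mm[2])^2 +
      ((all_idx[v, 3] - src[, 3]) * voxel_size_mm[3])^2
    if (any(d2 <= radius_mm^2 + 1e-9)) out[v] <- TRUE
  }
  out
}

# Quadrature oracle for the kinetic model: numerically integrate the
# delivery x decay product over the bolus passage.
quadrature_delta_m <- function(t, cbf, att, m0_blood, tau, constants) {
  if (t <= att) return(0)
  upper <- min(t, att + tau)
  f <- function(tp) {
    2 * m0_blood * constants$labeling_efficiency * (cbf / 6000) *
      exp(-att / constants$t1_blood_s) *
      exp(-(t - tp) / constants$t1_tissue_apparent_s)
  }
  stats::integrate(f, att, upper, rel.tol = 1e-10)$value
}
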