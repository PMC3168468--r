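# Essential dynamics: PCA of C-alpha positional fluctuations.  The
# covariance is mass-unweighted and computed on C-alpha atoms only, with
# the 1/n denominator so that per-residue tensor traces equal mean squared
# fluctuations exactly.

ca_deviation_matrix <- function(ens) {
  ca <- calpha_coords(ens)
  n3 <- 3L * ens$n_residues
  X <- t(matrix(aperm(ca, c(2, 1, 3)), nrow = n3))  # frames x 3N
  sweep(X, 2, colMeans(X))
}

check_superposed <- function(ens, drift_tol = 1e-3) {
  if (ens$superposed) return(invisible(TRUE))
  ca <- calpha_coords(ens)
  ctr <- t(apply(ca, 3, colMeans))  # frames x 3 centroid track
  drift <- max(apply(ctr, 2, stats::sd))
  if (drift > drift_tol)
    stop("ensemble shows net rigid drift (centroid sd ", signif(drift, 3),
         " nm); superpose() it before covariance analysis")
  invisible(TRUE)
}

#' Essential subspace of C-alpha fluctuations
#'
#' Diagonalises the 3N x 3N covariance matrix of C-alpha positional
#' fluctuations about the ensemble mean.  The essential subspace is the
#' span of the leading eigenvectors; its dimension k is chosen as the
#' smallest k whose cumulative variance fraction reaches `variance_target`
#' (or fixed via `k`).  Eigenvector signs are fixed by making each
#' vector's largest-magnitude component positive, so reports are
#' reproducible.
#'
#' @param ens a superposed [ensemble()] with at least 2 frames.
#' @param variance_target cumulative variance fraction for selecting k
#'   (default 0.70).
#' @param k optional fixed subspace dimension overriding the variance rule.
#' @return class `"essential_subspace"`: `eigenvalues` (nm^2, descending),
#'   `vectors` (3N x 3N orthonormal columns), `variance_fraction`
#'   (cumulative), `k`, `trace`, `mean` (3N mean coordinates),
#'   `n_residues`, `degenerate` flag (all eigenvalues ~ 0).
#' @export
compute_subspace <- function(ens, variance_target = 0.70, k = NULL) {
  if (n_frames(ens) < 2L) stop("need at least 2 frames")
  check_superposed(ens)
  D <- ca_deviation_matrix(ens)
  C <- crossprod(D) / nrow(D)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  tot <- sum(ev)
  degenerate <- tot <= 1e-12
  cumfrac <- if (degenerate) rep(NA_real_, length(ev)) else cumsum(ev) / tot
  if (is.null(k)) {
    k <- if (degenerate) NA_integer_ else which(cumfrac >= variance_target)[1]
  } else stopifnot(k >= 1, k <= length(ev))
  structure(list(eigenvalues = ev, vectors = V, variance_fraction = cumfrac,
                 k = k, trace = sum(diag(C)),
                 mean = colMeans(t(matrix(aperm(calpha_coords(ens), c(2, 1, 3)),
                                          nrow = 3 * ens$n_residues))),
                 n_residues = ens$n_residues, n_frames = n_frames(ens),
                 variance_target = variance_target, degenerate = degenerate),
            class = "essential_subspace")
}

#' @export
print.essential_subspace <- function(x, ...) {
  cat("Essential subspace:", 3 * x$n_residues, "coordinates,",
      x$n_frames, "frames\n")
  if (x$degenerate) cat("  degenerate: total fluctuation variance ~ 0\n")
  else cat(sprintf("  k = %d eigenvectors reach %.0f%% of variance (target %.0f%%)\n",
                   x$k, 100 * x$variance_fraction[x$k], 100 * x$variance_target))
  invisible(x)
}

subspace_filtered_deviations <- function(ens, sub, k) {
  D <- ca_deviation_matrix(ens)
  if (ncol(D) != nrow(sub$vectors))
    stop("ensemble and subspace dimensions do not match")
  Vk <- sub$vectors[, seq_len(k), drop = FALSE]
  (D %*% Vk) %*% t(Vk)
}

per_residue_msf <- function(R, n_residues) {
  # mean over frames of squared 3-component deviation, per residue
  vapply(seq_len(n_residues), function(i)
    mean(rowSums(R[, (3 * i - 2):(3 * i), drop = FALSE]^2)), 0)
}

#' Per-residue rmsf after projection on the essential subspace
#'
#' Frames are reconstructed from their projections on the first k
#' eigenvectors (motion filtered to the essential subspace) and the rmsf of
#' each C-alpha about the mean of the reconstructed ensemble is returned.
#' With `k = 3N` this equals the ordinary rmsf.
#'
#' @param ens the superposed [ensemble()].
#' @param sub its [compute_subspace()] result (or one from a compatible
#'   system with the same dimension).
#' @param k subspace dimension; default `sub$k`.
#' @return class `"flexibility_profile"`: data frame `residue_index`,
#'   `rmsf` (nm), with attribute `k`.
#' @export
project_and_rmsf <- function(ens, sub, k = sub$k) {
  if (is.na(k)) stop("degenerate subspace: no k selected")
  R <- subspace_filtered_deviations(ens, sub, k)
  rmsf <- sqrt(per_residue_msf(R, ens$n_residues))
  structure(data.frame(residue_index = ens$residue_index, rmsf = rmsf),
            k = k, class = c("flexibility_profile", "data.frame"))
}

#' Per-residue anisotropic U-tensors in the essential subspace
#'
#' The 3x3 covariance tensor of each C-alpha's subspace-filtered
#' fluctuations, drawable as a probability ellipsoid.  The ellipsoid axis
#' scale for the requested probability level follows the chi-squared (3 df)
#' quantile convention and is recorded with the result.
#'
#' @param ens the superposed [ensemble()].
#' @param sub its [compute_subspace()] result.
#' @param k subspace dimension; default `sub$k`.
#' @param prob ellipsoid probability level (default 0.1).
#' @return class `"anisotropic_tensors"`: list with `U` (array
#'   `c(3, 3, n_residues)`, nm^2), `ellipsoid_scale`
#'   (`sqrt(qchisq(prob, 3))`), `prob`, `residue_index`.
#' @export
anisotropic_tensors <- function(ens, sub, k = sub$k, prob = 0.1) {
  if (is.na(k)) stop("degenerate subspace: no k selected")
  R <- subspace_filtered_deviations(ens, sub, k)
  n <- ens$n_residues
  U <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    B <- R[, (3 * i - 2):(3 * i), drop = FALSE]
    U[, , i] <- crossprod(B) / nrow(B)
  }
  structure(list(U = U, ellipsoid_scale = sqrt(stats::qchisq(prob, df = 3)),
                 prob = prob, k = k, residue_index = ens$residue_index),
            class = "anisotropic_tensors")
}

#' Cosine content and subspace overlap (RMSIP)
#'
#' Sampling-quality indices: the cosine content of each of the first
#' `n_modes` principal projections (values near 1 indicate random-diffusion-
#' like, unconverged sampling), and optionally the root mean square inner
#' product between the leading eigenvectors of two subspaces (1 = identical
#' essential subspaces).  Cosine content uses trapezoidal quadrature so an
#' exact half-period cosine projection scores 1.
#'
#' @param ens the superposed [ensemble()].
#' @param sub its [compute_subspace()] result.
#' @param other optional second `essential_subspace` with the same ambient
#'   dimension, for RMSIP.
#' @param n_modes number of projections for cosine content (default 5).
#' @param n_rmsip number of leading eigenvectors entering RMSIP (default 10).
#' @return list `cosine_content` (numeric, length `n_modes`) and `rmsip`
#'   (scalar or `NA` when `other` is missing).
#' @export
sampling_quality <- function(ens, sub, other = NULL, n_modes = 5,
                             n_rmsip = 10) {
  D <- ca_deviation_matrix(ens)
  n_modes <- min(n_modes, ncol(D))
  P <- D %*% sub$vectors[, seq_len(n_modes), drop = FALSE]
  nf <- nrow(P)
  tt <- seq_len(nf) - 1L
  cc <- vapply(seq_len(n_modes), function(j) {
    p <- P[, j]
    cosj <- cos(j * pi * tt / (nf - 1))
    num <- pracma::trapz(tt, cosj * p)
    den <- pracma::trapz(tt, p^2)
    if (den <= 0) return(0)
    (2 / (nf - 1)) * num^2 / den
  }, 0)
  rmsip <- NA_real_
  if (!is.null(other)) rmsip <- rmsip_index(sub, other, n_rmsip)
  list(cosine_content = cc, rmsip = rmsip)
}

#' Root mean square inner product between two subspaces
#' @param a,b `essential_subspace` objects of equal ambient dimension (or
#'   plain matrices of column eigenvectors).
#' @param n number of leading eigenvectors compared (default 10, capped at
#'   availability).
#' @return RMSIP in `[0, 1]`.
#' @export
rmsip_index <- function(a, b, n = 10) {
  Va <- if (is.matrix(a)) a else a$vectors
  Vb <- if (is.matrix(b)) b else b$vectors
  if (nrow(Va) != nrow(Vb)) stop("subspaces have different ambient dimension")
  n <- min(n, ncol(Va), ncol(Vb))
  M <- crossprod(Va[, seq_len(n), drop = FALSE], Vb[, seq_len(n), drop = FALSE])
  sqrt(sum(M^2) / n)
}

#' rmsf convergence over sliding time windows
#'
#' For each requested window length, per-residue rmsf profiles are computed
#' on partially overlapping windows starting at the first frame and moving
#' onwards in steps of `step_ps`, then averaged into one profile per
#' length.  Window counts follow `floor((T - L)/step) + 1`.  Lengths
#' exceeding the trajectory are skipped with a warning.
#'
#' @param ens a superposed [ensemble()].
#' @param window_lengths_ns window lengths in ns (default
#'   `c(1, 2, 5, 10, 15, 20)`).
#' @param step_ps step between window starts in ps (default 500).
#' @return class `"rmsf_convergence"`: list with `profiles` (residues x
#'   lengths matrix of mean rmsf, nm), `n_windows` per length,
#'   `window_lengths_ns` actually used.
#' @export
rmsf_convergence <- function(ens, window_lengths_ns = c(1, 2, 5, 10, 15, 20),
                             step_ps = 500) {
  dt <- ens$time_per_frame
  nf <- n_frames(ens)
  T_ps <- nf * dt
  sf <- max(1L, round(step_ps / dt))
  use <- window_lengths_ns[window_lengths_ns * 1000 <= T_ps]
  skipped <- setdiff(window_lengths_ns, use)
  if (length(skipped))
    warning("window length(s) ", paste(skipped, collapse = ", "),
            " ns exceed the trajectory (", T_ps / 1000, " ns); skipped")
  if (!length(use)) stop("no window length fits the trajectory")
  ca <- calpha_coords(ens)
  n <- ens$n_residues
  profiles <- matrix(NA_real_, n, length(use),
                     dimnames = list(NULL, paste0(use, "ns")))
  n_windows <- integer(length(use))
  for (w in seq_along(use)) {
    wf <- round(use[w] * 1000 / dt)
    starts <- seq(1L, nf - wf + 1L, by = sf)
    acc <- matrix(0, n, length(starts))
    for (s in seq_along(starts)) {
      idx <- starts[s]:(starts[s] + wf - 1L)
      sub <- ca[, , idx, drop = FALSE]
      mu <- apply(sub, c(1, 2), mean)
      dev2 <- (sub - as.vector(mu))^2
      acc[, s] <- sqrt(apply(dev2, 1, function(v)
        mean(colSums(matrix(v, nrow = 3)))))
    }
    profiles[, w] <- rowMeans(acc)
    n_windows[w] <- length(starts)
  }
  structure(list(profiles = profiles, n_windows = n_windows,
                 window_lengths_ns = use, step_ps = sf * dt),
            class = "rmsf_convergence")
}
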