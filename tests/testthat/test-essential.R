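test_that("eigenvalue sum equals the covariance trace and rigid input degenerates", {
  set.seed(30)
  g <- gen_gaussian_ensemble(8, noise = 0.02, n_frames = 400, seed = 31)
  sub <- compute_subspace(g$ensemble)
  expect_lt(abs(sum(sub$eigenvalues) - sub$trace), 1e-8 * sub$trace)
  expect_lt(max(abs(crossprod(sub$vectors) - diag(24))), 1e-8)
  rigid <- gen_gaussian_ensemble(8, noise = 0, n_frames = 10, seed = 1)
  sub0 <- compute_subspace(rigid$ensemble)
  expect_true(sub0$degenerate)
  expect_true(is.na(sub0$k))
  expect_error(project_and_rmsf(rigid$ensemble, sub0), "degenerate")
})

test_that("unsuperposed drifting input is rejected", {
  set.seed(32)
  drift <- make_ens(lapply(1:10, function(f)
    matrix(runif(15), 5, 3) * 0 + matrix(rnorm(15, sd = 0.01), 5, 3) + f * 0.5),
    ca_atoms(5), superposed = FALSE)
  expect_error(compute_subspace(drift), "drift")
})

test_that("planted eigenvalues and subspace are recovered from samples", {
  n <- 10
  V <- make_modes(n, list(
    list(list(residue = 1, d = c(1, 0, 0)), list(residue = 6, d = c(1, 0, 0))),
    list(list(residue = 3, d = c(0, 1, 0)), list(residue = 8, d = c(0, -1, 0)))))
  lam <- c(0.2, 0.05); s2 <- 0.002
  g <- gen_gaussian_ensemble(n, eigenvalues = lam, modes = V, noise = s2,
                             n_frames = 6000, seed = 33)
  sub <- compute_subspace(g$ensemble)
  expect_lt(max(abs(sub$eigenvalues[1:2] - (lam + s2)) / (lam + s2)), 0.08)
  expect_gt(rmsip_index(sub$vectors[, 1:2], V, n = 2), 0.98)
})

test_that("subspace rmsf reduces to ordinary rmsf at k = 3N and is monotone", {
  set.seed(34)
  g <- gen_gaussian_ensemble(6, noise = 0.01, n_frames = 300, seed = 35)
  ens <- g$ensemble
  sub <- compute_subspace(ens)
  full <- project_and_rmsf(ens, sub, k = 18)
  expect_equal(full$rmsf, plain_rmsf(ens), tolerance = 1e-10)
  prev <- rep(0, 6)
  for (k in c(1, 3, 6, 12, 18)) {
    cur <- project_and_rmsf(ens, sub, k = k)$rmsf
    expect_true(all(cur >= prev - 1e-12))
    expect_true(all(cur <= full$rmsf + 1e-12))
    prev <- cur
  }
})

test_that("a mode localized on two residues leaves the rest rigid after projection", {
  n <- 8
  V <- make_modes(n, list(list(list(residue = 1, d = c(1, 0, 0)),
                               list(residue = 2, d = c(1, 0, 0)))))
  g <- gen_gaussian_ensemble(n, eigenvalues = 0.1, modes = V, noise = 1e-6,
                             n_frames = 800, seed = 36)
  sub <- compute_subspace(g$ensemble)
  fp <- project_and_rmsf(g$ensemble, sub, k = 1)
  expect_gt(min(fp$rmsf[1:2]), 0.1)
  expect_lt(max(fp$rmsf[3:n]), 0.01)
})

test_that("anisotropic U-tensors match planted isotropy and rmsf traces", {
  n <- 5
  g <- gen_gaussian_ensemble(n, noise = 0.04, n_frames = 4000, seed = 37)
  sub <- compute_subspace(g$ensemble)
  k <- 3 * n
  ut <- anisotropic_tensors(g$ensemble, sub, k = k, prob = 0.1)
  # isotropic planted motion: tensors close to sigma^2 I
  for (i in 1:n) {
    expect_lt(max(abs(ut$U[, , i] - 0.04 * diag(3))), 6 * 0.04 / sqrt(4000) * 3)
  }
  # trace identity against squared subspace rmsf
  fp <- project_and_rmsf(g$ensemble, sub, k = k)
  traces <- vapply(1:n, function(i) sum(diag(ut$U[, , i])), 0)
  expect_equal(traces, fp$rmsf^2, tolerance = 1e-10)
  expect_equal(ut$ellipsoid_scale, sqrt(qchisq(0.1, 3)))
  # rigid ensemble -> zero tensors
  base <- matrix(runif(15), 5, 3)
  rigid <- make_ens(replicate(4, base, simplify = FALSE), ca_atoms(5))
  subr <- compute_subspace(rigid)
  utr <- anisotropic_tensors(rigid, subr, k = 1)
  expect_lt(max(abs(utr$U)), 1e-20)
})

test_that("RMSIP is 1 on identical and 0 on orthogonal subspaces", {
  g <- gen_gaussian_ensemble(6, noise = 0.01, n_frames = 200, seed = 38)
  sub <- compute_subspace(g$ensemble)
  sq <- sampling_quality(g$ensemble, sub, other = sub)
  expect_equal(sq$rmsip, 1, tolerance = 1e-10)
  A <- diag(12)[, 1:3]; B <- diag(12)[, 4:6]
  expect_equal(rmsip_index(A, B, n = 3), 0)
  expect_error(rmsip_index(diag(6), diag(9)), "dimension")
})

test_that("a half-period cosine projection has cosine content 1", {
  nf <- 1000; n <- 4
  v <- make_modes(n, list(list(list(residue = 2, d = c(1, 1, 0)))))[, 1]
  tt <- seq_len(nf) - 1
  # build coordinates directly from the 3N vector layout
  co <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    x <- cos(pi * tt[f] / (nf - 1)) * v
    co[, , f] <- matrix(x, n, 3, byrow = TRUE)
  }
  ens <- ensemble(co, ca_atoms(n), superposed = TRUE)
  sub <- compute_subspace(ens, k = 1)
  cc <- sampling_quality(ens, sub, n_modes = 1)$cosine_content
  expect_equal(cc[1], 1, tolerance = 1e-6)
  # white-noise projections have low cosine content
  g <- gen_gaussian_ensemble(6, noise = 0.01, n_frames = 2000, seed = 39)
  subg <- compute_subspace(g$ensemble)
  expect_lt(max(sampling_quality(g$ensemble, subg, n_modes = 3)$cosine_content), 0.2)
})

test_that("rmsf window convergence has the right window counts and limits", {
  # 10 ns at 2 ps/frame = 5000 frames; 2 ns windows stepping 500 ps -> 17
  g <- gen_gaussian_ensemble(5, noise = 0.01, n_frames = 5000, seed = 40)
  conv <- rmsf_convergence(g$ensemble, window_lengths_ns = c(1, 2),
                           step_ps = 500)
  expect_equal(conv$n_windows[conv$window_lengths_ns == 2], 17L)
  expect_equal(conv$n_windows[conv$window_lengths_ns == 1], 19L)
  # window spanning the whole trajectory equals the plain rmsf
  conv_full <- rmsf_convergence(g$ensemble, window_lengths_ns = 10)
  expect_equal(conv_full$n_windows, 1L)
  expect_equal(unname(conv_full$profiles[, 1]), plain_rmsf(g$ensemble),
               tolerance = 1e-10)
  # stationary process: profiles agree across window lengths
  expect_lt(max(abs(conv$profiles[, "1ns"] - conv$profiles[, "2ns"])),
            5 * sqrt(0.01) / sqrt(500))
  expect_warning(rmsf_convergence(g$ensemble, window_lengths_ns = c(2, 50)),
                 "skipped")
})
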