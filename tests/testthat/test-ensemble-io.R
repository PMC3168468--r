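test_that("multi-model PDB round trip preserves structure and coordinates", {
  set.seed(42)
  atoms <- ca_atoms(5, name = c("ALA", "GLY", "LEU", "LYS", "GLU"))
  frames <- replicate(3, matrix(runif(15, 0, 2), 5, 3), simplify = FALSE)
  ens <- make_ens(frames, atoms)
  f <- tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  back <- load_ensemble(f)
  expect_equal(n_frames(back), 3)
  expect_length(back$calpha, 5)
  expect_equal(back$atoms$residue_name, atoms$residue_name)
  # PDB stores Angstrom at 3 decimals -> 5e-5 nm rounding
  expect_lt(max(abs(back$coords - ens$coords)), 6e-5)
})

test_that("a residue without a CA atom is a hard error naming the residue", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA     1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY     2       2.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(load_ensemble(f), "residue 2")
  expect_error(ensemble(array(0, c(1, 3, 2)),
                        data.frame(residue_index = 1, residue_name = "ALA",
                                   atom_name = "CB", element = "C")),
               "exactly one CA")
})

test_that("macro-trajectory joining is additive with per-part discards", {
  atoms <- ca_atoms(4)
  mk <- function(nf) make_ens(replicate(nf, matrix(rnorm(12), 4, 3),
                                        simplify = FALSE), atoms)
  p1 <- mk(100); p2 <- mk(100)
  expect_equal(n_frames(join_macrotrajectory(list(p1, p2))), 200)
  # 2 ps/frame, discard 20 ps each -> 10 frames dropped per part
  expect_equal(n_frames(join_macrotrajectory(list(p1, p2), discard_ps = 20)), 180)
  # six replicas with mixed discards: frame count equals brute-force sum
  parts <- lapply(c(80, 100, 120, 100, 90, 110), mk)
  disc <- c(0, 20, 40, 10, 0, 30)
  joined <- join_macrotrajectory(parts, disc)
  expect_equal(n_frames(joined),
               sum(vapply(parts, n_frames, 0L) - round(disc / 2)))
  # retained frames are the concatenation of the retained suffixes
  expect_equal(joined$coords[, , 1], parts[[1]]$coords[, , 1])
  bad <- make_ens(list(matrix(rnorm(9), 3, 3)), ca_atoms(3))
  expect_error(join_macrotrajectory(list(p1, bad)), "atom table")
  expect_error(join_macrotrajectory(list(p1), discard_ps = 1000), "discard")
})

test_that("superposition collapses rigid-body motion and is idempotent", {
  set.seed(1)
  base <- matrix(runif(30, 0, 2), 10, 3)
  rigid <- apply_rigid(make_ens(replicate(8, base, simplify = FALSE),
                                ca_atoms(10)))
  sup <- superpose(rigid)
  mu <- apply(calpha_coords(sup), c(1, 2), mean)
  rmsds <- vapply(1:8, function(f)
    sqrt(mean(rowSums((sup$coords[, , f] - mu)^2))), 0)
  expect_lt(max(rmsds), 1e-6)
  # idempotence
  sup2 <- superpose(sup)
  expect_lt(max(abs(sup2$coords - sup$coords)), 1e-5)
  # rigid transform only: intra-frame pairwise distances unchanged
  d0 <- as.matrix(dist(rigid$coords[, , 3]))
  d1 <- as.matrix(dist(sup$coords[, , 3]))
  expect_lt(max(abs(d0 - d1)), 1e-8)
  expect_error(superpose(make_ens(list(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
                                  ca_atoms(5))), "collinear")
})

test_that("superposition recovers internal motion under random rigid transforms", {
  set.seed(7)
  base <- matrix(runif(36, 0, 2), 12, 3)
  frames <- lapply(1:20, function(f) {
    m <- base
    m[1, ] <- m[1, ] + rnorm(3, sd = 0.1)  # internal motion on atom 1
    m
  })
  clean <- make_ens(frames, ca_atoms(12))
  scrambled <- apply_rigid(clean)
  rmsd_of <- function(e) {
    s <- superpose(e)
    mu <- apply(s$coords, c(1, 2), mean)
    vapply(1:20, function(f) sqrt(mean(rowSums((s$coords[, , f] - mu)^2))), 0)
  }
  expect_equal(rmsd_of(scrambled), rmsd_of(clean), tolerance = 1e-6)
})

test_that("representative frame equals the exhaustive rmsd argmin", {
  set.seed(3)
  atoms <- ca_atoms(6)
  # planted minimum: frames symmetric about frame 3, which is the mean
  base <- matrix(runif(18, 0, 2), 6, 3)
  d <- matrix(rnorm(18, sd = 0.2), 6, 3)
  ens <- make_ens(list(base + d, base - d, base, base + 0.5 * d, base - 0.5 * d),
                  atoms)
  expect_equal(representative_frame(ens), 3)
  # tie-break: all frames identical -> first frame
  same <- make_ens(replicate(4, base, simplify = FALSE), atoms)
  expect_equal(representative_frame(same), 1)
  # brute force over 50 random frames
  frames <- replicate(50, base + matrix(rnorm(18, sd = 0.3), 6, 3),
                      simplify = FALSE)
  ens50 <- make_ens(frames, atoms)
  mu <- apply(ens50$coords, c(1, 2), mean)
  brute <- which.min(vapply(1:50, function(f)
    sqrt(mean(rowSums((ens50$coords[, , f] - mu)^2))), 0))
  expect_equal(representative_frame(ens50), brute)
})

test_that("profile smoothing matches the truncated-window brute force", {
  expect_equal(smooth_profile(rep(3.5, 30), 5), rep(3.5, 30))
  x <- rnorm(20)
  expect_equal(smooth_profile(x, 1), x)
  brute <- vapply(1:20, function(i) mean(x[max(1, i - 2):min(20, i + 2)]), 0)
  expect_equal(smooth_profile(x, 5), brute)
  expect_error(smooth_profile(x, 4), "odd")
  expect_error(smooth_profile(x, 21), "larger")
})

test_that("profile mapping flags gaps and matches dictionary lookup", {
  v <- rnorm(5)
  idc <- identity_correspondence(5)
  m <- map_profile(v, idc)
  expect_equal(m$value, v)
  expect_true(all(m$mapped))
  expect_equal(m$index_b, 1:5)
  # one gap
  corr <- residue_correspondence(c(1, 2, 3, 4, 5), c(1, 2, NA, 3, 4))
  m2 <- map_profile(v, corr)
  expect_equal(sum(!m2$mapped), 1)
  expect_equal(m2$index_a[!m2$mapped], 3)
  # random gapped map vs explicit dictionary
  set.seed(9)
  bcol <- rep(NA_integer_, 12)
  keep <- sort(sample(12, 8))
  bcol[keep] <- seq_along(keep)
  corr3 <- residue_correspondence(1:12, bcol)
  m3 <- map_profile(rnorm(12), corr3)
  dict <- setNames(bcol, 1:12)
  expect_equal(m3$index_b, unname(dict[as.character(1:12)]))
  expect_error(map_profile(rnorm(20), corr3), "not covered")
})

test_that("correspondence I/O round-trips through TSV with gap markers", {
  corr <- residue_correspondence(c(1, 2, NA, 3), c(1, NA, 2, 3),
                                 labels = c("cold", "warm"))
  f <- tempfile(fileext = ".tsv")
  write_correspondence(corr, f)
  back <- read_correspondence(f)
  expect_equal(back$index_a, corr$index_a)
  expect_equal(back$index_b, corr$index_b)
  expect_error(residue_correspondence(c(1, 1), c(1, 2)), "one-to-one")
  expect_error(residue_correspondence(c(2, 1), c(1, 2)), "increasing")
})

test_that("domain definitions validate bounds and expand split domains", {
  dom <- domain_definition(list(A = list(c(1, 86), c(147, 356)),
                                B = c(87, 146), C = c(357, 448)), 448)
  expect_equal(domain_residues(dom, "B"), 87:146)
  expect_equal(length(domain_residues(dom, "A")), 86 + (356 - 147 + 1))
  expect_error(domain_definition(list(X = c(1, 500)), 448), "bounds")
})
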