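# Synthetic ensembles with analytic ground truth.  These are first-class
# generators, not fixtures: every downstream analysis (covariance recovery,
# correlation networks, salt-bridge persistence, homolog mapping) can be
# validated against the quantities planted here.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

bead_atom_table <- function(n_residues, residue_name = "ALA") {
  data.frame(residue_index = seq_len(n_residues),
             residue_name = rep_len(residue_name, n_residues),
             atom_name = "CA", element = "C",
             stringsAsFactors = FALSE)
}

bead_mean_structure <- function(n_residues, spacing = 0.38) {
  cbind(spacing * (seq_len(n_residues) - 1), 0, 0)
}

#' Construct an orthonormal set of planted fluctuation modes
#'
#' Helper for building `modes` inputs: takes per-mode lists of
#' `(residue, xyz displacement)` entries, assembles 3N-dimensional vectors,
#' and orthonormalises them by Gram-Schmidt.
#'
#' @param n_residues chain length.
#' @param mode_moves list; each element is a list of `list(residue =, d = c(dx,dy,dz))`.
#' @return matrix `3*n_residues x n_modes`, orthonormal columns.
#' @export
make_modes <- function(n_residues, mode_moves) {
  V <- matrix(0, 3 * n_residues, length(mode_moves))
  for (m in seq_along(mode_moves)) {
    for (mv in mode_moves[[m]]) {
      i <- mv$residue
      V[(3 * i - 2):(3 * i), m] <- V[(3 * i - 2):(3 * i), m] + mv$d
    }
  }
  # Gram-Schmidt
  for (m in seq_len(ncol(V))) {
    if (m > 1) for (p in seq_len(m - 1))
      V[, m] <- V[, m] - sum(V[, m] * V[, p]) * V[, p]
    nv <- sqrt(sum(V[, m]^2))
    if (nv < 1e-12) stop("planted modes are linearly dependent")
    V[, m] <- V[, m] / nv
  }
  V
}

# analytic residue-residue correlation implied by Sigma = V L V' + s2 I
analytic_correlation <- function(V, eigenvalues, noise, n_residues) {
  cc <- matrix(0, n_residues, n_residues)
  if (length(eigenvalues)) {
    W <- V %*% diag(sqrt(eigenvalues), length(eigenvalues))
    for (d in 1:3) {
      idx <- seq(d, 3 * n_residues, by = 3)
      cc <- cc + tcrossprod(W[idx, , drop = FALSE])
    }
  }
  diag(cc) <- diag(cc) + 3 * noise
  v <- diag(cc)
  if (all(v > 0)) cc / sqrt(outer(v, v)) else {
    C <- matrix(NA_real_, n_residues, n_residues)
    ok <- v > 0
    C[ok, ok] <- cc[ok, ok] / sqrt(outer(v[ok], v[ok]))
    C
  }
}

#' Generate a Gaussian bead-chain ensemble with a planted covariance
#'
#' Samples `n_frames` conformations of an `n_residues` C-alpha bead chain
#' from a multivariate normal about a fixed extended mean structure, with
#' covariance `Sigma = V diag(eigenvalues) V' + noise * I` in the
#' 3N-dimensional coordinate space.  Because the true covariance is known,
#' the analytic cross-correlation matrix and eigensystem are returned with
#' the sample, providing exact ground truth for essential-dynamics and
#' correlation-network recovery.
#'
#' @param n_residues chain length.
#' @param eigenvalues numeric vector of planted mode variances (nm^2), >= 0.
#' @param modes matrix `3*n_residues x length(eigenvalues)` with orthonormal
#'   columns (see [make_modes()]); may be `NULL` when `eigenvalues` is empty.
#' @param noise isotropic per-coordinate noise variance (nm^2).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; same seed reproduces the ensemble bit for bit.
#' @param time_per_frame ps per frame.
#' @param label system label.
#' @param residue_name residue name(s) for the bead chain.
#' @return list with elements `ensemble` (an [ensemble()], flagged
#'   superposed since frames fluctuate about a fixed mean), `correlation`
#'   (analytic residue-pair correlation matrix), `eigenvalues` (full 3N
#'   analytic spectrum, descending: planted + noise, then the noise floor),
#'   `modes`, `noise`, `mean` (mean structure), `sigma_trace`.
#' @export
gen_gaussian_ensemble <- function(n_residues, eigenvalues = numeric(),
                                  modes = NULL, noise = 0, n_frames = 100,
                                  seed = NULL, time_per_frame = 2,
                                  label = "synthetic",
                                  residue_name = "ALA") {
  stopifnot(n_frames >= 2, noise >= 0, all(eigenvalues >= 0))
  n3 <- 3L * n_residues
  if (length(eigenvalues)) {
    if (is.null(modes) || ncol(modes) != length(eigenvalues) || nrow(modes) != n3)
      stop("'modes' must be a ", n3, " x ", length(eigenvalues), " matrix")
    g <- crossprod(modes)
    if (max(abs(g - diag(ncol(modes)))) > 1e-8)
      stop("mode vectors are not orthonormal")
  }
  mu <- bead_mean_structure(n_residues)
  mu_vec <- as.vector(t(mu))  # x1,y1,z1,...
  X <- with_seed(seed, {
    base <- matrix(stats::rnorm(n_frames * n3, sd = sqrt(noise)), n_frames, n3)
    if (length(eigenvalues)) {
      z <- matrix(stats::rnorm(n_frames * length(eigenvalues)), n_frames)
      base <- base + z %*% (t(modes) * sqrt(eigenvalues))
    }
    sweep(base, 2, mu_vec, "+")
  })
  coords <- aperm(array(t(X), dim = c(3, n_residues, n_frames)), c(2, 1, 3))
  ens <- ensemble(coords, bead_atom_table(n_residues, residue_name),
                  time_per_frame = time_per_frame, label = label,
                  superposed = TRUE)
  spec_full <- sort(c(eigenvalues + noise, rep(noise, n3 - length(eigenvalues))),
                    decreasing = TRUE)
  list(ensemble = ens,
       correlation = analytic_correlation(modes, eigenvalues, noise, n_residues),
       eigenvalues = spec_full,
       modes = modes, noise = noise, mean = mu,
       sigma_trace = sum(eigenvalues) + noise * n3)
}

#' Draw salt-bridge persistences from a bimodal signal/noise mixture
#'
#' Two-component Beta mixture: a "noise" component supported on
#' `[0, 0.10]` with mode near 0.05, and a "signal" component supported on
#' `[0.30, 1]` with mode near 0.6, leaving the interval `(0.10, 0.30)`
#' empty.  This emulates the empirically bimodal distribution of ion-pair
#' persistences in equilibrium ensembles, where contacts are either
#' transient encounters or structurally relevant bridges.
#'
#' @param n number of persistences to draw.
#' @param signal_weight probability of the signal component.
#' @param seed integer seed or `NULL`.
#' @return list `p` (numeric persistences) and `class` (`"noise"`/`"signal"`).
#' @export
rpersistence_mixture <- function(n, signal_weight = 0.5, seed = NULL) {
  with_seed(seed, {
    is_sig <- stats::runif(n) < signal_weight
    p <- numeric(n)
    p[!is_sig] <- 0.10 * stats::rbeta(sum(!is_sig), 2, 2)
    p[is_sig] <- 0.30 + 0.70 * stats::rbeta(sum(is_sig), 2.5, 3)
    list(p = p, class = ifelse(is_sig, "signal", "noise"))
  })
}

#' Generate charged pseudo-residue pairs with planted contact persistence
#'
#' Builds an ensemble of `n_pairs` independent, spatially well-separated
#' GLU/LYS pseudo-residue pairs.  For pair `k` with planted persistence
#' `p[k]`, each frame independently places the charged atoms at the
#' `formed` distance with probability `p[k]` and at the `broken` distance
#' otherwise (a Bernoulli contact time series).  The true per-pair
#' persistence is returned, giving exact ground truth for salt-bridge
#' detection and cutoff selection.
#'
#' @param n_pairs number of charged pairs.
#' @param n_frames frames.
#' @param p planted persistences in `[0,1]`; default drawn from
#'   [rpersistence_mixture()].
#' @param formed,broken charged-group distances (nm) in the formed and
#'   broken state; must satisfy `formed < detect_cutoff < broken`.
#' @param detect_cutoff the detection cutoff the series is built for (nm).
#' @param seed integer seed.
#' @param time_per_frame ps per frame.
#' @param label system label.
#' @return list: `ensemble` (an [ensemble()] with CA + charged side-chain
#'   pseudo-atoms), `truth` (data frame `pair`, `res_neg`, `res_pos`,
#'   `p_true`).
#' @export
gen_contact_series <- function(n_pairs, n_frames = 1000, p = NULL,
                               formed = 0.30, broken = 0.80,
                               detect_cutoff = 0.40, seed = NULL,
                               time_per_frame = 2, label = "contacts") {
  if (!(formed < detect_cutoff && detect_cutoff < broken))
    stop("need formed < detect_cutoff < broken")
  drawn <- NULL
  if (is.null(p)) {
    drawn <- rpersistence_mixture(n_pairs, seed = seed)
    p <- drawn$p
    seed <- if (is.null(seed)) NULL else seed + 1L
  }
  stopifnot(length(p) == n_pairs, all(p >= 0), all(p <= 1))
  n_res <- 2L * n_pairs
  atoms <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    data.frame(residue_index = c(2L * k - 1L, 2L * k - 1L, 2L * k, 2L * k),
               residue_name = c("GLU", "GLU", "LYS", "LYS"),
               atom_name = c("CA", "OE1", "CA", "NZ"),
               element = c("C", "O", "C", "N"),
               stringsAsFactors = FALSE)
  }))
  n_at <- nrow(atoms)
  coords <- array(0, dim = c(n_at, 3, n_frames))
  contact <- with_seed(seed, {
    matrix(stats::runif(n_pairs * n_frames), n_pairs, n_frames) < p
  })
  for (k in seq_len(n_pairs)) {
    x0 <- 10 * k  # pairs 10 nm apart: no cross-pair contacts possible
    a <- 4L * (k - 1L)
    coords[a + 1L, , ] <- c(x0, 0, 0)            # GLU CA
    coords[a + 2L, , ] <- c(x0, 0.2, 0)          # GLU OE1 (fixed)
    coords[a + 3L, , ] <- c(x0, 2.0, 0)          # LYS CA
    d <- ifelse(contact[k, ], formed, broken)
    coords[a + 4L, 1, ] <- x0
    coords[a + 4L, 2, ] <- 0.2 + d               # LYS NZ toggles
    coords[a + 4L, 3, ] <- 0
  }
  ens <- ensemble(coords, atoms, time_per_frame = time_per_frame,
                  label = label, superposed = TRUE)
  truth <- data.frame(pair = seq_len(n_pairs),
                      res_neg = 2L * seq_len(n_pairs) - 1L,
                      res_pos = 2L * seq_len(n_pairs),
                      p_true = p,
                      class = if (!is.null(drawn)) drawn$class else
                        ifelse(p > 0.30, "signal", ifelse(p < 0.10, "noise", "mid")))
  list(ensemble = ens, truth = truth)
}

#' Generate a homolog pair with shared planted dynamics and indels
#'
#' Produces two bead-chain ensembles related by a gapped residue
#' correspondence.  Positions mapped between the systems share the same
#' planted fluctuation modes (transferred through the correspondence), so
#' cross-system recovery of correlated motions can be checked exactly;
#' insertion residues carry only isotropic noise.
#'
#' @param n_residues length of system A.
#' @param indels list of `list(system = "A"|"B", at =, length =)`:
#'   an insertion of `length` extra residues in the named system after
#'   its aligned position `at` (positions on the A frame of reference).
#'   Insertions must not overlap.
#' @param eigenvalues,mode_moves planted modes on A-numbered residues (see
#'   [make_modes()]); moved residues must be mapped in both systems.
#' @param noise isotropic noise variance (nm^2).
#' @param n_frames frames per system.
#' @param seed integer seed.
#' @param labels the two system labels.
#' @return list: `a`, `b` (each as returned by [gen_gaussian_ensemble()]),
#'   `correspondence` (a [residue_correspondence()]).
#' @export
gen_homolog_pair <- function(n_residues, indels = list(),
                             eigenvalues = numeric(), mode_moves = list(),
                             noise = 0.01, n_frames = 500, seed = NULL,
                             labels = c("A", "B")) {
  at_pos <- vapply(indels, function(x) x$at, 0)
  if (anyDuplicated(at_pos)) stop("overlapping indels")
  if (length(at_pos) && (any(at_pos < 0) || any(at_pos > n_residues)))
    stop("indel position out of bounds")
  # build alignment rows on the A frame of reference
  align <- data.frame(a = seq_len(n_residues), b = seq_len(n_residues))
  for (ind in indels) {
    ins <- data.frame(a = rep(NA_integer_, ind$length), b = rep(NA_integer_, ind$length))
    side <- match.arg(ind$system, c("A", "B"))
    if (side == "B") ins$b <- -1L else ins$a <- -1L  # placeholders, renumbered below
    # insert after aligned A-position 'at'
    pos <- if (ind$at == 0) 0 else max(which(!is.na(align$a) & align$a == ind$at))
    align <- rbind(align[seq_len(pos), , drop = FALSE], ins,
                   if (pos < nrow(align)) align[(pos + 1):nrow(align), , drop = FALSE])
  }
  # renumber each side consecutively
  align$a[!is.na(align$a)] <- seq_len(sum(!is.na(align$a)))
  align$b[!is.na(align$b)] <- seq_len(sum(!is.na(align$b)))
  corr <- residue_correspondence(align$a, align$b, labels = labels)
  nA <- sum(!is.na(align$a)); nB <- sum(!is.na(align$b))

  # map A-numbered mode moves to B numbering through the correspondence
  a2b <- align$b[match(seq_len(nA), align$a)]
  moves_b <- lapply(mode_moves, function(mm) lapply(mm, function(mv) {
    bi <- a2b[mv$residue]
    if (is.na(bi)) stop("planted mode touches a residue unmapped in B")
    list(residue = bi, d = mv$d)
  }))
  modes_a <- if (length(eigenvalues)) make_modes(nA, mode_moves) else NULL
  modes_b <- if (length(eigenvalues)) make_modes(nB, moves_b) else NULL
  seeds <- if (is.null(seed)) c(NA, NA) else c(seed, seed + 1L)
  a <- gen_gaussian_ensemble(nA, eigenvalues, modes_a, noise, n_frames,
                             seed = if (is.null(seed)) NULL else seeds[1],
                             label = labels[1])
  b <- gen_gaussian_ensemble(nB, eigenvalues, modes_b, noise, n_frames,
                             seed = if (is.null(seed)) NULL else seeds[2],
                             label = labels[2])
  list(a = a, b = b, correspondence = corr)
}
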