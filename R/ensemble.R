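#' Conformational ensemble container
#'
#' An `ensemble` holds an ordered set of conformations (frames) of one
#' molecular system together with per-atom metadata.  All coordinates are in
#' nanometres and frame spacing in picoseconds.  Every analysis in the
#' package consumes this object, whether it was read from a multi-model PDB
#' file or produced by one of the synthetic generators.
#'
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, in nm.
#' @param atoms data frame with columns `residue_index` (1-based integer),
#'   `residue_name`, `atom_name`, `element`; one row per atom, identical for
#'   every frame.
#' @param time_per_frame frame spacing in ps (> 0).
#' @param label free-text system label used in reports.
#' @param superposed logical; `TRUE` if the frames are already least-squares
#'   fitted to a common reference (set by [superpose()] and by the synthetic
#'   generators, which sample fluctuations about a fixed mean structure).
#'
#' @return An object of class `"ensemble"`: a list with elements `coords`,
#'   `atoms`, `calpha` (per-residue atom index of the C-alpha), `n_residues`,
#'   `time_per_frame`, `label`, `superposed`.
#' @export
ensemble <- function(coords, atoms, time_per_frame = 2, label = "system",
                     superposed = FALSE) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("'coords' must be an n_atoms x 3 x n_frames array")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in ensemble")
  if (nrow(atoms) != dim(coords)[1])
    stop("atom table size does not match coordinate array")
  need <- c("residue_index", "residue_name", "atom_name", "element")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  if (!(is.numeric(time_per_frame) && length(time_per_frame) == 1L &&
        time_per_frame > 0))
    stop("'time_per_frame' must be a single positive number (ps)")

  atoms$residue_index <- as.integer(atoms$residue_index)
  res_idx <- sort(unique(atoms$residue_index))
  calpha <- integer(length(res_idx))
  for (k in seq_along(res_idx)) {
    hit <- which(atoms$residue_index == res_idx[k] & atoms$atom_name == "CA")
    if (length(hit) != 1L)
      stop("residue ", res_idx[k], " (",
           atoms$residue_name[atoms$residue_index == res_idx[k]][1],
           ") must have exactly one CA atom, found ", length(hit))
    calpha[k] <- hit
  }
  structure(list(coords = coords, atoms = atoms, calpha = calpha,
                 residue_index = res_idx,
                 n_residues = length(res_idx),
                 time_per_frame = time_per_frame, label = label,
                 superposed = isTRUE(superposed)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Conformational ensemble:", x$label, "\n")
  cat(sprintf("  %d frames x %d atoms (%d residues), %.3g ps/frame, %s\n",
              n_frames(x), nrow(x$atoms), x$n_residues, x$time_per_frame,
              if (x$superposed) "superposed" else "not superposed"))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an [ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Total simulated duration of an ensemble in ps
#' @param ens an [ensemble()].
#' @return duration in ps (`n_frames * time_per_frame`).
#' @export
duration_ps <- function(ens) n_frames(ens) * ens$time_per_frame

#' C-alpha coordinates of an ensemble
#' @param ens an [ensemble()].
#' @return array `c(n_residues, 3, n_frames)` in nm.
#' @export
calpha_coords <- function(ens) {
  ens$coords[ens$calpha, , , drop = FALSE]
}

#' Subset an ensemble by frame
#' @param x an [ensemble()].
#' @param frames integer frame indices to retain (in order).
#' @param ... unused.
#' @return an [ensemble()] with the selected frames.
#' @export
subset_frames <- function(x, frames, ...) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(x)))
  ensemble(x$coords[, , frames, drop = FALSE], x$atoms,
           time_per_frame = x$time_per_frame, label = x$label,
           superposed = x$superposed)
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", atom_name)
  first <- substr(nm, 1, 1)
  ifelse(first %in% c("H", "C", "N", "O", "S", "P"), first, first)
}

#' Read a conformational ensemble
#'
#' Loads a multi-model PDB file (MODEL/ENDMDL records) into an [ensemble()].
#' Coordinates are converted from Angstrom to nm on read.  Residues are
#' renumbered 1-based in file order if `renumber = TRUE` (the default keeps
#' the file's numbering, which must already be usable as 1-based indices for
#' profile outputs).
#'
#' @param path path to a multi-model PDB file.
#' @param time_per_frame frame spacing in ps to record on the ensemble.
#' @param label system label; default the file base name.
#' @return an [ensemble()].
#' @export
load_ensemble <- function(path, time_per_frame = 2,
                          label = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * n_at)
    stop("inconsistent atom count across frames in ", path)
  ele <- pdb$atom$elesy
  ele[is.na(ele) | ele == ""] <- guess_element(pdb$atom$elety[is.na(ele) | ele == ""])
  atoms <- data.frame(residue_index = pdb$atom$resno,
                      residue_name = pdb$atom$resid,
                      atom_name = pdb$atom$elety,
                      element = ele,
                      stringsAsFactors = FALSE)
  # xyz rows are frames laid out x1,y1,z1,x2,...  (Angstrom -> nm)
  coords <- aperm(array(t(xyz) / 10, dim = c(3, n_at, nrow(xyz))), c(2, 1, 3))
  ensemble(coords, atoms, time_per_frame = time_per_frame, label = label)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstrom (PDB convention, 3 decimal
#' places, so the round-trip precision is 1e-4 nm).
#'
#' @param ens an [ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  n_at <- nrow(ens$atoms)
  xyz <- t(matrix(aperm(ens$coords * 10, c(2, 1, 3)), nrow = 3 * n_at))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ens$atoms$residue_index,
                   resid = ens$atoms$residue_name,
                   elety = ens$atoms$atom_name,
                   elesy = ens$atoms$element)
  invisible(path)
}

#' Join replica trajectories into a macro-trajectory
#'
#' Concatenates the equilibrated portions of independent replica simulations
#' of one system into a single ensemble, discarding a per-replica
#' equilibration prefix.
#'
#' @param parts list of [ensemble()] objects sharing the same atom table and
#'   frame spacing.
#' @param discard_ps numeric vector (recycled if length 1) of prefix
#'   durations to discard from each part, in ps.
#' @return an [ensemble()] with the retained frames of all parts, in order.
#' @export
join_macrotrajectory <- function(parts, discard_ps = 0) {
  stopifnot(length(parts) >= 1L)
  discard_ps <- rep_len(discard_ps, length(parts))
  ref <- parts[[1]]$atoms
  dt <- parts[[1]]$time_per_frame
  kept <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (!identical(dim(p$atoms), dim(ref)) || !all(p$atoms == ref, na.rm = TRUE))
      stop("part ", i, " has a different atom table; cannot join")
    if (p$time_per_frame != dt)
      stop("part ", i, " has a different frame spacing; cannot join")
    n_drop <- round(discard_ps[i] / dt)
    if (n_drop >= n_frames(p))
      stop("discard (", discard_ps[i], " ps) >= length of part ", i)
    kept[[i]] <- p$coords[, , (n_drop + 1):n_frames(p), drop = FALSE]
  }
  coords <- array(unlist(kept), dim = c(nrow(ref), 3, sum(vapply(kept, function(k) dim(k)[3], 0L))))
  ensemble(coords, ref, time_per_frame = dt, label = parts[[1]]$label)
}

kabsch_prepare <- function(sel_coords) {
  # rank check on the centered selection: a collinear selection leaves the
  # rotation about its axis undetermined
  ctr <- sweep(sel_coords, 2, colMeans(sel_coords))
  sv <- svd(ctr)$d
  if (length(sv) < 2L || sv[2] < 1e-8 * max(sv[1], 1e-300))
    stop("degenerate (collinear) superposition selection")
  invisible(NULL)
}

#' Least-squares superposition onto the iteratively refined mean structure
#'
#' Fits every frame onto the ensemble mean by rigid-body least squares on a
#' selection of atoms, recomputes the mean, and iterates until the mean
#' structure moves by less than `tol` (nm).  This is the standard
#' prerequisite for covariance/essential-dynamics analysis: it removes
#' overall translation and rotation so that only internal fluctuations
#' remain.
#'
#' @param ens an [ensemble()].
#' @param selection integer atom indices to fit on; default all C-alpha
#'   atoms.  Must contain at least 3 non-collinear atoms.
#' @param tol convergence tolerance on the mean-structure shift, nm.
#' @param max_iter maximum number of fit/re-mean iterations.
#' @return the superposed [ensemble()] (`superposed = TRUE`).
#' @export
superpose <- function(ens, selection = ens$calpha, tol = 1e-6, max_iter = 50) {
  if (length(selection) < 3L) stop("superposition selection needs >= 3 atoms")
  n_at <- nrow(ens$atoms)
  kabsch_prepare(ens$coords[selection, , 1])
  xyz <- t(matrix(aperm(ens$coords, c(2, 1, 3)), nrow = 3 * n_at))
  sel3 <- as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
  ref <- xyz[1, ]
  for (it in seq_len(max_iter)) {
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                             fixed.inds = sel3, mobile.inds = sel3)
    m <- colMeans(fitted)
    shift <- max(abs(m[sel3] - ref[sel3]))
    ref <- m
    xyz <- fitted
    if (shift < tol) break
  }
  coords <- aperm(array(t(xyz), dim = c(3, n_at, nrow(xyz))), c(2, 1, 3))
  out <- ensemble(coords, ens$atoms, time_per_frame = ens$time_per_frame,
                  label = ens$label, superposed = TRUE)
  out
}

mainchain_selection <- function(ens) {
  sel <- which(ens$atoms$atom_name %in% c("N", "CA", "C", "O"))
  if (length(unique(ens$atoms$atom_name[sel])) < 2L) {
    message("main-chain atoms beyond CA not present; using CA only")
    sel <- ens$calpha
  }
  sel
}

#' Representative (average) conformation of an ensemble
#'
#' Returns the index of the sampled frame with the least main-chain rmsd
#' from the ensemble average of atomic positions; this frame stands in for
#' the (unphysical) coordinate mean in structural reports.  Main chain means
#' N, CA, C, O where present, otherwise C-alpha only.
#'
#' @param ens a superposed [ensemble()].
#' @param selection atom indices defining "main chain"; default as above.
#' @return integer frame index (1-based); ties broken by the lowest index.
#' @export
representative_frame <- function(ens, selection = mainchain_selection(ens)) {
  nf <- n_frames(ens)
  if (nf < 1L) stop("empty ensemble")
  sub <- ens$coords[selection, , , drop = FALSE]
  mu <- apply(sub, c(1, 2), mean)
  rmsd <- vapply(seq_len(nf), function(f)
    sqrt(mean(rowSums((sub[, , f] - mu)^2))), 0)
  which.min(rmsd)
}

#' Smooth a per-residue profile by centered window averaging
#'
#' @param values numeric per-residue series.
#' @param window odd window size in residues (default 5).  Windows are
#'   truncated at the chain ends, so the output has the same length.
#' @return smoothed numeric vector.
#' @export
smooth_profile <- function(values, window = 5) {
  n <- length(values)
  if (window %% 2 != 1 || window < 1) stop("'window' must be odd and >= 1")
  if (window > n) stop("'window' larger than the profile")
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(values[max(1L, i - h):min(n, i + h)]), 0)
}
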