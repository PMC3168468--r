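# shared test utilities: small hand-built ensembles and rigid transforms

random_rotation <- function() {
  # QR of a random matrix, sign-fixed to det +1
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(ens, per_frame = TRUE) {
  # random rotation + translation, optionally different per frame
  co <- ens$coords
  nf <- dim(co)[3]
  R <- random_rotation(); tr <- rnorm(3)
  for (f in seq_len(nf)) {
    if (per_frame && f > 1) { R <- random_rotation(); tr <- rnorm(3) }
    co[, , f] <- co[, , f] %*% t(R) + matrix(tr, nrow(co), 3, byrow = TRUE)
  }
  ensemble(co, ens$atoms, time_per_frame = ens$time_per_frame,
           label = ens$label, superposed = FALSE)
}

# an ensemble with arbitrary atoms built from a list of frame matrices
make_ens <- function(frames, atoms, dt = 2, superposed = TRUE) {
  co <- array(unlist(frames), dim = c(nrow(atoms), 3, length(frames)))
  ensemble(co, atoms, time_per_frame = dt, superposed = superposed)
}

ca_atoms <- function(n, name = "ALA") {
  data.frame(residue_index = seq_len(n), residue_name = name,
             atom_name = "CA", element = "C", stringsAsFactors = FALSE)
}

# ordinary (full-space) per-residue rmsf computed directly
plain_rmsf <- function(ens) {
  ca <- calpha_coords(ens)
  mu <- apply(ca, c(1, 2), mean)
  sqrt(vapply(seq_len(dim(ca)[1]), function(i)
    mean(colSums((ca[i, , ] - mu[i, ])^2)), 0))
}

# two-residue donor/acceptor system: residue 1 has backbone N-H, residue 2
# a backbone O; CA atoms are parked away from the interaction geometry
hb_atoms <- data.frame(
  residue_index = c(1L, 1L, 1L, 2L, 2L),
  residue_name = "ALA",
  atom_name = c("CA", "N", "H", "CA", "O"),
  element = c("C", "N", "H", "C", "O"),
  stringsAsFactors = FALSE)

hb_frame <- function(da_dist, angle_deg) {
  # donor N at origin, acceptor along +x, hydrogen at angle_deg from the
  # donor-acceptor axis
  rad <- angle_deg * pi / 180
  rbind(c(0, 5, 0),                               # CA res 1 (remote)
        c(0, 0, 0),                               # N (donor)
        0.1 * c(cos(rad), sin(rad), 0),           # H
        c(5, 5, 0),                               # CA res 2 (remote)
        c(da_dist, 0, 0))                         # O (acceptor)
}

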