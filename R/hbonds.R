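#' Load a donor/acceptor atom table
#'
#' Three-column TSV (`residue`, `atom`, `role` in donor/acceptor) declaring
#' which atoms of each residue type can donate or accept intramolecular
#' hydrogen bonds.  `*` in the residue column matches any residue type
#' (used for the backbone N donor and O acceptor).  The packaged default
#' follows standard amino-acid chemistry; backbone N of proline is never
#' treated as a donor (it carries no amide hydrogen).
#'
#' @param path TSV path; `NULL` loads the packaged default.
#' @return data frame `residue`, `atom`, `role`.
#' @export
load_donor_acceptor_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hbond_donors_acceptors.tsv",
                        package = "ensembledyn", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!nrow(tab)) stop("empty donor/acceptor table")
  tab$role <- match.arg(tab$role, c("donor", "acceptor"), several.ok = TRUE)
  tab
}

#' Geometric hydrogen-bond criteria
#'
#' @param distance_cutoff donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_cutoff angular cutoff in degrees (default 30).
#' @param table donor/acceptor table, see [load_donor_acceptor_table()].
#' @param vertex `"donor"` (default): the angle is measured at the donor,
#'   between the donor-hydrogen and donor-acceptor vectors (the common MD
#'   convention with a 30 degree cutoff).  `"hydrogen"`: the criterion is
#'   instead the deviation from linearity of D-H...A, i.e.
#'   `180 - angle(D,H,A) <= angle_cutoff`.
#' @return class `"hbond_criteria"` list.
#' @export
hbond_criteria <- function(distance_cutoff = 0.35, angle_cutoff = 30,
                           table = load_donor_acceptor_table(),
                           vertex = c("donor", "hydrogen")) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, nrow(table) > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff, table = table,
                 vertex = match.arg(vertex)),
            class = "hbond_criteria")
}

match_role <- function(ens, table, role) {
  tab <- table[table$role == role, , drop = FALSE]
  resn <- toupper(ens$atoms$residue_name)
  hit <- rep(FALSE, nrow(ens$atoms))
  for (r in seq_len(nrow(tab))) {
    ok <- ens$atoms$atom_name == tab$atom[r] &
      (tab$residue[r] == "*" | resn == toupper(tab$residue[r]))
    hit <- hit | ok
  }
  if (role == "donor")  # proline backbone N has no hydrogen
    hit <- hit & !(resn == "PRO" & ens$atoms$atom_name == "N")
  which(hit)
}

attach_hydrogens <- function(ens, donors, d_bond = 0.115) {
  # hydrogens covalently bound to each donor: same residue, within d_bond
  # (nm) in the first frame
  hyd <- which(ens$atoms$element == "H")
  x0 <- ens$coords[, , 1]
  out <- lapply(donors, function(d) {
    cand <- hyd[ens$atoms$residue_index[hyd] == ens$atoms$residue_index[d]]
    if (!length(cand)) return(integer())
    dd <- sqrt(colSums((t(x0[cand, , drop = FALSE]) - x0[d, ])^2))
    cand[dd <= d_bond]
  })
  names(out) <- as.character(donors)
  out
}

#' Detect intramolecular hydrogen bonds over an ensemble
#'
#' A bond exists in a frame iff the donor-acceptor distance is at most the
#' distance cutoff and the angular criterion of `crit` is satisfied for at
#' least one hydrogen attached to the donor.  Donor and acceptor must
#' belong to different residues.  Structures lacking explicit hydrogens on
#' their donors are rejected rather than silently falling back to a
#' distance-only criterion.
#'
#' @param ens an [ensemble()] with explicit hydrogens.
#' @param crit an [hbond_criteria()].
#' @return class `"hbond_summary"`: list with `pairs` (data frame `donor`,
#'   `acceptor` atom indices, residue columns, `persistence`), `per_frame`
#'   (logical pairs x frames matrix), `n_donors`, `n_acceptors`, `criteria`.
#' @export
detect_hbonds <- function(ens, crit = hbond_criteria()) {
  donors <- match_role(ens, crit$table, "donor")
  acceptors <- match_role(ens, crit$table, "acceptor")
  if (!length(donors) || !length(acceptors))
    stop("empty donor or acceptor set for this system")
  hyd <- attach_hydrogens(ens, donors)
  bare <- donors[lengths(hyd) == 0L]
  if (length(bare))
    stop("donor atom(s) without attached hydrogens: ",
         paste(sprintf("%s%d:%s", ens$atoms$residue_name[bare],
                       ens$atoms$residue_index[bare],
                       ens$atoms$atom_name[bare]), collapse = ", "),
         " (explicit hydrogens are required)")
  res_d <- ens$atoms$residue_index[donors]
  res_a <- ens$atoms$residue_index[acceptors]
  diff_res <- outer(res_d, res_a, "!=")
  nf <- n_frames(ens)
  cosmin <- cos(crit$angle_cutoff * pi / 180)
  pair_key <- NULL
  per_frame <- list()
  hits <- vector("list", nf)
  for (f in seq_len(nf)) {
    X <- ens$coords[, , f]
    D <- X[donors, , drop = FALSE]
    A <- X[acceptors, , drop = FALSE]
    d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * tcrossprod(D, A)
    cand <- which(diff_res & d2 <= crit$distance_cutoff^2, arr.ind = TRUE)
    ok <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      di <- donors[cand[r, 1]]; ai <- acceptors[cand[r, 2]]
      hs <- hyd[[as.character(di)]]
      vda <- X[ai, ] - X[di, ]
      found <- FALSE
      for (h in hs) {
        if (crit$vertex == "donor") {
          vdh <- X[h, ] - X[di, ]
          cosang <- sum(vdh * vda) / sqrt(sum(vdh^2) * sum(vda^2))
          if (cosang >= cosmin) { found <- TRUE; break }
        } else {
          vhd <- X[di, ] - X[h, ]; vha <- X[ai, ] - X[h, ]
          cosang <- sum(vhd * vha) / sqrt(sum(vhd^2) * sum(vha^2))
          # linear D-H...A means angle(D,H,A) near 180 deg; accept when the
          # deviation from linearity is at most the cutoff
          if (cosang <= cos((180 - crit$angle_cutoff) * pi / 180)) {
            found <- TRUE; break
          }
        }
      }
      ok[r] <- found
    }
    hits[[f]] <- cand[ok, , drop = FALSE]
  }
  keys <- unique(do.call(rbind, hits))
  if (is.null(keys) || nrow(keys) == 0L)
    keys <- matrix(integer(), 0, 2)
  pf <- matrix(FALSE, nrow(keys), nf)
  if (nrow(keys)) {
    key_id <- paste(keys[, 1], keys[, 2])
    for (f in seq_len(nf)) {
      if (nrow(hits[[f]]))
        pf[match(paste(hits[[f]][, 1], hits[[f]][, 2]), key_id), f] <- TRUE
    }
  }
  pairs <- data.frame(donor = donors[keys[, 1]],
                      acceptor = acceptors[keys[, 2]],
                      donor_residue = res_d[keys[, 1]],
                      acceptor_residue = res_a[keys[, 2]],
                      persistence = if (nrow(keys)) rowMeans(pf) else numeric())
  structure(list(pairs = pairs, per_frame = pf,
                 donors = donors, acceptors = acceptors,
                 n_donors = length(donors), n_acceptors = length(acceptors),
                 criteria = crit, n_frames = nf),
            class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf("H-bond summary: %d pairs observed over %d frames (%d donors, %d acceptors)\n",
              nrow(x$pairs), x$n_frames, x$n_donors, x$n_acceptors))
  invisible(x)
}

#' Percentage of donors and acceptors involved in hydrogen bonds
#'
#' Per frame, the number of distinct donor atoms plus distinct acceptor
#' atoms participating in at least one detected bond, divided by the total
#' number of donors plus acceptors, times 100; the ensemble value is the
#' mean over frames.
#'
#' @param summary an `hbond_summary` from [detect_hbonds()].
#' @return percentage in `[0, 100]`.
#' @export
normalized_hbond_fraction <- function(summary) {
  denom <- summary$n_donors + summary$n_acceptors
  if (denom == 0) stop("no donors or acceptors")
  if (!nrow(summary$pairs)) return(0)
  per_frame <- vapply(seq_len(summary$n_frames), function(f) {
    on <- summary$per_frame[, f]
    length(unique(summary$pairs$donor[on])) +
      length(unique(summary$pairs$acceptor[on]))
  }, 0)
  100 * mean(per_frame / denom)
}
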