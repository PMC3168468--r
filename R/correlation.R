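# Dynamic cross-correlation of C-alpha fluctuations, computed on
# non-overlapping time windows and averaged.  Frames are re-fitted within
# each window so slow inter-window drift does not inflate correlations.

window_correlation_one <- function(ca, refit) {
  # ca: n x 3 x frames for one window
  n <- dim(ca)[1]
  if (refit && dim(ca)[3] >= 2) {
    tmp <- ensemble(ca, bead_atom_table(n), superposed = FALSE)
    ca <- calpha_coords(suppressMessages(superpose(tmp)))
  }
  n3 <- 3L * n
  X <- t(matrix(aperm(ca, c(2, 1, 3)), nrow = n3))
  D <- sweep(X, 2, colMeans(X))
  cc <- matrix(0, n, n)
  for (d in 1:3) {
    idx <- seq(d, n3, by = 3)
    cc <- cc + crossprod(D[, idx, drop = FALSE]) / nrow(D)
  }
  v <- diag(cc)
  C <- matrix(NA_real_, n, n)
  ok <- v > 1e-14
  if (any(ok))
    C[ok, ok] <- cc[ok, ok, drop = FALSE] / sqrt(outer(v[ok], v[ok]))
  C
}

#' Windowed dynamic cross-correlation matrix
#'
#' Splits the trajectory into non-overlapping windows of `window_ps`
#' (trailing partial window dropped), computes within each window the
#' normalised covariance `C(i,j) = c(i,j)/sqrt(c(i,i) c(j,j))` of C-alpha
#' fluctuation vectors about the window mean, and averages the per-window
#' matrices elementwise.  Residues with zero variance in a window yield
#' masked (`NA`) entries for that window, excluded from the average with a
#' message.
#'
#' @param ens a superposed [ensemble()].
#' @param window_ps averaging-window length in ps (default 1000, i.e. 1 ns);
#'   `NULL` uses the whole trajectory as a single window.
#' @param refit additionally re-fit frames rigid-body onto the window mean
#'   before computing the covariance (default `FALSE`).  Fluctuations are
#'   always taken about the window mean, which removes inter-window drift;
#'   per-window re-fitting is only useful when substantial rotational
#'   drift survives the global superposition, and it spreads a small
#'   spurious anticorrelation over all residues, so it is off by default.
#' @return class `"correlation_matrix"`: list with `C` (averaged matrix,
#'   symmetric, unit diagonal), `per_window` (array n x n x windows),
#'   `window_ps`, `n_windows`.
#' @export
windowed_correlation <- function(ens, window_ps = 1000, refit = FALSE) {
  check_superposed(ens)
  nf <- n_frames(ens)
  dt <- ens$time_per_frame
  wf <- if (is.null(window_ps)) nf else round(window_ps / dt)
  if (wf < 2) stop("window shorter than 2 frames")
  nw <- nf %/% wf
  if (nw < 1) stop("trajectory shorter than one window")
  ca <- calpha_coords(ens)
  n <- ens$n_residues
  per_window <- array(NA_real_, dim = c(n, n, nw))
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * wf + 1L):(w * wf)
    per_window[, , w] <- window_correlation_one(ca[, , idx, drop = FALSE], refit)
  }
  if (anyNA(per_window))
    message("zero-variance residue(s) in some windows; entries masked")
  C <- apply(per_window, c(1, 2), mean, na.rm = TRUE)
  C[is.nan(C)] <- NA_real_
  structure(list(C = C, per_window = per_window,
                 window_ps = wf * dt, n_windows = nw),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Cross-correlation matrix: %d residues, %d window(s) of %.3g ns\n",
              nrow(x$C), x$n_windows, x$window_ps / 1000))
  invisible(x)
}

#' Pair-exclusion mask from secondary-structure annotation
#'
#' Builds the logical residue-pair mask used to discard correlations that
#' merely reflect secondary structure: pairs lying in the same annotated
#' helix segment, and pairs both belonging to the annotated barrel-strand
#' residue set.
#'
#' @param ss per-residue secondary-structure labels (DSSP-style; helices
#'   are contiguous runs of labels in `helix_labels`).
#' @param barrel_strands integer residue indices forming the beta barrel
#'   (optional).
#' @param helix_labels labels counted as helix (default `c("H","G","I")`).
#' @return logical n x n matrix, `TRUE` = excluded pair.
#' @export
ss_pair_mask <- function(ss, barrel_strands = NULL,
                         helix_labels = c("H", "G", "I")) {
  n <- length(ss)
  mask <- matrix(FALSE, n, n)
  is_h <- ss %in% helix_labels
  r <- rle(is_h)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    idx <- starts[seg]:ends[seg]
    mask[idx, idx] <- TRUE
  }
  if (length(barrel_strands)) {
    bs <- intersect(barrel_strands, seq_len(n))
    mask[bs, bs] <- TRUE
  }
  diag(mask) <- TRUE
  mask
}

#' Filter a correlation matrix into a significant long-range network
#'
#' Retains residue pairs with `|C(i,j)| > c_cut` and sequence separation
#' `|i - j| > sep_cut` (both strict), optionally removing pairs excluded by
#' a secondary-structure mask.  Edge weights are preserved for
#' width-proportional export.
#'
#' @param cm a [windowed_correlation()] result (or plain matrix).
#' @param c_cut correlation magnitude cutoff (default 0.4).
#' @param sep_cut sequence-separation cutoff in residues (default 12).
#' @param mask optional logical n x n exclusion matrix from
#'   [ss_pair_mask()].
#' @return class `"correlation_network"`: data frame `i`, `j`, `c`
#'   (`i < j`), with attributes `c_cut`, `sep_cut`, `masked` (whether a
#'   mask was applied).
#' @export
filter_network <- function(cm, c_cut = 0.4, sep_cut = 12, mask = NULL) {
  C <- if (is.list(cm)) cm$C else cm
  n <- nrow(C)
  keep <- matrix(FALSE, n, n)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  ok <- !is.na(C[iu]) & abs(C[iu]) > c_cut & (iu[, 2] - iu[, 1]) > sep_cut
  if (!is.null(mask)) ok <- ok & !mask[iu]
  sel <- iu[ok, , drop = FALSE]
  net <- data.frame(i = sel[, 1], j = sel[, 2], c = C[sel])
  net <- net[order(net$i, net$j), , drop = FALSE]
  rownames(net) <- NULL
  structure(net, c_cut = c_cut, sep_cut = sep_cut,
            masked = !is.null(mask), n_residues = n,
            class = c("correlation_network", "data.frame"))
}

edge_keys <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

#' Cross-system difference of correlation networks
#'
#' Maps the edges of network `a` onto system B numbering through a residue
#' correspondence and reports the shared edges, the edges private to either
#' system, and the edges touching gapped (unmappable) residues, which are
#' listed separately rather than silently dropped.
#'
#' @param a,b [filter_network()] results for systems A and B.
#' @param corr a [residue_correspondence()] from A to B.
#' @return list of data frames `shared`, `only_a`, `only_b`,
#'   `unmappable_a`, `unmappable_b` (edges in the owning system's own
#'   numbering; `shared` carries both systems' correlation values).
#' @export
network_diff <- function(a, b, corr) {
  ab <- map_pairs(a[, c("i", "j")], corr)
  covered_a <- a$i %in% corr$index_a & a$j %in% corr$index_a
  if (!all(covered_a))
    stop("network A contains residues absent from the correspondence")
  unmap_a <- is.na(ab$b_i) | is.na(ab$b_j)
  b_known <- b$i %in% corr$index_b & b$j %in% corr$index_b
  if (!all(b_known))
    stop("network B contains residues absent from the correspondence")
  # B edges whose residues are gapped on the A side
  b2a <- corr$index_a[match(b$i, corr$index_b)]
  b2a_j <- corr$index_a[match(b$j, corr$index_b)]
  unmap_b <- is.na(b2a) | is.na(b2a_j)

  keys_a_in_b <- edge_keys(ab$b_i[!unmap_a], ab$b_j[!unmap_a])
  keys_b <- edge_keys(b$i[!unmap_b], b$j[!unmap_b])
  a_map <- a[!unmap_a, , drop = FALSE]
  b_map <- b[!unmap_b, , drop = FALSE]
  sh <- keys_a_in_b %in% keys_b
  shared <- cbind(a_map[sh, c("i", "j", "c")],
                  b_i = ab$b_i[!unmap_a][sh], b_j = ab$b_j[!unmap_a][sh],
                  c_b = b_map$c[match(keys_a_in_b[sh], keys_b)])
  names(shared)[1:3] <- c("a_i", "a_j", "c_a")
  rownames(shared) <- NULL
  out <- list(shared = shared,
              only_a = a_map[!sh, , drop = FALSE],
              only_b = b_map[!(keys_b %in% keys_a_in_b), , drop = FALSE],
              unmappable_a = a[unmap_a, , drop = FALSE],
              unmappable_b = b[unmap_b, , drop = FALSE])
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
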