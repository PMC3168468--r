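#' Load a residue hydrophobicity scale
#'
#' Reads a two-column TSV (`residue_name`, `h_kcal_per_mol`) mapping the 20
#' standard residues to hydrophobicity indices from thermodynamic transfer
#' experiments.  The packaged default is the Jones (1975) transfer
#' free-energy scale; any scale with the same layout can be supplied, and
#' every report records the scale's provenance label, since absolute Hp
#' values depend on the scale while comparative statements do not.
#'
#' @param path TSV path; `NULL` loads the packaged default scale.
#' @param provenance label recorded with results; default the file name.
#' @return named numeric vector (kcal/mol) with attribute `provenance`.
#' @export
load_hydrophobicity_scale <- function(path = NULL, provenance = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hydrophobicity_jones1975.tsv",
                        package = "ensembledyn", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  h <- tab[[2]]
  names(h) <- toupper(tab[[1]])
  if (!all(is.finite(h))) stop("non-finite hydrophobicity index in scale")
  attr(h, "provenance") <- if (is.null(provenance)) basename(path) else provenance
  h
}

#' Per-residue surrounding hydrophobicity over an ensemble
#'
#' For each residue i and frame, Hp(i) is the sum of the hydrophobicity
#' indices h_j of all residues j whose C-alpha lies within `r_d` of residue
#' i's C-alpha (Heaviside step on `r_d - r_ij`, with the boundary
#' `r_ij = r_d` counting as inside since H(0) = 1).  The residue's own index
#' is excluded by default ("surrounding" residues).  The reported profile is
#' the mean over frames; per-frame values are retained.
#'
#' @param ens an [ensemble()].
#' @param scale named numeric scale from [load_hydrophobicity_scale()].
#' @param r_d C-alpha distance cutoff in nm (default 0.8).
#' @param exclude_self logical; drop j = i from the sum (default `TRUE`).
#' @param on `"frames"` averages Hp over frames (default); `"mean"` computes
#'   Hp once on the mean structure.
#' @return class `"hp_profile"`: data frame `residue_index`, `residue_name`,
#'   `hp` (kcal/mol) with attributes `per_frame` (residues x frames matrix,
#'   `on = "frames"` only), `r_d`, `scale_provenance`.
#' @export
compute_hp <- function(ens, scale = load_hydrophobicity_scale(), r_d = 0.8,
                       exclude_self = TRUE, on = c("frames", "mean")) {
  on <- match.arg(on)
  stopifnot(r_d > 0)
  res_names <- toupper(ens$atoms$residue_name[ens$calpha])
  unknown <- setdiff(unique(res_names), names(scale))
  if (length(unknown))
    stop("residue name(s) missing from the hydrophobicity scale: ",
         paste(unknown, collapse = ", "))
  h <- unname(scale[res_names])
  ca <- calpha_coords(ens)
  one_frame <- function(xyz) {
    if (length(h) == 1L) return(if (exclude_self) 0 else h)
    A <- as.matrix(stats::dist(xyz)) <= r_d
    if (!exclude_self) diag(A) <- TRUE else diag(A) <- FALSE
    as.vector(A %*% h)
  }
  if (on == "mean") {
    hp <- one_frame(apply(ca, c(1, 2), mean))
    per_frame <- NULL
  } else {
    per_frame <- matrix(vapply(seq_len(n_frames(ens)),
                               function(f) one_frame(ca[, , f]),
                               numeric(ens$n_residues)),
                        nrow = ens$n_residues)
    hp <- rowMeans(per_frame)
  }
  structure(data.frame(residue_index = ens$residue_index,
                       residue_name = res_names, hp = hp),
            per_frame = per_frame, r_d = r_d, on = on,
            scale_provenance = attr(scale, "provenance"),
            class = c("hp_profile", "data.frame"))
}

#' Histogram of a surrounding-hydrophobicity profile
#'
#' Tallies the percentage of residues falling in each Hp range.  Bins are
#' half-open `[low, high)`; values below the first edge fall in an initial
#' open bin and values at or above the last edge in a final open bin.
#'
#' @param profile an `hp_profile` from [compute_hp()] (or numeric vector).
#' @param bin_edges strictly increasing numeric edges (kcal/mol).
#' @return data frame `bin` (label), `low`, `high`, `count`, `percent`
#'   (sums to 100).
#' @export
hp_histogram <- function(profile, bin_edges) {
  x <- if (is.data.frame(profile)) profile$hp else as.numeric(profile)
  if (!length(x)) stop("empty profile")
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE))
    stop("'bin_edges' must be strictly increasing")
  idx <- findInterval(x, bin_edges)  # 0 = below first edge
  k <- length(bin_edges)
  counts <- tabulate(idx + 1L, nbins = k + 1L)
  low <- c(-Inf, bin_edges)
  high <- c(bin_edges, Inf)
  data.frame(bin = paste0("[", low, ",", high, ")"),
             low = low, high = high, count = counts,
             percent = 100 * counts / length(x))
}
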