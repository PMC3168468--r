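#' Charged-group table for salt-bridge detection
#'
#' Default side-chain charged groups: Asp (OD1/OD2, -), Glu (OE1/OE2, -),
#' Lys (NZ, +), Arg (NE/NH1/NH2, +).  Histidine is excluded by default
#' (protonation-dependent); chain termini can be added via the flags.
#' Every report records the table used.
#'
#' @param include_his add His ND1/NE2 as a positive group.
#' @param n_terminus,c_terminus add the backbone N of the first residue
#'   (+) / OXT of the last residue (-) as charged groups.
#' @return data frame `residue`, `atom`, `sign` (class
#'   `"charged_group_table"`).
#' @export
charged_group_table <- function(include_his = FALSE, n_terminus = FALSE,
                                c_terminus = FALSE) {
  tab <- data.frame(
    residue = c("ASP", "ASP", "GLU", "GLU", "LYS", "ARG", "ARG", "ARG"),
    atom = c("OD1", "OD2", "OE1", "OE2", "NZ", "NE", "NH1", "NH2"),
    sign = c(-1, -1, -1, -1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  if (include_his)
    tab <- rbind(tab, data.frame(residue = c("HIS", "HIS"),
                                 atom = c("ND1", "NE2"), sign = c(1, 1)))
  attr(tab, "termini") <- c(n = n_terminus, c = c_terminus)
  class(tab) <- c("charged_group_table", "data.frame")
  tab
}

#' Detect salt bridges and their persistence over an ensemble
#'
#' A residue pair with oppositely signed charged groups is in contact in a
#' frame iff the minimum distance between any two oppositely signed atoms
#' of the two groups is below `dist_cut`.  Persistence is the fraction of
#' frames in contact over the (macro-)trajectory.  All observed pairs are
#' returned unfiltered, with their full persistence spectrum; apply
#' [filter_salt_bridges()] with the active persistence cutoff afterwards.
#'
#' @param ens an [ensemble()].
#' @param table a [charged_group_table()].
#' @param dist_cut distance cutoff in nm (default 0.4; the sensitivity
#'   values 0.45 and 0.5 are also meaningful choices).
#' @return class `"saltbridge_set"`: list with `pairs` (data frame `res_a`
#'   (negative), `res_b` (positive), residue names, `persistence`),
#'   `contact` (pairs x frames logical), `min_dist` (pairs x frames, nm),
#'   `dist_cut`, `n_frames`, `table`.
#' @export
detect_salt_bridges <- function(ens, table = charged_group_table(),
                                dist_cut = 0.4) {
  resn <- toupper(ens$atoms$residue_name)
  grp <- merge(data.frame(idx = seq_len(nrow(ens$atoms)),
                          residue = resn, atom = ens$atoms$atom_name,
                          res_idx = ens$atoms$residue_index),
               table, by = c("residue", "atom"))
  ter <- attr(table, "termini")
  if (isTRUE(ter["n"])) {
    first <- min(ens$atoms$residue_index)
    i <- which(ens$atoms$residue_index == first & ens$atoms$atom_name == "N")
    if (length(i)) grp <- rbind(grp, data.frame(residue = resn[i], atom = "N",
                                                idx = i, res_idx = first, sign = 1))
  }
  if (isTRUE(ter["c"])) {
    last <- max(ens$atoms$residue_index)
    i <- which(ens$atoms$residue_index == last & ens$atoms$atom_name == "OXT")
    if (length(i)) grp <- rbind(grp, data.frame(residue = resn[i], atom = "OXT",
                                                idx = i, res_idx = last, sign = -1))
  }
  if (!nrow(grp)) stop("no charged groups found in this system")
  # one group = all charged atoms of one sign in one residue
  grp$gid <- paste(grp$res_idx, grp$sign)
  groups <- split(grp, grp$gid)
  ginfo <- do.call(rbind, lapply(groups, function(g)
    data.frame(res_idx = g$res_idx[1], sign = g$sign[1],
               residue = g$residue[1])))
  neg <- which(ginfo$sign < 0); pos <- which(ginfo$sign > 0)
  if (!length(neg) || !length(pos))
    stop("need both positive and negative charged groups")
  nf <- n_frames(ens)
  combos <- expand.grid(a = neg, b = pos)
  # drop same-residue pairings (e.g. termini on a charged residue)
  combos <- combos[ginfo$res_idx[combos$a] != ginfo$res_idx[combos$b], , drop = FALSE]
  np <- nrow(combos)
  min_dist <- matrix(NA_real_, np, nf)
  for (p in seq_len(np)) {
    ia <- groups[[combos$a[p]]]$idx
    ib <- groups[[combos$b[p]]]$idx
    for (f in seq_len(nf)) {
      A <- matrix(ens$coords[ia, , f], ncol = 3)
      B <- matrix(ens$coords[ib, , f], ncol = 3)
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      min_dist[p, f] <- sqrt(max(min(d2), 0))
    }
  }
  contact <- min_dist < dist_cut
  pairs <- data.frame(res_a = ginfo$res_idx[combos$a],
                      res_b = ginfo$res_idx[combos$b],
                      name_a = ginfo$residue[combos$a],
                      name_b = ginfo$residue[combos$b],
                      persistence = rowMeans(contact))
  ord <- order(pairs$res_a, pairs$res_b)
  structure(list(pairs = pairs[ord, , drop = FALSE],
                 contact = contact[ord, , drop = FALSE],
                 min_dist = min_dist[ord, , drop = FALSE],
                 dist_cut = dist_cut, n_frames = nf, table = table),
            class = "saltbridge_set")
}

#' @export
print.saltbridge_set <- function(x, ...) {
  cat(sprintf("Salt bridges: %d charged pairs over %d frames (%.2g nm cutoff); %d with persistence >= 0.24\n",
              nrow(x$pairs), x$n_frames, x$dist_cut,
              sum(x$pairs$persistence >= 0.24)))
  invisible(x)
}

#' Filter salt bridges at a persistence cutoff
#'
#' @param sb a [detect_salt_bridges()] result.
#' @param persistence_cutoff minimum persistence fraction (default 0.24,
#'   i.e. present in at least 24% of the frames; 0.20 is a common
#'   sensitivity value).
#' @return data frame of retained pairs (`res_a`, `res_b`, names,
#'   `persistence`), with attribute `persistence_cutoff`.
#' @export
filter_salt_bridges <- function(sb, persistence_cutoff = 0.24) {
  keep <- sb$pairs$persistence >= persistence_cutoff
  out <- sb$pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "persistence_cutoff") <- persistence_cutoff
  out
}

# 1-D k-nearest-neighbour classification with deterministic tie handling:
# ties at k = 4 are broken toward the noise class (conservative: fewer
# bridges admitted).
knn1d_classify <- function(train_x, train_lab, x, k = 4) {
  vapply(x, function(xi) {
    d <- abs(train_x - xi)
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(factor(train_lab[nn], levels = c("noise", "signal")))
    if (votes["signal"] > votes["noise"]) "signal" else "noise"
  }, "")
}

# threshold on a 1-D feature minimising disagreement with given labels;
# returns the midpoint of the optimal threshold interval
best_threshold <- function(x, lab, lower, upper) {
  ord <- order(x)
  x <- x[ord]; lab <- lab[ord]
  cand <- sort(unique(c(lower, upper, x)))
  mids <- (cand[-length(cand)] + cand[-1]) / 2
  err <- vapply(mids, function(t)
    sum(x < t & lab == "signal") + sum(x >= t & lab == "noise"), 0)
  best <- which(err == min(err))
  mean(range(mids[best]))
}

#' Select the salt-bridge persistence cutoff by supervised classification
#'
#' Implements the classifier-based cutoff-selection procedure: interactions
#' with persistence below `noise_below` form the "noise" class and those
#' above `signal_above` the "signal" class; a maximum-margin linear SVM and
#' a k-nearest-neighbour classifier (k = 4) are trained on these two
#' classes (1-D persistence feature) and used to classify the mid-range
#' interactions.  Each classifier induces a boundary persistence; the
#' selected cutoff is their common boundary, or the midpoint when they
#' disagree, with the disagreement width reported.
#'
#' @param persistences numeric persistence fractions, or a
#'   [detect_salt_bridges()] result.
#' @param noise_below,signal_above class-defining bounds (defaults 0.10 and
#'   0.30).
#' @param k neighbours for the k-NN classifier (default 4; ties break
#'   toward noise).
#' @return class `"persistence_cutoff"`: list with `cutoff`,
#'   `svm_boundary`, `knn_boundary`, `disagreement` (width), `mid_labels`
#'   (data frame of mid-range persistences with both classifiers' labels
#'   and their agreement), `n_noise`, `n_signal`.
#' @export
select_persistence_cutoff <- function(persistences, noise_below = 0.10,
                                      signal_above = 0.30, k = 4) {
  p <- if (inherits(persistences, "saltbridge_set"))
    persistences$pairs$persistence else as.numeric(persistences)
  lab <- ifelse(p < noise_below, "noise",
                ifelse(p > signal_above, "signal", "mid"))
  n_noise <- sum(lab == "noise"); n_signal <- sum(lab == "signal")
  if (n_noise == 0L || n_signal == 0L)
    stop("training class '", if (n_noise == 0L) "noise" else "signal",
         "' is empty; classifier-based selection needs both classes - ",
         "use a fixed persistence cutoff (default 0.24) instead")
  tr_x <- p[lab != "mid"]
  tr_lab <- factor(lab[lab != "mid"], levels = c("noise", "signal"))

  fit <- e1071::svm(x = matrix(tr_x, ncol = 1), y = tr_lab,
                    kernel = "linear", scale = FALSE, cost = 1000)
  grid <- seq(noise_below, signal_above, length.out = 2001)
  svm_lab <- ifelse(stats::predict(fit, matrix(grid, ncol = 1)) == "signal",
                    "signal", "noise")
  svm_boundary <- best_threshold(grid, svm_lab, noise_below, signal_above)

  knn_lab <- knn1d_classify(tr_x, as.character(tr_lab), grid, k = k)
  knn_boundary <- best_threshold(grid, knn_lab, noise_below, signal_above)

  cutoff <- (svm_boundary + knn_boundary) / 2
  mid <- p[lab == "mid"]
  mid_labels <- data.frame(
    persistence = mid,
    svm = if (length(mid)) as.character(stats::predict(fit, matrix(mid, ncol = 1))) else character(),
    knn = knn1d_classify(tr_x, as.character(tr_lab), mid, k = k))
  mid_labels$agree <- mid_labels$svm == mid_labels$knn
  structure(list(cutoff = cutoff, svm_boundary = svm_boundary,
                 knn_boundary = knn_boundary,
                 disagreement = abs(svm_boundary - knn_boundary),
                 mid_labels = mid_labels,
                 n_noise = n_noise, n_signal = n_signal,
                 noise_below = noise_below, signal_above = signal_above),
            class = "persistence_cutoff")
}

#' @export
print.persistence_cutoff <- function(x, ...) {
  cat(sprintf("Persistence cutoff %.3f (SVM %.3f, 4-NN %.3f, disagreement %.3f)\n",
              x$cutoff, x$svm_boundary, x$knn_boundary, x$disagreement))
  cat(sprintf("  trained on %d noise (< %.2f) and %d signal (> %.2f) interactions\n",
              x$n_noise, x$noise_below, x$n_signal, x$signal_above))
  invisible(x)
}

#' Spatial-proximity clusters of salt-bridging residues
#'
#' Residues involved in (filtered) salt bridges become nodes of an
#' undirected graph; two nodes are connected if they bridge each other or
#' if they are less than `seq_dist` residues apart in the sequence
#' (`|i - j| <= seq_dist - 1`; with the default 5 this means separations
#' up to 4).  Clusters are the connected components, ordered by their
#' smallest member residue.
#'
#' @param bridges data frame with `res_a`, `res_b` (e.g. from
#'   [filter_salt_bridges()]).
#' @param seq_dist sequence-distance threshold in residues (strict `<`,
#'   default 5).
#' @return class `"proximity_clusters"`: data frame `cluster`, `residue`,
#'   with attribute `edges` (the full arc list).
#' @export
build_proximity_clusters <- function(bridges, seq_dist = 5) {
  if (!nrow(bridges)) {
    out <- data.frame(cluster = integer(), residue = integer())
    attr(out, "edges") <- data.frame(from = integer(), to = integer(),
                                     type = character())
    class(out) <- c("proximity_clusters", "data.frame")
    return(out)
  }
  nodes <- sort(unique(c(bridges$res_a, bridges$res_b)))
  e_bridge <- data.frame(from = pmin(bridges$res_a, bridges$res_b),
                         to = pmax(bridges$res_a, bridges$res_b),
                         type = "bridge")
  close_pairs <- which(outer(nodes, nodes, function(a, b)
    a < b & abs(a - b) < seq_dist), arr.ind = TRUE)
  e_seq <- data.frame(from = nodes[close_pairs[, 1]],
                      to = nodes[close_pairs[, 2]],
                      type = rep("sequence", nrow(close_pairs)))
  edges <- unique(rbind(e_bridge, e_seq))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE, vertices = as.character(nodes))
  comp <- igraph::components(g)
  member <- data.frame(residue = nodes, comp = comp$membership[as.character(nodes)])
  # deterministic cluster ids: order components by smallest member residue
  first <- tapply(member$residue, member$comp, min)
  relabel <- match(member$comp, names(sort(first)))
  out <- data.frame(cluster = relabel, residue = member$residue)
  out <- out[order(out$cluster, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "edges") <- edges
  attr(out, "seq_dist") <- seq_dist
  class(out) <- c("proximity_clusters", "data.frame")
  out
}

#' Classify cross-system conservation of salt bridges
#'
#' Labels each salt bridge by its conservation pattern across a cold-adapted
#' reference, a warm-adapted reference and a set of mutants of the cold
#' system, after mapping all bridges into the cold reference numbering:
#' group `"I"` = present in every system; `"IV"` = present in the warm
#' reference and at least one mutant but absent from the cold wild-type
#' (mesophilic-like bridges acquired by mutants); `"II/III"` = present in
#' exactly one of the two wild-types with no corresponding residues in the
#' other (gap-mediated); everything else `"unclassified"`.
#'
#' @param per_system named list of bridge data frames (`res_a`, `res_b`) in
#'   each system's own numbering.
#' @param corr_maps named list of [residue_correspondence()] objects from
#'   the cold reference to each non-cold system (A side = cold).  Mutants
#'   sharing the cold numbering may be omitted (identity assumed).
#' @param cold,warm names of the two wild-type reference systems in
#'   `per_system`.
#' @return data frame `res_a`, `res_b` (cold numbering; `NA` for bridges
#'   unmappable to the cold system), `system` (owner for unmappable
#'   bridges), `group`, plus one presence column per system.
#' @export
classify_conservation <- function(per_system, corr_maps = list(), cold, warm) {
  systems <- names(per_system)
  if (!(cold %in% systems && warm %in% systems))
    stop("missing correspondence or bridge table for the reference systems")
  mutants <- setdiff(systems, c(cold, warm))
  to_cold <- function(sys, pairs) {
    if (sys == cold || is.null(corr_maps[[sys]]))
      return(data.frame(res_a = pmin(pairs$res_a, pairs$res_b),
                        res_b = pmax(pairs$res_a, pairs$res_b),
                        mapped = rep(TRUE, nrow(pairs))))
    cm <- corr_maps[[sys]]
    lut <- function(i) cm$index_a[match(i, cm$index_b)]
    a <- lut(pairs$res_a); b <- lut(pairs$res_b)
    data.frame(res_a = pmin(a, b), res_b = pmax(a, b),
               mapped = !(is.na(a) | is.na(b)))
  }
  mapped <- lapply(systems, function(s) to_cold(s, per_system[[s]]))
  names(mapped) <- systems
  all_keys <- unique(unlist(lapply(systems, function(s) {
    m <- mapped[[s]]
    ifelse(m$mapped, paste(m$res_a, m$res_b), paste("unmappable", s, seq_len(nrow(m))))
  })))
  presence <- sapply(systems, function(s) {
    m <- mapped[[s]]
    keys <- ifelse(m$mapped, paste(m$res_a, m$res_b),
                   paste("unmappable", s, seq_len(nrow(m))))
    all_keys %in% keys
  })
  presence <- matrix(presence, nrow = length(all_keys),
                     dimnames = list(all_keys, systems))
  gapped_in <- function(sys, res) {
    # TRUE when a cold residue has no counterpart in `sys`
    if (is.null(corr_maps[[sys]])) return(rep(FALSE, length(res)))
    cm <- corr_maps[[sys]]
    is.na(cm$index_b[match(res, cm$index_a)])
  }
  rows <- lapply(seq_along(all_keys), function(r) {
    key <- all_keys[r]
    pres <- presence[r, ]
    unmappable <- startsWith(key, "unmappable")
    res <- if (unmappable) c(NA_integer_, NA_integer_)
           else as.integer(strsplit(key, " ")[[1]])
    owner <- if (unmappable) strsplit(key, " ")[[1]][2] else NA_character_
    group <- "unclassified"
    if (!unmappable && all(pres)) group <- "I"
    else if (!unmappable && pres[warm] && !pres[cold] && any(pres[mutants]))
      group <- "IV"
    else if (unmappable && owner == warm && sum(pres) == 1L)
      group <- "II/III"  # warm-only bridge on residues absent from cold
    else if (!unmappable && pres[cold] && !pres[warm] &&
             any(gapped_in(warm, res)))
      group <- "II/III"  # cold-only bridge on residues absent from warm
    data.frame(res_a = res[1], res_b = res[2], system = owner, group = group,
               t(pres))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of acquired mesophilic-like bridges with phenotype
#'
#' Correlates a per-mutant feature (typically the count of group-IV,
#' mesophilic-like salt bridges acquired) with experimentally determined
#' phenotypes such as Tm and kcat/Km.
#'
#' @param feature named numeric vector, one value per mutant.
#' @param phenotypes data frame of phenotype columns with mutant row names
#'   (or a `mutant` column).
#' @return data frame `phenotype`, `r` (Pearson), `n`.  A zero-variance
#'   feature yields `NA` with a warning.
#' @export
phenotype_correlation <- function(feature, phenotypes) {
  if ("mutant" %in% names(phenotypes)) {
    rownames(phenotypes) <- phenotypes$mutant
    phenotypes$mutant <- NULL
  }
  common <- intersect(names(feature), rownames(phenotypes))
  if (length(common) < 3L)
    stop("need at least 3 mutants with both feature and phenotype")
  f <- feature[common]
  res <- lapply(names(phenotypes), function(ph) {
    y <- phenotypes[common, ph]
    ok <- is.finite(f) & is.finite(y)
    if (stats::sd(f[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero variance in feature or phenotype '", ph, "'; r undefined")
      r <- NA_real_
    } else r <- stats::cor(f[ok], y[ok])
    data.frame(phenotype = ph, r = r, n = sum(ok))
  })
  do.call(rbind, res)
}
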