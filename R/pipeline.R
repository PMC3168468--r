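#' Persistence degree of secondary structure profile (PDSSP)
#'
#' Consumes an externally computed per-frame, per-residue secondary-
#' structure label table (DSSP-style) and returns, for each residue, the
#' most frequently attained label and the fraction of frames in which it is
#' attained.  Ties are broken by a fixed label-priority order and flagged.
#'
#' @param labels character matrix (frames x residues) or data frame / list
#'   of equal-length per-frame label vectors.
#' @param priority label order used to break ties (first wins); labels not
#'   listed rank after listed ones, alphabetically.
#' @return data frame `residue_index`, `label` (modal), `persistence`
#'   (fraction in `[0, 1]`), `tie` (logical).
#' @export
pdssp <- function(labels, priority = c("H", "G", "I", "E", "B", "T", "S", "C", "-")) {
  if (is.data.frame(labels)) labels <- as.matrix(labels)
  if (is.list(labels)) {
    if (length(unique(lengths(labels))) != 1L)
      stop("ragged label table: all frames must label the same residues")
    labels <- do.call(rbind, labels)
  }
  if (!is.matrix(labels)) stop("'labels' must be a matrix of per-frame labels")
  nf <- nrow(labels)
  res <- lapply(seq_len(ncol(labels)), function(i) {
    tab <- table(labels[, i])
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1L
    if (tie) {
      rank <- match(top, priority)
      rank[is.na(rank)] <- length(priority) + rank(top[is.na(rank)])
      top <- top[order(rank)][1]
    }
    data.frame(residue_index = i, label = top,
               persistence = as.numeric(tab[top]) / nf, tie = tie)
  })
  out <- do.call(rbind, res)
  if (any(out$tie))
    message("tied modal label at residue(s) ",
            paste(out$residue_index[out$tie], collapse = ", "),
            "; priority order applied")
  out
}

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the standard defaults: Hp
#' cutoff 0.8 nm, H-bond criteria 0.35 nm / 30 deg, correlation windows of
#' 1 ns filtered at |C| > 0.4 and |i-j| > 12, salt bridges at 0.4 nm / 24%
#' persistence, profile smoothing window 5, ellipsoid probability 0.1.
#'
#' @param systems named list; each element an [ensemble()] or a path to a
#'   multi-model PDB file.
#' @param reference name of the reference system for cross-system
#'   comparisons (default the first).
#' @param correspondences named list of [residue_correspondence()] from the
#'   reference to each other system; omitted entries default to the
#'   identity when lengths match.
#' @param outdir output directory for TSV reports (`NULL` = no files).
#' @param seed integer seed recorded in report headers and used by any
#'   stochastic stage.
#' @param hp_r_d,hbond_distance,hbond_angle,corr_window_ps,corr_c_cut,corr_sep_cut,sb_dist_cut,sb_persistence,smooth_window,ellipsoid_prob
#'   stage parameters (see module functions).
#' @param select_cutoff if `TRUE`, derive the salt-bridge persistence
#'   cutoff with [select_persistence_cutoff()] instead of `sb_persistence`.
#' @param stages character subset of
#'   `c("hp", "hbonds", "ed", "corr", "saltbridges")` to run.
#' @return class `"analysis_config"` list.
#' @export
analysis_config <- function(systems, reference = names(systems)[1],
                            correspondences = list(), outdir = NULL,
                            seed = 1L,
                            hp_r_d = 0.8, hbond_distance = 0.35,
                            hbond_angle = 30, corr_window_ps = 1000,
                            corr_c_cut = 0.4, corr_sep_cut = 12,
                            sb_dist_cut = 0.4, sb_persistence = 0.24,
                            smooth_window = 5, ellipsoid_prob = 0.1,
                            select_cutoff = FALSE,
                            stages = c("hp", "ed", "corr", "saltbridges")) {
  if (is.null(names(systems)) || any(names(systems) == ""))
    stop("'systems' must be a named list")
  num <- c(hp_r_d = hp_r_d, hbond_distance = hbond_distance,
           hbond_angle = hbond_angle, corr_window_ps = corr_window_ps,
           corr_c_cut = corr_c_cut, corr_sep_cut = corr_sep_cut,
           sb_dist_cut = sb_dist_cut, sb_persistence = sb_persistence,
           smooth_window = smooth_window, ellipsoid_prob = ellipsoid_prob)
  if (any(num <= 0)) stop("all cutoffs must be positive")
  structure(c(list(systems = systems, reference = reference,
                   correspondences = correspondences, outdir = outdir,
                   seed = as.integer(seed), select_cutoff = select_cutoff,
                   stages = stages), as.list(num)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Scalar parameters are taken from the file; `systems` entries must be
#' file paths.  Requires the `yaml` package.
#'
#' @param path YAML file.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

tsv_header <- function(config, extra = character()) {
  pars <- vapply(c("hp_r_d", "hbond_distance", "hbond_angle",
                   "corr_window_ps", "corr_c_cut", "corr_sep_cut",
                   "sb_dist_cut", "sb_persistence", "smooth_window",
                   "ellipsoid_prob"),
                 function(p) paste0(p, "=", format(config[[p]])), "")
  c(paste0("# ensembledyn ",
           as.character(utils::packageVersion("ensembledyn"))),
    paste0("# seed=", config$seed),
    paste0("# ", paste(pars, collapse = " ")),
    extra)
}

write_report_tsv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bridge_pair_diff <- function(a, b, corr) {
  lut <- function(i) corr$index_b[match(i, corr$index_a)]
  a_i <- lut(a$res_a); a_j <- lut(a$res_b)
  unmap_a <- is.na(a_i) | is.na(a_j)
  keys_a <- edge_keys(a_i[!unmap_a], a_j[!unmap_a])
  keys_b <- edge_keys(b$res_a, b$res_b)
  list(shared = a[!unmap_a, , drop = FALSE][keys_a %in% keys_b, , drop = FALSE],
       only_a = a[!unmap_a, , drop = FALSE][!(keys_a %in% keys_b), , drop = FALSE],
       only_b = b[!(keys_b %in% keys_a), , drop = FALSE],
       unmappable_a = a[unmap_a, , drop = FALSE])
}

#' Run the full comparative analysis pipeline
#'
#' Executes the per-system analyses selected in the configuration
#' (surrounding hydrophobicity, H-bonds, essential-dynamics flexibility,
#' cross-correlation networks, salt-bridge networks and clusters), then the
#' cross-system comparisons against the reference system (correlation-
#' network differences and salt-bridge gains/losses through the residue
#' correspondences).  All tabular outputs are written as TSV with a
#' commented parameter header when `outdir` is set; reruns on the same
#' inputs are byte-identical.
#'
#' @param config an [analysis_config()].
#' @return class `"comparison_report"`: list with `per_system` (each:
#'   `hp`, `rmsf`, `eigenvalues`, `network`, `bridges`, `clusters`,
#'   `hbond_fraction`) and `comparisons` (per non-reference system:
#'   `network` and `bridges` diff sets), plus `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  labs <- sort(names(config$systems))
  scale <- load_hydrophobicity_scale()
  per_system <- list()
  for (lab in labs) {
    sys <- config$systems[[lab]]
    ens <- if (is.character(sys)) load_ensemble(sys, label = lab) else sys
    res <- list()
    if (!ens$superposed) ens <- superpose(ens)
    res$n_residues <- ens$n_residues
    if ("hp" %in% config$stages) {
      hp <- compute_hp(ens, scale, r_d = config$hp_r_d)
      hp$hp_smooth <- smooth_profile(hp$hp, config$smooth_window)
      res$hp <- hp
    }
    if ("hbonds" %in% config$stages) {
      hb <- detect_hbonds(ens, hbond_criteria(config$hbond_distance,
                                              config$hbond_angle))
      res$hbonds <- hb$pairs
      res$hbond_fraction <- normalized_hbond_fraction(hb)
    }
    if ("ed" %in% config$stages) {
      sub <- compute_subspace(ens)
      res$eigenvalues <- data.frame(mode = seq_along(sub$eigenvalues),
                                    eigenvalue = sub$eigenvalues,
                                    cum_variance = sub$variance_fraction)
      if (!sub$degenerate) {
        fp <- project_and_rmsf(ens, sub)
        fp$rmsf_smooth <- smooth_profile(fp$rmsf, config$smooth_window)
        res$rmsf <- fp
        res$subspace <- sub
      }
    }
    if ("corr" %in% config$stages) {
      cm <- windowed_correlation(ens, window_ps = config$corr_window_ps)
      res$network <- filter_network(cm, c_cut = config$corr_c_cut,
                                    sep_cut = config$corr_sep_cut)
    }
    if ("saltbridges" %in% config$stages) {
      sb <- detect_salt_bridges(ens, dist_cut = config$sb_dist_cut)
      cutoff <- config$sb_persistence
      if (isTRUE(config$select_cutoff)) {
        sel <- select_persistence_cutoff(sb)
        cutoff <- sel$cutoff
        res$cutoff_model <- sel
      }
      res$bridges <- filter_salt_bridges(sb, cutoff)
      res$all_persistences <- sb$pairs
      res$clusters <- build_proximity_clusters(res$bridges)
    }
    per_system[[lab]] <- res
  }
  ref <- config$reference
  comparisons <- list()
  for (lab in setdiff(labs, ref)) {
    corr <- config$correspondences[[lab]]
    if (is.null(corr)) {
      if (per_system[[ref]]$n_residues != per_system[[lab]]$n_residues)
        stop("no correspondence given for '", lab,
             "' and system sizes differ from the reference")
      corr <- identity_correspondence(per_system[[ref]]$n_residues,
                                      labels = c(ref, lab))
    }
    cmp <- list()
    if (!is.null(per_system[[ref]]$network))
      cmp$network <- network_diff(per_system[[ref]]$network,
                                  per_system[[lab]]$network, corr)
    if (!is.null(per_system[[ref]]$bridges))
      cmp$bridges <- bridge_pair_diff(per_system[[ref]]$bridges,
                                      per_system[[lab]]$bridges, corr)
    comparisons[[lab]] <- cmp
  }
  report <- structure(list(per_system = per_system, comparisons = comparisons,
                           config = config),
                      class = "comparison_report")
  if (!is.null(config$outdir)) write_report_files(report)
  report
}

write_report_files <- function(report) {
  config <- report$config
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- tsv_header(config)
  path <- function(...) file.path(config$outdir, paste0(...))
  for (lab in names(report$per_system)) {
    rs <- report$per_system[[lab]]
    h <- c(hdr, paste0("# system=", lab))
    if (!is.null(rs$hp))
      write_report_tsv(format_num(rs$hp), path(lab, "_hp.tsv"), h)
    if (!is.null(rs$rmsf))
      write_report_tsv(format_num(rs$rmsf), path(lab, "_rmsf.tsv"), h)
    if (!is.null(rs$eigenvalues))
      write_report_tsv(format_num(rs$eigenvalues), path(lab, "_eigenvalues.tsv"), h)
    if (!is.null(rs$network))
      write_report_tsv(format_num(as.data.frame(rs$network)),
                       path(lab, "_corr_edges.tsv"), h)
    if (!is.null(rs$all_persistences))
      write_report_tsv(format_num(rs$all_persistences),
                       path(lab, "_saltbridges.tsv"), h)
    if (!is.null(rs$clusters))
      write_report_tsv(as.data.frame(rs$clusters), path(lab, "_clusters.tsv"), h)
  }
  for (lab in names(report$comparisons)) {
    cmp <- report$comparisons[[lab]]
    h <- c(hdr, paste0("# comparison=", config$reference, "_vs_", lab))
    if (!is.null(cmp$network)) {
      tag <- function(set, nm) if (nrow(set)) cbind(set = nm, format_num(set))
      sh <- cmp$network$shared[, c("a_i", "a_j", "c_a")]
      names(sh) <- c("i", "j", "c")
      tab <- do.call(rbind, Filter(Negate(is.null), list(
        tag(cmp$network$only_a, "only_reference"),
        tag(cmp$network$only_b, "only_other"),
        tag(sh, "shared"))))
      if (is.null(tab)) tab <- data.frame(set = character())
      write_report_tsv(tab, path(lab, "_network_diff.tsv"), h)
    }
    if (!is.null(cmp$bridges)) {
      tag <- function(set, nm) if (nrow(set)) cbind(set = nm, format_num(set))
      tab <- do.call(rbind, Filter(Negate(is.null), list(
        tag(cmp$bridges$only_a, "only_reference"),
        tag(cmp$bridges$only_b, "only_other"),
        tag(cmp$bridges$shared, "shared"))))
      if (is.null(tab)) tab <- data.frame(set = character())
      write_report_tsv(tab, path(lab, "_bridge_diff.tsv"), h)
    }
  }
  invisible(config$outdir)
}

format_num <- function(df, digits = 6) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], digits)
  df
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparative ensemble analysis of",
      length(x$per_system), "system(s):",
      paste(names(x$per_system), collapse = ", "), "\n")
  for (lab in names(x$comparisons)) {
    cmp <- x$comparisons[[lab]]
    cat(sprintf("  %s vs %s:", x$config$reference, lab))
    if (!is.null(cmp$network))
      cat(sprintf(" correlation edges +%d/-%d;",
                  nrow(cmp$network$only_b), nrow(cmp$network$only_a)))
    if (!is.null(cmp$bridges))
      cat(sprintf(" salt bridges +%d/-%d",
                  nrow(cmp$bridges$only_b), nrow(cmp$bridges$only_a)))
    cat("\n")
  }
  invisible(x)
}

#' Two-system synthetic comparison fixture
#'
#' Builds a matched pair of synthetic systems for exercising the full
#' pipeline with known ground truth: both share a bead chain with one
#' planted long-range correlated pair and a common set of salt bridges;
#' optionally system B additionally gains one highly persistent salt
#' bridge (`gain_bridge`) and one extra long-range correlated pair
#' (`extra_corr`), so a comparison report should list exactly those
#' differences.
#'
#' @param n_core bead-chain length (default 40).
#' @param n_frames frames per system (default 1000).
#' @param seed integer seed.
#' @param gain_bridge,extra_corr plant the system-B-only differences.
#' @return list `a`, `b` ([ensemble()] objects), `truth` (list with the
#'   planted edge/bridge coordinates), `correspondence`.
#' @export
gen_two_system_fixture <- function(n_core = 40, n_frames = 1000, seed = 1,
                                   gain_bridge = TRUE, extra_corr = TRUE) {
  base_edge <- c(5L, 20L)
  extra_edge <- c(8L, 30L)
  shared_p <- c(0.90, 0.60, 0.05)
  gained_p <- 0.90
  make_system <- function(sd, with_extra, p_extra_bridge) {
    moves <- list(list(list(residue = base_edge[1], d = c(1, 0, 0)),
                       list(residue = base_edge[2], d = c(1, 0, 0))))
    ev <- 0.12
    if (with_extra) {
      moves <- c(moves, list(list(list(residue = extra_edge[1], d = c(0, 1, 0)),
                                  list(residue = extra_edge[2], d = c(0, 1, 0)))))
      ev <- c(ev, 0.12)
    }
    core <- gen_gaussian_ensemble(n_core, eigenvalues = ev,
                                  modes = make_modes(n_core, moves),
                                  noise = 0.01, n_frames = n_frames,
                                  seed = sd)
    p <- c(shared_p, p_extra_bridge)
    contacts <- gen_contact_series(length(p), n_frames = n_frames, p = p,
                                   seed = sd + 1L)
    # merge: bead chain then charged pseudo-residues, renumbered after it
    cens <- contacts$ensemble
    catoms <- cens$atoms
    catoms$residue_index <- catoms$residue_index + n_core
    ccoords <- cens$coords
    ccoords[, 1, ] <- ccoords[, 1, ] + 0.38 * n_core + 5  # keep clear of the chain
    # charged-residue CA jitter so no residue is variance-free
    jit <- with_seed(sd + 2L, array(stats::rnorm(length(ccoords), sd = 0.05),
                                    dim = dim(ccoords)))
    ca_rows <- which(catoms$atom_name == "CA")
    ccoords[ca_rows, , ] <- ccoords[ca_rows, , ] + jit[ca_rows, , ]
    atoms <- rbind(core$ensemble$atoms, catoms)
    coords <- array(0, dim = c(nrow(atoms), 3, n_frames))
    coords[seq_len(n_core), , ] <- core$ensemble$coords
    coords[-seq_len(n_core), , ] <- ccoords
    ensemble(coords, atoms, time_per_frame = 2,
             label = if (with_extra) "B" else "A", superposed = TRUE)
  }
  a <- make_system(seed, FALSE, 0.02)
  b <- make_system(seed + 100L, extra_corr, if (gain_bridge) gained_p else 0.02)
  n_total <- a$n_residues
  truth <- list(base_edge = base_edge,
                extra_edge = if (extra_corr) extra_edge,
                shared_bridges = cbind(n_core + c(1L, 3L, 5L) ,
                                       n_core + c(2L, 4L, 6L))[shared_p >= 0.24, ,
                                                               drop = FALSE],
                gained_bridge = if (gain_bridge) n_core + c(7L, 8L))
  list(a = a, b = b, truth = truth,
       correspondence = identity_correspondence(n_total, labels = c("A", "B")))
}
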