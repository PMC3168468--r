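test_that("detection respects opposite signs and recovers planted persistence", {
  cs <- gen_contact_series(2, n_frames = 2000, p = c(0.5, 0.9), seed = 60)
  sb <- detect_salt_bridges(cs$ensemble)
  # no same-sign pairs are ever reported
  expect_true(all(sb$pairs$name_a == "GLU" & sb$pairs$name_b == "LYS"))
  for (k in 1:2) {
    est <- sb$pairs$persistence[sb$pairs$res_a == 2 * k - 1 &
                                  sb$pairs$res_b == 2 * k]
    p <- cs$truth$p_true[k]
    expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / 2000))
  }
  # two same-sign residues close together: never a bridge
  atoms <- data.frame(residue_index = c(1, 1, 2, 2),
                      residue_name = c("GLU", "GLU", "ASP", "ASP"),
                      atom_name = c("CA", "OE1", "CA", "OD1"),
                      element = c("C", "O", "C", "O"))
  frame <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(1, 0, 0), c(0.4, 0, 0))
  expect_error(detect_salt_bridges(make_ens(list(frame), atoms)),
               "positive and negative")
})

test_that("bridge counts are monotone in distance and persistence cutoffs", {
  # pairs at fixed charged-atom distances straddling the sensitivity cutoffs
  dists <- c(0.35, 0.42, 0.48, 0.55)
  atoms <- do.call(rbind, lapply(seq_along(dists), function(k)
    data.frame(residue_index = c(2 * k - 1, 2 * k - 1, 2 * k, 2 * k),
               residue_name = c("GLU", "GLU", "LYS", "LYS"),
               atom_name = c("CA", "OE1", "CA", "NZ"),
               element = c("C", "O", "C", "N"))))
  frame <- do.call(rbind, lapply(seq_along(dists), function(k)
    rbind(c(10 * k, 0, 0), c(10 * k, 0.2, 0),
          c(10 * k, 2, 0), c(10 * k, 0.2 + dists[k], 0))))
  ens <- make_ens(list(frame, frame), atoms)
  n_kept <- function(dc, pc) {
    sb <- detect_salt_bridges(ens, dist_cut = dc)
    nrow(filter_salt_bridges(sb, pc))
  }
  expect_equal(n_kept(0.4, 0.24), 1)   # only the 0.35 nm pair
  expect_equal(n_kept(0.45, 0.24), 2)
  expect_equal(n_kept(0.5, 0.24), 3)
  expect_gte(n_kept(0.5, 0.20), n_kept(0.5, 0.24))
  expect_gte(n_kept(0.45, 0.24), n_kept(0.4, 0.24))
  # persistence cutoff monotonicity on mixed-persistence synthetic data
  cs <- gen_contact_series(20, n_frames = 400, seed = 61)
  sb <- detect_salt_bridges(cs$ensemble)
  expect_gte(nrow(filter_salt_bridges(sb, 0.20)),
             nrow(filter_salt_bridges(sb, 0.24)))
})

test_that("filtering keeps persistence >= cutoff, excluding just-below pairs", {
  cs <- gen_contact_series(2, n_frames = 100, p = c(0.23, 0.25), seed = 62)
  sb <- detect_salt_bridges(cs$ensemble)
  sb$pairs$persistence[sb$pairs$res_a == 1 & sb$pairs$res_b == 2] <- 0.23
  sb$pairs$persistence[sb$pairs$res_a == 3 & sb$pairs$res_b == 4] <- 0.25
  kept <- filter_salt_bridges(sb, 0.24)
  expect_equal(nrow(kept), 1)
  expect_equal(c(kept$res_a, kept$res_b), c(3, 4))
})

test_that("classifier cutoff lands in the gap and separates the classes", {
  for (s in 1:10) {
    mx <- rpersistence_mixture(150, seed = 100 + s)
    sel <- select_persistence_cutoff(mx$p)
    expect_gt(sel$cutoff, 0.10)
    expect_lt(sel$cutoff, 0.30)
    expect_true(all(mx$p[mx$class == "noise"] < sel$cutoff))
    expect_true(all(mx$p[mx$class == "signal"] > sel$cutoff))
    expect_true(all(mx$p[mx$class == "noise"] < sel$svm_boundary))
    expect_true(all(mx$p[mx$class == "signal"] > sel$svm_boundary))
    expect_true(all(mx$p[mx$class == "noise"] < sel$knn_boundary))
    expect_true(all(mx$p[mx$class == "signal"] > sel$knn_boundary))
  }
})

test_that("an empty training class aborts with the fixed-cutoff instruction", {
  expect_error(select_persistence_cutoff(c(0.4, 0.5, 0.6)), "0.24")
  expect_error(select_persistence_cutoff(c(0.01, 0.05)), "signal")
})

test_that("a lone mid-range point near heavy noise is labelled noise by 4-NN", {
  p <- c(0.05, 0.06, 0.07, 0.08, 0.6, 0.65, 0.7, 0.12)
  sel <- select_persistence_cutoff(p)
  expect_equal(nrow(sel$mid_labels), 1)
  expect_equal(sel$mid_labels$persistence, 0.12)
  expect_equal(sel$mid_labels$knn, "noise")  # 4 nearest are all noise
})

test_that("proximity clusters equal brute-force connected components", {
  # two bridges sharing a residue -> one cluster of 3
  b1 <- data.frame(res_a = c(10, 10), res_b = c(50, 90))
  cl1 <- build_proximity_clusters(b1)
  expect_equal(unique(cl1$cluster), 1L)
  expect_setequal(cl1$residue, c(10, 50, 90))
  # sequence arc: nearest members 4 apart merge (strict < 5), 5 apart do not
  b2 <- data.frame(res_a = c(10, 24), res_b = c(20, 60))
  expect_equal(max(build_proximity_clusters(b2)$cluster), 1L)
  b3 <- data.frame(res_a = c(10, 25), res_b = c(20, 60))
  expect_equal(max(build_proximity_clusters(b3)$cluster), 2L)
  # empty input
  expect_equal(nrow(build_proximity_clusters(data.frame(res_a = integer(),
                                                        res_b = integer()))), 0)
  # membership invariant to record order
  perm <- build_proximity_clusters(b2[2:1, ])
  expect_equal(perm, build_proximity_clusters(b2), ignore_attr = TRUE)
  # 100 random graphs vs an independent flood fill
  flood <- function(nodes, edges) {
    comp <- setNames(rep(0L, length(nodes)), nodes)
    cid <- 0L
    for (s in nodes) {
      if (comp[as.character(s)] > 0) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[as.character(v)] > 0) next
        comp[as.character(v)] <- cid
        nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
        queue <- c(queue, nb[comp[as.character(nb)] == 0])
      }
    }
    comp
  }
  set.seed(63)
  for (rep in 1:100) {
    nb <- sample(2:8, 1)
    br <- data.frame(res_a = sample(30, nb, replace = TRUE),
                     res_b = sample(30, nb, replace = TRUE))
    br <- br[br$res_a != br$res_b, , drop = FALSE]
    if (!nrow(br)) next
    got <- build_proximity_clusters(br, seq_dist = 5)
    nodes <- sort(unique(c(br$res_a, br$res_b)))
    seq_edges <- subset(expand.grid(from = nodes, to = nodes),
                        from < to & abs(from - to) < 5)
    edges <- rbind(data.frame(from = pmin(br$res_a, br$res_b),
                              to = pmax(br$res_a, br$res_b)),
                   seq_edges)
    want <- flood(nodes, edges)
    # same partition: equal label co-membership
    got_lab <- got$cluster[match(nodes, got$residue)]
    expect_equal(outer(got_lab, got_lab, "=="), outer(want, want, "=="),
                 ignore_attr = TRUE)
  }
})

test_that("conservation groups follow the presence rules exactly", {
  idc <- function(n = 100) identity_correspondence(n)
  bridge <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(res_a = m[, 1], res_b = m[, 2])
  }
  # group I: present everywhere
  per <- list(cold = bridge(10, 20), warm = bridge(10, 20),
              m1 = bridge(10, 20), m2 = bridge(10, 20))
  lab <- classify_conservation(per, list(warm = idc(), m1 = idc(), m2 = idc()),
                               cold = "cold", warm = "warm")
  expect_equal(lab$group, "I")
  # group IV: warm + one mutant, absent from cold
  per2 <- list(cold = bridge(1, 2), warm = bridge(1, 2, 30, 40),
               m1 = bridge(1, 2, 30, 40), m2 = bridge(1, 2))
  lab2 <- classify_conservation(per2, list(warm = idc(), m1 = idc(), m2 = idc()),
                                cold = "cold", warm = "warm")
  expect_equal(lab2$group[lab2$res_a == 30], "IV")
  expect_equal(lab2$group[lab2$res_a == 1], "I")
  # gap-mediated II/III: cold-only bridge on residues gapped in warm
  gap_corr <- residue_correspondence(1:100, c(1:49, NA, 50:98, NA))
  per3 <- list(cold = bridge(50, 60), warm = bridge(70, 80)[0, ],
               m1 = bridge(50, 60))
  lab3 <- classify_conservation(per3, list(warm = gap_corr, m1 = idc()),
                                cold = "cold", warm = "warm")
  expect_equal(lab3$group, "II/III")
  # warm-only bridge on residues absent from cold
  warm_corr <- residue_correspondence(c(1:99, NA), c(1:99, 100))
  per4 <- list(cold = bridge(1, 2), warm = bridge(1, 2, 99, 100), m1 = bridge(1, 2))
  lab4 <- classify_conservation(per4, list(warm = warm_corr, m1 = idc()),
                                cold = "cold", warm = "warm")
  expect_equal(sort(lab4$group), c("I", "II/III"))
  # randomized presence tables vs an independent rule evaluation
  set.seed(64)
  systems <- c("cold", "warm", "m1", "m2", "m3")
  for (rep in 1:20) {
    pool <- bridge(5, 15, 20, 35, 40, 55, 60, 75)
    pres <- matrix(runif(4 * 5) < 0.5, 4, 5, dimnames = list(NULL, systems))
    per5 <- lapply(systems, function(s) pool[pres[, s], , drop = FALSE])
    names(per5) <- systems
    lab5 <- classify_conservation(per5,
                                  setNames(lapply(systems[-1], function(s) idc()),
                                           systems[-1]),
                                  cold = "cold", warm = "warm")
    for (r in seq_len(nrow(pool))) {
      row <- lab5[lab5$res_a == pool$res_a[r] & lab5$res_b == pool$res_b[r], ]
      pr <- pres[r, ]
      want <- if (!any(pr)) NULL
      else if (all(pr)) "I"
      else if (pr["warm"] && !pr["cold"] && any(pr[c("m1", "m2", "m3")])) "IV"
      else "unclassified"
      if (is.null(want)) expect_equal(nrow(row), 0)
      else expect_equal(row$group, want)
    }
  }
})

test_that("phenotype correlation reproduces the textbook Pearson formula", {
  f <- c(a = 1, b = 2, c = 3, d = 4)
  ph <- data.frame(Tm = c(1, 2, 3, 4), kcat_km = c(4, 3, 2, 1),
                   row.names = c("a", "b", "c", "d"))
  r <- phenotype_correlation(f, ph)
  expect_equal(r$r, c(1, -1))
  expect_equal(r$n, c(4L, 4L))
  set.seed(65)
  f2 <- setNames(rnorm(7), letters[1:7])
  y <- rnorm(7)
  ph2 <- data.frame(y = y, row.names = letters[1:7])
  brute <- sum((f2 - mean(f2)) * (y - mean(y))) /
    sqrt(sum((f2 - mean(f2))^2) * sum((y - mean(y))^2))
  expect_equal(phenotype_correlation(f2, ph2)$r, brute, tolerance = 1e-12)
  expect_error(phenotype_correlation(f[1:2], ph[1:2, ]), "at least 3")
  expect_warning(phenotype_correlation(setNames(rep(1, 4), letters[1:4]),
                                       ph["Tm"]),
                 "zero variance")
})
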