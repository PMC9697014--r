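test_that("IBS distance matches hand enumeration and equals 1 - similarity", {
  ## per-marker shared alleles 2,1,1,2 of 8 -> distance 0.25
  a <- c("A/A", "A/G", "C/C", "T/T")
  b <- c("A/A", "A/A", "C/T", "T/T")
  expect_equal(ibs_distance(a, b), 0.25)
  expect_equal(ibs_distance(a, b), 1 - similarity_rate(a, b))
  expect_equal(ibs_distance(a, a), 0)
  expect_equal(ibs_distance(rep("A/A", 4), rep("G/G", 4)), 1)
})

test_that("distance matrix equals the brute-force double loop and is symmetric", {
  set.seed(51)
  panel <- simulate_panel(simulation_config(
    n_markers = 40, n_lines = c(G1 = 6), divergence_F = c(G1 = 0.1),
    n_replicates = 1, missing_rate = 0.1, seed = 52))
  gm <- panel$genotypes
  dm <- distance_matrix(gm)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dm[i, j], ibs_distance(gm$calls[i, ], gm$calls[j, ]))
  }
})

test_that("identical lines give a zero distance matrix", {
  g <- rep("A/G", 10)
  gm <- make_gm(rbind(g, g, g), lines = c("L1", "L2", "L3"))
  dm <- distance_matrix(gm)
  expect_true(all(dm == 0))
})

test_that("distance bins count a known panel exactly and always partition", {
  dm <- matrix(0, 4, 4, dimnames = list(paste0("L", 1:4), paste0("L", 1:4)))
  d <- c(0, 0.2, 0.4, 0.4, 0.6, 0.6)
  dm[upper.tri(dm)] <- d
  dm <- dm + t(dm)
  b <- bin_distances(dm)
  expect_equal(b$bins$n_pairs, c(1L, 0L, 1L, 2L, 2L))
  expect_equal(sum(b$bins$pct), 100)
  expect_equal(b$n_zero, 1L)
  expect_equal(b$n_below_guard, 1L)
  expect_equal(unname(b$pct_greater[3]), 100 * 4 / 6)
  expect_equal(b$mean_distance, mean(d))
  ## all-identical panel: everything in the zero bin
  z <- matrix(0, 3, 3)
  bz <- bin_distances(z)
  expect_equal(bz$bins$pct[1], 100)
  expect_equal(bz$n_zero, 3L)
})

test_that("subgroup distances equal brute-force recomputation", {
  set.seed(53)
  n <- 8
  dm <- matrix(runif(n * n, 0.1, 0.6), n, n)
  dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- paste0("L", 1:n)
  grp <- setNames(rep(c("X", "Y"), each = 4), rownames(dm))
  sg <- subgroup_distances(dm, grp)
  wx <- dm[1:4, 1:4][upper.tri(dm[1:4, 1:4])]
  btw <- as.vector(dm[1:4, 5:8])
  expect_equal(sg$mean_distance[sg$group_a == "X" & sg$group_b == "X"],
               mean(wx))
  expect_equal(sg$mean_distance[sg$type == "between"], mean(btw))
  expect_equal(sg$n_pairs[sg$type == "between"], 16L)
})

test_that("a single pair per group yields that pair's distance; small groups NA", {
  dm <- matrix(c(0, 0.3, 0.1, 0.3, 0, 0.2, 0.1, 0.2, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sg <- subgroup_distances(dm, setNames(c("G", "G", "H"), c("a", "b", "c")))
  expect_equal(sg$mean_distance[sg$group_a == "G" & sg$group_b == "G"], 0.3)
  expect_true(is.na(sg$mean_distance[sg$group_a == "H" & sg$group_b == "H"]))
})

test_that("two diverged subgroups are farther apart than within themselves", {
  cfg <- simulation_config(n_markers = 100,
                           n_lines = c(P = 20, Q = 20),
                           divergence_F = c(P = 0.3, Q = 0.3),
                           n_replicates = 1, residual_het = 0,
                           call_error_rate = 0, missing_rate = 0, seed = 54)
  panel <- simulate_panel(cfg)
  dm <- distance_matrix(panel$genotypes)
  grp <- setNames(panel$genotypes$samples$subgroup, rownames(dm))
  sg <- subgroup_distances(dm, grp)
  btw <- sg$mean_distance[sg$type == "between"]
  wit <- sg$mean_distance[sg$type == "within"]
  expect_true(btw > max(wit))
})

test_that("PCA: duplicates coincide, variance fractions are a spectrum", {
  set.seed(55)
  rc <- random_calls(30, miss_rate = 0)
  mats <- t(replicate(6, random_calls(30, alleles = rc$alleles,
                                      miss_rate = 0)$calls))
  mats <- rbind(mats, mats[3, ])   # duplicated line
  gm <- make_gm(mats)
  pc <- genotype_pca(gm, 4)
  expect_equal(unname(pc$scores[7, ]), unname(pc$scores[3, ]))
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  expect_true(all(diff(frac) <= 1e-12))
  expect_lte(sum(pc$explained), 1)
  expect_true(all(pc$explained >= 0))
})

test_that("PCA coordinates are marker-order invariant and PC1 splits diverged groups", {
  cfg <- simulation_config(n_markers = 80, n_lines = c(P = 15, Q = 15),
                           divergence_F = c(P = 0.3, Q = 0.3),
                           n_replicates = 1, residual_het = 0,
                           call_error_rate = 0, missing_rate = 0.02,
                           seed = 56)
  panel <- simulate_panel(cfg)
  gm <- panel$genotypes
  pc <- genotype_pca(gm, 2)
  perm <- sample(n_markers(gm))
  pc_perm <- genotype_pca(gm[, perm], 2)
  expect_equal(abs(unname(pc$scores[, 1])), abs(unname(pc_perm$scores[, 1])),
               tolerance = 1e-8)
  grp <- gm$samples$subgroup
  between_var <- diff(tapply(pc$scores[, 1], grp, mean))^2
  within_var <- mean(tapply(pc$scores[, 1], grp, var))
  expect_true(between_var > within_var)
})

test_that("zero-variance genotype matrices are rejected for PCA", {
  gm <- make_gm(rbind(rep("A/A", 5), rep("A/A", 5)))
  expect_error(genotype_pca(gm), "zero-variance")
})

test_that("three-taxon NJ solves the three-point closed form", {
  dm <- matrix(c(0, 0.3, 0.4,
                 0.3, 0, 0.5,
                 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  ## x_a = (d_ab + d_ac - d_bc)/2, etc.
  want <- c(a = 0.1, b = 0.2, c = 0.3)
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(got[names(want)], want)
})

test_that("NJ recovers the generating split of additive 4-taxon matrices", {
  set.seed(57)
  for (i in 1:10) {
    tree <- ape::rtree(4, br = function(n) runif(n, 0.2, 1))
    dm <- ape::cophenetic.phylo(tree)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("replicate clusters form clades in the NJ tree", {
  cfg <- simulation_config(n_markers = 100, n_lines = c(G1 = 5),
                           divergence_F = c(G1 = 0.1), n_replicates = 5,
                           call_error_rate = 0.005, missing_rate = 0.02,
                           seed = 58)
  panel <- simulate_panel(cfg)
  gm <- panel$genotypes
  dm <- distance_matrix(gm)
  tr <- nj_tree(dm)
  for (l in unique(gm$samples$line_name)) {
    tips <- gm$samples$sample_id[gm$samples$line_name == l]
    expect_true(ape::is.monophyletic(tr, tips))
  }
})

test_that("degenerate two-label trees carry the pair distance", {
  dm <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(tr <- nj_tree(dm), "degenerate")
  expect_equal(sum(tr$edge.length), 0.4)
})

test_that("conversion test annotates distances and skips absent lines", {
  dm <- matrix(c(0, 0.05, 0.4,
                 0.05, 0, 0.42,
                 0.4, 0.42, 0), 3, 3,
               dimnames = list(c("P", "C", "U"), c("P", "C", "U")))
  pairs <- data.frame(original = c("P", "P", "P"),
                      converted = c("C", "P", "ZZ"),
                      stringsAsFactors = FALSE)
  expect_warning(res <- conversion_test(pairs, dm), "ZZ")
  expect_equal(res$distance, c(0.05, 0))
  expect_equal(res$flagged, c(FALSE, FALSE))
  expect_equal(nrow(attr(res, "skipped")), 1L)
  res2 <- conversion_test(data.frame(original = "P", converted = "U"), dm)
  expect_true(res2$flagged)
})
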