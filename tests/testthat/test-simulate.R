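test_that("simulation is deterministic under a fixed seed, distinct across seeds", {
  p1 <- simulate_panel(paper_like_preset(seed = 3))
  p2 <- simulate_panel(paper_like_preset(seed = 3))
  p3 <- simulate_panel(paper_like_preset(seed = 4))
  expect_identical(p1$genotypes$calls, p2$genotypes$calls)
  expect_identical(p1$truth$samples, p2$truth$samples)
  expect_false(identical(p1$genotypes$calls, p3$genotypes$calls))
})

test_that("a noise-free configuration gives identical homozygous replicates", {
  cfg <- simulation_config(n_markers = 50, n_lines = c(G1 = 10),
                           divergence_F = c(G1 = 0.05), residual_het = 0,
                           call_error_rate = 0, missing_rate = 0,
                           n_replicates = 3, seed = 61)
  panel <- simulate_panel(cfg)
  gm <- panel$genotypes
  expect_false(any(call_is_het(gm$calls)))
  expect_false(anyNA(gm$calls))
  for (l in unique(gm$samples$line_name)) {
    rows <- gm$calls[gm$samples$line_name == l, , drop = FALSE]
    for (i in seq_len(nrow(rows))[-1]) {
      expect_identical(unname(rows[i, ]), unname(rows[1, ]))
    }
  }
})

test_that("subgroup separation grows with the drift parameter", {
  ## Under Balding-Nichols drift around a common ancestral frequency the
  ## expected between-subgroup distance is F-free; what grows with F is
  ## the separation between-minus-within (drift shrinks within-group
  ## distances while between-group distances stay put).
  separation <- function(f, seed) {
    cfg <- simulation_config(n_markers = 80, n_lines = c(P = 12, Q = 12),
                             divergence_F = c(P = f, Q = f),
                             n_replicates = 1, residual_het = 0,
                             call_error_rate = 0, missing_rate = 0,
                             seed = seed)
    panel <- simulate_panel(cfg)
    dm <- distance_matrix(panel$genotypes)
    grp <- setNames(panel$genotypes$samples$subgroup, rownames(dm))
    sg <- subgroup_distances(dm, grp)
    sg$mean_distance[sg$type == "between"] -
      mean(sg$mean_distance[sg$type == "within"])
  }
  for (seed in c(62, 63, 64)) {
    expect_gt(separation(0.3, seed), separation(0.02, seed))
  }
})

test_that("the preset filter excludes a planted low-quality tail but keeps most markers", {
  panel <- simulate_panel(paper_like_preset(seed = 65))
  st <- compute_marker_stats(panel$genotypes)
  res <- filter_markers(st)
  expect_gt(nrow(res$exclusions), 0)
  expect_gt(length(res$retained), 0.8 * n_markers(panel$genotypes))
  ## planted defect markers dominate the exclusions
  truth_defect <- panel$truth$markers$marker_id[
    !is.na(panel$truth$markers$defect)]
  expect_gt(mean(res$exclusions$marker_id %in% truth_defect), 0.8)
})

test_that("observed purity proportions track the planted heterozygosity targets", {
  cfg <- paper_like_preset(seed = 66)
  panel <- simulate_panel(cfg)
  pur <- classify_purity(panel$genotypes)
  ## expected per-line sample heterozygosity: planted target plus the
  ## assay-defect and call-error contributions
  defect_add <- 100 * cfg$n_high_het_markers * cfg$defect_het_rate /
    cfg$n_markers
  err_add <- 100 * cfg$call_error_rate * cfg$hom_to_het_ratio
  exp_het <- 100 * panel$truth$lines$het_target + defect_add + err_add
  expect_lt(abs(mean(pur$het_pct, na.rm = TRUE) - mean(exp_het)), 0.5)
  ## the impure (>5%) class sits far from the bulk of the planted
  ## distribution, so its proportion is stable: within 10 points
  obs_imp <- mean(pur$purity_level == "HETEROZYGOUS", na.rm = TRUE)
  exp_imp <- mean(exp_het > 5)
  expect_lt(abs(obs_imp - exp_imp), 0.10)
})

test_that("empirical marker frequencies converge to the generating frequencies", {
  rmse <- function(n_lines, seed) {
    cfg <- simulation_config(n_markers = 60, n_lines = c(G = n_lines),
                             divergence_F = c(G = 0.02), n_replicates = 1,
                             residual_het = 0, call_error_rate = 0,
                             missing_rate = 0, seed = seed)
    panel <- simulate_panel(cfg)
    d <- kaspqc:::dosage_encode(panel$genotypes$calls,
                                panel$genotypes$markers$alleles)
    emp <- colMeans(d) / 2
    gen <- panel$truth$markers[["freq2_G"]]
    sqrt(mean((emp - gen)^2))
  }
  expect_lt(mean(vapply(1:3, function(s) rmse(400, s + 70), numeric(1))),
            mean(vapply(1:3, function(s) rmse(25, s + 80), numeric(1))))
})

test_that("planted relationships are recorded and honoured by the genotypes", {
  cfg <- simulation_config(n_markers = 100, n_lines = c(G = 30),
                           divergence_F = c(G = 0.05), n_replicates = 1,
                           residual_het = 0, call_error_rate = 0,
                           missing_rate = 0, n_sibling_pairs = 2,
                           n_conversions = 2, conversion_fraction = 0.05,
                           seed = 67)
  panel <- simulate_panel(cfg)
  rel <- panel$truth$relationships
  expect_equal(sum(rel$type == "sibling"), 2L)
  expect_equal(sum(rel$type == "conversion"), 2L)
  gm <- panel$genotypes
  for (r in which(rel$type == "conversion")) {
    a <- gm$calls[gm$samples$line_name == rel$line_a[r], ]
    b <- gm$calls[gm$samples$line_name == rel$line_b[r], ]
    intro <- panel$truth$introgressions$marker_id[
      panel$truth$introgressions$line_name == rel$line_b[r]]
    ## outside the introgressed block the conversion equals its parent
    keep <- setdiff(colnames(gm$calls), intro)
    expect_identical(a[keep], b[keep])
    expect_equal(length(intro), round(0.05 * 100))
  }
})

test_that("infeasible configurations fail fast", {
  expect_error(simulation_config(n_markers = 20, n_lines = c(G = 4),
                                 divergence_F = c(G = 0.1),
                                 n_mislabels = 3),
               "exceed")
  expect_error(simulation_config(n_markers = 10, n_lines = c(G = 5),
                                 divergence_F = c(G = 0.1),
                                 n_high_missing_markers = 11),
               "defect")
  expect_error(simulation_config(n_lines = c(G = 5),
                                 divergence_F = c(H = 0.1)))
})

test_that("pooled divergence makes out-of-pool subgroups the most distant", {
  panel <- simulate_panel(paper_like_preset(seed = 68))
  pur <- classify_purity(panel$genotypes)
  flt <- filter_markers(compute_marker_stats(panel$genotypes))
  ref <- build_reference(panel$genotypes, flt$retained, pur)
  dm <- distance_matrix(ref)
  grp <- setNames(ref$genotypes$samples$subgroup, rownames(dm))
  sg <- subgroup_distances(dm, grp)
  tropical <- c("Lowland Tropical", "Subtropical/Mid-altitude",
                "Highland Tropical")
  temp_trop <- sg$mean_distance[sg$type == "between" &
    (sg$group_a == "Temperate" | sg$group_b == "Temperate")]
  trop_trop <- sg$mean_distance[sg$type == "between" &
    sg$group_a %in% tropical & sg$group_b %in% tropical]
  expect_true(min(temp_trop) > max(trop_trop))
})
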