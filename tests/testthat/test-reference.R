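## Frozen merge-rule table: every unordered pair of biallelic calls at an
## A/G marker, derived by hand from the three consensus criteria.
MERGE_TABLE <- list(
  list(c("A/A", "A/A"), "A/A"),   # consistent -> merged directly
  list(c("A/G", "A/G"), "A/G"),
  list(c("G/G", "G/G"), "G/G"),
  list(c("A/A", "A/G"), "A/A"),   # hom + het sharing allele -> hom kept
  list(c("G/G", "A/G"), "G/G"),
  list(c("A/A", "G/G"), NA),      # conflicting homozygotes -> missing
  list(c("A/A", NA), "A/A"),      # dropout -> observed call (default policy)
  list(c("A/G", NA), "A/G"),
  list(c("G/G", NA), "G/G"),
  list(c(NA, NA), NA))

test_that("pairwise merge reproduces the three-rule consensus table, order-invariantly", {
  for (case in MERGE_TABLE) {
    x <- case[[1]]; want <- case[[2]]
    got_fwd <- merge_replicates(x)
    got_rev <- merge_replicates(rev(x))
    if (is.na(want)) {
      expect_true(is.na(got_fwd))
      expect_true(is.na(got_rev))
    } else {
      expect_equal(got_fwd, want)
      expect_equal(got_rev, want)
    }
  }
})

test_that("strict missing policy sets dropout sites to missing", {
  expect_true(is.na(merge_replicates(c("A/A", NA), "strict")))
  expect_equal(merge_replicates(c("A/A", "A/A"), "strict"), "A/A")
})

test_that("merge generalizes to more than two replicates", {
  expect_equal(merge_replicates(c("A/A", "A/G", "A/G")), "A/A")
  expect_equal(merge_replicates(c("A/G", "A/G", "A/G")), "A/G")
  expect_true(is.na(merge_replicates(c("A/A", "A/G", "G/G"))))
  expect_true(is.na(merge_replicates(c("A/A", "C/G"))))  # het sharing no allele
  expect_equal(merge_replicates(c("A/A", NA, "A/G", "A/A")), "A/A")
  expect_error(merge_replicates(character(0)), "no replicate")
})

test_that("mislabel resolution excludes exactly the planted swap among five replicates", {
  cfg <- simulation_config(n_markers = 120, n_lines = c(G1 = 15),
                           divergence_F = c(G1 = 0.05), n_replicates = 5,
                           n_mislabels = 1, call_error_rate = 0.003,
                           missing_rate = 0.02, seed = 17)
  panel <- simulate_panel(cfg)
  truth_mis <- panel$truth$samples$sample_id[
    panel$truth$samples$issue == "MISLABEL"]
  res <- resolve_mislabels(panel$genotypes)
  expect_setequal(res$exclusions$sample_id, truth_mis)
  expect_true(all(res$line_status$status == "RESOLVED"))
  expect_true(all(res$exclusions$nj_agrees))
})

test_that("fully consistent replicates yield no exclusions", {
  m <- 80
  set.seed(8)
  g <- random_calls(m, miss_rate = 0)
  other <- random_calls(m, alleles = g$alleles, miss_rate = 0)$calls
  g <- g$calls
  gm <- make_gm(rbind(g, g, g, g, g, other, other),
                lines = c(rep("L1", 5), "L2", "L2"))
  res <- resolve_mislabels(gm, flagged_lines = "L1")
  expect_equal(nrow(res$exclusions), 0L)
  expect_equal(res$line_status$status, "CLEAN")
})

test_that("a 2-vs-3 split of internally consistent replicates is UNRESOLVED", {
  m <- 80
  set.seed(9)
  a <- random_calls(m, miss_rate = 0)
  b <- random_calls(m, alleles = a$alleles, miss_rate = 0)$calls
  gm <- make_gm(rbind(a$calls, a$calls, b, b, b),
                lines = rep("L1", 5), validate = FALSE)
  res <- resolve_mislabels(gm, flagged_lines = "L1")
  expect_equal(res$line_status$status, "UNRESOLVED")
  expect_equal(nrow(res$exclusions), 0L)
})

test_that("lines with fewer than three replicates cannot be resolved", {
  gm <- make_gm(rbind(c("A/A", "C/C"), c("G/G", "T/T")),
                lines = c("L1", "L1"))
  res <- resolve_mislabels(gm, flagged_lines = "L1")
  expect_equal(res$line_status$status, "INSUFFICIENT_REPLICATES")
})

test_that("the merge never creates heterozygous calls a replicate lacked", {
  ## rule 2 only removes heterozygosity: a consensus call is het only if
  ## every replicate that called the site called it het, so with full
  ## call rates the consensus het count is bounded by every replicate's
  cfg <- simulation_config(n_markers = 100, n_lines = c(G1 = 20),
                           divergence_F = c(G1 = 0.05),
                           residual_het = 0.02, call_error_rate = 0.005,
                           missing_rate = 0, n_replicates = 2, seed = 41)
  panel <- simulate_panel(cfg)
  gm <- panel$genotypes
  ref <- build_reference(gm, het_max_pct = 100)
  for (i in seq_len(nrow(ref$lines))) {
    l <- ref$lines$line_name[i]
    cons_het <- sum(call_is_het(ref$genotypes$calls[l, ]), na.rm = TRUE)
    rep_het <- rowSums(call_is_het(gm$calls[gm$samples$line_name == l, ,
                                            drop = FALSE]), na.rm = TRUE)
    expect_lte(cons_het, min(rep_het))
  }
})

test_that("replicate disagreements become missing consensus sites", {
  m <- 50; k <- 7
  gm <- make_gm(two_rep_line(m, k_diff = k), lines = rep("L1", 2))
  ref <- build_reference(gm, het_max_pct = 100)
  expect_true(is.na(ref$lines$het_pct) || ref$lines$het_pct == 0)
  expect_equal(ref$lines$missing_pct, 100 * k / m)
  expect_true(all(is.na(ref$genotypes$calls[1, 1:k])))
})

test_that("a single-replicate line's consensus is that replicate verbatim", {
  set.seed(12)
  g <- random_calls(30, miss_rate = 0.2)$calls
  other <- random_calls(30, miss_rate = 0)$calls
  gm <- make_gm(rbind(g, other, other), lines = c("L1", "L2", "L2"),
                validate = FALSE)
  ref <- build_reference(gm, het_max_pct = 100)
  expect_identical(unname(ref$genotypes$calls["L1", ]), unname(g))
})

test_that("low-heterozygosity replicates are preferred and others set aside", {
  m <- 200
  clean <- rep("A/A", m)
  dirty <- clean; dirty[1:20] <- "A/G"   # 10% heterozygosity
  other <- rep(c("C/C", "T/T"), m / 2)
  gm <- make_gm(rbind(clean, dirty, other, other),
                lines = c("L1", "L1", "L2", "L2"), validate = FALSE)
  ref <- build_reference(gm)
  prov <- ref$provenance[ref$provenance$line_name == "L1", ]
  expect_equal(prov$status[prov$sample_id == "L1_R1"], "used")
  expect_equal(prov$status[prov$sample_id == "L1_R2"], "excluded")
  expect_equal(prov$reason[prov$sample_id == "L1_R2"], "HIGH_HET")
  expect_equal(ref$lines$het_pct[ref$lines$line_name == "L1"], 0)
})

test_that("excluded mislabels and unresolved lines drop out of the reference", {
  set.seed(13)
  g1 <- random_calls(60, miss_rate = 0)
  g2 <- random_calls(60, alleles = g1$alleles, miss_rate = 0)$calls
  gm <- make_gm(rbind(g1$calls, g1$calls, g2, g2),
                lines = c("L1", "L1", "L2", "L2"), validate = FALSE)
  excl <- data.frame(sample_id = c("L2_R1", "L2_R2"),
                     reason = "MISLABEL", stringsAsFactors = FALSE)
  ref <- build_reference(gm, exclusions = excl, het_max_pct = 100)
  expect_equal(ref$missing_lines, "L2")
  expect_equal(rownames(ref$genotypes$calls), "L1")
})

test_that("reference building is deterministic", {
  panel <- simulate_panel(paper_like_preset(seed = 5))
  r1 <- build_reference(panel$genotypes)
  r2 <- build_reference(panel$genotypes)
  expect_identical(r1$genotypes$calls, r2$genotypes$calls)
  expect_identical(r1$summary, r2$summary)
})
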