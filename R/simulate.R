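#' Simulation configuration
#'
#' Parameters of the synthetic inbred-panel generator.  The generator
#' draws ancestral minor allele frequencies per marker, diverges them
#' into adaptation subgroups under a Balding-Nichols drift model,
#' samples inbred lines as homozygotes from the subgroup frequencies
#' with a per-line residual-heterozygosity target, and then emits
#' biological replicates with call errors and missingness, plus planted
#' QC issues (mislabels, contaminations, siblings, conversions) and
#' planted low-quality markers, all with full ground truth.
#'
#' @param n_markers number of biallelic markers.
#' @param n_lines named integer vector: lines per subgroup.  Names are
#'   the subgroup labels.
#' @param divergence_F named numeric vector (same names): Balding-
#'   Nichols drift parameter per subgroup, in (0, 1); the subgroup
#'   frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#'   ancestral frequency p, with variance F p (1-p).
#' @param pools optional named character vector assigning each subgroup
#'   to a germplasm pool, giving two-level hierarchical divergence: the
#'   pool frequency drifts from the ancestral frequency with
#'   `pool_divergence_F`, and subgroups drift within their pool.
#'   Subgroups of a common pool are thereby correlated — closer to each
#'   other than to subgroups of other pools.  `NULL` (default) puts
#'   every subgroup in its own pool with no pool-level drift.
#' @param pool_divergence_F named numeric vector (pool names): pool-
#'   level drift parameter in (0, 1).
#' @param marker_maf_floor minimum expected panel-wide MAF for regular
#'   markers (0 disables).  Emulates the upstream selection of QC assay
#'   panels for informativeness: markers drifting below the floor are
#'   redrawn.  Planted low-MAF defect markers are exempt.
#' @param residual_het mean per-line residual heterozygosity target in
#'   \[0, 0.2\]; per-line targets are drawn from an exponential with
#'   this mean (truncated at 0.2), so most lines fall well under 5%.
#' @param n_replicates biological replicates per line.
#' @param call_error_rate per-call error probability; errors are
#'   allele-level cluster mis-assignments: a homozygote miscalls to the
#'   heterozygote with probability `hom_to_het_ratio` (else to the
#'   opposite homozygote), a heterozygote miscalls to a random
#'   homozygote.
#' @param hom_to_het_ratio see above (default 0.8).
#' @param missing_rate per-call missing probability.
#' @param n_mislabels number of planted replicate label swaps (each
#'   swap exchanges one replicate between two lines).
#' @param n_contaminated number of replicates carrying seed/pollen
#'   contamination, modelled as a per-marker mixture: each marker
#'   independently takes one allele from the line and one from a random
#'   contaminant line with probability `contamination_fraction`.
#' @param contamination_fraction see above.
#' @param n_sibling_pairs pairs of lines sharing ~50% of their genome
#'   (one common parent).
#' @param n_conversions pairs (parent, converted line): the conversion
#'   copies the parent and replaces `conversion_fraction` of markers
#'   with donor genotypes.
#' @param conversion_fraction introgressed genome fraction.
#' @param n_high_het_markers,n_high_missing_markers,n_low_maf_markers
#'   planted low-quality markers (assay artifacts): forced
#'   heterozygote rate `defect_het_rate` at high-het markers, missing
#'   rate `defect_missing_rate` at high-missing markers, ancestral
#'   minor frequency below 0.02 at low-MAF markers.
#' @param n_het_missing_overlap,n_maf_missing_overlap how many of the
#'   high-het (resp. low-MAF) markers coincide with high-missing
#'   markers.
#' @param defect_het_rate,defect_missing_rate see above.
#' @param chromosome_counts optional named integer vector giving the
#'   number of markers per chromosome label (must sum to `n_markers`);
#'   by default markers are spread evenly over chromosomes 1-10.
#' @param seed integer random seed; the same seed reproduces the panel
#'   byte for byte.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_markers = 180,
                              n_lines = c("Lowland Tropical" = 67,
                                          "Subtropical/Mid-altitude" = 46,
                                          "Highland Tropical" = 7,
                                          "Temperate" = 3),
                              divergence_F = c("Lowland Tropical" = 0.06,
                                               "Subtropical/Mid-altitude" = 0.06,
                                               "Highland Tropical" = 0.10,
                                               "Temperate" = 0.35),
                              pools = NULL,
                              pool_divergence_F = NULL,
                              marker_maf_floor = 0,
                              residual_het = 0.012,
                              n_replicates = 2,
                              call_error_rate = 0.003,
                              hom_to_het_ratio = 0.8,
                              missing_rate = 0.03,
                              n_mislabels = 0,
                              n_contaminated = 0,
                              contamination_fraction = 0.2,
                              n_sibling_pairs = 0,
                              n_conversions = 0,
                              conversion_fraction = 0.05,
                              n_high_het_markers = 0,
                              n_high_missing_markers = 0,
                              n_low_maf_markers = 0,
                              n_het_missing_overlap = 0,
                              n_maf_missing_overlap = 0,
                              defect_het_rate = 0.15,
                              defect_missing_rate = 0.25,
                              chromosome_counts = NULL,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_markers >= 1, all(n_lines >= 0), sum(n_lines) >= 1,
            !is.null(names(n_lines)),
            all(names(n_lines) %in% names(divergence_F)),
            all(divergence_F > 0), all(divergence_F < 1),
            residual_het >= 0, residual_het <= 0.2,
            n_replicates >= 1,
            call_error_rate >= 0, call_error_rate <= 1,
            hom_to_het_ratio >= 0, hom_to_het_ratio <= 1,
            missing_rate >= 0, missing_rate <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            conversion_fraction >= 0, conversion_fraction <= 1,
            marker_maf_floor >= 0, marker_maf_floor < 0.5)
  if (!is.null(pools)) {
    stopifnot(all(names(n_lines) %in% names(pools)),
              !is.null(pool_divergence_F),
              all(pools[names(n_lines)] %in% names(pool_divergence_F)),
              all(pool_divergence_F > 0), all(pool_divergence_F < 1))
  }
  n_total <- sum(n_lines)
  special <- 2 * n_mislabels + n_contaminated + 2 * n_sibling_pairs +
    2 * n_conversions
  if (special > n_total) {
    stop("planted issue counts exceed the panel size (", special, " > ",
         n_total, ")")
  }
  if (n_mislabels > 0 && n_replicates < 1) stop("mislabels need replicates")
  if (!is.null(chromosome_counts) && sum(chromosome_counts) != n_markers) {
    stop("chromosome_counts must sum to n_markers")
  }
  if (n_het_missing_overlap > min(n_high_het_markers, n_high_missing_markers) ||
      n_maf_missing_overlap > min(n_low_maf_markers, n_high_missing_markers)) {
    stop("defect overlaps exceed the defect set sizes")
  }
  if (n_high_het_markers + n_high_missing_markers + n_low_maf_markers -
      n_het_missing_overlap - n_maf_missing_overlap > n_markers) {
    stop("defect marker counts exceed n_markers")
  }
  structure(cfg, class = "simulation_config")
}

#' Panel preset emulating the reference study conditions
#'
#' A [simulation_config()] whose defaults reproduce the structure of a
#' tropical inbred fingerprinting panel at one fifth scale (for speed):
#' 180 markers laid out on chromosomes 1-10 plus one unplaced contig
#' with the reference per-chromosome counts (21, 18, 19, 12, 19, 22,
#' 15, 20, 13, 20, 1); adaptation subgroups of 67 lowland-tropical, 46
#' subtropical/mid-altitude, 7 highland-tropical and 3 temperate lines
#' (a 0.2 scaling of 336/230/37/14); two biological replicates per
#' line; marker-defect tails of 8 high-heterozygosity, 16 high-missing
#' and 10 low-MAF markers with 3 het/missing and 4 MAF/missing
#' overlaps; and a planted issue set mixing mislabels, contaminations,
#' siblings and trait conversions.  Marginals target a mean missing
#' rate near 3%, mean sample heterozygosity near 2%, and mean MAF near
#' 0.3.
#'
#' @param seed integer random seed.
#' @param n_replicates replicates per line (2 emulates the first
#'   genotyping round; 5 the full two-round design used for mislabel
#'   resolution).
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
paper_like_preset <- function(seed = 1, n_replicates = 2, ...) {
  simulation_config(
    n_markers = 180,
    chromosome_counts = c("1" = 21, "2" = 18, "3" = 19, "4" = 12,
                          "5" = 19, "6" = 22, "7" = 15, "8" = 20,
                          "9" = 13, "10" = 20, "0" = 1),
    pools = c("Lowland Tropical" = "tropical",
              "Subtropical/Mid-altitude" = "tropical",
              "Highland Tropical" = "tropical",
              "Temperate" = "temperate"),
    pool_divergence_F = c(tropical = 0.15, temperate = 0.15),
    marker_maf_floor = 0.08,
    n_replicates = n_replicates,
    n_mislabels = 2,
    n_contaminated = 3,
    n_sibling_pairs = 2,
    n_conversions = 2,
    n_high_het_markers = 8,
    n_high_missing_markers = 16,
    n_low_maf_markers = 10,
    n_het_missing_overlap = 3,
    n_maf_missing_overlap = 4,
    seed = seed,
    ...)
}

#' Simulate a genotype panel with ground truth
#'
#' Generates a [genotype_matrix()] under a [simulation_config()],
#' together with the complete ground truth needed to score every
#' pipeline stage.  See [simulation_config()] for the generative model.
#' Calls `set.seed(config$seed)`: the same configuration always yields
#' an identical panel.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_panel` with elements
#'   `genotypes` (the `genotype_matrix`), `truth` (list: `samples` with
#'   per-sample true line and issue labels, `lines` with subgroup and
#'   heterozygosity targets, `markers` with ancestral and per-subgroup
#'   allele-2 frequencies and defect labels, `relationships` with
#'   sibling/conversion records, `introgressions` with the introgressed
#'   marker ids per conversion), and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$n_markers
  sg_names <- names(config$n_lines)

  ## ---- markers -----------------------------------------------------
  if (is.null(config$chromosome_counts)) {
    chrom <- as.character(rep_len(rep(1:10, each = ceiling(m / 10)), m))
  } else {
    chrom <- rep(names(config$chromosome_counts), config$chromosome_counts)
  }
  marker_id <- sprintf("SM%03d", seq_len(m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    sort(sample.int(3e8, length(i)))
  }), use.names = FALSE)[order(order(chrom))]
  ## mutation classes with field-realistic proportions
  cls <- sample(c("ts", "tvACGT", "tvATCG"), m, replace = TRUE,
                prob = c(0.599, 0.209, 0.192))
  pair_pool <- list(ts = c("A/G", "C/T"), tvACGT = c("A/C", "G/T"),
                    tvATCG = c("A/T", "C/G"))
  alleles <- vapply(cls, function(k) sample(pair_pool[[k]], 1L), character(1))
  ## defect marker sets (size-safe sampling: never sample(1:x))
  resample <- function(x, k) x[sample.int(length(x), k)]
  idx_all <- seq_len(m)
  hm <- resample(idx_all, config$n_high_missing_markers)
  hh <- c(resample(hm, config$n_het_missing_overlap),
          resample(setdiff(idx_all, hm),
                   config$n_high_het_markers - config$n_het_missing_overlap))
  lm_pool <- setdiff(hm, hh)
  lmaf <- c(resample(lm_pool, config$n_maf_missing_overlap),
            resample(setdiff(idx_all, union(hm, hh)),
                     config$n_low_maf_markers - config$n_maf_missing_overlap))
  ## ancestral minor allele frequencies, then two-level Balding-Nichols
  ## drift: ancestral -> (pool ->) subgroup
  p_minor <- q2 <- numeric(m)
  q_sub <- matrix(NA_real_, m, length(sg_names),
                  dimnames = list(NULL, sg_names))
  pool_of <- if (!is.null(config$pools)) config$pools[sg_names] else
    stats::setNames(sg_names, sg_names)
  pool_f <- if (!is.null(config$pools)) config$pool_divergence_F else
    stats::setNames(rep(NA_real_, length(sg_names)), sg_names)
  draw_freqs <- function(idx) {
    k <- length(idx)
    pm <- stats::runif(k, 0.1, 0.5)
    q <- ifelse(sample(c(TRUE, FALSE), k, replace = TRUE), pm, 1 - pm)
    bn <- function(center, f) {
      if (is.na(f)) return(center)
      pmin(pmax(stats::rbeta(k, center * (1 - f) / f,
                             (1 - center) * (1 - f) / f), 1e-6), 1 - 1e-6)
    }
    qp <- sapply(unique(pool_of), function(pl) bn(q, pool_f[[pl]]))
    qp <- matrix(qp, nrow = k)
    colnames(qp) <- unique(pool_of)
    qs <- sapply(sg_names, function(g) {
      pmin(pmax(bn_k(qp[, pool_of[[g]]], config$divergence_F[[g]], k),
                1e-6), 1 - 1e-6)
    })
    p_minor[idx] <<- pm
    q2[idx] <<- q
    q_sub[idx, ] <<- matrix(qs, nrow = k)
  }
  bn_k <- function(center, f, k) {
    stats::rbeta(k, center * (1 - f) / f, (1 - center) * (1 - f) / f)
  }
  draw_freqs(seq_len(m))
  ## planted low-MAF assay failures override the ancestral draw
  redraw_lmaf <- function() {
    if (!length(lmaf)) return()
    pm <- stats::runif(length(lmaf), 0.002, 0.02)
    q <- ifelse(q2[lmaf] <= 0.5, pm, 1 - pm)
    p_minor[lmaf] <<- pm
    q2[lmaf] <<- q
    for (g in sg_names) {
      q_sub[lmaf, g] <<- pmin(pmax(
        bn_k(q, config$divergence_F[[g]], length(lmaf)), 1e-6), 1 - 1e-6)
    }
  }
  redraw_lmaf()
  ## emulate assay-panel selection for informativeness: redraw markers
  ## whose expected panel-wide MAF falls below the floor (defect
  ## low-MAF markers are exempt: they model assay failures)
  if (config$marker_maf_floor > 0) {
    w <- config$n_lines[sg_names] / sum(config$n_lines)
    low_panel_maf <- function() {
      qbar <- as.vector(q_sub %*% w)
      setdiff(which(pmin(qbar, 1 - qbar) < config$marker_maf_floor), lmaf)
    }
    it <- 0L
    bad <- low_panel_maf()
    while (length(bad) && it < 100L) {
      draw_freqs(bad)
      bad <- low_panel_maf()
      it <- it + 1L
    }
  }

  ## ---- lines (dosage of allele 2: 0/1/2) ---------------------------
  n_lines_total <- sum(config$n_lines)
  subgroup <- rep(sg_names, config$n_lines)
  line_name <- sprintf("SL%03d%s", seq_len(n_lines_total),
                       rep_len(c("A", "B"), n_lines_total))
  draw_line <- function(g) {
    2L * (stats::runif(m) < q_sub[, g])
  }
  L <- t(vapply(subgroup, draw_line, integer(m)))
  het_target <- pmin(stats::rexp(n_lines_total, 1 / max(config$residual_het, 1e-9)),
                     0.2)
  if (config$residual_het == 0) het_target[] <- 0
  for (i in seq_len(n_lines_total)) {
    k <- round(het_target[i] * m)
    if (k > 0) L[i, sample.int(m, k)] <- 1L
  }

  ## ---- planted relationships --------------------------------------
  ## reserve disjoint line sets for each issue class
  pool <- sample(seq_len(n_lines_total))
  take <- function(k) {
    if (k == 0) return(integer(0))
    if (k > length(pool)) stop("infeasible issue counts")
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  mis_lines <- if (config$n_mislabels) matrix(take(2 * config$n_mislabels),
                                              ncol = 2) else
    matrix(integer(0), ncol = 2)
  cont_lines <- take(config$n_contaminated)
  sib_lines <- if (config$n_sibling_pairs)
    matrix(take(2 * config$n_sibling_pairs), ncol = 2) else
    matrix(integer(0), ncol = 2)
  conv_lines <- if (config$n_conversions)
    matrix(take(2 * config$n_conversions), ncol = 2) else
    matrix(integer(0), ncol = 2)

  relationships <- list()
  introgressions <- list()
  for (r in seq_len(nrow(sib_lines))) {
    a <- sib_lines[r, 1L]; b <- sib_lines[r, 2L]
    share <- stats::runif(m) < 0.5
    L[b, share] <- L[a, share]
    relationships[[length(relationships) + 1L]] <- data.frame(
      type = "sibling", line_a = line_name[a], line_b = line_name[b],
      fraction = mean(share), stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(conv_lines))) {
    a <- conv_lines[r, 1L]; b <- conv_lines[r, 2L]
    k <- max(1L, round(config$conversion_fraction * m))
    intro <- sample.int(m, k)
    L[b, ] <- L[a, ]
    L[b, intro] <- 2L * (stats::runif(k) < q_sub[intro, subgroup[b]])
    relationships[[length(relationships) + 1L]] <- data.frame(
      type = "conversion", line_a = line_name[a], line_b = line_name[b],
      fraction = config$conversion_fraction, stringsAsFactors = FALSE)
    introgressions[[length(introgressions) + 1L]] <- data.frame(
      line_name = line_name[b], marker_id = marker_id[intro],
      stringsAsFactors = FALSE)
  }

  ## ---- replicates --------------------------------------------------
  nrep <- config$n_replicates
  n_samp <- n_lines_total * nrep
  G <- matrix(NA_integer_, n_samp, m)   # dosage incl. NA
  samp_line <- rep(seq_len(n_lines_total), each = nrep)
  samp_rep <- rep(seq_len(nrep), times = n_lines_total)
  e <- config$call_error_rate
  for (s in seq_len(n_samp)) {
    g <- L[samp_line[s], ]
    if (e > 0) {
      err <- which(stats::runif(m) < e)
      for (j in err) {
        g[j] <- if (g[j] == 1L) sample(c(0L, 2L), 1L)
                else if (stats::runif(1) < config$hom_to_het_ratio) 1L
                else 2L - g[j]
      }
    }
    G[s, ] <- g
  }
  ## forced heterozygosity at defective assays
  if (length(hh) && config$defect_het_rate > 0) {
    for (j in hh) {
      hit <- stats::runif(n_samp) < config$defect_het_rate
      G[hit, j] <- 1L
    }
  }
  ## contamination: per-marker allele mixture on one replicate
  cont_samples <- integer(0)
  if (length(cont_lines)) {
    for (l in cont_lines) {
      s <- which(samp_line == l)[1L]
      donor <- resample(setdiff(seq_len(n_lines_total), l), 1L)
      mix <- which(stats::runif(m) < config$contamination_fraction)
      own_allele <- ifelse(L[l, mix] == 1L,
                           as.integer(stats::runif(length(mix)) < 0.5),
                           L[l, mix] / 2L)
      don_allele <- ifelse(L[donor, mix] == 1L,
                           as.integer(stats::runif(length(mix)) < 0.5),
                           L[donor, mix] / 2L)
      G[s, mix] <- as.integer(own_allele + don_allele)
      cont_samples <- c(cont_samples, s)
    }
  }
  ## mislabels: swap the genotype content of one replicate between lines
  mis_samples <- integer(0)
  true_line <- samp_line
  for (r in seq_len(nrow(mis_lines))) {
    a <- mis_lines[r, 1L]; b <- mis_lines[r, 2L]
    sa <- which(samp_line == a)[min(2L, nrep)]
    sb <- which(samp_line == b)[min(2L, nrep)]
    tmp <- G[sa, ]; G[sa, ] <- G[sb, ]; G[sb, ] <- tmp
    true_line[sa] <- b; true_line[sb] <- a
    mis_samples <- c(mis_samples, sa, sb)
  }
  ## missingness (applied last, after all content edits)
  miss_rate <- rep(config$missing_rate, m)
  miss_rate[hm] <- config$defect_missing_rate
  for (j in seq_len(m)) {
    if (miss_rate[j] <= 0) next
    G[stats::runif(n_samp) < miss_rate[j], j] <- NA_integer_
  }

  ## ---- materialize calls ------------------------------------------
  a1 <- call_allele1(alleles); a2 <- call_allele2(alleles)
  calls <- matrix(NA_character_, n_samp, m)
  for (j in seq_len(m)) {
    gj <- G[, j]
    cj <- c(paste0(a1[j], "/", a1[j]),
            paste0(a1[j], "/", a2[j]),
            paste0(a2[j], "/", a2[j]))[gj + 1L]
    calls[, j] <- cj
  }
  sample_id <- paste0(line_name[samp_line], "_R", samp_rep)
  het_grp <- sub("^SL[0-9]+", "", line_name)
  samples <- data.frame(sample_id = sample_id,
                        line_name = line_name[samp_line],
                        replicate_id = paste0("R", samp_rep),
                        subgroup = subgroup[samp_line],
                        heterotic_group = het_grp[samp_line],
                        stringsAsFactors = FALSE)
  markers <- data.frame(marker_id = marker_id, chromosome = chrom,
                        position_bp = pos, alleles = alleles,
                        trait_tag = NA_character_, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, samples, markers, validate = FALSE)

  ## ---- truth -------------------------------------------------------
  issue <- rep("NONE", n_samp)
  issue[cont_samples] <- "CONTAMINATED"
  issue[mis_samples] <- "MISLABEL"
  defect <- rep(NA_character_, m)
  defect[hm] <- "HIGH_MISSING"
  defect[hh] <- ifelse(is.na(defect[hh]), "HIGH_HET",
                       paste(defect[hh], "HIGH_HET", sep = "+"))
  defect[lmaf] <- ifelse(is.na(defect[lmaf]), "LOW_MAF",
                         paste(defect[lmaf], "LOW_MAF", sep = "+"))
  truth <- list(
    samples = data.frame(sample_id = sample_id,
                         labelled_line = line_name[samp_line],
                         true_line = line_name[true_line],
                         issue = issue, stringsAsFactors = FALSE),
    lines = data.frame(line_name = line_name, subgroup = subgroup,
                       heterotic_group = het_grp,
                       het_target = het_target, stringsAsFactors = FALSE),
    markers = cbind(data.frame(marker_id = marker_id,
                               ancestral_freq2 = q2,
                               minor_allele_freq = p_minor,
                               defect = defect, stringsAsFactors = FALSE),
                    stats::setNames(as.data.frame(q_sub),
                                    paste0("freq2_", sg_names))),
    relationships = if (length(relationships)) do.call(rbind, relationships)
      else data.frame(type = character(), line_a = character(),
                      line_b = character(), fraction = numeric(),
                      stringsAsFactors = FALSE),
    introgressions = if (length(introgressions)) do.call(rbind, introgressions)
      else data.frame(line_name = character(), marker_id = character(),
                      stringsAsFactors = FALSE))
  structure(list(genotypes = gm, truth = truth, config = config),
            class = "simulated_panel")
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat("simulated_panel (seed ", x$config$seed, ")\n", sep = "")
  print(x$genotypes)
  tab <- table(x$truth$samples$issue)
  cat("  planted issues:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
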