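#' Merge replicate calls at one marker
#'
#' Collapses the calls of a line's biological replicates at a single
#' marker into one consensus call:
#' \enumerate{
#'   \item all non-missing calls identical — merged directly to that
#'     call;
#'   \item one distinct homozygote plus heterozygotes sharing that
#'     allele — the homozygote is kept (residual heterozygosity in one
#'     replicate does not overwrite a clean homozygous call);
#'   \item any remaining conflict (two different homozygotes, or a
#'     heterozygote sharing no allele with the homozygote, or two
#'     different heterozygotes) — set to missing.
#' }
#' When some replicates are missing, the default policy
#' (`missing_policy = "observed"`) treats missingness as technical
#' dropout and merges the observed calls by the rules above; the literal
#' alternative (`"strict"`) sets any site not called in every replicate
#' to missing.
#'
#' The merge generalizes to any number of replicates and is invariant to
#' the order of its input.
#'
#' @param calls character vector of genotype calls (one per replicate)
#'   at a single marker.
#' @param missing_policy `"observed"` (default) or `"strict"`.
#' @return a single canonical call, or `NA` for missing.
#' @export
merge_replicates <- function(calls, missing_policy = c("observed", "strict")) {
  missing_policy <- match.arg(missing_policy)
  if (!length(calls)) stop("no replicate calls to merge")
  calls <- canonicalize_calls(calls)
  if (missing_policy == "strict" && anyNA(calls)) return(NA_character_)
  obs <- calls[!is.na(calls)]
  if (!length(obs)) return(NA_character_)
  u <- unique(obs)
  if (length(u) == 1L) return(u)
  het <- call_is_het(u)
  homs <- u[!het]
  hets <- u[het]
  if (length(homs) != 1L) return(NA_character_)  # conflicting homozygotes (or >=2 distinct hets)
  hom_allele <- call_allele1(homs)
  shares <- vapply(hets, function(h) {
    hom_allele %in% c(call_allele1(h), call_allele2(h))
  }, logical(1))
  if (all(shares)) homs else NA_character_
}

#' Resolve mislabeled replicates within flagged lines
#'
#' For each flagged line with at least three biological replicates, a
#' replicate is declared `MISLABEL` when (a) the remaining replicates
#' are mutually consistent (all pairwise similarity rates above
#' `sim_threshold_pct`) and (b) the candidate's mean similarity to them
#' is at or below the threshold.  When no single exclusion restores
#' consistency (e.g. a 2-vs-3 split of internally consistent but
#' mutually distant replicate sets) the line is `UNRESOLVED` and no
#' consensus should be emitted for it.
#'
#' Decisions can be cross-checked against a neighbor-joining tree of all
#' flagged-line replicates: a genuine mislabel attaches outside its
#' line's clade, so its nearest tip by tree path length is a replicate
#' of some *other* line (for a label swap, typically the line whose
#' genotype it carries).  In `"advisory"` mode (default) the similarity
#' rule decides and the tree verdict is reported; `"strict"` mode
#' excludes a replicate only when both signals agree; `"off"` skips the
#' tree.
#'
#' @param gm a [genotype_matrix()] holding all replicates of the lines
#'   to examine (round 1 + round 2).
#' @param flagged_lines character vector of line names to resolve; when
#'   `NULL`, the lines flagged by [cross_line_similarity_screen()].
#' @param sim_threshold_pct consistency threshold, percent.
#' @param nj_mode `"advisory"`, `"strict"` or `"off"`.
#' @return list with `exclusions` (data frame: `line_name`, `sample_id`,
#'   `reason = "MISLABEL"`, `mean_sim_to_rest_pct`, `nj_agrees`) and
#'   `line_status` (data frame: `line_name`, `status` in
#'   RESOLVED/CLEAN/UNRESOLVED/INSUFFICIENT_REPLICATES).
#' @export
resolve_mislabels <- function(gm, flagged_lines = NULL,
                              sim_threshold_pct = 95,
                              nj_mode = c("advisory", "strict", "off")) {
  nj_mode <- match.arg(nj_mode)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(flagged_lines)) {
    scr <- cross_line_similarity_screen(gm)
    flagged_lines <- scr$flags$line_name[scr$flags$flagged]
  }
  thr <- sim_threshold_pct / 100
  sim <- pairwise_similarity_matrix(gm$calls, gm$markers$alleles)
  ln <- gm$samples$line_name
  ids <- gm$samples$sample_id
  excl <- list(); status <- list()
  for (l in flagged_lines) {
    idx <- which(ln == l)
    if (length(idx) < 3L) {
      status[[l]] <- "INSUFFICIENT_REPLICATES"
      next
    }
    s <- sim[idx, idx, drop = FALSE]
    consistent <- function(sub) {
      if (length(sub) < 2L) return(TRUE)
      m <- s[sub, sub]
      all(m[upper.tri(m)] > thr)
    }
    if (consistent(seq_along(idx))) {
      status[[l]] <- "CLEAN"
      next
    }
    hits <- integer(0)
    for (k in seq_along(idx)) {
      rest <- setdiff(seq_along(idx), k)
      if (consistent(rest) && mean(s[k, rest]) <= thr) hits <- c(hits, k)
    }
    if (!length(hits)) {
      status[[l]] <- "UNRESOLVED"
      next
    }
    status[[l]] <- "RESOLVED"
    for (k in hits) {
      excl[[length(excl) + 1L]] <-
        data.frame(line_name = l, sample_id = ids[idx[k]],
                   reason = "MISLABEL",
                   mean_sim_to_rest_pct =
                     100 * mean(s[k, setdiff(seq_along(idx), k)]),
                   nj_agrees = NA, stringsAsFactors = FALSE)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(line_name = character(), sample_id = character(),
               reason = character(), mean_sim_to_rest_pct = numeric(),
               nj_agrees = logical(), stringsAsFactors = FALSE)
  ## NJ cross-check over all flagged-line replicates
  if (nj_mode != "off" && nrow(exclusions) && length(flagged_lines) >= 2L) {
    fl_idx <- which(ln %in% flagged_lines)
    if (length(fl_idx) >= 4L) {
      d <- 1 - sim[fl_idx, fl_idx]
      dimnames(d) <- list(ids[fl_idx], ids[fl_idx])
      tree <- ape::nj(d)
      tree$edge.length[tree$edge.length < 0] <- 0
      pathd <- ape::cophenetic.phylo(tree)
      for (r in seq_len(nrow(exclusions))) {
        cand <- exclusions$sample_id[r]
        keep <- ids[ln == exclusions$line_name[r]]
        keep <- setdiff(keep, exclusions$sample_id[exclusions$line_name ==
                                                     exclusions$line_name[r]])
        if (length(keep) >= 1L) {
          others <- setdiff(rownames(pathd), c(cand, keep))
          exclusions$nj_agrees[r] <-
            min(pathd[cand, others]) < min(pathd[cand, keep])
        }
      }
      if (nj_mode == "strict") {
        disagree <- !is.na(exclusions$nj_agrees) & !exclusions$nj_agrees
        if (any(disagree)) {
          for (l in unique(exclusions$line_name[disagree])) status[[l]] <- "UNRESOLVED"
          exclusions <- exclusions[!disagree, , drop = FALSE]
        }
      }
    }
  }
  line_status <- data.frame(line_name = names(status),
                            status = unlist(status, use.names = FALSE),
                            stringsAsFactors = FALSE)
  list(exclusions = exclusions, line_status = line_status)
}

#' Build the consensus reference fingerprint dataset
#'
#' Merges the biological replicates of every line into a per-line
#' consensus fingerprint and assembles the reference dataset:
#' \enumerate{
#'   \item replicates excluded by mislabel resolution are dropped;
#'   \item when any replicate of a line has residual heterozygosity
#'     below `het_max_pct` (default 3%), only those low-heterozygosity
#'     replicates are merged (the others are set aside with reason
#'     `HIGH_HET`); otherwise all remaining replicates are used;
#'   \item the survivors are merged marker by marker with
#'     [merge_replicates()], restricted to the retained marker set.
#' }
#' Lines typed on a marker subset are accepted; the per-line marker
#' coverage is recorded rather than enforced.  Lines left with no usable
#' replicate (or `UNRESOLVED` by mislabel resolution) are listed as
#' missing from the reference.
#'
#' @param gm a [genotype_matrix()] of all replicates.
#' @param retained_markers character vector of marker ids to keep
#'   (typically [filter_markers()] output); `NULL` keeps all.
#' @param purity purity table from [classify_purity()] (computed if
#'   absent).
#' @param exclusions exclusion decisions: the list returned by
#'   [resolve_mislabels()], or a data frame with columns `sample_id`,
#'   `reason`; `NULL` for none.
#' @param het_max_pct replicate heterozygosity (percent, exclusive
#'   upper bound) below which a replicate is preferred for merging.
#' @param missing_policy passed to [merge_replicates()].
#' @return an object of class `reference_dataset`: list with
#'   `genotypes` (consensus [genotype_matrix()], one pseudo-sample per
#'   line), `lines` (per-line `n_replicates_used`, `het_pct`,
#'   `missing_pct`, `n_markers_typed`), `provenance` (per input sample:
#'   used/excluded and reason), `missing_lines`, and `summary`
#'   (dataset-level mean heterozygosity, missing rate and MAF).
#' @export
build_reference <- function(gm, retained_markers = NULL, purity = NULL,
                            exclusions = NULL, het_max_pct = 3,
                            missing_policy = c("observed", "strict")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(purity)) purity <- classify_purity(gm)
  unresolved <- character(0)
  if (is.list(exclusions) && !is.data.frame(exclusions) &&
      !is.null(exclusions$exclusions)) {
    if (!is.null(exclusions$line_status)) {
      unresolved <- exclusions$line_status$line_name[
        exclusions$line_status$status == "UNRESOLVED"]
    }
    exclusions <- exclusions$exclusions
  }
  excl_ids <- if (is.null(exclusions)) character(0) else exclusions$sample_id
  if (!is.null(retained_markers)) {
    gm <- gm[, retained_markers]
  }
  het <- stats::setNames(purity$het_pct, purity$sample_id)
  ln <- gm$samples$line_name
  lines <- unique(ln)
  m <- n_markers(gm)
  cons <- matrix(NA_character_, length(lines), m,
                 dimnames = list(lines, gm$markers$marker_id))
  prov <- list()
  line_rows <- list()
  missing_lines <- character(0)
  for (i in seq_along(lines)) {
    l <- lines[i]
    idx <- which(ln == l)
    s_ids <- gm$samples$sample_id[idx]
    status <- rep("used", length(idx))
    reason <- rep(NA_character_, length(idx))
    is_excl <- s_ids %in% excl_ids
    status[is_excl] <- "excluded"
    reason[is_excl] <- if (is.null(exclusions)) NA_character_ else
      exclusions$reason[match(s_ids[is_excl], exclusions$sample_id)]
    usable <- which(!is_excl)
    if (l %in% unresolved) {
      status[!is_excl] <- "excluded"
      reason[!is_excl] <- "UNRESOLVED_LINE"
      usable <- integer(0)
    }
    if (length(usable)) {
      low <- usable[!is.na(het[s_ids[usable]]) &
                      het[s_ids[usable]] < het_max_pct]
      if (length(low)) {
        high <- setdiff(usable, low)
        status[high] <- "excluded"
        reason[high] <- "HIGH_HET"
        usable <- low
      }
    }
    prov[[i]] <- data.frame(line_name = l, sample_id = s_ids,
                            status = status, reason = reason,
                            stringsAsFactors = FALSE)
    if (!length(usable)) {
      missing_lines <- c(missing_lines, l)
      next
    }
    sub <- gm$calls[idx[usable], , drop = FALSE]
    if (nrow(sub) == 1L) {
      cons[i, ] <- sub[1L, ]
    } else {
      cons[i, ] <- apply(sub, 2L, merge_replicates,
                         missing_policy = missing_policy)
    }
    ncalled <- sum(!is.na(cons[i, ]))
    line_rows[[length(line_rows) + 1L]] <- data.frame(
      line_name = l,
      n_replicates_used = length(usable),
      het_pct = if (ncalled) 100 * sum(call_is_het(cons[i, ]), na.rm = TRUE) / ncalled else NA_real_,
      missing_pct = 100 * (m - ncalled) / m,
      n_markers_typed = ncalled,
      stringsAsFactors = FALSE)
  }
  keep <- !(lines %in% missing_lines)
  first_idx <- match(lines[keep], ln)
  cons_samples <- data.frame(
    sample_id = lines[keep],
    line_name = lines[keep],
    replicate_id = "consensus",
    subgroup = gm$samples$subgroup[first_idx],
    heterotic_group = gm$samples$heterotic_group[first_idx],
    stringsAsFactors = FALSE)
  cons_gm <- genotype_matrix(cons[keep, , drop = FALSE], cons_samples,
                             gm$markers, validate = FALSE)
  lines_df <- do.call(rbind, line_rows)
  stats <- compute_marker_stats(cons_gm)
  summary <- list(n_lines = nrow(lines_df),
                  n_markers = m,
                  mean_het_pct = mean(lines_df$het_pct, na.rm = TRUE),
                  mean_missing_pct = mean(lines_df$missing_pct, na.rm = TRUE),
                  mean_maf = mean(stats$maf, na.rm = TRUE))
  structure(list(genotypes = cons_gm, lines = lines_df,
                 provenance = do.call(rbind, prov),
                 missing_lines = missing_lines,
                 summary = summary),
            class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat("reference_dataset: ", x$summary$n_lines, " consensus fingerprints x ",
      x$summary$n_markers, " markers\n", sep = "")
  cat(sprintf("  mean het %.2f%%, mean missing %.2f%%, mean MAF %.3f\n",
              x$summary$mean_het_pct, x$summary$mean_missing_pct,
              x$summary$mean_maf))
  if (length(x$missing_lines)) {
    cat("  lines missing from reference: ",
        paste(x$missing_lines, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
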