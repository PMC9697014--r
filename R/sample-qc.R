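#' Classify per-sample seed purity
#'
#' For each sample (biological replicate), computes the residual
#' heterozygosity over non-missing calls and classifies the seed purity:
#' \itemize{
#'   \item `PURE`: heterozygosity below 1% — fully purified inbred seed;
#'   \item `BASIC`: heterozygosity from 1% to 5% — acceptable basic
#'     purity;
#'   \item `HETEROZYGOUS`: heterozygosity above 5% — impure seed lot.
#' }
#' Independently, `regenotype_flag` marks any replicate with
#' heterozygosity above 3%: lines with at least one such replicate are
#' candidates for a second round of genotyping.  The three levels
#' partition \[0, 100\] with no gaps or overlaps.
#'
#' @param gm a [genotype_matrix()].
#' @param pure_max upper bound (exclusive) of the PURE level, percent.
#' @param basic_max upper bound (inclusive) of the BASIC level, percent.
#' @param regenotype_min heterozygosity (exclusive) above which a
#'   replicate triggers re-genotyping, percent.
#' @return data frame with one row per sample: `sample_id`, `line_name`,
#'   `replicate_id`, `n_called`, `het_pct`, `missing_pct`,
#'   `purity_level`, `regenotype_flag`, `review` (`TRUE` for all-missing
#'   samples whose heterozygosity is undefined).
#' @export
classify_purity <- function(gm, pure_max = 1, basic_max = 5,
                            regenotype_min = 3) {
  stopifnot(inherits(gm, "genotype_matrix"), n_samples(gm) > 0)
  het <- call_is_het(gm$calls)
  n_called <- rowSums(!is.na(gm$calls))
  het_pct <- 100 * rowSums(het, na.rm = TRUE) / n_called  # NaN if 0 called
  het_pct[n_called == 0L] <- NA_real_
  missing_pct <- 100 * (n_markers(gm) - n_called) / n_markers(gm)
  level <- ifelse(het_pct < pure_max, "PURE",
                  ifelse(het_pct <= basic_max, "BASIC", "HETEROZYGOUS"))
  data.frame(sample_id = gm$samples$sample_id,
             line_name = gm$samples$line_name,
             replicate_id = gm$samples$replicate_id,
             n_called = n_called,
             het_pct = het_pct,
             missing_pct = missing_pct,
             purity_level = level,
             regenotype_flag = het_pct > regenotype_min,
             review = n_called == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allele-sharing similarity rate between two genotype vectors
#'
#' The similarity rate is the total number of identical alleles divided
#' by the total number of non-missing alleles, over markers non-missing
#' in *both* vectors (pairwise-complete).  Each compared marker
#' contributes two alleles; the shared count at a marker is the size of
#' the best pairing between the two allele multisets: identical calls
#' share 2 alleles, a homozygote and a heterozygote carrying that allele
#' share 1, calls with disjoint alleles share 0.  The value lies in
#' \[0, 1\], is symmetric, and is invariant to marker order.
#'
#' @param a,b character vectors of genotype calls at the same markers, in
#'   the same order (any token form accepted; canonicalized internally).
#' @return similarity rate, a fraction in \[0, 1\].
#' @seealso [ibs_distance()], which is `1 - similarity_rate()`.
#' @export
similarity_rate <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  a <- canonicalize_calls(a)
  b <- canonicalize_calls(b)
  shared <- shared_allele_count(a, b)
  ok <- !is.na(shared)
  if (!any(ok)) stop("no marker is non-missing in both vectors; similarity undefined")
  sum(shared[ok]) / (2 * sum(ok))
}

#' Classify the genetic identity of replicate pairs
#'
#' Scores all pairs of biological replicates within each line with the
#' allele-sharing [similarity_rate()] (in percent) and classifies each
#' pair:
#' \itemize{
#'   \item `ESSENTIALLY_IDENTICAL`: similarity above 99%;
#'   \item `IDENTICAL_WITH_DRIFT`: similarity above 95% and at most 99%
#'     — identical up to slight divergence from genetic drift;
#'   \item `ISSUE`: similarity at most 95% — a genetic identity problem
#'     or a mislabeled sample.
#' }
#' ISSUE pairs are further diagnosed from the replicates' own residual
#' heterozygosity: `IMPURITY` when similarity exceeds 85% and either
#' replicate has heterozygosity above 5%; `LIKELY_IMPURITY` when
#' similarity is at most 85% with such a heterozygous replicate; and
#' `LIKELY_MISLABEL` when similarity is at most 85% but both replicates
#' look like clean inbreds (heterozygosity at most 5%).  The diagnosis
#' thresholds are descriptive field rules, hence exposed as arguments.
#'
#' @param gm a [genotype_matrix()].
#' @param purity optional purity table from [classify_purity()]
#'   (computed if absent).
#' @param identical_min similarity (percent, exclusive) above which a
#'   pair is essentially identical.
#' @param drift_min similarity (percent, exclusive) above which a pair
#'   is identical-with-drift; at or below it the pair is an ISSUE.
#' @param mislabel_sim_max similarity (percent) at or below which an
#'   ISSUE is attributed to mislabeling rather than impurity alone.
#' @param het_issue_min replicate heterozygosity (percent, exclusive)
#'   above which impurity is the suspected cause.
#' @return data frame with one row per replicate pair: `line_name`,
#'   `sample_a`, `sample_b`, `similarity_pct`, `identity_class`,
#'   `diagnosis` (`NA` unless the pair is an ISSUE).  Lines with a
#'   single replicate are skipped with a warning.
#' @export
classify_identity <- function(gm, purity = NULL, identical_min = 99,
                              drift_min = 95, mislabel_sim_max = 85,
                              het_issue_min = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(purity)) purity <- classify_purity(gm)
  sim <- pairwise_similarity_matrix(gm$calls, gm$markers$alleles)
  het <- stats::setNames(purity$het_pct, purity$sample_id)
  lines <- split(seq_len(n_samples(gm)), gm$samples$line_name)
  singles <- names(lines)[lengths(lines) < 2L]
  if (length(singles)) {
    warning("line(s) with a single replicate skipped: ",
            paste(singles, collapse = ", "))
  }
  rows <- list()
  for (ln in names(lines)[lengths(lines) >= 2L]) {
    idx <- lines[[ln]]
    prs <- utils::combn(idx, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1L, k]; j <- prs[2L, k]
      s <- 100 * sim[i, j]
      ids <- gm$samples$sample_id[c(i, j)]
      cls <- if (is.nan(s)) NA_character_
             else if (s > identical_min) "ESSENTIALLY_IDENTICAL"
             else if (s > drift_min) "IDENTICAL_WITH_DRIFT"
             else "ISSUE"
      diag <- NA_character_
      if (!is.na(cls) && cls == "ISSUE") {
        maxhet <- max(het[ids], na.rm = TRUE)
        diag <- if (s > mislabel_sim_max && maxhet > het_issue_min) "IMPURITY"
                else if (s <= mislabel_sim_max && maxhet > het_issue_min) "LIKELY_IMPURITY"
                else if (s <= mislabel_sim_max) "LIKELY_MISLABEL"
                else NA_character_
      }
      rows[[length(rows) + 1L]] <-
        data.frame(line_name = ln, sample_a = ids[1L], sample_b = ids[2L],
                   similarity_pct = s, identity_class = cls,
                   diagnosis = diag, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(line_name = character(), sample_a = character(),
                      sample_b = character(), similarity_pct = numeric(),
                      identity_class = character(), diagnosis = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Screen for within-line distances exceeding between-line distances
#'
#' Flags a line when the genetic distance (1 - similarity) between its
#' own biological replicates exceeds the minimum distance from any of
#' its replicates to any replicate of a *different* line — the signature
#' of a replicate swap or mislabel.  Pairs of lines whose replicates are
#' mutually indistinguishable (distance 0 both within and between, e.g.
#' duplicated seed sources) are reported separately, not as mislabels.
#'
#' @param gm a [genotype_matrix()] with at least two lines.
#' @return list with `flags` (data frame: `line_name`,
#'   `max_within_dist`, `min_between_dist`, `nearest_other_line`,
#'   `flagged`) and `identical_pairs` (data frame of line pairs with
#'   between-line distance 0).
#' @export
cross_line_similarity_screen <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ln <- gm$samples$line_name
  if (length(unique(ln)) < 2L) stop("need at least two lines")
  d <- 1 - pairwise_similarity_matrix(gm$calls, gm$markers$alleles)
  diag(d) <- NA
  rows <- list()
  for (l in unique(ln)) {
    idx <- which(ln == l)
    if (length(idx) < 2L) next
    within <- d[idx, idx, drop = FALSE]
    max_within <- max(within, na.rm = TRUE)
    between <- d[idx, ln != l, drop = FALSE]
    min_between <- suppressWarnings(min(between, na.rm = TRUE))
    nb <- which(between == min_between, arr.ind = TRUE)[1L, ]
    nearest <- ln[ln != l][nb[["col"]]]
    rows[[length(rows) + 1L]] <-
      data.frame(line_name = l, max_within_dist = max_within,
                 min_between_dist = min_between,
                 nearest_other_line = nearest,
                 flagged = max_within > min_between,
                 stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, rows)
  ## indistinguishable line pairs: zero between-line distance
  ident <- list()
  ul <- unique(ln)
  for (i in seq_along(ul)) {
    for (j in seq_len(i - 1L)) {
      dij <- d[ln == ul[i], ln == ul[j], drop = FALSE]
      m <- suppressWarnings(min(dij, na.rm = TRUE))
      if (is.finite(m) && m == 0) {
        ident[[length(ident) + 1L]] <-
          data.frame(line_a = ul[j], line_b = ul[i],
                     min_between_dist = m, stringsAsFactors = FALSE)
      }
    }
  }
  identical_pairs <- if (length(ident)) do.call(rbind, ident) else
    data.frame(line_a = character(), line_b = character(),
               min_between_dist = numeric(), stringsAsFactors = FALSE)
  list(flags = flags, identical_pairs = identical_pairs)
}
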