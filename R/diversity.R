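#' Identity-by-state genetic distance between two genotype vectors
#'
#' `ibs_distance(a, b)` is exactly `1 - similarity_rate(a, b)`: one
#' minus the allele-sharing fraction over pairwise-complete markers.
#' The distance lies in \[0, 1\] and is symmetric; it is not guaranteed
#' to satisfy the triangle inequality.
#'
#' @inheritParams similarity_rate
#' @return IBS distance in \[0, 1\].
#' @export
ibs_distance <- function(a, b) 1 - similarity_rate(a, b)

#' Pairwise IBS distance matrix
#'
#' Computes all unordered pairwise IBS distances among the lines of a
#' reference dataset (or the samples of a genotype matrix).
#'
#' @param x a [build_reference()] result or a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal, labelled by line
#'   name (reference) or sample id (genotype matrix).  Pairs with no
#'   mutually non-missing marker are `NA`, with a warning.
#' @export
distance_matrix <- function(x) {
  gm <- if (inherits(x, "reference_dataset")) x$genotypes else x
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) < 2L) stop("need at least two lines")
  d <- 1 - pairwise_similarity_matrix(gm$calls, gm$markers$alleles)
  if (any(is.nan(d))) {
    warning("pair(s) with no comparable marker: distance undefined (NA)")
    d[is.nan(d)] <- NA_real_
  }
  diag(d) <- 0
  d
}

#' Distance-distribution bins
#'
#' Tabulates the distribution of pairwise distances over unordered
#' distinct pairs into the intervals delimited by `breaks`
#' (\eqn{[0, b_1], (b_1, b_2], \dots, (b_k, 1]}), reporting the pair
#' fraction in each bin (fractions sum to 100%) plus, for each break,
#' the percentage of pairs strictly above it.  Exact-zero pairs
#' (indistinguishable fingerprints) and pairs below the relatedness
#' guard (default 0.05, the minimum distance expected between a new
#' line and any released line) are counted separately.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param breaks increasing break points in (0, 1).
#' @param guard relatedness guard threshold.
#' @return list with `bins` (data frame `lower`, `upper`, `n_pairs`,
#'   `pct`), `pct_greater` (named vector, % of pairs above each break),
#'   `n_pairs`, `n_zero`, `n_below_guard`, `mean_distance`.
#' @export
bin_distances <- function(dm, breaks = c(0.05, 0.10, 0.30, 0.50),
                          guard = 0.05) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  d <- dm[upper.tri(dm)]
  d <- d[!is.na(d)]
  edges <- c(-Inf, breaks, Inf)
  cnt <- as.integer(table(cut(d, edges)))
  bins <- data.frame(lower = c(0, breaks), upper = c(breaks, 1),
                     n_pairs = cnt, pct = 100 * cnt / length(d))
  pct_greater <- vapply(breaks, function(b) 100 * mean(d > b), numeric(1))
  names(pct_greater) <- paste0(">", as.character(breaks))
  list(bins = bins, pct_greater = pct_greater, n_pairs = length(d),
       n_zero = sum(d == 0), n_below_guard = sum(d < guard),
       mean_distance = mean(d))
}

#' Mean within- and between-group distances
#'
#' Computes the mean pairwise distance within each group (over unordered
#' distinct pairs) and between each pair of groups (over the full cross
#' product).  Used for adaptation subgroups (Lowland Tropical,
#' Subtropical/Mid-altitude, Highland Tropical, Temperate) and equally
#' for heterotic groups A/B.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param groups character vector of group labels, either named by the
#'   matrix labels or aligned with them; `NA` labels are dropped.
#' @return data frame: `group_a`, `group_b`, `type`
#'   (within/between), `mean_distance` (`NA` when a group has fewer
#'   than 2 members), `n_pairs`.
#' @export
subgroup_distances <- function(dm, groups) {
  stopifnot(is.matrix(dm))
  if (!is.null(names(groups))) {
    groups <- groups[rownames(dm)]
  } else if (length(groups) != nrow(dm)) {
    stop("groups must be named or match the distance matrix dimension")
  }
  keep <- !is.na(groups)
  dm <- dm[keep, keep, drop = FALSE]
  groups <- groups[keep]
  gl <- sort(unique(groups))
  rows <- list()
  for (i in seq_along(gl)) {
    for (j in seq_len(i)) {
      a <- which(groups == gl[j]); b <- which(groups == gl[i])
      if (i == j) {
        if (length(a) < 2L) {
          rows[[length(rows) + 1L]] <- data.frame(
            group_a = gl[j], group_b = gl[i], type = "within",
            mean_distance = NA_real_, n_pairs = 0L,
            stringsAsFactors = FALSE)
          next
        }
        sub <- dm[a, a, drop = FALSE]
        v <- sub[upper.tri(sub)]
        type <- "within"
      } else {
        v <- as.vector(dm[a, b, drop = FALSE])
        type <- "between"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gl[j], group_b = gl[i], type = type,
        mean_distance = mean(v, na.rm = TRUE), n_pairs = sum(!is.na(v)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Principal component analysis of fingerprints
#'
#' Encodes genotypes as minor-allele dosage (0/1/2), imputes missing
#' calls to the marker mean, centers each marker column (no variance
#' scaling), and eigen-decomposes the covariance via
#' [stats::prcomp()].  Explained-variance fractions are each
#' component's share of the total variance of the centered matrix; they
#' are non-increasing and sum to at most 1.
#'
#' @param x a [build_reference()] result or [genotype_matrix()].
#' @param n_components number of components to return.
#' @return list with `scores` (lines x components coordinate matrix),
#'   `explained` (variance fraction per returned component), `sdev`
#'   (all singular values / sqrt(n-1)).
#' @export
genotype_pca <- function(x, n_components = 3) {
  gm <- if (inherits(x, "reference_dataset")) x$genotypes else x
  stopifnot(inherits(gm, "genotype_matrix"), n_samples(gm) >= 2L,
            n_markers(gm) >= 2L)
  d <- dosage_encode(gm$calls, gm$markers$alleles)
  storage.mode(d) <- "double"
  ## orient to minor-allele dosage
  for (j in seq_len(ncol(d))) {
    mu <- mean(d[, j], na.rm = TRUE)
    if (is.nan(mu)) { d[, j] <- 0; next }
    if (mu > 1) d[, j] <- 2 - d[, j]
    d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  }
  d <- scale(d, center = TRUE, scale = FALSE)
  if (all(abs(d) < .Machine$double.eps^0.5)) {
    stop("zero-variance genotype matrix: PCA undefined")
  }
  pc <- stats::prcomp(d, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], sdev = pc$sdev)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted binary tree by Saitou-Nei neighbor joining
#' (via [ape::nj()]) and, by default, clamps negative branch-length
#' estimates to zero, transferring the deficit to the sibling edge so
#' that path lengths are approximately preserved.  The result is
#' serializable to Newick with [ape::write.tree()].
#'
#' @param dm symmetric distance matrix with labels.
#' @param clamp_negative clamp negative branch lengths (default `TRUE`).
#' @return an [ape::phylo] tree; with fewer than 3 labels a degenerate
#'   two-leaf tree is returned with a warning.
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (nrow(dm) < 3L) {
    warning("fewer than 3 labels: returning degenerate single-edge tree")
    lab <- rownames(dm)
    txt <- sprintf("(%s:%g,%s:%g);", lab[1L], dm[1L, 2L] / 2,
                   lab[2L], dm[1L, 2L] / 2)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(dm)
  if (clamp_negative && any(tree$edge.length < 0)) {
    neg <- which(tree$edge.length < 0)
    for (e in neg) {
      len <- tree$edge.length[e]
      parent <- tree$edge[e, 1L]
      sib <- which(tree$edge[, 1L] == parent)
      sib <- setdiff(sib, e)
      tree$edge.length[e] <- 0
      if (length(sib)) {
        tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + len
      }
    }
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Parent-conversion distance test
#'
#' A conversion line is derived from a recurrent parent by introgressing
#' a target trait and is expected to stay genetically close to that
#' parent.  For each (original, converted) pair the IBS distance is
#' looked up in the distance matrix and pairs exceeding the closeness
#' expectation are flagged.
#'
#' @param pairs data frame with columns `original` and `converted`
#'   (line names); extra columns (e.g. `relationship`) are carried
#'   through.
#' @param dm distance matrix over the reference lines.
#' @param max_expected flag threshold on the distance (default 0.2).
#' @return the `pairs` data frame with `distance` and `flagged` columns;
#'   pairs with a line absent from the matrix are dropped with a
#'   warning and reported in the `skipped` attribute.
#' @export
conversion_test <- function(pairs, dm, max_expected = 0.2) {
  stopifnot(all(c("original", "converted") %in% names(pairs)))
  present <- pairs$original %in% rownames(dm) &
    pairs$converted %in% rownames(dm)
  skipped <- pairs[!present, , drop = FALSE]
  if (nrow(skipped)) {
    warning("pair(s) skipped, line not in reference: ",
            paste(paste(skipped$original, skipped$converted, sep = "-"),
                  collapse = ", "))
  }
  pairs <- pairs[present, , drop = FALSE]
  pairs$distance <- dm[cbind(pairs$original, pairs$converted)]
  pairs$flagged <- pairs$distance > max_expected
  attr(pairs, "skipped") <- skipped
  pairs
}
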