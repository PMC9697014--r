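#' Per-marker summary statistics
#'
#' Computes, for every marker of a genotype matrix, the minor allele
#' frequency (MAF), heterozygosity rate, missing rate, polymorphic
#' information content (PIC) and mutation class that together drive the
#' marker filter cascade.
#'
#' Definitions (per marker):
#' \itemize{
#'   \item `maf` = minor-allele count / (2 x non-missing calls); each
#'     heterozygote contributes one copy of each allele.
#'   \item `het_pct` = heterozygous calls / non-missing calls x 100.
#'     The denominator is non-missing calls so that missingness does not
#'     dilute heterozygosity.
#'   \item `missing_pct` = missing calls / total samples x 100.
#'   \item `pic` = biallelic Botstein formula
#'     \eqn{1 - (p^2 + q^2) - 2 p^2 q^2} with allele frequencies p, q.
#'   \item `mutation_class`: one of `"A/G|T/C"`, `"A/C|G/T"`,
#'     `"A/T|C/G"`, determined solely by the marker's reference allele
#'     pair, collapsing strand complements.
#' }
#' A marker with all calls missing gets `missing_pct = 100` and `NA` for
#' `maf`, `het_pct`, `pic` (flagged, never dropped).
#'
#' @param gm a [genotype_matrix()].
#' @return data frame with one row per marker: `marker_id`, `maf`,
#'   `het_pct`, `missing_pct`, `pic`, `mutation_class`, `n_called`.
#' @export
compute_marker_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  n <- nrow(calls)
  out <- data.frame(marker_id = gm$markers$marker_id,
                    maf = NA_real_, het_pct = NA_real_,
                    missing_pct = NA_real_, pic = NA_real_,
                    mutation_class = mutation_class(gm$markers$alleles),
                    n_called = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    called <- !is.na(cj)
    nc <- sum(called)
    out$n_called[j] <- nc
    out$missing_pct[j] <- 100 * (n - nc) / n
    if (nc == 0L) next
    al <- c(call_allele1(cj[called]), call_allele2(cj[called]))
    cnt <- sort(table(al), decreasing = TRUE)
    p <- as.numeric(cnt[1L]) / (2 * nc)
    maf <- if (length(cnt) > 1L) as.numeric(cnt[2L]) / (2 * nc) else 0
    out$maf[j] <- maf
    out$het_pct[j] <- 100 * sum(call_is_het(cj[called])) / nc
    q <- 1 - p
    out$pic[j] <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  }
  out
}

#' Mutation class of a biallelic marker
#'
#' Assigns each reference allele pair to one of the three
#' complementary-pair SNP mutation classes: transitions `"A/G|T/C"`,
#' and the two transversion classes `"A/C|G/T"` and `"A/T|C/G"`.
#'
#' @param alleles character vector of canonical `"X/Y"` allele pairs.
#' @return character vector of class labels (`NA` for degenerate or
#'   missing pairs).
#' @export
mutation_class <- function(alleles) {
  map <- c("A/G" = "A/G|T/C", "C/T" = "A/G|T/C",
           "A/C" = "A/C|G/T", "G/T" = "A/C|G/T",
           "A/T" = "A/T|C/G", "C/G" = "A/T|C/G")
  out <- unname(map[alleles])
  out[is.na(alleles)] <- NA_character_
  out
}

#' Marker filter thresholds
#'
#' The filter cascade retains a marker only if its heterozygosity rate,
#' missing rate and MAF are all acceptable.  Defaults are the reference
#' pipeline values: heterozygosity at most 5%, missing rate at most 10%,
#' MAF at least 0.05.
#'
#' @param max_het_pct maximum heterozygosity rate, percent.
#' @param max_missing_pct maximum missing rate, percent.
#' @param min_maf minimum minor allele frequency.
#' @param inclusive if `TRUE` (default), markers exactly at a boundary
#'   are retained (exclusion is strictly "greater than" / "lower than");
#'   if `FALSE`, boundary markers are excluded.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_het_pct = 5, max_missing_pct = 10,
                              min_maf = 0.05, inclusive = TRUE) {
  stopifnot(max_het_pct > 0, max_het_pct < 100,
            max_missing_pct > 0, min_maf >= 0)
  structure(list(max_het_pct = max_het_pct,
                 max_missing_pct = max_missing_pct,
                 min_maf = min_maf, inclusive = inclusive),
            class = "filter_thresholds")
}

#' Apply the marker filter cascade
#'
#' Retains a marker iff `het_pct <= max_het_pct` AND
#' `missing_pct <= max_missing_pct` AND `maf >= min_maf` (strict
#' inequalities when `inclusive = FALSE`).  The exclusion report names
#' the first failing criterion per excluded marker, checked in the order
#' HET, MISS, MAF.  Markers with undefined MAF (all calls missing) fail
#' MISS at any usable threshold.
#'
#' @param stats marker statistics from [compute_marker_stats()].
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `retained` (character vector of marker ids) and
#'   `exclusions` (data frame `marker_id`, `reason` in HET/MISS/MAF,
#'   plus the offending value).
#' @export
filter_markers <- function(stats, thresholds = filter_thresholds()) {
  if (!nrow(stats)) stop("empty marker statistics table")
  stopifnot(inherits(thresholds, "filter_thresholds"))
  gt <- if (thresholds$inclusive) `>` else `>=`
  lt <- if (thresholds$inclusive) `<` else `<=`
  fail_het <- !is.na(stats$het_pct) & gt(stats$het_pct, thresholds$max_het_pct)
  fail_miss <- gt(stats$missing_pct, thresholds$max_missing_pct)
  fail_maf <- is.na(stats$maf) | lt(stats$maf, thresholds$min_maf)
  reason <- rep(NA_character_, nrow(stats))
  value <- rep(NA_real_, nrow(stats))
  reason[fail_maf] <- "MAF";  value[fail_maf] <- stats$maf[fail_maf]
  reason[fail_miss] <- "MISS"; value[fail_miss] <- stats$missing_pct[fail_miss]
  reason[fail_het] <- "HET";  value[fail_het] <- stats$het_pct[fail_het]
  excluded <- !is.na(reason)
  list(retained = stats$marker_id[!excluded],
       exclusions = data.frame(marker_id = stats$marker_id[excluded],
                               reason = reason[excluded],
                               value = value[excluded],
                               stringsAsFactors = FALSE))
}

#' Per-chromosome marker summary
#'
#' Summarizes marker statistics by chromosome: marker count and mean MAF,
#' heterozygosity and missing rate per chromosome, an overall row, and
#' the mean number of markers per numbered chromosome (labels 1-10;
#' contig-anchored markers, chromosome `"0"` or a contig name, are
#' excluded from that mean but keep their own row).
#'
#' @param stats marker statistics from [compute_marker_stats()].
#' @param markers marker metadata table (must cover every marker in
#'   `stats`).
#' @return list with `per_chromosome` (data frame), `overall` (one-row
#'   data frame of means) and `mean_markers_per_chromosome` (numeric).
#' @export
summarize_by_chromosome <- function(stats, markers) {
  idx <- match(stats$marker_id, markers$marker_id)
  if (anyNA(idx)) {
    stop("marker(s) without metadata: ",
         paste(stats$marker_id[is.na(idx)], collapse = ", "))
  }
  chrom <- as.character(markers$chromosome[idx])
  agg <- function(v) tapply(v, chrom, mean, na.rm = TRUE)
  tab <- data.frame(chromosome = names(agg(stats$maf)),
                    n_markers = as.integer(table(chrom)[names(agg(stats$maf))]),
                    mean_maf = as.numeric(agg(stats$maf)),
                    mean_het_pct = as.numeric(agg(stats$het_pct)),
                    mean_missing_pct = as.numeric(agg(stats$missing_pct)),
                    stringsAsFactors = FALSE)
  ## order numbered chromosomes numerically, others after
  num <- suppressWarnings(as.numeric(tab$chromosome))
  tab <- tab[order(is.na(num), num, tab$chromosome), , drop = FALSE]
  rownames(tab) <- NULL
  overall <- data.frame(n_markers = nrow(stats),
                        mean_maf = mean(stats$maf, na.rm = TRUE),
                        mean_het_pct = mean(stats$het_pct, na.rm = TRUE),
                        mean_missing_pct = mean(stats$missing_pct, na.rm = TRUE))
  numbered <- tab$chromosome %in% as.character(1:10)
  mean_per_chrom <- if (any(numbered)) mean(tab$n_markers[numbered]) else NA_real_
  list(per_chromosome = tab, overall = overall,
       mean_markers_per_chromosome = mean_per_chrom)
}
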