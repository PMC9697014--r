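#' Construct a genotype matrix
#'
#' The central container of the pipeline: an ordered set of samples, an
#' ordered set of biallelic markers, and a samples x markers grid of
#' unordered diploid genotype calls with missing-data support.
#'
#' @param calls character matrix (samples x markers) of genotype tokens;
#'   normalized with [canonicalize_calls()].
#' @param samples data frame with columns `sample_id`, `line_name`,
#'   `replicate_id` and optional `subgroup`, `heterotic_group`.  One row
#'   per row of `calls`.
#' @param markers data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `alleles` (canonical `"X/Y"` reference pair) and
#'   optional `trait_tag`.  One row per column of `calls`.  May be `NULL`,
#'   in which case marker ids are taken from `colnames(calls)` and the
#'   allele pair of each marker is inferred from the observed calls.
#' @param validate validate invariants (recommended; see
#'   [validate_genotype_matrix()]).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `calls`, `samples`, `markers`.
#' @details Positions are 1-based base pairs.  Markers anchored on
#'   unplaced contigs carry chromosome label `"0"` or a contig name.
#'   Duplicate `(line_name, replicate_id)` pairs are an error, never a
#'   silent overwrite.
#' @export
genotype_matrix <- function(calls, samples, markers = NULL, validate = TRUE) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  calls <- matrix(canonicalize_calls(calls), nrow = nrow(calls),
                  dimnames = dimnames(calls))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "line_name", "replicate_id")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("samples table lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (opt in c("subgroup", "heterotic_group")) {
    if (is.null(samples[[opt]])) samples[[opt]] <- NA_character_
    samples[[opt]][samples[[opt]] %in% c("", "NA")] <- NA_character_
  }
  samples <- samples[c(req, "subgroup", "heterotic_group")]
  if (is.null(markers)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("M%03d", seq_len(ncol(calls)))
    markers <- data.frame(marker_id = ids, chromosome = NA_character_,
                          position_bp = NA_integer_,
                          alleles = infer_marker_alleles(calls),
                          trait_tag = NA_character_,
                          stringsAsFactors = FALSE)
  } else {
    markers <- as.data.frame(markers, stringsAsFactors = FALSE)
    reqm <- c("marker_id", "chromosome", "position_bp", "alleles")
    missm <- setdiff(reqm, names(markers))
    if (length(missm)) {
      stop("markers table lacks column(s): ", paste(missm, collapse = ", "))
    }
    if (is.null(markers$trait_tag)) markers$trait_tag <- NA_character_
    markers$alleles <- canonicalize_calls(markers$alleles)
    markers <- markers[c(reqm, "trait_tag")]
    for (ch in c("chromosome", "trait_tag")) {
      markers[[ch]][markers[[ch]] %in% c("", "NA")] <- NA_character_
    }
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- markers$marker_id
  gm <- structure(list(calls = calls, samples = samples, markers = markers),
                  class = "genotype_matrix")
  if (validate) validate_genotype_matrix(gm)
  gm
}

## Observed allele pair per column, as canonical "X/Y"; monomorphic columns
## give a degenerate "X/X" pair, all-missing columns NA.
infer_marker_alleles <- function(calls) {
  apply(calls, 2L, function(cj) {
    al <- c(call_allele1(cj), call_allele2(cj))
    al <- al[!is.na(al)]
    if (!length(al)) return(NA_character_)
    u <- sort(unique(al))
    if (length(u) == 1L) u <- c(u, u)
    paste(u[1L], u[2L], sep = "/")
  })
}

#' Validate a genotype matrix
#'
#' Checks the container invariants: grid dimensions match the sample and
#' marker tables; `sample_id` and `marker_id` unique; no duplicate
#' `(line_name, replicate_id)` pair; every non-missing call draws both of
#' its alleles from its marker's reference allele pair.  Offending cells
#' are listed in the error message (never silently dropped).
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly, if valid; otherwise an error.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls; samples <- gm$samples; markers <- gm$markers
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers)) {
    stop("call grid is ", nrow(calls), " x ", ncol(calls),
         " but tables describe ", nrow(samples), " samples and ",
         nrow(markers), " markers")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  key <- paste(samples$line_name, samples$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key), c("line_name", "replicate_id")]
    stop("duplicate (line_name, replicate_id) pair(s): ",
         paste(paste(dup$line_name, dup$replicate_id, sep = "/"),
               collapse = ", "))
  }
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker_id: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
               collapse = ", "))
  }
  bad_cells <- character(0)
  for (j in seq_len(ncol(calls))) {
    ref <- markers$alleles[j]
    if (is.na(ref)) next
    ok_al <- c(call_allele1(ref), call_allele2(ref))
    cj <- calls[, j]
    bad <- !is.na(cj) &
      (!(call_allele1(cj) %in% ok_al) | !(call_allele2(cj) %in% ok_al))
    if (any(bad)) {
      bad_cells <- c(bad_cells,
                     paste0("marker ", markers$marker_id[j], ", sample ",
                            samples$sample_id[which(bad)], ": ",
                            cj[bad]))
    }
  }
  if (length(bad_cells)) {
    stop("call(s) inconsistent with marker reference alleles:\n  ",
         paste(utils::head(bad_cells, 20L), collapse = "\n  "),
         if (length(bad_cells) > 20L) "\n  ..." else "")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$calls))
  cat("genotype_matrix: ", nrow(x$samples), " samples x ",
      nrow(x$markers), " markers\n", sep = "")
  cat("  lines: ", length(unique(x$samples$line_name)),
      "; missing calls: ", nmiss, " (",
      sprintf("%.2f%%", 100 * nmiss / length(x$calls)), ")\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (integer, logical, or `sample_id` character).
#' @param j marker index (integer, logical, or `marker_id` character).
#' @param ... unused.
#' @return the subsetted `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$markers))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$markers$marker_id)
  if (anyNA(i)) stop("unknown sample_id in subset")
  if (anyNA(j)) stop("unknown marker_id in subset")
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$samples[i, , drop = FALSE],
                  x$markers[j, , drop = FALSE],
                  validate = FALSE)
}

#' Number of samples / markers
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' @rdname n_samples
#' @export
n_markers <- function(gm) nrow(gm$markers)
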