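## Standard 11 HapMap metadata columns.
HAPMAP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

WIDE_META <- c("sample_id", "line_name", "replicate_id", "subgroup",
               "heterotic_group")

#' Read a genotype table
#'
#' Reads a genotype matrix from one of the two layouts the pipeline
#' touches: the *wide-calls* CSV (one row per sample, one `"X/Y"` column
#' per marker, preceded by the sample-metadata columns `sample_id`,
#' `line_name`, `replicate_id`, `subgroup`, `heterotic_group`) or a
#' standard HapMap text file (tab-separated, 11 metadata columns, one
#' two-letter genotype column per sample, rows are markers).
#'
#' Missing tokens (`"--"`, `"NN"`, `"NA"`, `""`, ...) are normalized to
#' `NA` and allele pairs are canonicalized (sorted) on input; calls
#' inconsistent with a marker's reference alleles raise a validation
#' error listing the offending cells.
#'
#' @param path path to the file.
#' @param dialect `"wide"` or `"hapmap"`.
#' @param markers optional marker metadata table (see
#'   [read_marker_table()]); supplies reference allele pairs, chromosome
#'   and position for the wide dialect (HapMap carries its own).  When
#'   absent, allele pairs are inferred from the observed calls.
#' @param samples optional sample metadata table (`sample_id`,
#'   `line_name`, `replicate_id`, ...); useful with HapMap, whose columns
#'   carry only sample ids.  Without it, HapMap sample ids of the form
#'   `"LINE_REP"` are split at the last underscore.
#' @return a validated [genotype_matrix()].
#' @export
read_genotype_table <- function(path, dialect = c("wide", "hapmap"),
                                markers = NULL, samples = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "wide") {
    read_wide_calls(path, markers = markers)
  } else {
    read_hapmap(path, samples = samples)
  }
}

read_wide_calls <- function(path, markers = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  need <- c("sample_id", "line_name", "replicate_id")
  if (!all(need %in% names(df))) {
    stop("parse error at line 1 of ", path,
         ": wide-calls header must name columns ",
         paste(need, collapse = ", "))
  }
  meta_cols <- intersect(WIDE_META, names(df))
  marker_cols <- setdiff(names(df), WIDE_META)
  if (!length(marker_cols)) {
    stop("parse error at line 1 of ", path, ": no marker columns found")
  }
  samples <- df[meta_cols]
  calls <- as.matrix(df[marker_cols])
  if (!is.null(markers)) {
    miss <- setdiff(markers$marker_id, marker_cols)
    if (length(miss)) {
      stop("marker(s) in metadata absent from ", path, ": ",
           paste(miss, collapse = ", "))
    }
    calls <- calls[, markers$marker_id, drop = FALSE]
  }
  genotype_matrix(calls, samples, markers)
}

read_hapmap <- function(path, samples = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  if (ncol(df) < 12L || names(df)[1L] != HAPMAP_META[1L]) {
    stop("parse error at line 1 of ", path,
         ": not a HapMap header (expected first column 'rs#' and >= 12 columns)")
  }
  sample_ids <- names(df)[-seq_along(HAPMAP_META)]
  markers <- data.frame(marker_id = df[["rs#"]],
                        chromosome = df[["chrom"]],
                        position_bp = as.integer(df[["pos"]]),
                        alleles = canonicalize_calls(df[["alleles"]]),
                        trait_tag = NA_character_,
                        stringsAsFactors = FALSE)
  calls <- t(as.matrix(df[sample_ids]))  # samples x markers
  if (is.null(samples)) {
    line <- sub("_[^_]*$", "", sample_ids)
    rep <- ifelse(grepl("_", sample_ids), sub("^.*_", "", sample_ids), "1")
    samples <- data.frame(sample_id = sample_ids, line_name = line,
                          replicate_id = rep, stringsAsFactors = FALSE)
  } else {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    idx <- match(sample_ids, samples$sample_id)
    if (anyNA(idx)) {
      stop("sample(s) in ", path, " absent from sample metadata: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    samples <- samples[idx, , drop = FALSE]
  }
  genotype_matrix(calls, samples, markers)
}

#' Write a genotype table
#'
#' Writes a [genotype_matrix()] in either dialect.  Missing calls are
#' written as `"--"` in the wide dialect and `"NN"` in HapMap.  The
#' round-trip `read_genotype_table(write_genotype_table(m))` is the
#' identity on the call grid for both dialects (the wide dialect also
#' round-trips sample metadata; HapMap also round-trips marker metadata).
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param dialect `"wide"` or `"hapmap"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path, dialect = c("wide", "hapmap")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (dialect == "wide") {
    calls <- gm$calls
    calls[is.na(calls)] <- "--"
    df <- cbind(gm$samples, as.data.frame(calls, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    two <- matrix(paste0(call_allele1(gm$calls), call_allele2(gm$calls)),
                  nrow = nrow(gm$calls))
    two[is.na(gm$calls)] <- "NN"
    meta <- data.frame(gm$markers$marker_id, gm$markers$alleles,
                       gm$markers$chromosome, gm$markers$position_bp,
                       "+", NA, NA, NA, NA, NA, NA,
                       stringsAsFactors = FALSE, check.names = FALSE)
    names(meta) <- HAPMAP_META
    body <- as.data.frame(t(two), check.names = FALSE)
    names(body) <- gm$samples$sample_id
    utils::write.table(cbind(meta, body), path, sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read / write a marker metadata table
#'
#' Marker metadata CSV: columns `marker_id`, `chromosome`, `position_bp`,
#' `alleles` (reference allele pair, `"X/Y"`), optional `trait_tag`
#' (e.g. PVA, MSV, MLN, QPM, TSC for breeder-ready trait markers).
#'
#' @param path path to the CSV file.
#' @return data frame of marker records.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("marker_id", "chromosome", "position_bp", "alleles")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parse error at line 1 of ", path, ": marker table lacks column(s) ",
         paste(miss, collapse = ", "))
  }
  df$position_bp <- as.integer(df$position_bp)
  df$alleles <- canonicalize_calls(df$alleles)
  bad <- !is.na(df$alleles) &
    call_allele1(df$alleles) == call_allele2(df$alleles)
  if (any(bad)) {
    stop("marker(s) with non-distinct reference alleles: ",
         paste(df$marker_id[bad], collapse = ", "))
  }
  if (is.null(df$trait_tag)) df$trait_tag <- NA_character_
  df[c(need, "trait_tag")]
}

#' @rdname read_marker_table
#' @param markers data frame of marker records.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
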