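#' @keywords internal
"_PACKAGE"

## Tokens accepted as missing on input.  KASP exports are inconsistent;
## everything is normalized once, at the boundary.
MISSING_TOKENS <- c("--", "NN", "NA", "N/A", "", "?", "./.", ".")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Canonicalize genotype call tokens
#'
#' Normalizes a character vector of diploid genotype tokens to the canonical
#' unordered form `"X/Y"` with alleles sorted alphabetically, or `NA` for
#' missing.  Accepted input forms are `"X/Y"`, `"X|Y"`, `"X:Y"`, the
#' two-letter HapMap form `"XY"`, and the missing tokens `"--"`, `"NN"`,
#' `"NA"`, `""`, `"?"`, `"./."`.  Half-calls (one allele missing) are
#' invalid: a call carries either both alleles or none.
#'
#' @param x character vector of genotype tokens.
#' @return character vector of the same length with entries `"X/Y"`
#'   (X \eqn{\le} Y alphabetically) or `NA_character_`.
#' @examples
#' canonicalize_calls(c("G/A", "AG", "NN", "--", "T:T"))
#' @export
canonicalize_calls <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  x <- trimws(x)
  miss <- is.na(x) | x %in% MISSING_TOKENS
  if (all(miss)) return(out)
  y <- toupper(x[!miss])
  y <- gsub("[|:]", "/", y)
  nosep <- !grepl("/", y, fixed = TRUE) & nchar(y) == 2L
  y[nosep] <- paste(substr(y[nosep], 1L, 1L), substr(y[nosep], 2L, 2L), sep = "/")
  a1 <- substr(y, 1L, 1L)
  a2 <- substr(y, 3L, 3L)
  bad <- nchar(y) != 3L | substr(y, 2L, 2L) != "/" |
    !(a1 %in% VALID_ALLELES) | !(a2 %in% VALID_ALLELES)
  if (any(bad)) {
    stop("invalid genotype token(s): ",
         paste(unique(x[!miss][bad]), collapse = ", "),
         call. = FALSE)
  }
  out[!miss] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  out
}

## First and second allele of canonical calls (NA-safe).
call_allele1 <- function(x) substr(x, 1L, 1L)
call_allele2 <- function(x) substr(x, 3L, 3L)

#' Heterozygosity indicator for canonical calls
#'
#' @param x character vector of canonical calls (`"X/Y"` or `NA`).
#' @return logical vector: `TRUE` for heterozygous, `FALSE` for homozygous,
#'   `NA` for missing.
#' @export
call_is_het <- function(x) {
  ifelse(is.na(x), NA, call_allele1(x) != call_allele2(x))
}

## Number of shared alleles between two canonical calls at the same marker:
## the size of the best pairing between the two allele multisets
## (2 for identical calls, 1 for one allele in common, 0 for disjoint).
## Vectorized; NA where either call is missing.
shared_allele_count <- function(a, b) {
  a1 <- call_allele1(a); a2 <- call_allele2(a)
  b1 <- call_allele1(b); b2 <- call_allele2(b)
  s1 <- (a1 == b1) + (a2 == b2)
  s2 <- (a1 == b2) + (a2 == b1)
  out <- pmax(s1, s2)
  out[is.na(a) | is.na(b)] <- NA_integer_
  out
}

## Dosage encoding of a call matrix: per marker, the count (0/1/2) of the
## alphabetically larger allele of the marker's reference pair.  NA stays NA.
## `alleles` is the markers' canonical "X/Y" pair vector (one per column).
dosage_encode <- function(calls, alleles) {
  stopifnot(ncol(calls) == length(alleles))
  ref2 <- call_allele2(alleles)
  d <- matrix(NA_integer_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    d[, j] <- (call_allele1(cj) == ref2[j]) + (call_allele2(cj) == ref2[j])
  }
  d
}

## Pairwise allele-sharing similarity between the rows of a canonical call
## matrix, over pairwise-complete markers.  Returns an n x n matrix of
## fractions in [0,1]; NaN where two rows share no non-missing marker.
## Uses the 3-genotype indicator decomposition of the per-pair mismatch
## count so the whole computation is six matrix products.
pairwise_similarity_matrix <- function(calls, alleles) {
  d <- dosage_encode(calls, alleles)
  n <- !is.na(d)
  d0 <- d; d0[!n] <- 0L
  i0 <- (d0 == 0L) & n
  i1 <- (d0 == 1L) & n
  i2 <- (d0 == 2L) & n
  storage.mode(i0) <- "double"
  storage.mode(i1) <- "double"
  storage.mode(i2) <- "double"
  nn <- matrix(as.double(n), nrow(d))
  mismatch <- i0 %*% t(i1) + i1 %*% t(i0) +
    i1 %*% t(i2) + i2 %*% t(i1) +
    2 * (i0 %*% t(i2) + i2 %*% t(i0))
  ncomp <- nn %*% t(nn)
  sim <- 1 - mismatch / (2 * ncomp)   # NaN where ncomp == 0
  dimnames(sim) <- list(rownames(calls), rownames(calls))
  sim
}
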