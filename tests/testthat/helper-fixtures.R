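## Shared fixture builders and independent oracles.

## Build a genotype_matrix from a token matrix; one row per sample.
## `lines`/`reps` default to one line per sample, replicate "R1".
make_gm <- function(calls, lines = NULL, reps = NULL, subgroup = NULL,
                    markers = NULL, validate = TRUE) {
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1)
  n <- nrow(calls)
  if (is.null(lines)) lines <- sprintf("L%02d", seq_len(n))
  if (is.null(reps)) {
    reps <- stats::ave(seq_len(n), lines, FUN = seq_along)
    reps <- paste0("R", reps)
  }
  samples <- data.frame(sample_id = paste(lines, reps, sep = "_"),
                        line_name = lines, replicate_id = reps,
                        subgroup = if (is.null(subgroup)) NA_character_ else subgroup,
                        stringsAsFactors = FALSE)
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("M%02d", seq_len(ncol(calls)))
  }
  genotype_matrix(calls, samples, markers, validate = validate)
}

## Independent allele-by-allele similarity oracle: explicit multiset
## matching per marker, no shared code with similarity_rate().
oracle_similarity <- function(a, b) {
  shared <- 0L; compared <- 0L
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    aa <- sort(strsplit(a[i], "/", fixed = TRUE)[[1]])
    bb <- sort(strsplit(b[i], "/", fixed = TRUE)[[1]])
    compared <- compared + 2L
    for (al in aa) {
      j <- match(al, bb)
      if (!is.na(j)) {
        shared <- shared + 1L
        bb <- bb[-j]
      }
    }
  }
  shared / compared
}

## Random biallelic call vector over a fixed allele pair per marker.
random_calls <- function(m, alleles = NULL, miss_rate = 0.1) {
  if (is.null(alleles)) {
    alleles <- replicate(m, paste(sort(sample(c("A", "C", "G", "T"), 2)),
                                  collapse = "/"))
  }
  a1 <- substr(alleles, 1, 1); a2 <- substr(alleles, 3, 3)
  g <- sample(0:2, m, replace = TRUE)
  out <- ifelse(g == 0, paste0(a1, "/", a1),
                ifelse(g == 1, paste0(a1, "/", a2), paste0(a2, "/", a2)))
  out[runif(m) < miss_rate] <- NA
  list(calls = out, alleles = alleles)
}

## Small two-replicate two-line panel where line "LX" replicates differ
## at `k_diff` of `m` markers (opposite homozygotes).
two_rep_line <- function(m, k_diff = 0, k_het_b = 0) {
  base <- rep("A/A", m)
  repb <- base
  if (k_diff > 0) repb[seq_len(k_diff)] <- "G/G"
  if (k_het_b > 0) repb[m - seq_len(k_het_b) + 1] <- "A/G"
  rbind(base, repb)
}
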