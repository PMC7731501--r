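#' Count matrix with transcript lengths
#'
#' Container for a transcripts-by-samples matrix of non-negative integer
#' counts plus per-transcript lengths in bp.
#'
#' @param counts numeric matrix with transcript row names and sample column
#'   names; values must be non-negative integers.
#' @param lengths named positive integer vector covering every transcript.
#' @return object of class \code{count_matrix} with elements \code{counts}
#'   and \code{lengths}.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs transcript row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths))) stop("lengths missing for some transcripts")
  if (any(lengths < 1)) stop("lengths must be >= 1 bp")
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

# 75th percentile of counts-per-million; edgeR's reference-selection statistic
.quantile_cpm <- function(counts, lib_sizes, p = 0.75) {
  apply(counts, 2, stats::quantile, probs = p) / lib_sizes
}

# single-pair TMM factor of sample obs against sample ref
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  if (length(o) == 0) return(1)
  po <- o / n_obs; pr <- r / n_ref
  m <- log2(po / pr)
  a <- 0.5 * log2(po * pr)
  # inverse asymptotic variance of M, on the proportion scale so that the
  # factor is exactly invariant to rescaling either library's depth
  w <- (1 - po) / po + (1 - pr) / pr
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  sel <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(1)
  f <- sum(m[sel] / w[sel]) / sum(1 / w[sel])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values: for each sample against a reference sample, the
#' factor is 2 to the inverse-variance-weighted mean of per-transcript
#' log2 ratios (M-values) after trimming the top and bottom \code{trim_m}
#' fraction of M-values and \code{trim_a} fraction of A-values. Transcripts
#' with a zero count in either member of a pair are dropped from that pair
#' only. Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()] or plain counts matrix.
#' @param trim_m,trim_a tail fractions trimmed from the M- and A-value
#'   distributions (each side).
#' @param ref reference sample name or index; by default the sample whose
#'   75th-percentile count-per-million is closest to the mean across samples.
#' @return named numeric vector of per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stop("all-zero sample column: ", paste(colnames(counts)[zero], collapse = ", "))
  if (is.null(ref)) {
    f75 <- .quantile_cpm(counts, lib)
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) {
    ref <- match(ref, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else
      .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Effective library sizes
#'
#' @param counts a [count_matrix()] or counts matrix.
#' @param factors TMM factors; computed with [tmm_factors()] when omitted.
#' @return named vector of library size times TMM factor per sample.
#' @export
effective_lib_sizes <- function(counts, factors = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(factors)) factors <- tmm_factors(counts)
  colSums(counts) * factors[colnames(counts)]
}

#' FPKM against effective library sizes
#'
#' fpkm[i, j] = counts[i, j] * 1e9 / (length_i * effective_size_j).
#'
#' @param counts a [count_matrix()], or a plain matrix if \code{lengths}
#'   given.
#' @param effective_sizes per-sample positive effective library sizes.
#' @param lengths per-transcript lengths (bp); taken from the
#'   \code{count_matrix} when omitted.
#' @return matrix of FPKM values.
#' @export
compute_fpkm <- function(counts, effective_sizes, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lengths)) lengths <- counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) stop("lengths required")
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (any(effective_sizes <= 0)) stop("effective library sizes must be positive")
  sweep(counts / lengths, 2, effective_sizes, "/") * 1e9
}

#' Log2-transform (and optionally row-center) an FPKM matrix
#'
#' @param fpkm non-negative matrix.
#' @param pseudocount positive value added before log2.
#' @param center_rows if TRUE every row is centered to mean 0.
#' @return matrix of log2(fpkm + pseudocount), optionally row-centered.
#' @export
log_center <- function(fpkm, pseudocount = 1, center_rows = TRUE) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(fpkm < 0)) stop("fpkm must be non-negative")
  x <- log2(fpkm + pseudocount)
  if (center_rows) x <- x - rowMeans(x)
  x
}

#' One-call normalization summary
#'
#' Computes TMM factors, library sizes, effective sizes, FPKM and the
#' log2-transformed (optionally centered) expression matrix.
#'
#' @inheritParams tmm_factors
#' @inheritParams log_center
#' @return list with \code{tmm_factor}, \code{lib_size},
#'   \code{effective_size}, \code{fpkm}, \code{log_expression} and a
#'   per-sample summary data.frame \code{table}.
#' @export
normalize_counts <- function(counts, trim_m = 0.30, trim_a = 0.05,
                             pseudocount = 1, center_rows = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  f <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a)
  lib <- colSums(counts$counts)
  eff <- lib * f
  fpkm <- compute_fpkm(counts, eff)
  list(tmm_factor = f, lib_size = lib, effective_size = eff, fpkm = fpkm,
       log_expression = log_center(fpkm, pseudocount, center_rows),
       table = data.frame(sample = colnames(counts$counts), lib_size = lib,
                          tmm_factor = f, effective_size = eff,
                          row.names = NULL, stringsAsFactors = FALSE))
}
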