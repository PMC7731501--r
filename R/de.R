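#' Pairwise comparison specification
#'
#' @param group_a,group_b disjoint sample id vectors, each of length >= 2.
#' @param label human-readable comparison label.
#' @param min_total_count a transcript is "expressed" in this comparison when
#'   its total raw count over both groups reaches this value.
#' @return object of class \code{comparison_spec}.
#' @export
comparison_spec <- function(group_a, group_b, label = "A vs B",
                            min_total_count = 10) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  structure(list(group_a = group_a, group_b = group_b, label = label,
                 min_total_count = min_total_count),
            class = "comparison_spec")
}

# rescale counts to a common (geometric-mean) effective library size and
# round to integers; expectation-matching quantile adjustment
.adjust_counts <- function(counts, eff_sizes) {
  target <- exp(mean(log(eff_sizes)))
  round(sweep(counts, 2, target / eff_sizes, "*"))
}

# summed conditional NB log-likelihood of phi for one group of
# equal-library-size counts (rows = transcripts)
.cond_loglik <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) - rowSums(lgamma(y + 1)) -
    (lgamma(z + n * r) - lgamma(n * r) - lgamma(z + 1))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Counts are quantile-adjusted to a common effective library size, then the
#' dispersion maximizing the summed conditional log-likelihood over
#' transcripts and groups is found by 1-D bounded search.
#'
#' @param counts a [count_matrix()] or counts matrix.
#' @param spec a [comparison_spec()].
#' @param interval search interval for phi.
#' @param tol optimizer tolerance.
#' @return list with \code{phi}, \code{interval}, \code{loglik}.
#' @export
estimate_common_dispersion <- function(counts, spec, interval = c(1e-6, 10),
                                       tol = 1e-4) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  a <- counts[, spec$group_a, drop = FALSE]
  b <- counts[, spec$group_b, drop = FALSE]
  expressed <- rowSums(a) + rowSums(b) >= spec$min_total_count
  if (!any(expressed)) stop("no expressed transcripts in this comparison")
  sub <- counts[expressed, c(spec$group_a, spec$group_b), drop = FALSE]
  eff <- effective_lib_sizes(sub)
  adj <- .adjust_counts(sub, eff)
  ya <- adj[, spec$group_a, drop = FALSE]
  yb <- adj[, spec$group_b, drop = FALSE]
  ll <- function(phi) sum(.cond_loglik(ya, phi)) + sum(.cond_loglik(yb, phi))
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE, tol = tol)
  list(phi = opt$maximum, interval = interval, loglik = opt$objective)
}

#' Exact negative-binomial p-value for two group sums
#'
#' Conditional on the total s = sum_a + sum_b, group sums are independent
#' negative binomials (sums of n iid NB(mu, phi) draws are NB(n mu, phi/n)).
#' The two-sided p-value sums, over all splits (a, s - a), the conditional
#' probabilities no larger than that of the observed split
#' (minimum-likelihood method, the default) or doubles the smaller tail
#' (\code{method = "doubletail"}); either is capped at 1. phi = 0 reduces to
#' the conditional Poisson, i.e. an exact binomial test.
#'
#' @param sum_a,sum_b non-negative integer group sums of (library-adjusted)
#'   counts.
#' @param n_a,n_b numbers of replicates behind each sum.
#' @param phi non-negative common dispersion.
#' @param method "smallp" or "doubletail".
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_pvalue <- function(sum_a, sum_b, n_a, n_b, phi,
                            method = c("smallp", "doubletail")) {
  method <- match.arg(method)
  if (phi < 0) stop("phi must be >= 0")
  s <- sum_a + sum_b
  if (s == 0) return(1)
  mu <- s / (n_a + n_b)
  splits <- 0:s
  if (phi == 0) {
    pa <- stats::dpois(splits, n_a * mu)
    pb <- stats::dpois(s - splits, n_b * mu)
  } else {
    pa <- stats::dnbinom(splits, size = n_a / phi, mu = n_a * mu)
    pb <- stats::dnbinom(s - splits, size = n_b / phi, mu = n_b * mu)
  }
  joint <- pa * pb
  tot <- sum(joint)
  p_obs <- joint[sum_a + 1]
  p <- if (method == "smallp") {
    sum(joint[joint <= p_obs * (1 + 1e-12)]) / tot
  } else {
    lower <- sum(joint[splits <= sum_a]) / tot
    upper <- sum(joint[splits >= sum_a]) / tot
    2 * min(lower, upper)
  }
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector in [0, 1].
#' @return step-up adjusted q-values (empty input gives empty output).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the DET thresholds to a differential-expression table
#'
#' A transcript is a differentially expressed transcript (DET) when its
#' BH-adjusted q-value is at most \code{fdr_max} and |log2FC| is at least
#' \code{min_abs_log2fc}. Direction follows the sign of log2FC (B over A).
#'
#' @param table data.frame with columns transcript, logFC, p, q.
#' @param fdr_max FDR cut-off.
#' @param min_abs_log2fc minimum absolute log2 fold change.
#' @param label comparison label carried into the summary.
#' @return object of class \code{de_result}: the augmented table plus the
#'   comparison totals n_expressed, n_DET, pct_DET (round-half-up to 2
#'   decimals), n_up_A, n_up_B.
#' @export
call_dets <- function(table, fdr_max = 0.001, min_abs_log2fc = 5,
                      label = "A vs B") {
  stopifnot(all(c("transcript", "logFC", "p", "q") %in% names(table)))
  is_det <- table$q <= fdr_max & abs(table$logFC) >= min_abs_log2fc
  direction <- ifelse(!is_det, "none",
                      ifelse(table$logFC > 0, "up_in_B", "up_in_A"))
  table$is_DET <- is_det
  table$direction <- direction
  n_exp <- nrow(table)
  n_det <- sum(is_det)
  structure(list(table = table, label = label,
                 n_expressed = n_exp, n_DET = n_det,
                 pct_DET = round_half_up(100 * n_det / max(n_exp, 1), 2),
                 n_up_A = sum(direction == "up_in_A"),
                 n_up_B = sum(direction == "up_in_B"),
                 fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("%s: %d expressed, %d DETs (%s%%), up in A %d / up in B %d\n",
              x$label, x$n_expressed, x$n_DET, format_pct(x$n_DET, x$n_expressed),
              x$n_up_A, x$n_up_B))
  invisible(x)
}

#' Round half away from zero
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a DET percentage the way summary tables print it
#'
#' @param n_det,n_expressed counts.
#' @return character like "23.34" (round-half-up, two decimals).
#' @export
format_pct <- function(n_det, n_expressed) {
  sprintf("%.2f", round_half_up(100 * n_det / n_expressed, 2))
}

#' Pairwise exact-test differential expression
#'
#' Runs the whole comparison: expression gate, TMM normalization on the two
#' groups' samples, common-dispersion estimation (unless supplied), the
#' exact negative-binomial test per transcript, BH adjustment and the DET
#' call. log2FC is B over A, computed from group sums of adjusted counts
#' with a 0.5 pseudocount.
#'
#' @param counts a [count_matrix()] or counts matrix.
#' @param spec a [comparison_spec()].
#' @param phi common dispersion; estimated by
#'   [estimate_common_dispersion()] when NULL.
#' @param fdr_max,min_abs_log2fc DET thresholds.
#' @param method exact-test two-sided method, see [nb_exact_pvalue()].
#' @return a \code{de_result} (see [call_dets()]) with the dispersion used
#'   stored as \code{phi}.
#' @export
run_exact_de <- function(counts, spec, phi = NULL, fdr_max = 0.001,
                         min_abs_log2fc = 5, method = "smallp") {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  missing <- setdiff(c(spec$group_a, spec$group_b), colnames(counts))
  if (length(missing) > 0)
    stop("samples absent from counts: ", paste(missing, collapse = ", "))
  if (is.null(phi)) phi <- estimate_common_dispersion(counts, spec)$phi
  sub <- counts[, c(spec$group_a, spec$group_b), drop = FALSE]
  expressed <- rowSums(sub) >= spec$min_total_count
  sub <- sub[expressed, , drop = FALSE]
  if (nrow(sub) == 0) stop("no expressed transcripts in this comparison")
  eff <- effective_lib_sizes(sub)
  adj <- .adjust_counts(sub, eff)
  n_a <- length(spec$group_a); n_b <- length(spec$group_b)
  sa <- rowSums(adj[, spec$group_a, drop = FALSE])
  sb <- rowSums(adj[, spec$group_b, drop = FALSE])
  p <- vapply(seq_along(sa), function(i)
    nb_exact_pvalue(sa[i], sb[i], n_a, n_b, phi, method = method), numeric(1))
  logfc <- log2((sb + 0.5) / n_b) - log2((sa + 0.5) / n_a)
  tab <- data.frame(transcript = rownames(sub), logFC = logfc, p = p,
                    q = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  res <- call_dets(tab, fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                   label = spec$label)
  res$phi <- phi
  res
}
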