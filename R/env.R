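# median of the chi-squared distribution with 1 df, to 7 digits
CHISQ1_MEDIAN <- 0.4549364

# pull the numeric soil-variable block out of a soil table
.soil_matrix <- function(table) {
  miss <- setdiff(soil_variables, colnames(table))
  if (length(miss) > 0)
    stop("soil table lacks variables: ", paste(miss, collapse = ", "))
  x <- as.matrix(table[, soil_variables])
  if (any(is.na(x))) stop("soil table contains missing values")
  storage.mode(x) <- "double"
  rownames(x) <- if ("site" %in% colnames(table)) table$site else rownames(table)
  x
}

#' PCA of a soil-geochemistry table
#'
#' Standardizes the 14 variables (unless \code{standardize = FALSE}), runs a
#' principal component analysis and orients PC1 so its loading on Na is
#' non-negative, giving a reproducible edaphic predictor. PC1 scores are the
#' predictor used by [fit_lfmm_ridge()].
#'
#' @param table soil table with the 14 [soil_variables] columns.
#' @param standardize scale columns to unit variance.
#' @return list with \code{scores}, \code{loadings}, \code{var_explained}
#'   (proportions summing to 1) and \code{pc1} (named PC1 scores).
#' @export
soil_pca <- function(table, standardize = TRUE) {
  x <- .soil_matrix(table)
  if (nrow(x) < 3) stop("PCA needs at least 3 sites")
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0))
    stop("zero-variance soil variable: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  if (fit$rotation["Na", 1] < 0) {
    fit$rotation[, 1] <- -fit$rotation[, 1]
    fit$x[, 1] <- -fit$x[, 1]
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation, var_explained = ve,
       pc1 = stats::setNames(fit$x[, 1], rownames(x)))
}

#' Linear discriminant analysis of soil sites
#'
#' Discriminant directions maximize the ratio of between- to within-group
#' variance, found as eigenvectors of W^-1 B where W is the pooled
#' within-group covariance and B the between-group covariance. Because soil
#' designs often have fewer sites than variables, W is ridge-regularized by
#' epsilon = 1e-8 * trace(W)/p (or more if still singular). Coefficients are
#' scaled so each discriminant has unit pooled within-group variance, and at
#' most (number of groups - 1) discriminants are returned.
#'
#' @param table soil table.
#' @param groups group label per site; defaults to the table's group column.
#' @return list with \code{coefficients} (variables x discriminants),
#'   \code{scores} (sites x discriminants), \code{eigenvalues} and
#'   \code{group_means}.
#' @export
soil_lda <- function(table, groups = table$group) {
  x <- .soil_matrix(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stop("one group label per site required")
  tab <- table(groups)
  if (length(tab) < 2) stop("LDA needs >= 2 groups")
  if (any(tab < 2))
    stop("each group needs >= 2 sites; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  p <- ncol(x)
  gm <- rowsum(x, groups) / as.vector(tab[sort(unique(groups))])
  gm <- gm[unique(groups), , drop = FALSE]
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  for (g in rownames(gm)) {
    xc <- sweep(x[groups == g, , drop = FALSE], 2, gm[g, ])
    W <- W + crossprod(xc)
  }
  W <- W / (nrow(x) - nrow(gm))
  B <- matrix(0, p, p)
  for (g in rownames(gm)) {
    d <- gm[g, ] - grand
    B <- B + sum(groups == g) * tcrossprod(d)
  }
  B <- B / (nrow(gm) - 1)
  eps <- max(1e-8 * sum(diag(W)) / p, 1e-12)
  Wr <- W + diag(eps, p)
  while (kappa(Wr) > 1e12) {
    eps <- eps * 100
    Wr <- W + diag(eps, p)
  }
  eg <- eigen(solve(Wr, B))
  ord <- order(Re(eg$values), decreasing = TRUE)
  k <- min(nrow(gm) - 1, p)
  vec <- Re(eg$vectors[, ord[seq_len(k)], drop = FALSE])
  # unit within-group variance per discriminant (MASS scaling convention)
  for (j in seq_len(k)) {
    s <- sqrt(drop(t(vec[, j]) %*% Wr %*% vec[, j]))
    vec[, j] <- vec[, j] / s
  }
  dimnames(vec) <- list(colnames(x), paste0("LD", seq_len(k)))
  scores <- sweep(x, 2, grand) %*% vec
  list(coefficients = vec, scores = scores,
       eigenvalues = Re(eg$values[ord[seq_len(k)]]), group_means = gm)
}

# Frobenius objective of the ridge latent-factor model
.lfmm_objective <- function(Y, X, U, V, B, lambda) {
  R <- Y - U %*% t(V) - X %*% t(B)
  sum(R^2) + lambda * sum(B^2)
}

#' Ridge latent factor mixed model
#'
#' Minimizes ||Y - U V' - X B'||_F^2 + lambda ||B||_F^2 over latent factors
#' U (samples x K), loadings V (transcripts x K) and effects B
#' (transcripts x d). Profiling B out of the objective leaves
#' ||(I - P)^(1/2) (Y - U V')||_F^2 with P = X (X'X + lambda I)^-1 X', whose
#' rank-K minimizer is a truncated SVD in the transformed sample space
#' (Eckart-Young), so the global optimum is available in closed form; the
#' fit starts there and then applies exact block-coordinate updates (SVD for
#' (U, V) given B, per-transcript ridge for B given (U, V)) until the
#' relative objective change drops below \code{tol}. Each block update is an
#' exact minimizer, so the stored objective trace never increases.
#'
#' @param Y samples x transcripts response matrix; columns are centered
#'   internally.
#' @param X samples x d predictor matrix (or vector); centered and scaled
#'   internally.
#' @param K number of latent factors (0 <= K < number of samples).
#' @param lambda positive ridge penalty.
#' @param tol relative-objective convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with \code{U}, \code{V}, \code{B}, \code{lambda},
#'   \code{objective} (final value), \code{trace} (per-iteration values) and
#'   \code{iterations}.
#' @export
fit_lfmm_ridge <- function(Y, X, K = 2, lambda = 1e-5, tol = 1e-8,
                           max_iter = 500) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("X and Y need the same number of samples")
  if (K >= n) stop("K must be smaller than the number of samples")
  if (lambda <= 0) stop("lambda must be positive")
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- scale(X, center = TRUE, scale = FALSE)
  xsd <- apply(X, 2, stats::sd)
  X[, xsd > 0] <- sweep(X[, xsd > 0, drop = FALSE], 2, xsd[xsd > 0], "/")
  d <- ncol(X)
  p <- ncol(Y)
  B <- matrix(0, p, d)
  U <- matrix(0, n, max(K, 1))[, seq_len(K), drop = FALSE]
  V <- matrix(0, p, max(K, 1))[, seq_len(K), drop = FALSE]
  XtX <- crossprod(X)
  ridge_inv <- solve(XtX + diag(lambda, d))
  if (K > 0) {
    # closed-form global solution: rank-K Eckart-Young in the sample space
    # transformed by the matrix square root of I - X (X'X + lambda)^-1 X'
    P <- X %*% ridge_inv %*% t(X)
    ea <- eigen(diag(n) - P, symmetric = TRUE)
    ev <- pmax(ea$values, 0)
    Dhalf <- ea$vectors %*% (sqrt(ev) * t(ea$vectors))
    Dhalf_inv <- ea$vectors %*% (1 / sqrt(pmax(ev, 1e-12)) * t(ea$vectors))
    sv <- svd(Dhalf %*% Y, nu = K, nv = K)
    W <- Dhalf_inv %*% sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
    # split W into factors and loadings for reporting
    sw <- svd(W, nu = K, nv = K)
    U <- sw$u %*% diag(sw$d[seq_len(K)], K)
    V <- sw$v
  }
  B <- t(ridge_inv %*% crossprod(X, Y - U %*% t(V)))
  trace <- .lfmm_objective(Y, X, U, V, B, lambda)
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (K > 0) {
      sv <- svd(Y - X %*% t(B), nu = K, nv = K)
      U <- sv$u %*% diag(sv$d[seq_len(K)], K)
      V <- sv$v
    }
    B <- t(ridge_inv %*% crossprod(X, Y - U %*% t(V)))
    obj <- .lfmm_objective(Y, X, U, V, B, lambda)
    trace <- c(trace, obj)
    if (obj > trace[length(trace) - 1] + 1e-8 * max(1, abs(obj)))
      stop("objective increased; this indicates a numerical problem")
    rel <- abs(trace[length(trace) - 1] - obj) / max(1, abs(obj))
    if (rel < tol) break
  }
  obj <- trace[length(trace)]
  list(U = U, V = V, B = B, lambda = lambda, objective = obj,
       trace = trace, iterations = it, X = X, Y = Y)
}

#' Per-transcript association tests given fitted latent factors
#'
#' Ordinary least squares of each (centered) transcript on the design
#' [intercept, X, U]; the z-score is the t-statistic of the X coefficient
#' and the raw p-value uses the normal approximation.
#'
#' @param Y samples x transcripts matrix (or a fit from
#'   [fit_lfmm_ridge()], in which case X and U default to its).
#' @param X predictor column.
#' @param U latent factor matrix.
#' @return data.frame with transcript, effect, z, p.
#' @export
association_tests <- function(Y, X = NULL, U = NULL) {
  if (is.list(Y) && !is.null(Y$U)) {
    fit <- Y
    Y <- fit$Y
    if (is.null(X)) X <- fit$X
    if (is.null(U)) U <- fit$U
  }
  Y <- as.matrix(Y)
  D <- cbind(intercept = 1, X = as.matrix(X), U)
  if (qr(D)$rank < ncol(D)) stop("rank-deficient design")
  n <- nrow(D)
  H <- solve(crossprod(D))
  beta <- H %*% crossprod(D, Y)
  resid <- Y - D %*% beta
  df <- n - ncol(D)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * H[2, 2])
  z <- beta[2, ] / se
  data.frame(transcript = colnames(Y) %||% paste0("t", seq_len(ncol(Y))),
             effect = beta[2, ], z = z,
             p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic-inflation calibration of association z-scores
#'
#' The genomic inflation factor is median(z^2) divided by the chi-squared(1)
#' median 0.4549364; calibrated p-values are the upper chi-squared(1) tail
#' of z^2 / lambda_gif.
#'
#' @param z numeric vector of at least 10 z-scores.
#' @param alpha significance threshold for the calibrated p-values.
#' @return list with \code{lambda_gif}, \code{p_calibrated},
#'   \code{significant} (logical) and \code{alpha}.
#' @export
gif_calibrate <- function(z, alpha = 0.05) {
  if (length(z) < 10) stop("need at least 10 z-scores")
  lambda_gif <- stats::median(z^2) / CHISQ1_MEDIAN
  if (lambda_gif == 0) stop("all z-scores are zero; inflation factor degenerate")
  p_cal <- stats::pchisq(z^2 / lambda_gif, df = 1, lower.tail = FALSE)
  list(lambda_gif = lambda_gif, p_calibrated = p_cal,
       significant = p_cal < alpha, alpha = alpha)
}
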