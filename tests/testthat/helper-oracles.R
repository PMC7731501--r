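# Independent straight-line oracles used across the suite. Each reimplements
# the quantity it checks from the definition, without calling the package's
# own code path.

# TMM factor for one sample pair, by explicit sorting/trimming
oracle_tmm_pair <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  po <- obs[keep] / n_obs
  pr <- ref[keep] / n_ref
  m <- log2(po / pr)
  a <- 0.5 * log2(po * pr)
  w <- (1 - po) / po + (1 - pr) / pr
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  sel <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

# exact conditional NB p-value by enumeration, pmf written out via lgamma
oracle_exact_p <- function(sum_a, sum_b, n_a, n_b, phi) {
  s <- sum_a + sum_b
  if (s == 0) return(1)
  mu <- s / (n_a + n_b)
  lnb <- function(y, n) {
    if (phi == 0) return(-n * mu + y * log(n * mu) - lfactorial(y))
    r <- n / phi
    lgamma(y + r) - lgamma(r) - lfactorial(y) +
      r * log(r / (r + n * mu)) + y * log(n * mu / (r + n * mu))
  }
  lp <- vapply(0:s, function(a) lnb(a, n_a) + lnb(s - a, n_b), numeric(1))
  pr <- exp(lp - max(lp))
  obs <- pr[sum_a + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr))
}

# rule-by-rule inheritance classifier, written independently of the
# vectorized decision table
oracle_classify <- function(ab, ah, bh) {
  h_above_a <- ah == "second_higher"; h_below_a <- ah == "first_higher"
  h_above_b <- bh == "second_higher"; h_below_b <- bh == "first_higher"
  if (ab == "none" && ah == "none" && bh == "none") return("conserved")
  if (h_above_a && h_above_b) return("transgressive_up")
  if (h_below_a && h_below_b) return("transgressive_down")
  if ((h_above_a && h_below_b) || (h_below_a && h_above_b)) return("additive")
  if (ah == "none" && bh != "none") return("dominantA")
  if (bh == "none" && ah != "none") return("dominantB")
  "ambiguous"
}

# generic multi-restart minimizer of the ridge LFMM objective
oracle_lfmm <- function(Y, X, K, lambda, restarts = 20, seed = 1) {
  Y <- scale(Y, scale = FALSE)
  X <- scale(as.matrix(X))
  n <- nrow(Y); p <- ncol(Y); d <- ncol(X)
  unpack <- function(par) list(U = matrix(par[1:(n * K)], n, K),
                               V = matrix(par[n * K + 1:(p * K)], p, K),
                               B = matrix(par[n * K + p * K + 1:(p * d)], p, d))
  fn <- function(par) {
    th <- unpack(par)
    R <- Y - th$U %*% t(th$V) - X %*% t(th$B)
    sum(R^2) + lambda * sum(th$B^2)
  }
  gr <- function(par) {
    th <- unpack(par)
    R <- Y - th$U %*% t(th$V) - X %*% t(th$B)
    c(-2 * R %*% th$V, -2 * t(R) %*% th$U, -2 * t(R) %*% X + 2 * lambda * th$B)
  }
  set.seed(seed)
  best <- Inf
  for (i in seq_len(restarts)) {
    o <- stats::optim(stats::rnorm(n * K + p * K + p * d), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = 2000, factr = 1e1, pgtol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# one-sided two-sample KS statistic D+ = sup (F_x - F_y), by brute force
oracle_ks_dplus <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1)))
}

# counts -> samples x transcripts log2(FPKM + 1) matrix (uncentered)
build_log_fpkm <- function(cm) {
  eff <- effective_lib_sizes(cm)
  t(log_center(compute_fpkm(cm, eff), pseudocount = 1, center_rows = FALSE))
}

# mirror a de_result as if its two groups had been swapped
flip_de <- function(de) {
  de$table$logFC <- -de$table$logFC
  de$table$direction <- c(up_in_A = "up_in_B", up_in_B = "up_in_A",
                          none = "none")[de$table$direction]
  tmp <- de$n_up_A; de$n_up_A <- de$n_up_B; de$n_up_B <- tmp
  de
}

# three-group sample sets from simulated metadata
taxon_samples <- function(md, taxon) md$sample[md$taxon == taxon]
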