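#' The fourteen soil variables measured at each site
#'
#' Variable roster used throughout the soil module: pH, organic matter (OM),
#' cation exchange capacity (CEC), sum of bases (SB), base saturation
#' percentage (BSP), aluminum saturation percentage (ASP), potential acidity
#' (PA), and extractable/exchangeable P, K, Ca, Na, S, Al and Mg.
#'
#' @export
soil_variables <- c("pH", "OM", "CEC", "SB", "BSP", "ASP", "PA",
                    "P", "K", "Ca", "Na", "S", "Al", "Mg")

#' Inheritance modes recognized by the simulator and classifier
#' @export
inheritance_modes <- c("conserved", "additive", "dominantA", "dominantB",
                       "transgressive_up", "transgressive_down")

#' Simulation configuration for hybrid-zone count data
#'
#' Describes a three-group (two parental taxa plus their hybrids) RNA-seq
#' sampling design with negative-binomial counts, a configurable mixture of
#' inheritance modes, optional latent confounders and an optional edaphic
#' gradient acting on a subset of transcripts.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param replicates_per_group biological replicates per group (>= 2).
#' @param mode_fractions named non-negative proportions over
#'   \code{inheritance_modes}; must sum to 1. Transcripts left over after
#'   rounding are assigned to \code{conserved}.
#' @param base_mean expected count of a conserved transcript at library
#'   factor 1.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param effect_log2fc true |log2 fold change| separating groups for
#'   non-conserved modes (see Details).
#' @param lib_size_range range of relative library-size factors; factors are
#'   drawn log-uniformly within it.
#' @param n_latent number of latent confounder axes.
#' @param latent_sd standard deviation of per-transcript latent loadings on
#'   the log2 scale (0 disables the contribution).
#' @param env_effect_fraction proportion of transcripts whose expression
#'   tracks the environmental predictor.
#' @param env_effect_size log2-scale slope per unit of the predictor for
#'   environment-associated transcripts.
#' @param length_range integer range of transcript lengths in bp.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#'
#' @details Group offsets on the log2 scale, with e = \code{effect_log2fc}
#'   and s a per-transcript sign alternating within each mode so neither
#'   parent accumulates all up-regulation: conserved (0, 0, 0);
#'   additive (+e s, -e s, 0) so the hybrid sits at the parental midpoint and
#'   parents differ by 2e; dominantA (+e/2 s, -e/2 s, +e/2 s) so the hybrid
#'   matches parent A while parents differ by e; dominantB is the mirror;
#'   transgressive_up (0, 0, +e) and transgressive_down (0, 0, -e) place the
#'   hybrid outside the parental range.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_transcripts = 1000L,
                       replicates_per_group = 4L,
                       mode_fractions = c(conserved = 0.70, additive = 0.06,
                                          dominantA = 0.06, dominantB = 0.06,
                                          transgressive_up = 0.06,
                                          transgressive_down = 0.06),
                       base_mean = 100,
                       dispersion = 0.1,
                       effect_log2fc = 6,
                       lib_size_range = c(0.5, 2),
                       n_latent = 0L,
                       latent_sd = 0,
                       env_effect_fraction = 0,
                       env_effect_size = 0,
                       length_range = c(300L, 3000L),
                       seed = 1L) {
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (replicates_per_group != round(replicates_per_group))
    stop("replicates_per_group must be an integer")
  if (replicates_per_group < 2) stop("replicates_per_group must be >= 2")
  mf <- mode_fractions[inheritance_modes]
  mf[is.na(mf)] <- 0
  names(mf) <- inheritance_modes
  if (any(mf < 0)) stop("mode_fractions must be non-negative")
  if (abs(sum(mf) - 1) > 1e-9) stop("mode_fractions must sum to 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (base_mean <= 0) stop("base_mean must be positive")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0))
    stop("lib_size_range must be two positive values")
  if (env_effect_fraction < 0 || env_effect_fraction > 1)
    stop("env_effect_fraction must be a proportion")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 replicates_per_group = as.integer(replicates_per_group),
                 mode_fractions = mf,
                 base_mean = base_mean,
                 dispersion = dispersion,
                 effect_log2fc = effect_log2fc,
                 lib_size_range = sort(as.numeric(lib_size_range)),
                 n_latent = as.integer(n_latent),
                 latent_sd = latent_sd,
                 env_effect_fraction = env_effect_fraction,
                 env_effect_size = env_effect_size,
                 length_range = sort(as.integer(length_range)),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-mode transcript counts: round each non-conserved mode,
# hand the remainder to "conserved"
mode_counts_from_fractions <- function(mf, n) {
  others <- setdiff(inheritance_modes, "conserved")
  cnt <- round(mf[others] * n)
  n_cons <- n - sum(cnt)
  if (n_cons < 0) stop("mode fractions leave no room for conserved remainder")
  c(conserved = n_cons, cnt)
}

#' Simulate a three-group hybrid-zone count matrix with known truth
#'
#' Draws negative-binomial counts for two parental groups and their hybrids
#' under the group-mean structure described in [sim_config()], with
#' log-uniform library-size factors, optional latent confounders and an
#' optional uniform(-1, 1) environmental predictor affecting a flagged subset
#' of transcripts. A single RNG stream is seeded once for sample-level draws;
#' per-transcript sub-streams are derived by fixed seed offsets so extending
#' the transcript set does not reshuffle earlier transcripts.
#'
#' @param config a [sim_config()] object.
#' @param zone label stored in the sample metadata.
#' @return a list with elements \code{counts} (a [count_matrix()]),
#'   \code{metadata} (sample, taxon, zone), and \code{truth} (per-transcript
#'   mode, true group log2 offsets and environment flag, plus per-sample
#'   latent factors, environmental predictor and library factors).
#' @export
simulate_counts <- function(config, zone = "zone1") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  r <- config$replicates_per_group
  ns <- 3L * r
  taxa <- rep(c("parentA", "parentB", "hybrid"), each = r)
  samples <- paste0(rep(c("A", "B", "H"), each = r), seq_len(r))

  set.seed(config$seed)
  lsr <- log(config$lib_size_range)
  lib <- exp(stats::runif(ns, lsr[1], lsr[2]))
  U <- if (config$n_latent > 0)
    matrix(stats::rnorm(ns * config$n_latent), ns, config$n_latent)
  else matrix(0, ns, 0)
  env_x <- stats::runif(ns, -1, 1)
  lengths <- sample(seq(config$length_range[1], config$length_range[2]),
                    n, replace = TRUE)
  n_env <- round(config$env_effect_fraction * n)
  env_flag <- logical(n)
  if (n_env > 0) env_flag[sort(sample.int(n, n_env))] <- TRUE

  cnt <- mode_counts_from_fractions(config$mode_fractions, n)
  modes <- rep(names(cnt), cnt)
  e <- config$effect_log2fc
  # per-transcript parental sign, alternating within each mode
  sgn <- stats::ave(seq_len(n), modes, FUN = function(i) {
    rep_len(c(1, -1), length(i))
  })
  off <- matrix(0, n, 3, dimnames = list(NULL, c("parentA", "parentB", "hybrid")))
  off[modes == "additive", ] <- cbind(e, -e, 0)[rep(1, sum(modes == "additive")), , drop = FALSE]
  off[modes == "dominantA", ] <- cbind(e / 2, -e / 2, e / 2)[rep(1, sum(modes == "dominantA")), , drop = FALSE]
  off[modes == "dominantB", ] <- cbind(e / 2, -e / 2, -e / 2)[rep(1, sum(modes == "dominantB")), , drop = FALSE]
  off[modes == "transgressive_up", 3] <- e
  off[modes == "transgressive_down", 3] <- -e
  flip <- modes %in% c("additive", "dominantA", "dominantB")
  off[flip, ] <- off[flip, , drop = FALSE] * sgn[flip]

  ids <- sprintf("t%05d", seq_len(n))
  counts <- matrix(0L, n, ns, dimnames = list(ids, samples))
  group_idx <- match(taxa, c("parentA", "parentB", "hybrid"))
  phi <- config$dispersion
  loadings <- matrix(0, n, max(config$n_latent, 0))
  for (i in seq_len(n)) {
    set.seed((config$seed + 104729L + i) %% 2147483647L)
    w <- if (config$n_latent > 0) stats::rnorm(config$n_latent, sd = config$latent_sd) else numeric(0)
    if (config$n_latent > 0) loadings[i, ] <- w
    log2mu <- log2(config$base_mean) + off[i, group_idx]
    if (config$n_latent > 0) log2mu <- log2mu + as.numeric(U %*% w)
    if (env_flag[i]) log2mu <- log2mu + config$env_effect_size * env_x
    mu <- lib * 2^log2mu
    counts[i, ] <- if (phi > 0)
      stats::rnbinom(ns, mu = mu, size = 1 / phi)
    else stats::rpois(ns, lambda = mu)
  }

  truth <- list(
    transcripts = data.frame(transcript = ids, mode = modes,
                             log2_offset_parentA = off[, 1],
                             log2_offset_parentB = off[, 2],
                             log2_offset_hybrid = off[, 3],
                             env_associated = env_flag,
                             stringsAsFactors = FALSE),
    latent = U, loadings = loadings, env_predictor = env_x,
    lib_factor = lib)
  metadata <- data.frame(sample = samples, taxon = taxa, zone = zone,
                         stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, stats::setNames(lengths, ids)),
       metadata = metadata, truth = truth)
}

# built-in synthetic group means for the 14 soil variables: parentA emulates a
# sand-dune profile (higher pH and Na), parentB a seasonally flooded swale
# (more organic matter, acidity and Al), hybrids intermediate
default_soil_means <- function() {
  m <- rbind(
    parentA = c(pH = 6.2, OM = 15, CEC = 40, SB = 25, BSP = 60, ASP = 5,
                PA = 15, P = 5, K = 1.2, Ca = 15, Na = 3.5, S = 8, Al = 1, Mg = 8),
    parentB = c(pH = 4.8, OM = 60, CEC = 120, SB = 60, BSP = 45, ASP = 25,
                PA = 60, P = 12, K = 2.5, Ca = 30, Na = 1.0, S = 20, Al = 8, Mg = 18),
    hybrid = c(pH = 5.5, OM = 35, CEC = 80, SB = 40, BSP = 50, ASP = 15,
               PA = 35, P = 8, K = 1.8, Ca = 20, Na = 2.0, S = 14, Al = 4, Mg = 12))
  m[, soil_variables]
}

#' Simulate a soil-geochemistry table
#'
#' Draws multivariate-normal rows per site around group-specific means for
#' the fixed 14-variable roster in [soil_variables].
#'
#' @param site_counts named integer vector of sites per group.
#' @param group_means matrix (groups x 14 variables) of means; defaults to a
#'   built-in synthetic dune/swale/intermediate profile.
#' @param covariance 14 x 14 positive-semidefinite covariance shared by all
#'   groups; defaults to a diagonal matrix with standard deviations equal to
#'   15\% of each variable's grand mean.
#' @param seed integer seed.
#' @return data.frame with columns site, group, then the 14 variables.
#' @export
simulate_soil <- function(site_counts = c(parentA = 6, parentB = 6, hybrid = 6),
                          group_means = NULL, covariance = NULL, seed = 1L) {
  if (is.null(group_means)) group_means <- default_soil_means()
  if (is.null(dim(group_means)) || !all(soil_variables %in% colnames(group_means)))
    stop("group_means must be a matrix with all 14 soil variables: ",
         paste(soil_variables, collapse = ", "))
  group_means <- group_means[, soil_variables, drop = FALSE]
  if (!all(names(site_counts) %in% rownames(group_means)))
    stop("every group in site_counts needs a row of group_means")
  p <- length(soil_variables)
  if (is.null(covariance)) covariance <- diag((0.15 * colMeans(group_means))^2, p)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(dim(covariance), c(p, p))))
    stop("covariance must be 14 x 14")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance is not positive-semidefinite")
  set.seed(seed)
  rows <- lapply(names(site_counts), function(g) {
    k <- site_counts[[g]]
    x <- MASS::mvrnorm(k, mu = group_means[g, ], Sigma = covariance)
    x <- matrix(x, nrow = k, dimnames = list(NULL, soil_variables))
    data.frame(site = paste0(g, "_", seq_len(k)), group = g, x,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a toy GO DAG and gene annotations
#'
#' Builds a random single-rooted acyclic term graph of bounded depth and a
#' direct gene-to-term annotation table (true-path propagation is left to
#' [propagate_annotations()]). Terms flagged in \code{enriched_terms} carry a
#' strength used by [simulate_gene_scores()] to concentrate small scores on
#' their genes.
#'
#' @param n_terms number of terms including the single root.
#' @param max_depth maximum depth (>= 2 unless \code{n_terms} is 1).
#' @param genes character vector of gene identifiers.
#' @param annotation_density probability a given gene is directly annotated
#'   to a given non-root term.
#' @param enriched_terms named numeric vector term -> enrichment strength
#'   (1 = null); may be empty.
#' @param seed integer seed.
#' @return list with \code{dag} (a [go_dag()]), \code{annotations}
#'   (data.frame gene, term) and \code{enriched}.
#' @export
simulate_go <- function(n_terms = 30L, max_depth = 4L, genes,
                        annotation_density = 0.08,
                        enriched_terms = numeric(0), seed = 1L) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (n_terms > 1 && max_depth < 2) stop("max_depth must be >= 2")
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  if (anyDuplicated(ids)) stop("duplicate term ids")
  set.seed(seed)
  edges <- NULL
  depth <- c(0L, rep(NA_integer_, n_terms - 1))
  if (n_terms > 1) {
    for (k in 2:n_terms) {
      eligible <- which(depth[seq_len(k - 1)] < max_depth)
      par1 <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      depth[k] <- depth[par1] + 1L
      parents <- par1
      # occasional second parent keeps the graph a DAG rather than a tree
      extra <- which(depth[seq_len(k - 1)] < depth[k] & seq_len(k - 1) != par1)
      if (length(extra) > 0 && stats::runif(1) < 0.3)
        parents <- c(parents, if (length(extra) == 1) extra else sample(extra, 1))
      edges <- rbind(edges, data.frame(child = ids[k], parent = ids[parents],
                                       stringsAsFactors = FALSE))
    }
  }
  dag <- go_dag(edges, terms = ids)
  ann <- NULL
  if (n_terms == 1) {
    keep <- stats::runif(length(genes)) < min(1, annotation_density * 5)
    if (!any(keep)) keep[1] <- TRUE
    ann <- data.frame(gene = genes[keep], term = ids[1], stringsAsFactors = FALSE)
  } else {
    hit <- matrix(stats::runif(length(genes) * (n_terms - 1)) < annotation_density,
                  length(genes), n_terms - 1)
    idx <- which(hit, arr.ind = TRUE)
    ann <- data.frame(gene = genes[idx[, 1]], term = ids[idx[, 2] + 1L],
                      stringsAsFactors = FALSE)
    orphan <- setdiff(genes, ann$gene)
    if (length(orphan) > 0)
      ann <- rbind(ann, data.frame(gene = orphan,
                                   term = sample(ids[-1], length(orphan), replace = TRUE),
                                   stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$gene, ann$term), ]
  rownames(ann) <- NULL
  if (length(enriched_terms) > 0 && !all(names(enriched_terms) %in% ids))
    stop("enriched_terms refer to unknown term ids")
  list(dag = dag, annotations = ann, enriched = enriched_terms)
}

#' Simulate per-gene scores with planted enrichment
#'
#' Null genes receive Uniform(0, 1) scores; genes annotated (after
#' propagation) to an enriched term of strength s receive Beta(1, s) scores,
#' which concentrate near 0 as s grows (s = 1 is null).
#'
#' @param go output of [simulate_go()].
#' @param genes genes to score; defaults to all annotated genes.
#' @param seed integer seed.
#' @return named numeric vector of scores in [0, 1].
#' @export
simulate_gene_scores <- function(go, genes = NULL, seed = 1L) {
  if (is.null(genes)) genes <- sort(unique(go$annotations$gene))
  set.seed(seed)
  scores <- stats::setNames(stats::runif(length(genes)), genes)
  if (length(go$enriched) > 0) {
    ann <- propagate_annotations(go$dag, go$annotations)
    for (term in names(go$enriched)) {
      s <- go$enriched[[term]]
      g <- intersect(ann$term_genes[[term]], genes)
      if (length(g) > 0) scores[g] <- stats::rbeta(length(g), 1, s)
    }
  }
  scores
}
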