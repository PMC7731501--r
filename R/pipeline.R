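config_error <- function(...) {
  stop(structure(class = c("hz_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

data_error <- function(...) {
  stop(structure(class = c("hz_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Assemble a pipeline run configuration
#'
#' @param counts,lengths,metadata,soil,go_edges,annotations input file paths
#'   (only the ones a given stage needs must exist).
#' @param outdir output directory (created if missing).
#' @param seed integer seed recorded in the run metadata.
#' @param fdr_max,min_abs_log2fc,min_total_count DET thresholds.
#' @param k,lambda latent-factor count and ridge penalty for the
#'   gene-environment association.
#' @param alpha significance threshold for calibrated association p-values
#'   and enrichment reporting.
#' @param elim_cutoff,sim_threshold enrichment elimination cut-off and
#'   redundancy similarity threshold.
#' @param comparisons optional list of comparisons, each a list with fields
#'   label, zone, taxon_a, taxon_b.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(counts = NULL, lengths = NULL, metadata = NULL,
                       soil = NULL, go_edges = NULL, annotations = NULL,
                       outdir = "hzexpr_out", seed = 1L,
                       fdr_max = 0.001, min_abs_log2fc = 5,
                       min_total_count = 10, k = 2, lambda = 1e-5,
                       alpha = 0.05, elim_cutoff = 0.01, sim_threshold = 0.5,
                       comparisons = NULL) {
  if (fdr_max <= 0 || fdr_max > 1) config_error("fdr_max must be in (0, 1]")
  if (min_abs_log2fc < 0) config_error("min_abs_log2fc must be >= 0")
  if (lambda <= 0) config_error("lambda must be positive")
  if (alpha <= 0 || alpha > 1) config_error("alpha must be in (0, 1]")
  if (k < 0) config_error("k must be >= 0")
  for (p in c(counts, lengths, metadata, soil, go_edges, annotations))
    if (!is.null(p) && !file.exists(p)) config_error("missing input file: ", p)
  structure(list(counts = counts, lengths = lengths, metadata = metadata,
                 soil = soil, go_edges = go_edges, annotations = annotations,
                 outdir = outdir, seed = as.integer(seed), fdr_max = fdr_max,
                 min_abs_log2fc = min_abs_log2fc,
                 min_total_count = min_total_count, k = k, lambda = lambda,
                 alpha = alpha, elim_cutoff = elim_cutoff,
                 sim_threshold = sim_threshold, comparisons = comparisons),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    config_error("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  config$outdir
}

# append threshold/log lines; no timestamps so reruns are byte-identical
.log_lines <- function(config, ...) {
  cat(paste0(c(...), "\n", collapse = ""),
      file = file.path(config$outdir, "run.log"), append = TRUE)
}

.log_thresholds <- function(config, stage) {
  .log_lines(config, sprintf(
    "[%s] seed=%d fdr_max=%g min_abs_log2fc=%g min_total_count=%g k=%g lambda=%g alpha=%g elim_cutoff=%g sim_threshold=%g",
    stage, config$seed, config$fdr_max, config$min_abs_log2fc,
    config$min_total_count, config$k, config$lambda, config$alpha,
    config$elim_cutoff, config$sim_threshold))
}

.load_expression <- function(config) {
  if (is.null(config$counts) || is.null(config$lengths) ||
      is.null(config$metadata))
    config_error("counts, lengths and metadata paths are required")
  list(cm = read_counts(config$counts, config$lengths),
       metadata = read_metadata(config$metadata))
}

.samples_of <- function(metadata, zone, taxon) {
  metadata$sample[metadata$zone == zone & metadata$taxon == taxon]
}

.spec_from_taxa <- function(metadata, zone, taxon_a, taxon_b, label,
                            min_total_count) {
  a <- .samples_of(metadata, zone, taxon_a)
  b <- .samples_of(metadata, zone, taxon_b)
  if (length(a) < 2 || length(b) < 2)
    data_error("comparison group with < 2 samples in zone ", zone,
               " (", taxon_a, ": ", length(a), ", ", taxon_b, ": ",
               length(b), ")")
  comparison_spec(a, b, label = label, min_total_count = min_total_count)
}

#' Run the species-comparison analysis
#'
#' For each configured comparison (default: parentA vs parentB in every
#' zone): normalization, common dispersion, exact tests, BH adjustment and
#' the DET call; writes a per-comparison table and a combined summary table
#' with columns label, n_expressed, n_DET, pct_DET, n_up_A, n_up_B.
#'
#' @param config a [run_config()].
#' @return the summary data.frame (invisibly returns DE results as
#'   attribute \code{de}).
#' @export
run_species_comparison <- function(config) {
  dat <- .load_expression(config)
  .ensure_outdir(config)
  .log_thresholds(config, "compare")
  comps <- config$comparisons
  if (is.null(comps)) {
    comps <- lapply(unique(dat$metadata$zone), function(z)
      list(label = paste0("parentA vs parentB in ", z), zone = z,
           taxon_a = "parentA", taxon_b = "parentB"))
  }
  de_list <- list()
  rows <- list()
  for (cmp in comps) {
    spec <- .spec_from_taxa(dat$metadata, cmp$zone, cmp$taxon_a, cmp$taxon_b,
                            cmp$label, config$min_total_count)
    de <- run_exact_de(dat$cm, spec, fdr_max = config$fdr_max,
                       min_abs_log2fc = config$min_abs_log2fc)
    de_list[[cmp$label]] <- de
    write_tsv(de$table, file.path(config$outdir,
                                  paste0("de_", gsub("[^A-Za-z0-9]+", "_", cmp$label), ".tsv")))
    rows[[cmp$label]] <- data.frame(
      label = cmp$label, n_expressed = de$n_expressed, n_DET = de$n_DET,
      pct_DET = format_pct(de$n_DET, de$n_expressed),
      n_up_A = de$n_up_A, n_up_B = de$n_up_B, stringsAsFactors = FALSE)
    .log_lines(config, sprintf("[compare] %s: phi=%.5f n_expressed=%d n_DET=%d",
                               cmp$label, de$phi, de$n_expressed, de$n_DET))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  write_tsv(summary, file.path(config$outdir, "comparison_summary.tsv"))
  attr(summary, "de") <- de_list
  summary
}

#' Run the hybrid-zone inheritance analysis for one zone
#'
#' Performs the three pairwise comparisons (parents, and each parent against
#' the hybrids), classifies every transcript expressed in all three and
#' writes the per-transcript calls plus a mode-count summary.
#'
#' @param config a [run_config()].
#' @param zone zone label present in the metadata.
#' @return list with \code{calls}, \code{summary} and the three DE results.
#' @export
run_hybrid_zone <- function(config, zone) {
  dat <- .load_expression(config)
  .ensure_outdir(config)
  .log_thresholds(config, paste0("inherit:", zone))
  taxa <- unique(dat$metadata$taxon[dat$metadata$zone == zone])
  need <- c("parentA", "parentB", "hybrid")
  if (!all(need %in% taxa))
    data_error("zone ", zone, " lacks taxa: ",
               paste(setdiff(need, taxa), collapse = ", "))
  mk <- function(ta, tb, lab) .spec_from_taxa(dat$metadata, zone, ta, tb, lab,
                                              config$min_total_count)
  de_ab <- run_exact_de(dat$cm, mk("parentA", "parentB", paste0("A vs B in ", zone)),
                        fdr_max = config$fdr_max,
                        min_abs_log2fc = config$min_abs_log2fc)
  de_ah <- run_exact_de(dat$cm, mk("parentA", "hybrid", paste0("A vs H in ", zone)),
                        fdr_max = config$fdr_max,
                        min_abs_log2fc = config$min_abs_log2fc)
  de_bh <- run_exact_de(dat$cm, mk("parentB", "hybrid", paste0("B vs H in ", zone)),
                        fdr_max = config$fdr_max,
                        min_abs_log2fc = config$min_abs_log2fc)
  cls <- classify_zone(de_ab, de_ah, de_bh)
  write_tsv(cls$calls, file.path(config$outdir, paste0("inheritance_calls_", zone, ".tsv")))
  write_tsv(cls$summary, file.path(config$outdir, paste0("inheritance_summary_", zone, ".tsv")))
  .log_lines(config, sprintf("[inherit:%s] eligible=%d transgressive_total=%d",
                             zone, nrow(cls$calls),
                             attr(cls$summary, "transgressive_total")))
  c(cls, list(de_ab = de_ab, de_ah = de_ah, de_bh = de_bh))
}

#' Run the gene-environment association and enrichment for one zone
#'
#' Soil PCA gives the PC1 edaphic predictor; the ridge latent factor mixed
#' model is fitted to log2(FPKM + 1) of the zone's DET transcripts (DETs
#' from the parental comparison in that zone); association z-scores are
#' calibrated by the genomic inflation factor; calibrated p-values feed the
#' elim-KS enrichment and redundancy reduction when GO inputs are present.
#'
#' @param config a [run_config()].
#' @param zone zone label; soil sites must match the zone's sample ids.
#' @param all_transcripts if TRUE the response matrix covers every expressed
#'   transcript instead of DETs only.
#' @return list with \code{pca}, \code{lda}, \code{fit},
#'   \code{association} (data.frame with calibrated p), \code{lambda_gif},
#'   \code{enrichment}, \code{representatives}.
#' @export
run_env_association <- function(config, zone, all_transcripts = FALSE) {
  dat <- .load_expression(config)
  .ensure_outdir(config)
  .log_thresholds(config, paste0("associate:", zone))
  if (is.null(config$soil)) config_error("soil path is required")
  soil <- read_soil(config$soil)
  samples <- dat$metadata$sample[dat$metadata$zone == zone]
  if (length(samples) < 4) data_error("zone ", zone, " has too few samples")
  if (!all(samples %in% soil$site))
    data_error("soil table lacks sites for samples: ",
               paste(setdiff(samples, soil$site), collapse = ", "))
  soil <- soil[match(samples, soil$site), ]

  pca <- soil_pca(soil)
  lda <- tryCatch(soil_lda(soil), error = function(e) NULL)
  x <- pca$pc1[samples]

  spec <- .spec_from_taxa(dat$metadata, zone, "parentA", "parentB",
                          paste0("A vs B in ", zone), config$min_total_count)
  de <- run_exact_de(dat$cm, spec, fdr_max = config$fdr_max,
                     min_abs_log2fc = config$min_abs_log2fc)
  keep <- if (all_transcripts) de$table$transcript else
    de$table$transcript[de$table$is_DET]
  if (length(keep) < 2) data_error("fewer than 2 response transcripts in zone ", zone)
  sub <- dat$cm$counts[keep, samples, drop = FALSE]
  eff <- effective_lib_sizes(sub)
  fpkm <- compute_fpkm(sub, eff, lengths = dat$cm$lengths[keep])
  Y <- t(log_center(fpkm, pseudocount = 1, center_rows = FALSE))

  fit <- fit_lfmm_ridge(Y, x, K = config$k, lambda = config$lambda)
  assoc <- association_tests(fit)
  cal <- gif_calibrate(assoc$z, alpha = config$alpha)
  assoc$p_calibrated <- cal$p_calibrated
  assoc$significant <- cal$significant
  write_tsv(assoc, file.path(config$outdir, paste0("association_", zone, ".tsv")))
  write_tsv(data.frame(site = rownames(pca$scores), pca$scores,
                       stringsAsFactors = FALSE, check.names = FALSE),
            file.path(config$outdir, paste0("soil_pca_scores_", zone, ".tsv")))
  .log_lines(config, sprintf("[associate:%s] n_DET=%d lambda_gif=%.4f n_significant=%d",
                             zone, length(keep), cal$lambda_gif,
                             sum(cal$significant)))

  enr <- reps <- NULL
  if (!is.null(config$go_edges) && !is.null(config$annotations)) {
    dag <- read_go_edges(config$go_edges)
    ann <- propagate_annotations(dag, read_annotations(config$annotations))
    scores <- stats::setNames(assoc$p_calibrated, assoc$transcript)
    scores <- scores[names(scores) %in% unique(unlist(ann$term_genes))]
    if (length(scores) > 0) {
      enr <- elim_ks(scores, ann, dag, elim_cutoff = config$elim_cutoff)
      reps <- reduce_redundancy(enr, ann, dag,
                                sim_threshold = config$sim_threshold,
                                alpha = config$alpha)
      write_tsv(enr, file.path(config$outdir, paste0("enrichment_", zone, ".tsv")))
      write_tsv(reps, file.path(config$outdir, paste0("enrichment_representatives_", zone, ".tsv")))
    }
  }
  meta <- list(zone = zone, seed = config$seed, k = config$k,
               lambda = config$lambda, alpha = config$alpha,
               fdr_max = config$fdr_max,
               min_abs_log2fc = config$min_abs_log2fc,
               lambda_gif = cal$lambda_gif,
               n_response_transcripts = length(keep),
               n_significant = sum(cal$significant))
  jsonlite::write_json(meta, file.path(config$outdir, paste0("run_metadata_", zone, ".json")),
                       auto_unbox = TRUE, digits = NA)
  list(pca = pca, lda = lda, fit = fit, association = assoc,
       lambda_gif = cal$lambda_gif, enrichment = enr, representatives = reps)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates counts/lengths/metadata (via [simulate_counts()]), a matching
#' soil table whose sites are the sample ids, and a toy GO DAG with
#' annotations, then writes them all as plain-text files that round-trip
#' through the pipeline readers.
#'
#' @param outdir output directory.
#' @param config a [sim_config()]; a default is built from \code{seed}.
#' @param zone zone label.
#' @param seed integer seed used for every generator.
#' @return named list of written file paths (invisible).
#' @export
simulate_dataset <- function(outdir, config = NULL, zone = "zone1", seed = 1L) {
  if (is.null(config)) config <- sim_config(seed = seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- simulate_counts(config, zone = zone)
  r <- config$replicates_per_group
  soil <- simulate_soil(site_counts = c(parentA = r, parentB = r, hybrid = r),
                        seed = seed)
  # align soil sites with expression sample ids (taxon blocks match by construction)
  soil$site <- sim$metadata$sample[order(match(sim$metadata$taxon,
                                               c("parentA", "parentB", "hybrid")))]
  go <- simulate_go(n_terms = 30, max_depth = 4,
                    genes = rownames(sim$counts$counts),
                    annotation_density = 0.08, seed = seed)
  paths <- list(counts = file.path(outdir, "counts.tsv"),
                lengths = file.path(outdir, "lengths.tsv"),
                metadata = file.path(outdir, "metadata.tsv"),
                soil = file.path(outdir, "soil.csv"),
                go_edges = file.path(outdir, "go_edges.tsv"),
                annotations = file.path(outdir, "annotations.tsv"),
                truth = file.path(outdir, "truth.tsv"))
  write_counts(sim$counts, paths$counts, paths$lengths)
  write_tsv(sim$metadata, paths$metadata)
  utils::write.csv(soil, paths$soil, row.names = FALSE, quote = FALSE)
  edges <- do.call(rbind, lapply(go$dag$terms, function(t) {
    ps <- go$dag$parents[[t]]
    if (length(ps) == 0) NULL else data.frame(child = t, parent = ps,
                                              stringsAsFactors = FALSE)
  }))
  write_tsv(edges, paths$go_edges)
  write_tsv(go$annotations, paths$annotations)
  write_tsv(sim$truth$transcripts, paths$truth)
  invisible(paths)
}
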