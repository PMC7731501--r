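#' Build a GO-style DAG from child-parent edges
#'
#' Validates that the graph is acyclic with a single root and that every
#' non-root term has at least one parent, computes each term's depth
#' (longest path from the root) and the ancestor closure (including the term
#' itself) used by annotation propagation and semantic similarity.
#'
#' @param edges data.frame with columns child, parent (is_a links); NULL for
#'   a single-term DAG.
#' @param terms optional full term id vector (to include isolated terms only
#'   when the DAG is a single root).
#' @param term_names optional named character vector of term names.
#' @return object of class \code{go_dag} with elements \code{terms},
#'   \code{names}, \code{parents}, \code{children}, \code{depth},
#'   \code{ancestors}, \code{root}.
#' @export
go_dag <- function(edges = NULL, terms = NULL, term_names = NULL) {
  if (!is.null(edges) && nrow(edges) > 0) {
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        stringsAsFactors = FALSE)
    terms <- union(terms, union(edges$child, edges$parent))
  }
  if (is.null(terms) || length(terms) == 0) stop("no terms")
  if (anyDuplicated(terms)) stop("duplicate term ids")
  parents <- stats::setNames(vector("list", length(terms)), terms)
  children <- parents
  if (!is.null(edges) && nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      parents[[edges$child[i]]] <- union(parents[[edges$child[i]]], edges$parent[i])
      children[[edges$parent[i]]] <- union(children[[edges$parent[i]]], edges$child[i])
    }
  }
  roots <- terms[vapply(parents, length, integer(1)) == 0]
  if (length(roots) != 1)
    stop("DAG must have exactly one root; found: ", length(roots))
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  state <- stats::setNames(integer(length(terms)), terms)  # 0 new, 1 active, 2 done
  calc_depth <- function(t) {
    if (state[[t]] == 1L) stop("cycle detected at term ", t)
    if (state[[t]] == 2L) return(depth[[t]])
    state[[t]] <<- 1L
    d <- if (length(parents[[t]]) == 0) 0L else
      1L + max(vapply(parents[[t]], calc_depth, integer(1)))
    depth[[t]] <<- d
    state[[t]] <<- 2L
    d
  }
  for (t in terms) calc_depth(t)
  anc <- stats::setNames(vector("list", length(terms)), terms)
  done <- stats::setNames(logical(length(terms)), terms)
  calc_anc <- function(t) {
    if (done[[t]]) return(anc[[t]])
    a <- t
    for (p in parents[[t]]) a <- union(a, calc_anc(p))
    anc[[t]] <<- a
    done[[t]] <<- TRUE
    a
  }
  for (t in terms) calc_anc(t)
  if (is.null(term_names)) term_names <- stats::setNames(terms, terms)
  structure(list(terms = terms, names = term_names, parents = parents,
                 children = children, depth = depth, ancestors = anc,
                 root = roots),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", length(x$terms), "terms, root", x$root,
      ", max depth", max(x$depth), "\n")
  invisible(x)
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' Every gene directly annotated to a term is annotated to all of that
#' term's ancestors. Information content is computed from the propagated
#' counts as IC(t) = -log(n_t / n_root); terms with no propagated genes get
#' NA and are flagged.
#'
#' @param dag a [go_dag()].
#' @param direct data.frame with columns gene, term (direct annotations).
#' @return object of class \code{annotation_set} with \code{gene_terms}
#'   (direct, per gene), \code{term_genes} (propagated, per term),
#'   \code{n_genes}, \code{ic}, \code{undefined_ic}, \code{root}.
#' @export
propagate_annotations <- function(dag, direct) {
  stopifnot(inherits(dag, "go_dag"))
  direct <- data.frame(gene = as.character(direct$gene),
                       term = as.character(direct$term),
                       stringsAsFactors = FALSE)
  unknown <- setdiff(unique(direct$term), dag$terms)
  if (length(unknown) > 0)
    stop("unknown term id: ", paste(unknown, collapse = ", "))
  term_genes <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  if (nrow(direct) > 0) {
    # expand each direct annotation over the term's ancestor closure
    per_term <- split(direct$gene, direct$term)
    for (t in names(per_term)) {
      for (a in dag$ancestors[[t]])
        term_genes[[a]] <- union(term_genes[[a]], per_term[[t]])
    }
  }
  term_genes <- lapply(term_genes, function(g) sort(g %||% character(0)))
  n <- vapply(term_genes, length, integer(1))
  n_root <- n[[dag$root]]
  ic <- if (n_root > 0) -log(n / n_root) else rep(NA_real_, length(n))
  ic[n == 0] <- NA_real_
  names(ic) <- dag$terms
  structure(list(gene_terms = split(direct$term, direct$gene),
                 term_genes = term_genes, n_genes = n, ic = ic,
                 undefined_ic = names(ic)[is.na(ic)], root = dag$root),
            class = "annotation_set")
}

# one-sided two-sample KS p-value: are x's scores stochastically smaller
# than y's? (alternative "greater": CDF of x lies above that of y)
.ks_smaller_p <- function(x, y) {
  if (length(y) == 0 || length(x) == 0) return(1)
  suppressWarnings(stats::ks.test(x, y, alternative = "greater")$p.value)
}

#' GO enrichment by classic and elim Kolmogorov-Smirnov tests
#'
#' Scores are p-value-like (smaller = more interesting). Terms are processed
#' in decreasing depth order; each is tested by a one-sided two-sample KS
#' test of its currently retained genes' scores against all other scored
#' genes. When a term's p-value falls below \code{elim_cutoff}, its genes
#' are eliminated from the retained sets of all its ancestors before those
#' are tested (the elim rule); classic KS p-values are computed on the full
#' propagated sets for comparison. \code{elim_cutoff = 0} disables
#' elimination, making the elim column identical to the classic one.
#'
#' @param scores named numeric vector in [0, 1], gene -> score.
#' @param ann an [propagate_annotations()] result.
#' @param dag the matching [go_dag()].
#' @param elim_cutoff p-value below which a term's genes are eliminated from
#'   its ancestors.
#' @param min_genes terms with fewer scored (retained) genes are skipped
#'   (p-value NA).
#' @return data.frame of class \code{enrichment_result}: term, name,
#'   n_annotated (scored genes on the full set), n_retained, classic_p,
#'   elim_p, ordered by elim_p.
#' @export
elim_ks <- function(scores, ann, dag, elim_cutoff = 0.01, min_genes = 5) {
  if (length(scores) == 0) stop("empty score list")
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  scored <- names(scores)
  full <- lapply(ann$term_genes, intersect, scored)
  retained <- full
  ord <- order(-dag$depth, dag$terms)
  terms <- dag$terms[ord]
  classic_p <- elim_p <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (t in terms) {
    g_full <- full[[t]]
    if (length(g_full) >= min_genes)
      classic_p[t] <- .ks_smaller_p(scores[g_full],
                                    scores[setdiff(scored, g_full)])
    g <- retained[[t]]
    if (length(g) >= min_genes) {
      p <- .ks_smaller_p(scores[g], scores[setdiff(scored, g)])
      elim_p[t] <- p
      if (!is.na(p) && p < elim_cutoff) {
        for (a in setdiff(dag$ancestors[[t]], t))
          retained[[a]] <- setdiff(retained[[a]], g)
      }
    }
  }
  out <- data.frame(term = terms,
                    name = unname(dag$names[terms]),
                    n_annotated = vapply(full[terms], length, integer(1)),
                    n_retained = vapply(retained[terms], length, integer(1)),
                    classic_p = unname(classic_p),
                    elim_p = unname(elim_p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$elim_p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Lin semantic similarity between two terms
#'
#' sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2)) where MICA is the common
#' ancestor (ancestor closures include the terms themselves) of maximal
#' information content.
#'
#' @param t1,t2 term ids.
#' @param ann an [propagate_annotations()] result.
#' @param dag the matching [go_dag()].
#' @return similarity in [0, 1].
#' @export
lin_similarity <- function(t1, t2, ann, dag) {
  if (is.na(ann$ic[[t1]]) || is.na(ann$ic[[t2]]))
    stop("term without defined information content: ",
         paste(c(t1, t2)[is.na(ann$ic[c(t1, t2)])], collapse = ", "))
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  mica_ic <- if (length(common) == 0) 0 else max(ann$ic[common], na.rm = TRUE)
  denom <- ann$ic[[t1]] + ann$ic[[t2]]
  if (denom == 0) return(1)
  2 * mica_ic / denom
}

#' Reduce an enriched-term list to non-redundant representatives
#'
#' Greedy sweep in ascending p-value order (ties broken by larger
#' information content, then lexicographic term id): a term is kept as a
#' representative iff its Lin similarity to every already-kept term is at
#' most \code{sim_threshold}.
#'
#' @param result an [elim_ks()] result (or data.frame with term and a
#'   p-value column).
#' @param ann,dag annotation set and DAG.
#' @param sim_threshold similarity above which a term is redundant.
#' @param alpha only terms with p below alpha are considered.
#' @param p_col which p-value column drives selection and ordering.
#' @return the significant subset of \code{result} with a logical
#'   \code{representative} column added.
#' @export
reduce_redundancy <- function(result, ann, dag, sim_threshold = 0.5,
                              alpha = 0.05, p_col = "elim_p") {
  p <- result[[p_col]]
  sig <- result[!is.na(p) & p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    sig$representative <- logical(0)
    return(sig)
  }
  ic <- ann$ic[sig$term]
  ord <- order(sig[[p_col]], -ic, sig$term)
  sig <- sig[ord, , drop = FALSE]
  kept <- character(0)
  rep_flag <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    t <- sig$term[i]
    sims <- vapply(kept, function(k) lin_similarity(t, k, ann, dag), numeric(1))
    if (all(sims <= sim_threshold)) {
      kept <- c(kept, t)
      rep_flag[i] <- TRUE
    }
  }
  sig$representative <- rep_flag
  rownames(sig) <- NULL
  sig
}
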