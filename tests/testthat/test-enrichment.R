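# three-term chain with signal genes only on the leaf: the defining elim fixture
chain_fixture <- function() {
  dag <- go_dag(data.frame(child = c("GO:0000002", "GO:0000003"),
                           parent = c("GO:0000001", "GO:0000002")))
  genes <- paste0("g", sprintf("%02d", 1:60))
  direct <- data.frame(
    gene = genes,
    term = c(rep("GO:0000003", 15), rep("GO:0000002", 15), rep("GO:0000001", 30)))
  ann <- propagate_annotations(dag, direct)
  scores <- stats::setNames(numeric(60), genes)
  scores[1:15] <- seq(0.0005, 0.008, length.out = 15)      # leaf signal
  # parent-only and root-only genes both span the null range evenly
  vals <- seq(0.02, 0.99, length.out = 45)
  scores[16:30] <- vals[seq(1, 45, by = 3)]
  scores[31:60] <- vals[-seq(1, 45, by = 3)]
  list(dag = dag, ann = ann, scores = scores)
}

test_that("DAG construction validates rootedness and acyclicity", {
  expect_error(go_dag(data.frame(child = "a", parent = "b"),
                      terms = c("a", "b", "c")), "exactly one root")
  cyc <- data.frame(child = c("a", "b", "r2"), parent = c("b", "a", "root"))
  expect_error(go_dag(cyc), "root|cycle")
  # a <-> b cycle under a root
  cyc3 <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(go_dag(rbind(cyc3, data.frame(child = c("a"), parent = "root"))),
               "cycle")
  d <- go_dag(data.frame(child = c("b", "c", "c"), parent = c("a", "a", "b")))
  expect_identical(d$root, "a")
  expect_equal(unname(d$depth[c("a", "b", "c")]), c(0, 1, 2))  # longest path
  expect_setequal(d$ancestors[["c"]], c("a", "b", "c"))
})

test_that("annotation propagation follows the true-path rule", {
  dag <- go_dag(data.frame(child = c("a", "b"), parent = c("root", "a")))
  ann <- propagate_annotations(dag, data.frame(gene = "g1", term = "b"))
  expect_identical(ann$term_genes[["b"]], "g1")
  expect_identical(ann$term_genes[["a"]], "g1")
  expect_identical(ann$term_genes[["root"]], "g1")
  expect_equal(ann$ic[["root"]], 0)
  expect_error(propagate_annotations(dag, data.frame(gene = "g", term = "zz")),
               "unknown term")
  # no annotations: empty sets, IC flagged undefined
  ann0 <- propagate_annotations(dag, data.frame(gene = character(0),
                                                term = character(0)))
  expect_true(all(lengths(ann0$term_genes) == 0))
  expect_setequal(ann0$undefined_ic, dag$terms)
})

test_that("parent gene sets contain every child's set on random DAGs", {
  for (seed in 1:4) {
    go <- simulate_go(n_terms = 30, max_depth = 4, genes = paste0("g", 1:50),
                      annotation_density = 0.1, seed = seed)
    ann <- propagate_annotations(go$dag, go$annotations)
    for (t in go$dag$terms) {
      for (p in go$dag$parents[[t]])
        expect_true(all(ann$term_genes[[t]] %in% ann$term_genes[[p]]))
    }
    # IC never decreases from parent to child (when defined)
    for (t in go$dag$terms) {
      for (p in go$dag$parents[[t]]) {
        if (!is.na(ann$ic[[t]]) && !is.na(ann$ic[[p]]))
          expect_gte(ann$ic[[t]], ann$ic[[p]] - 1e-12)
      }
    }
  }
})

test_that("elim-KS flags only the signal leaf while classic KS also flags its parent", {
  fx <- chain_fixture()
  res <- elim_ks(fx$scores, fx$ann, fx$dag, elim_cutoff = 0.01)
  p <- function(col, term) res[res$term == term, col]
  expect_lt(p("classic_p", "GO:0000003"), 0.05)
  expect_lt(p("classic_p", "GO:0000002"), 0.05)
  expect_lt(p("elim_p", "GO:0000003"), 0.05)
  expect_gt(p("elim_p", "GO:0000002"), 0.05)
  # the leaf's genes were removed from the parent, not vice versa
  expect_equal(p("n_retained", "GO:0000002"), 15)
  expect_equal(p("n_retained", "GO:0000003"), 15)
  # manual KS statistic for the leaf agrees with the test's internals
  d_manual <- oracle_ks_dplus(fx$scores[1:15], fx$scores[16:60])
  ks <- suppressWarnings(stats::ks.test(fx$scores[1:15], fx$scores[16:60],
                                        alternative = "greater"))
  expect_equal(unname(ks$statistic), d_manual, tolerance = 1e-12)
})

test_that("elim_cutoff = 0 reproduces classic KS exactly", {
  fx <- chain_fixture()
  res <- elim_ks(fx$scores, fx$ann, fx$dag, elim_cutoff = 0)
  expect_equal(res$elim_p, res$classic_p)
  for (seed in 1:3) {
    go <- simulate_go(n_terms = 25, max_depth = 4, genes = paste0("g", 1:40),
                      seed = seed)
    ann <- propagate_annotations(go$dag, go$annotations)
    sc <- simulate_gene_scores(go, seed = seed)
    r <- elim_ks(sc, ann, go$dag, elim_cutoff = 0, min_genes = 3)
    expect_equal(r$elim_p, r$classic_p)
  }
})

test_that("a term containing all scored genes is uninformative", {
  fx <- chain_fixture()
  res <- elim_ks(fx$scores, fx$ann, fx$dag, elim_cutoff = 0)
  expect_equal(res[res$term == "GO:0000001", "classic_p"], 1)
  expect_error(elim_ks(stats::setNames(numeric(0), character(0)),
                       fx$ann, fx$dag), "empty")
  bad <- fx$scores; bad[1] <- 1.5
  expect_error(elim_ks(bad, fx$ann, fx$dag), "\\[0, 1\\]")
})

test_that("elim-KS p-values stay uniform on signal-free scores", {
  go <- simulate_go(n_terms = 12, max_depth = 3, genes = paste0("g", 1:60),
                    annotation_density = 0.25, seed = 3)
  ann <- propagate_annotations(go$dag, go$annotations)
  ps <- c()
  for (rep in 1:60) {
    sc <- simulate_gene_scores(go, seed = 1000 + rep)
    r <- elim_ks(sc, ann, go$dag, elim_cutoff = 0.01)
    ps <- c(ps, r$elim_p[!is.na(r$elim_p) & r$classic_p < 1])
  }
  # discrete small-sample KS p-values are conservative rather than exactly
  # uniform; require no anti-conservative excess of small p-values
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif",
                                            alternative = "greater")$p.value),
            0.01)
})

test_that("Lin similarity hits its boundary cases", {
  dag <- go_dag(data.frame(child = c("a", "b", "a2"),
                           parent = c("root", "root", "a")))
  direct <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                       term = c("a2", "a2", "b", "b"))
  ann <- propagate_annotations(dag, direct)
  # parent and child with identical propagated sets are fully redundant
  expect_equal(lin_similarity("a", "a2", ann, dag), 1)
  # only common ancestor is the root (IC 0)
  expect_equal(lin_similarity("a", "b", ann, dag), 0)
  dag2 <- go_dag(data.frame(child = "c", parent = "root"))
  ann2 <- propagate_annotations(dag2, data.frame(gene = "g", term = "root"))
  expect_error(lin_similarity("root", "c", ann2, dag2), "information content")
})

test_that("redundancy reduction matches a brute-force greedy oracle on a toy DAG", {
  dag <- go_dag(data.frame(
    child = c("t1", "t2", "t3", "t4", "t5"),
    parent = c("root", "root", "t1", "t1", "t2")))
  genes <- paste0("g", 1:16)
  direct <- rbind(
    data.frame(gene = genes[1:4], term = "t3"),
    data.frame(gene = genes[5:8], term = "t4"),
    data.frame(gene = genes[9:12], term = "t5"),
    data.frame(gene = genes[13:16], term = "t2"))
  ann <- propagate_annotations(dag, direct)
  res <- data.frame(term = c("t1", "t2", "t3", "t4", "t5"),
                    elim_p = c(0.001, 0.002, 0.003, 0.004, 0.005))
  out <- reduce_redundancy(res, ann, dag, sim_threshold = 0.5, alpha = 0.05)
  # independent greedy sweep over p-sorted terms with pairwise constraint
  kept <- character(0)
  for (t in res$term[order(res$elim_p)]) {
    ok <- all(vapply(kept, function(k) lin_similarity(t, k, ann, dag),
                     numeric(1)) <= 0.5)
    if (ok) kept <- c(kept, t)
  }
  expect_identical(out$term[out$representative], kept)
  # deterministic under reruns
  expect_identical(out, reduce_redundancy(res, ann, dag, 0.5, 0.05))
  # alpha filters out non-significant terms entirely
  out2 <- reduce_redundancy(res, ann, dag, alpha = 0.0035)
  expect_setequal(out2$term, c("t1", "t2", "t3"))
})
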