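outcomes <- c("none", "first_higher", "second_higher")

test_that("pairwise_outcome rejects contradictory states", {
  expect_identical(pairwise_outcome(TRUE, "first_higher"), "first_higher")
  expect_identical(pairwise_outcome(FALSE), "none")
  expect_error(pairwise_outcome(TRUE, "none"), "direction")
  expect_error(pairwise_outcome(FALSE, "second_higher"), "contradictory")
})

test_that("worked decision-table cases classify as expected", {
  expect_identical(classify_transcript("none", "none", "none"), "conserved")
  # hybrid significantly higher than both parents
  expect_identical(classify_transcript("none", "second_higher", "second_higher"),
                   "transgressive_up")
  expect_identical(classify_transcript("first_higher", "first_higher", "first_higher"),
                   "transgressive_down")
  # hybrid above one parent, below the other
  expect_identical(classify_transcript("second_higher", "second_higher", "first_higher"),
                   "additive")
  # hybrid matches parent A, differs from parent B
  expect_identical(classify_transcript("second_higher", "none", "first_higher"),
                   "dominantA")
  expect_identical(classify_transcript("second_higher", "second_higher", "none"),
                   "dominantB")
  # parents differ, hybrid indistinguishable from both
  expect_identical(classify_transcript("first_higher", "none", "none"), "ambiguous")
})

test_that("every consistent outcome triple maps to exactly one mode, matching the rule oracle", {
  grid <- expand.grid(ab = outcomes, ah = outcomes, bh = outcomes,
                      stringsAsFactors = FALSE)
  got <- classify_transcript(grid$ab, grid$ah, grid$bh)
  want <- mapply(oracle_classify, grid$ab, grid$ah, grid$bh)
  expect_identical(got, unname(want))
  expect_true(all(got %in% c(inheritance_modes, "ambiguous")))
  expect_length(got, 27)
})

test_that("zone classification recovers planted modes and is label-symmetric", {
  cfg <- sim_config(n_transcripts = 400, replicates_per_group = 6,
                    mode_fractions = c(conserved = 0.4, additive = 0.12,
                                       dominantA = 0.12, dominantB = 0.12,
                                       transgressive_up = 0.12,
                                       transgressive_down = 0.12),
                    effect_log2fc = 6, dispersion = 0.1, seed = 11)
  sim <- simulate_counts(cfg)
  md <- sim$metadata
  a <- taxon_samples(md, "parentA"); b <- taxon_samples(md, "parentB")
  h <- taxon_samples(md, "hybrid")
  de_ab <- run_exact_de(sim$counts, comparison_spec(a, b, "ab"))
  de_ah <- run_exact_de(sim$counts, comparison_spec(a, h, "ah"))
  de_bh <- run_exact_de(sim$counts, comparison_spec(b, h, "bh"))
  cls <- classify_zone(de_ab, de_ah, de_bh)

  # completeness: one call per eligible transcript, counts add up
  expect_equal(sum(cls$summary$n), nrow(cls$calls))
  expect_false(any(is.na(cls$calls$mode)))

  truth <- sim$truth$transcripts
  m <- merge(cls$calls, truth, by = "transcript")
  expect_gte(mean(m$mode.x == m$mode.y), 0.9)

  # swapping parent labels exchanges the comparisons: ab mirrored, ah/bh swap
  cls_sw <- classify_zone(flip_de(de_ab), de_bh, de_ah)
  s1 <- cls$summary$n; names(s1) <- cls$summary$mode
  s2 <- cls_sw$summary$n; names(s2) <- cls_sw$summary$mode
  expect_identical(s2[["dominantA"]], s1[["dominantB"]])
  expect_identical(s2[["dominantB"]], s1[["dominantA"]])
  expect_identical(s2[["conserved"]], s1[["conserved"]])
  expect_identical(s2[["additive"]], s1[["additive"]])
  expect_identical(s2[["transgressive_up"]], s1[["transgressive_up"]])
  expect_identical(s2[["transgressive_down"]], s1[["transgressive_down"]])
})

test_that("an all-conserved zone yields no inheritance calls beyond FDR noise", {
  cfg <- sim_config(n_transcripts = 300, replicates_per_group = 4,
                    mode_fractions = c(conserved = 1), dispersion = 0.15,
                    seed = 29)
  sim <- simulate_counts(cfg)
  md <- sim$metadata
  a <- taxon_samples(md, "parentA"); b <- taxon_samples(md, "parentB")
  h <- taxon_samples(md, "hybrid")
  cls <- classify_zone(run_exact_de(sim$counts, comparison_spec(a, b)),
                       run_exact_de(sim$counts, comparison_spec(a, h)),
                       run_exact_de(sim$counts, comparison_spec(b, h)))
  n <- cls$summary$n; names(n) <- cls$summary$mode
  expect_lte(sum(n) - n[["conserved"]], ceiling(0.01 * sum(n)))
})

test_that("halving the true effect size cannot increase additive calls", {
  run_zone <- function(effect, seed) {
    cfg <- sim_config(n_transcripts = 200, replicates_per_group = 5,
                      mode_fractions = c(conserved = 0.5, additive = 0.5),
                      effect_log2fc = effect, dispersion = 0.1, seed = seed)
    sim <- simulate_counts(cfg)
    md <- sim$metadata
    a <- taxon_samples(md, "parentA"); b <- taxon_samples(md, "parentB")
    h <- taxon_samples(md, "hybrid")
    cls <- classify_zone(run_exact_de(sim$counts, comparison_spec(a, b)),
                         run_exact_de(sim$counts, comparison_spec(a, h)),
                         run_exact_de(sim$counts, comparison_spec(b, h)))
    n <- cls$summary$n; names(n) <- cls$summary$mode
    n[["additive"]]
  }
  expect_lte(run_zone(3, 37), run_zone(6, 37))
})

test_that("the transgressive total is the sum of its up and down components", {
  modes <- c(rep("transgressive_up", 525), rep("transgressive_down", 3),
             rep("conserved", 100))
  s <- inheritance_summary(modes)
  expect_equal(attr(s, "transgressive_total"), 528)
  n <- s$n; names(n) <- s$mode
  expect_equal(unname(n[["transgressive_up"]] + n[["transgressive_down"]]), 528)
})

test_that("disjoint transcript universes are rejected", {
  mk <- function(ids) {
    tab <- data.frame(transcript = ids, logFC = 0, p = 1, q = 1)
    call_dets(tab)
  }
  expect_error(classify_zone(mk(c("a", "b")), mk(c("c", "d")), mk(c("e"))),
               "share no")
})
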