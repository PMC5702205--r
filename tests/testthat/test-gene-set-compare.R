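test_that("cluster_loci forms single-linkage chains of overlapping spans", {
  a <- toy_model("A", start = 1L, end = 100L)
  b <- toy_model("B", start = 50L, end = 150L)
  cc <- toy_model("C", start = 140L, end = 200L)
  loci <- cluster_loci(list(a, b, cc))
  expect_length(loci, 1)
  expect_setequal(model_ids(loci[[1]]$members), c("A", "B", "C"))
  expect_equal(c(loci[[1]]$start, loci[[1]]$end), c(1L, 200L))
  ## opposite strands with strand_aware -> two loci
  d <- toy_model("D", start = 1L, end = 100L, strand = "+")
  e <- toy_model("E", start = 50L, end = 150L, strand = "-")
  expect_length(cluster_loci(list(d, e), strand_aware = TRUE), 2)
  expect_length(cluster_loci(list(d, e), strand_aware = FALSE), 1)
  ## disjoint and merely adjacent models stay separate
  f <- toy_model("F", start = 101L, end = 150L, strand = "+")
  loci2 <- cluster_loci(list(d, f))
  expect_length(loci2, 2)
  expect_equal(model_ids(loci2[[1]]$members), "D")
})

test_that("select_best_per_locus applies aed, length and source tie-breaks", {
  mk <- function(id, aed, len, src) {
    toy_model(id, start = 1L, end = 2000L, aed = aed, source_label = src,
              exons = data.frame(start = 1L, end = len),
              cds = data.frame(start = 1L, end = len))
  }
  loci <- cluster_loci(list(mk("x", 0.3, 900L, "orig_snap"),
                            mk("y", 0.1, 900L, "high_snap")))
  expect_equal(model_ids(select_best_per_locus(loci)), "y")
  loci2 <- cluster_loci(list(mk("x", 0.2, 900L, "orig_snap"),
                             mk("y", 0.2, 1200L, "high_snap")))
  expect_equal(model_ids(select_best_per_locus(loci2)), "y")
  ## full tie on aed and length -> declared source order wins
  loci3 <- cluster_loci(list(mk("x", 0.2, 900L, "low_aug"),
                             mk("y", 0.2, 900L, "high_snap")))
  expect_equal(model_ids(select_best_per_locus(loci3)), "y")
  expect_equal(model_ids(select_best_per_locus(
    loci3, source_order = c("low_aug", "high_snap"))), "x")
})

test_that("merged choice equals the exhaustive per-locus argmin", {
  sim <- simulate_genome(simulation_config(seed = 9L, n_genes = 120L,
                                           n_chromosomes = 2L,
                                           cds_mean = 450L, cds_sd = 90L))
  sources <- simulate_sources(sim)
  all_models <- do.call(c, unname(sources))
  merged <- select_best_per_locus(cluster_loci(all_models))
  expect_length(merged, nrow(sim$truth))
  ## oracle: per gene, the source with the smallest truth AED
  truth_best <- apply(sim$source_aed, 1L, function(r)
    colnames(sim$source_aed)[which.min(r)])
  got_src <- vapply(merged, `[[`, "", "source_label")
  got_gene <- sub("\\..*$", "", vapply(merged, `[[`, "", "gene_id"))
  expect_equal(stats::setNames(got_src, got_gene),
               stats::setNames(truth_best, sim$truth$gene_id)[got_gene])
})

test_that("find_novel requires zero-overlap against every reference", {
  q1 <- toy_model("q1", start = 100L, end = 200L)
  r1 <- toy_model("r1", start = 150L, end = 250L)
  expect_length(find_novel(list(q1), list(r1)), 0)
  q2 <- toy_model("q2", seqid = "chr2", start = 100L, end = 200L)
  expect_equal(model_ids(find_novel(list(q2), list(r1))), "q2")
  ## exactly 1 bp of overlap disqualifies
  r2 <- toy_model("r2", start = 200L, end = 300L)
  expect_length(find_novel(list(q1), list(r2)), 0)
  r3 <- toy_model("r3", start = 201L, end = 300L)
  expect_equal(model_ids(find_novel(list(q1), list(r3))), "q1")
  ## strand-agnostic by default
  r4 <- toy_model("r4", start = 150L, end = 250L, strand = "-")
  q3 <- toy_model("q3", start = 100L, end = 200L, strand = "+")
  expect_length(find_novel(list(q3), list(r4)), 0)
  expect_equal(model_ids(find_novel(list(q3), list(r4),
                                    strand_aware = TRUE)), "q3")
})

test_that("find_novel is empty on itself and antitone in references", {
  sim <- small_sim()
  models <- sim$models
  expect_length(find_novel(models, models), 0)
  half <- models[seq(1, length(models), by = 2)]
  n1 <- find_novel(models, list(half))
  n2 <- find_novel(models, list(half, models[1:100]))
  expect_true(all(model_ids(n2) %in% model_ids(n1)))
})

test_that("find_improved flags strict AED decreases from non-standard sources", {
  std <- toy_model("s1", start = 1L, end = 500L, aed = 0.4,
                   source_label = "orig_snap")
  better <- toy_model("h1", start = 1L, end = 500L, aed = 0.2,
                      source_label = "high_snap")
  imp <- find_improved(list(std), list(better))
  expect_equal(nrow(imp), 1)
  expect_equal(imp$standard_id, "s1")
  expect_equal(imp$replacement_id, "h1")
  expect_equal(c(imp$aed_before, imp$aed_after), c(0.4, 0.2))
  ## merged choice is the standard model itself -> not improved
  expect_equal(nrow(find_improved(list(std), list(std))), 0)
  ## equal aeds -> not improved (strict decrease)
  tie <- toy_model("h2", start = 1L, end = 500L, aed = 0.4,
                   source_label = "high_snap")
  expect_equal(nrow(find_improved(list(std), list(tie))), 0)
  ## non-overlapping alternative -> not improved
  far <- toy_model("h3", start = 2000L, end = 2500L, aed = 0.1,
                   source_label = "high_snap")
  expect_equal(nrow(find_improved(list(std), list(far))), 0)
})

test_that("find_improved matches truth on merged six-source annotations", {
  sim <- simulate_genome(simulation_config(seed = 10L, n_genes = 100L,
                                           n_chromosomes = 2L,
                                           cds_mean = 450L, cds_sd = 90L))
  sources <- simulate_sources(sim)
  std_sources <- c("orig_snap", "orig_aug")
  standard <- select_best_per_locus(
    cluster_loci(do.call(c, unname(sources[std_sources]))))
  merged <- select_best_per_locus(
    cluster_loci(do.call(c, unname(sources))))
  imp <- find_improved(standard, merged, standard_sources = std_sources)
  ## oracle from the truth table
  aeds <- sim$source_aed
  has_std <- rowSums(!is.na(aeds[, std_sources, drop = FALSE])) > 0
  best_std <- apply(aeds[, std_sources, drop = FALSE], 1L,
                    function(r) suppressWarnings(min(r, na.rm = TRUE)))
  best_all <- apply(aeds, 1L, min, na.rm = TRUE)
  winner <- colnames(aeds)[apply(aeds, 1L, which.min)]
  should <- has_std & !(winner %in% std_sources) & best_all < best_std
  expect_setequal(sub("\\.(orig|high|low)_(snap|aug)$", "",
                      imp$standard_id),
                  sim$truth$transcript_id[should])
  expect_true(all(imp$aed_after < imp$aed_before))
})
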