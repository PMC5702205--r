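test_that("simulators are pure functions of their configuration", {
  cfg <- simulation_config(seed = 33L, n_genes = 40L, n_chromosomes = 2L,
                           cds_mean = 450L, cds_sd = 90L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$source_aed, s2$source_aed)
  e1 <- simulate_evidence(s1)
  e2 <- simulate_evidence(s2)
  expect_identical(e1$expected_aed, e2$expected_aed)
  t1 <- simulate_te_tables(s1)
  t2 <- simulate_te_tables(s2)
  expect_identical(t1$gypsy_hits, t2$gypsy_hits)
  ## a different seed changes the genome
  s3 <- simulate_genome(simulation_config(seed = 34L, n_genes = 40L,
                                          n_chromosomes = 2L,
                                          cds_mean = 450L, cds_sd = 90L))
  expect_false(identical(as.character(s1$genome),
                         as.character(s3$genome)))
})

test_that("gene models are consistent with the genome and truth table", {
  sim <- small_sim()
  expect_equal(length(sim$models), nrow(sim$truth))
  cds <- extract_cds_sequences(sim$models, sim$genome)
  ## every CDS is a clean ORF in transcript orientation
  expect_true(all(substr(as.character(cds), 1, 3) == "ATG"))
  expect_true(all(Biostrings::width(cds) %% 3 == 0))
  last3 <- substr(as.character(cds), Biostrings::width(cds) - 2,
                  Biostrings::width(cds))
  expect_true(all(last3 %in% c("TAA", "TAG", "TGA")))
  ## realized GC lands within 3 points of the target (and in practice
  ## much closer)
  gc <- gc_content(cds)
  expect_true(all(abs(gc$gc_percent - sim$truth$target_gc) <= 3))
  expect_equal(gc$gc_percent, sim$truth$realized_gc, tolerance = 1e-9)
  ## genes do not overlap
  expect_length(cluster_loci(sim$models, strand_aware = FALSE),
                length(sim$models))
})

test_that("gene GC is uncorrelated with flanking genomic GC", {
  sim <- simulate_genome(simulation_config(seed = 77L, n_genes = 800L,
                                           cds_mean = 600L,
                                           cds_sd = 150L))
  flank <- t(vapply(sim$models, flanking_gc, numeric(2),
                    genome = sim$genome, flank_bp = 5000L))
  fl <- rowMeans(flank, na.rm = TRUE)
  ok <- !is.na(fl)
  r <- stats::cor(sim$truth$realized_gc[ok], fl[ok])
  expect_lt(abs(r), 0.1)
})

test_that("an effectively unimodal mixture fails cutoff detection", {
  sim <- simulate_genome(simulation_config(seed = 3L, n_genes = 250L,
                                           prop_low = 0.999,
                                           cds_mean = 450L, cds_sd = 90L))
  gc <- gc_content(extract_cds_sequences(sim$models, sim$genome))
  h <- smooth_histogram(build_gc_histogram(gc), 7)
  expect_error(determine_cutoffs(h, 5), "fewer than two")
})

test_that("simulated evidence induces the closed-form AED", {
  sim <- small_sim()
  ## no extension, no dropout -> perfect concordance
  e0 <- simulate_evidence(sim, extend = 0L, dropout = 0)
  expect_true(all(e0$expected_aed == 0))
  tab0 <- aed_table(sim$models, e0$evidence)
  expect_true(all(tab0$aed == 0))
  ## total dropout -> no evidence, AED 1 everywhere
  e1 <- simulate_evidence(sim, dropout = 1)
  expect_length(e1$evidence, 0)
  expect_true(all(e1$expected_aed == 1))
  ## default extension: closed form checked in test-aed.R against
  ## aed_table; here check the e=50 formula on one gene directly
  ev <- simulate_evidence(sim, dropout = 0)
  L <- sim$truth$length[1]
  expect_equal(unname(ev$expected_aed[1]),
               1 - (1 + L / (L + 100)) / 2, tolerance = 1e-12)
})

test_that("TE table simulation matches the declared thresholds", {
  sim <- simulate_genome(simulation_config(seed = 8L, n_genes = 120L,
                                           n_chromosomes = 2L,
                                           te_fraction = 0.25,
                                           cds_mean = 450L, cds_sd = 90L))
  tabs <- simulate_te_tables(sim)
  te_ids <- sim$truth$transcript_id[sim$truth$is_te]
  ## qualifying records only for TE genes
  strong_gypsy <- tabs$gypsy_hits$query_id[
    tabs$gypsy_hits$full_seq_evalue <= 1e-5]
  expect_true(all(strong_gypsy %in% te_ids))
  weak_gypsy <- tabs$gypsy_hits$query_id[
    tabs$gypsy_hits$full_seq_evalue > 1e-5]
  expect_false(any(weak_gypsy %in% te_ids))
  strong_tp <- tabs$transposase_hits$query_id[
    tabs$transposase_hits$evalue <= 1e-10]
  expect_true(all(strong_tp %in% te_ids))
  expect_true(all(unlist(tabs$te_refmap$query_ids) %in% te_ids))
  ## every TE gene has at least one qualifying record
  te_pf <- tabs$pfam_hits$query_id[
    tabs$pfam_hits$domain_accession %in% tabs$te_pfam_domains &
      tabs$pfam_hits$full_seq_evalue <= 1e-10]
  covered <- unique(c(strong_gypsy, strong_tp, te_pf,
                      unlist(tabs$te_refmap$query_ids)))
  expect_setequal(covered, te_ids)
  ## zero TE fraction -> nothing removed
  sim0 <- simulate_genome(simulation_config(seed = 8L, n_genes = 50L,
                                            n_chromosomes = 2L,
                                            te_fraction = 0,
                                            cds_mean = 450L,
                                            cds_sd = 90L))
  tabs0 <- simulate_te_tables(sim0)
  v <- te_filter(sim0$models, tabs0$te_pfam_domains, tabs0$pfam_hits,
                 tabs0$gypsy_hits, tabs0$transposase_hits,
                 tabs0$te_refmap)
  expect_true(all(v$kept))
})

test_that("simulation round-trips through the plain-text fixtures", {
  sim <- simulate_genome(simulation_config(seed = 14L, n_genes = 15L,
                                           n_chromosomes = 2L,
                                           cds_mean = 450L, cds_sd = 90L))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  genome <- read_fasta(paths[["genome"]])
  expect_identical(as.character(genome), as.character(sim$genome))
  models <- read_gff3(paths[["models"]])$models
  expect_setequal(model_ids(models), sim$truth$transcript_id)
  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(nrow(truth), 15)
})
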