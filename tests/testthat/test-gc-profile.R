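test_that("extract_cds_sequence splices and orients CDS correctly", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGCCCGGT", chr2 = "ATGC"))
  m <- toy_model(tid = "t1", start = 1L, end = 9L,
                 cds = data.frame(start = c(1L, 7L), end = c(3L, 9L)))
  expect_equal(as.character(extract_cds_sequence(m, genome)[[1]]),
               "ATGGGT")
  minus <- toy_model(tid = "t2", seqid = "chr2", start = 1L, end = 4L,
                     strand = "-", cds = data.frame(start = 1L, end = 4L))
  expect_equal(as.character(extract_cds_sequence(minus, genome)[[1]]),
               "GCAT")
  out <- toy_model(tid = "t3", seqid = "chr2", start = 5L, end = 10L,
                   cds = data.frame(start = 5L, end = 10L))
  expect_error(extract_cds_sequence(out, genome), "beyond")
  m$seqid <- "chrX"
  expect_error(extract_cds_sequence(m, genome), "not found")
  ## batched extraction agrees with one-at-a-time
  sim <- small_sim()
  idx <- c(1L, 50L, 149L)
  batch <- extract_cds_sequences(sim$models[idx], sim$genome)
  for (j in seq_along(idx)) {
    single <- extract_cds_sequence(sim$models[[idx[j]]], sim$genome)
    expect_equal(as.character(batch[[j]]), as.character(single[[1]]))
  }
})

test_that("gc_content counts composition and excludes N from denominator", {
  gc <- gc_content(c(a = "ATGCATGC", b = "GCGCGC", c = "ATGN",
                     d = "NNNN"))
  expect_equal(gc$gc_percent[1], 50)
  expect_equal(gc$gc_percent[2], 100)
  expect_equal(gc$gc_percent[3], 100 / 3, tolerance = 1e-12)
  expect_equal(gc$N[3], 1L)
  expect_true(is.na(gc$gc_percent[4]) && gc$flagged[4])
  expect_equal(gc$A + gc$C + gc$G + gc$T + gc$N, gc$length)
})

test_that("gc_content of extracted CDS is invariant under strand flip", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AATGGGCCCTTTACG"))
  m_plus <- toy_model(start = 3L, end = 11L,
                      cds = data.frame(start = 3L, end = 11L),
                      strand = "+")
  ## reverse-complement the genome and mirror the coordinates
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- "chr1"
  L <- Biostrings::width(genome)[1]
  m_minus <- toy_model(start = L - 11L + 1L, end = L - 3L + 1L,
                       cds = data.frame(start = L - 11L + 1L,
                                        end = L - 3L + 1L),
                       strand = "-")
  gc1 <- gc_content(extract_cds_sequence(m_plus, genome))
  gc2 <- gc_content(extract_cds_sequence(m_minus, rc))
  expect_equal(gc1$gc_percent, gc2$gc_percent)
})

test_that("histogram binning uses floor with 100 folded into bin 100", {
  h <- build_gc_histogram(c(47.2, 47.9, 68.0, 100, 0))
  expect_equal(h$raw[47 + 1], 2)
  expect_equal(h$raw[68 + 1], 1)
  expect_equal(h$raw[100 + 1], 1)
  expect_equal(h$raw[0 + 1], 1)
  expect_equal(sum(h$raw), 5)
  expect_equal(sum(build_gc_histogram(numeric(0))$raw), 0)
  expect_equal(sum(build_gc_histogram(runif(1000, 0, 100))$raw), 1000)
})

test_that("smoothing is a truncated centred moving average", {
  vals <- c(10, 0, 0, 30, 0, 0, 10)
  ## left edge: window truncated below bin 0
  h <- build_gc_histogram(rep(0:6, times = vals))
  hs <- smooth_histogram(h, 3)
  expect_equal(hs$smoothed[1:8],
               c(5, 10 / 3, 10, 10, 10, 10 / 3, 10 / 3, 10 / 3),
               tolerance = 1e-12)
  ## right edge: window truncated above bin 100
  h2 <- build_gc_histogram(rep(94:100, times = vals))
  expect_equal(smooth_histogram(h2, 3)$smoothed[95:101],
               c(10 / 3, 10 / 3, 10, 10, 10, 10 / 3, 5),
               tolerance = 1e-12)
  expect_equal(smooth_histogram(h, 1)$smoothed, as.numeric(h$raw))
  expect_error(smooth_histogram(h, 4), "odd")
  ## total mass is conserved up to edge effects: interior counts each
  ## contribute exactly 1, counts within w bins of an edge between
  ## 1 - w/101 and 1 + w/101 of their mass (smaller truncated windows)
  h3 <- build_gc_histogram(runif(500, 0, 100))
  for (w in c(3, 7, 11)) {
    s <- sum(smooth_histogram(h3, w)$smoothed)
    expect_lte(s, sum(h3$raw) * (1 + w / 101))
    expect_gte(s, sum(h3$raw) * (1 - w / 101))
  }
  ## with no mass near the edges conservation is exact
  h4 <- build_gc_histogram(runif(500, 20, 80))
  expect_equal(sum(smooth_histogram(h4, 7)$smoothed), sum(h4$raw),
               tolerance = 1e-9)
})

test_that("detect_peaks applies the strict two-sided window rule", {
  h <- hist_from_smoothed(c(1, 2, 5, 3, 2, 4, 8, 4, 1, rep(0, 92)))
  expect_equal(detect_peaks(h, 5), c(2L, 6L))
  mono <- hist_from_smoothed(c(1, 2, 3, 4, 5, rep(0, 96)))
  ## bins beyond the ramp are zero; only spurious max at bin 4 qualifies
  expect_equal(detect_peaks(mono, 3), 4L)
  plateau <- hist_from_smoothed(c(1, 3, 3, 1, rep(0, 97)))
  expect_equal(detect_peaks(plateau, 3), integer(0))
  expect_error(detect_peaks(h, 4), "odd")
})

test_that("detect_peaks matches the exhaustive oracle on random histograms", {
  set.seed(7)
  for (i in 1:200) {
    s <- if (i %% 2 == 0) runif(101, 0, 50) else
      smooth_histogram(build_gc_histogram(runif(300, 0, 100)), 7)$smoothed
    h <- hist_from_smoothed(s)
    for (w in c(3L, 5L, 7L)) {
      expect_identical(detect_peaks(h, w), oracle_peaks(s, w))
    }
  }
})

test_that("determine_cutoffs keeps the two tallest peaks in order", {
  s <- numeric(101)
  s[47 + 1] <- 900; s[68 + 1] <- 400
  expect_equal(unclass(determine_cutoffs(hist_from_smoothed(s), 5))[1:2],
               list(low_peak = 47L, high_peak = 68L))
  s2 <- numeric(101)
  s2[40 + 1] <- 100; s2[48 + 1] <- 900; s2[68 + 1] <- 400
  co <- determine_cutoffs(hist_from_smoothed(s2), 5)
  expect_equal(co$low_peak, 48L)
  expect_equal(co$high_peak, 68L)
  ## height tie broken toward the bin farther from 50
  s3 <- numeric(101)
  s3[45 + 1] <- 500; s3[48 + 1] <- 500; s3[70 + 1] <- 600
  co3 <- determine_cutoffs(hist_from_smoothed(s3), 5)
  expect_equal(co3$low_peak, 45L)
  unimodal <- hist_from_smoothed(c(numeric(50), 10, numeric(50)))
  expect_error(determine_cutoffs(unimodal, 5), "fewer than two")
})

test_that("flanking_gc reports truncated flanks and undefined edges", {
  chr <- paste(c(rep("G", 100), rep("A", 50), rep("C", 100)),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  m <- toy_model(start = 101L, end = 150L,
                 cds = data.frame(start = 101L, end = 150L))
  fg <- flanking_gc(m, genome, 100L)
  expect_equal(unname(fg), c(100, 100))
  m2 <- toy_model(start = 1L, end = 50L,
                  cds = data.frame(start = 1L, end = 50L))
  fg2 <- flanking_gc(m2, genome, 100L)
  expect_true(is.na(fg2[["upstream"]]))
  expect_equal(flanking_gc(m, genome, 0L),
               c(upstream = NA_real_, downstream = NA_real_))
})

test_that("profile outputs have the documented formats and round-trip", {
  sim <- small_sim()
  models <- sim$models[1:3]
  cds <- extract_cds_sequences(models, sim$genome)
  rec <- gc_content(cds)
  h <- smooth_histogram(build_gc_histogram(rec), 7)
  dir <- withr::local_tempdir()
  paths <- write_profile_outputs(rec, h, gc_cutoffs(47, 68), "toy",
                                 dir = dir, cds = cds)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  cut_lines <- readLines(paths[["cutoff"]])
  expect_equal(cut_lines, c("low\t47", "high\t68"))
  gl <- readLines(paths[["gc_content"]])
  expect_true(all(lengths(strsplit(gl, "\t")) == 8))
  back <- read_gc_content(paths[["gc_content"]])
  expect_equal(back$gc_percent, rec$gc_percent, tolerance = 1e-12)
  expect_equal(back$A, unname(rec$A))
  expect_equal(read_gc_cutoffs(paths[["cutoff"]])$low_peak, 47L)
  dist <- utils::read.delim(paths[["distribution"]])
  expect_equal(dist$raw, h$raw)
})
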