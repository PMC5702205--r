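## Shared fixture builders.  Everything is generated in code; the only
## frozen values are tiny hand-checked constants.

toy_model <- function(tid = "t1", seqid = "chr1", start = 101L,
                      end = 200L, strand = "+", cds = NULL, exons = NULL,
                      source_label = "est2genome", aed = NA_real_,
                      gene_id = paste0("g_", tid)) {
  if (is.null(cds)) cds <- data.frame(start = start, end = end)
  gene_model(gene_id, tid, seqid, start, end, strand = strand, cds = cds,
             exons = exons, source_label = source_label, aed = aed)
}

toy_evidence <- function(id = "ev1", seqid = "chr1", start = 101L,
                         end = 200L, kind = "transcript", strand = "*") {
  evidence_alignment(id, seqid, data.frame(start = start, end = end),
                     kind = kind, strand = strand)
}

## Brute-force per-base AED: explicit position sets, no interval algebra.
oracle_aed <- function(fp, ev_blocks) {
  a <- unlist(mapply(seq.int, fp$start, fp$end, SIMPLIFY = FALSE))
  b <- unlist(mapply(seq.int, ev_blocks$start, ev_blocks$end,
                     SIMPLIFY = FALSE))
  o <- length(intersect(a, b))
  1 - (o / length(b) + o / length(a)) / 2
}

## Exhaustive per-bin check of the peak rule on a smoothed vector
## (101 bins, 0-based): all (w-1)/2 bins on each side must exist and be
## strictly lower.
oracle_peaks <- function(smoothed, w) {
  half <- (w - 1L) / 2L
  out <- integer(0)
  for (b in 0:100) {
    i <- b + 1L
    if (i - half < 1L || i + half > 101L) next
    side <- smoothed[c((i - half):(i - 1L), (i + 1L):(i + half))]
    if (all(side < smoothed[i])) out <- c(out, b)
  }
  out
}

hist_from_smoothed <- function(smoothed) {
  h <- build_gc_histogram(numeric(0))
  h$smoothed <- smoothed
  h
}

## Small simulation shared across test files (computed once per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(simulation_config(
        seed = 42L, n_genes = 150L, n_chromosomes = 3L,
        cds_mean = 600L, cds_sd = 150L))
    }
    cache
  }
})

random_intervals <- function(n_max = 4L, lo = 1L, hi = 400L) {
  n <- sample.int(n_max, 1L)
  pts <- sort(sample.int(hi - lo, 2L * n, replace = FALSE) + lo)
  starts <- pts[seq(1L, 2L * n, by = 2L)]
  ends <- pts[seq(2L, 2L * n, by = 2L)]
  data.frame(start = starts, end = ends)
}
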