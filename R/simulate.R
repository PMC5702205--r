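#' Configuration for the synthetic-genome simulator
#'
#' Defaults emulate the statistical structure of a grass genome as these
#' methods assume it: per-gene CDS GC percent follows a two-component
#' normal mixture with modes near 47 and 68, gene GC is independent of
#' the GC of the flanking intergenic sequence (no isochores), evidence
#' alignments have controlled concordance, and a fraction of genes are
#' transposable-element decoys.
#'
#' @param seed integer seed; every simulator is a pure function of the
#'   configuration, so the same config yields byte-identical output.
#' @param n_genes number of genes (default 2000).
#' @param prop_low mixing proportion of the low-GC component (default
#'   0.6; the low-GC mode is the major one).
#' @param mu_low,sigma_low,mu_high,sigma_high component means/sds of CDS
#'   GC percent (defaults 47/3 and 68/3).
#' @param cds_mean,cds_sd,cds_min CDS length distribution in bp (normal,
#'   truncated at `cds_min`, rounded up to a multiple of 3; defaults
#'   900/300/300).
#' @param n_chromosomes number of genome sequences to spread genes over
#'   (default 5, exercising multi-sequence code paths).
#' @param intergenic_mean,intergenic_min intergenic spacer lengths in bp
#'   (log-normal around `intergenic_mean` plus `intergenic_min`; defaults
#'   1000/300).
#' @param intergenic_gc GC percent of intergenic sequence (default 43,
#'   drawn independently of neighbouring gene GC).
#' @param evidence_extend bases added to each terminal exon end of
#'   simulated evidence (default 50); for a single-exon gene of length L
#'   this induces `AED = 1 - (1 + L/(L + 2e))/2` exactly.
#' @param evidence_dropout fraction of genes with no evidence (default
#'   0.1).
#' @param te_fraction fraction of genes flagged as TE-related (default
#'   0.1).
#' @param n_sources number of predictor sources emulated (default 6).
#' @param source_present_prob probability each source predicts a given
#'   locus (default 0.8; at least one source always does).
#' @param n_tissues tissues for count simulation (default 3).
#' @param mean_depth target mean mRNA count per gene (default 1000).
#' @param nb_dispersion negative-binomial size parameter (default 100).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 2000L, prop_low = 0.6,
                              mu_low = 47, sigma_low = 3, mu_high = 68,
                              sigma_high = 3, cds_mean = 900L,
                              cds_sd = 300L, cds_min = 300L,
                              n_chromosomes = 5L, intergenic_mean = 1000L,
                              intergenic_min = 300L, intergenic_gc = 43,
                              evidence_extend = 50L,
                              evidence_dropout = 0.1, te_fraction = 0.1,
                              n_sources = 6L, source_present_prob = 0.8,
                              n_tissues = 3L, mean_depth = 1000,
                              nb_dispersion = 100) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  if (cfg$prop_low <= 0 || cfg$prop_low >= 1) {
    stop("prop_low must lie strictly between 0 and 1")
  }
  if (cfg$mu_low >= cfg$mu_high) stop("mu_low must be below mu_high")
  if (cfg$sigma_low <= 0 || cfg$sigma_high <= 0) {
    stop("component sds must be positive")
  }
  if (cfg$n_genes < 1L || cfg$n_chromosomes < 1L) {
    stop("n_genes and n_chromosomes must be positive")
  }
  if (cfg$cds_min < 9L) stop("cds_min must be at least 9 bp")
  if (cfg$te_fraction < 0 || cfg$te_fraction > 1 ||
      cfg$evidence_dropout < 0 || cfg$evidence_dropout > 1) {
    stop("fractions must lie in [0, 1]")
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> seed=%d n_genes=%d GC mixture ",
                     "%.1f%%@%g / %.1f%%@%g\n"),
              x$seed, x$n_genes, 100 * x$prop_low, x$mu_low,
              100 * (1 - x$prop_low), x$mu_high))
  invisible(x)
}

sample_bases <- function(n, p_gc) {
  if (n <= 0L) return(character(0))
  c("A", "T", "G", "C")[sample.int(4L, n, replace = TRUE,
                                   prob = c((1 - p_gc) / 2, (1 - p_gc) / 2,
                                            p_gc / 2, p_gc / 2))]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Generate one CDS of the given length with overall GC tuned to
## gc_target (a fraction).  GC is targeted mainly through third-position
## composition so encoded peptides stay realistic; a final correction
## pass flips third-position bases (never creating stop codons) until the
## realized GC count matches round(gc_target * len).  Returns a base
## vector (one element per nucleotide).
make_cds <- function(len, gc_target) {
  ncod <- len %/% 3L
  inner <- ncod - 2L
  if (inner < 1L) stop("CDS length must be at least 9 bp")
  p12 <- min(max(gc_target, 0.30), 0.70)
  p3 <- min(max(3 * gc_target - 2 * p12, 0.02), 0.98)
  b1 <- sample_bases(inner, p12)
  b2 <- sample_bases(inner, p12)
  b3 <- sample_bases(inner, p3)
  ta <- b1 == "T" & b2 == "A" & b3 %in% c("A", "G")
  if (any(ta)) b3[ta] <- sample(c("C", "T"), sum(ta), replace = TRUE)
  tga <- b1 == "T" & b2 == "G" & b3 == "A"
  if (any(tga)) b3[tga] <- sample(c("C", "G", "T"), sum(tga),
                                  replace = TRUE)
  stop_cod <- switch(sample.int(3L, 1L), c("T", "A", "A"),
                     c("T", "A", "G"), c("T", "G", "A"))
  is_gc <- function(x) x == "G" | x == "C"
  cur <- sum(is_gc(b1)) + sum(is_gc(b2)) + sum(is_gc(b3)) + 1L +
    sum(is_gc(stop_cod))
  delta <- round(gc_target * len) - cur
  eligible <- !(b1 == "T" & (b2 == "A" | b2 == "G"))
  if (delta > 0L) {
    cand <- which(eligible & !is_gc(b3))
    pick <- cand[seq_len(min(delta, length(cand)))]
    b3[pick] <- sample(c("G", "C"), length(pick), replace = TRUE)
  } else if (delta < 0L) {
    cand <- which(eligible & is_gc(b3))
    pick <- cand[seq_len(min(-delta, length(cand)))]
    b3[pick] <- sample(c("A", "T"), length(pick), replace = TRUE)
  }
  bases <- character(len)
  bases[seq.int(4L, len - 3L, by = 3L)] <- b1
  bases[seq.int(5L, len - 3L, by = 3L)] <- b2
  bases[seq.int(6L, len - 3L, by = 3L)] <- b3
  bases[1:3] <- c("A", "T", "G")
  bases[(len - 2L):len] <- stop_cod
  bases
}

#' Simulate a genome, its gene annotation and a truth table
#'
#' Genes are laid out without overlap on `n_chromosomes` sequences, on
#' both strands, separated by independent intergenic spacers whose GC is
#' unrelated to the neighbouring genes' GC.  Each gene is a single-exon
#' CDS generated codon-wise with its GC tuned to a target drawn from the
#' two-component mixture; the realized GC lands within a fraction of a
#' percent of the target.
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `gc_simulation`: `genome`
#'   ([Biostrings::DNAStringSet]), `models` (list of [gene_model()]),
#'   `truth` (data.frame: ids, coordinates, strand, length, `gc_class`,
#'   `target_gc`, `realized_gc`, `is_te`), `source_aed` (genes x sources
#'   matrix of true AEDs, `NA` where a source predicts nothing) and
#'   `cfg`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_genes
    low <- runif(n) < cfg$prop_low
    target <- ifelse(low, rnorm(n, cfg$mu_low, cfg$sigma_low),
                     rnorm(n, cfg$mu_high, cfg$sigma_high))
    target <- pmin(pmax(target, 20), 90)
    len <- pmax(cfg$cds_min, round(rnorm(n, cfg$cds_mean, cfg$cds_sd)))
    len <- as.integer(3L * ceiling(len / 3L))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- sort(rep(seq_len(cfg$n_chromosomes), length.out = n))
    cds_seq <- lapply(seq_len(n),
                      function(i) make_cds(len[i], target[i] / 100))
    realized <- vapply(seq_len(n), function(i) {
      100 * sum(cds_seq[[i]] == "G" | cds_seq[[i]] == "C") / len[i]
    }, 0)

    seqs <- character(cfg$n_chromosomes)
    start <- integer(n)
    end <- integer(n)
    meanlog <- log(cfg$intergenic_mean)
    for (cc in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom == cc)
      spacer_len <- cfg$intergenic_min +
        round(rlnorm(length(idx) + 1L, meanlog, 0.4))
      parts <- vector("list", 2L * length(idx) + 1L)
      pos <- 0L
      for (j in seq_along(idx)) {
        parts[[2L * j - 1L]] <- sample_bases(spacer_len[j],
                                             cfg$intergenic_gc / 100)
        pos <- pos + spacer_len[j]
        i <- idx[j]
        start[i] <- pos + 1L
        end[i] <- pos + len[i]
        parts[[2L * j]] <- if (strand[i] == "+") cds_seq[[i]]
                           else unname(rev(COMPLEMENT[cds_seq[[i]]]))
        pos <- pos + len[i]
      }
      parts[[2L * length(idx) + 1L]] <-
        sample_bases(spacer_len[length(idx) + 1L], cfg$intergenic_gc / 100)
      seqs[cc] <- paste(unlist(parts), collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(cfg$n_chromosomes))

    gene_id <- sprintf("G%05d", seq_len(n))
    tid <- paste0(gene_id, ".1")
    seqid <- paste0("chr", chrom)
    models <- lapply(seq_len(n), function(i) {
      iv <- intervals(start[i], end[i])
      gene_model(gene_id[i], tid[i], seqid[i], start[i], end[i],
                 strand = strand[i], cds = iv, exons = iv,
                 source_label = "est2genome")
    })

    is_te <- runif(n) < cfg$te_fraction
    labels <- DEFAULT_SOURCE_ORDER[seq_len(min(cfg$n_sources, 6L))]
    if (cfg$n_sources > 6L) {
      labels <- c(labels, paste0("src", 7:cfg$n_sources))
    }
    present <- matrix(runif(n * cfg$n_sources) < cfg$source_present_prob,
                      nrow = n)
    none <- which(rowSums(present) == 0L)
    for (i in none) present[i, sample(cfg$n_sources, 1L)] <- TRUE
    source_aed <- matrix(NA_real_, nrow = n, ncol = cfg$n_sources,
                         dimnames = list(tid, labels))
    source_aed[present] <- runif(sum(present), 0.01, 0.95)

    truth <- data.frame(
      gene_id = gene_id, transcript_id = tid, seqid = seqid,
      start = start, end = end, strand = strand, length = len,
      gc_class = ifelse(low, "low", "high"), target_gc = target,
      realized_gc = realized, is_te = is_te
    )
    structure(list(genome = genome, models = models, truth = truth,
                   source_aed = source_aed, cfg = cfg),
              class = "gc_simulation")
  })
}

#' @export
print.gc_simulation <- function(x, ...) {
  cat(sprintf("<gc_simulation> %d genes on %d sequence(s), seed=%d\n",
              nrow(x$truth), length(x$genome), x$cfg$seed))
  invisible(x)
}

#' Simulate evidence alignments with controlled concordance
#'
#' Each gene escapes dropout with probability `1 - dropout` and receives
#' one transcript-evidence alignment: its exons with each terminal end
#' extended by `extend` bases (clipped at sequence ends).  For a
#' single-exon gene of length L the induced AED is exactly
#' `1 - (1 + L/(L + 2e))/2`; dropped genes have expected AED 1.
#'
#' @param sim a `gc_simulation`.
#' @param extend,dropout override the config values.
#' @return list with `evidence` (list of [evidence_alignment()]) and
#'   `expected_aed` (named numeric vector over all transcripts).
#' @export
simulate_evidence <- function(sim, extend = NULL, dropout = NULL) {
  stopifnot(inherits(sim, "gc_simulation"))
  cfg <- sim$cfg
  if (is.null(extend)) extend <- cfg$evidence_extend
  if (is.null(dropout)) dropout <- cfg$evidence_dropout
  extend <- as.integer(extend)
  chr_len <- stats::setNames(Biostrings::width(sim$genome),
                             names(sim$genome))
  with_local_seed(cfg$seed + 1L, {
    tr <- sim$truth
    kept <- runif(nrow(tr)) >= dropout
    expected <- stats::setNames(rep(1, nrow(tr)), tr$transcript_id)
    evidence <- vector("list", sum(kept))
    j <- 0L
    for (i in which(kept)) {
      up <- max(1L, tr$start[i] - extend)
      dn <- min(chr_len[[tr$seqid[i]]], tr$end[i] + extend)
      j <- j + 1L
      evidence[[j]] <- evidence_alignment(
        evidence_id = paste0("ev_", tr$transcript_id[i]),
        seqid = tr$seqid[i],
        blocks = data.frame(start = up, end = dn),
        kind = "transcript", strand = tr$strand[i])
      ev_len <- dn - up + 1L
      expected[i] <- 1 - (1 + tr$length[i] / ev_len) / 2
    }
    list(evidence = evidence, expected_aed = expected)
  })
}

#' Build per-source model sets from the simulation truth
#'
#' Each predictor source contributes a model at every locus where the
#' truth table assigns it an AED, with coordinates copied from the true
#' gene, so per-locus merging can be checked against the truth exactly.
#'
#' @param sim a `gc_simulation`.
#' @return Named list (one element per source label) of gene-model lists.
#' @export
simulate_sources <- function(sim) {
  stopifnot(inherits(sim, "gc_simulation"))
  tr <- sim$truth
  labels <- colnames(sim$source_aed)
  out <- lapply(labels, function(lab) {
    idx <- which(!is.na(sim$source_aed[, lab]))
    lapply(idx, function(i) {
      iv <- intervals(tr$start[i], tr$end[i])
      gene_model(paste(tr$gene_id[i], lab, sep = "."),
                 paste(tr$transcript_id[i], lab, sep = "."),
                 tr$seqid[i], tr$start[i], tr$end[i],
                 strand = tr$strand[i], cds = iv, exons = iv,
                 source_label = lab,
                 aed = sim$source_aed[i, lab])
    })
  })
  stats::setNames(out, labels)
}

#' Default list of TE-associated Pfam accessions used by the simulator
#' @export
TE_PFAM_DOMAINS <- c("PF03732", "PF07727", "PF00078", "PF13456",
                     "PF03004", "PF13963")

REGULAR_PFAM_DOMAINS <- c("PF00069", "PF00067", "PF00076", "PF00153",
                          "PF00400", "PF07714")

runif_log10 <- function(n, lo, hi) 10^runif(n, lo, hi)

#' Simulate the four TE-filter input tables
#'
#' Genes flagged `is_te` in the truth table receive at least one
#' qualifying record (a Gypsy domain hit below 1e-5, a transposase
#' homology hit below 1e-10, a TE-listed Pfam domain below 1e-10, or a
#' reference-TE refmap entry); clean genes receive only sub-threshold
#' decoys or ordinary Pfam domains.  Feeding the tables to [te_filter()]
#' therefore removes exactly the truth TE set.
#'
#' @param sim a `gc_simulation`.
#' @return list with `pfam_hits`, `gypsy_hits`, `transposase_hits`,
#'   `te_refmap` data.frames and the `te_pfam_domains` vector used.
#' @export
simulate_te_tables <- function(sim) {
  stopifnot(inherits(sim, "gc_simulation"))
  tr <- sim$truth
  with_local_seed(sim$cfg$seed + 2L, {
    pfam <- list(); gypsy <- list(); tpase <- list(); refmap <- list()
    dom_hit <- function(id, name, acc, ev) {
      data.frame(query_id = id, domain_name = name,
                 domain_accession = acc, full_seq_evalue = ev,
                 domain_evalue = ev)
    }
    for (i in seq_len(nrow(tr))) {
      id <- tr$transcript_id[i]
      if (runif(1) < 0.5) {
        k <- sample(length(REGULAR_PFAM_DOMAINS), 1L)
        pfam[[length(pfam) + 1L]] <-
          dom_hit(id, paste0("Dom", k), REGULAR_PFAM_DOMAINS[k],
                  runif_log10(1, -30, -11))
      }
      if (tr$is_te[i]) {
        mech <- runif(4) < 0.5
        if (!any(mech)) mech[sample(4, 1L)] <- TRUE
        if (mech[1L]) {
          gypsy[[length(gypsy) + 1L]] <-
            dom_hit(id, "Gypsy", "GyDB_Ty3", runif_log10(1, -30, -5.2))
        }
        if (mech[2L]) {
          tpase[[length(tpase) + 1L]] <- data.frame(
            query_id = id, subject_id = "Tpase_0001",
            percent_identity = round(runif(1, 40, 95), 1),
            evalue = runif_log10(1, -50, -10.2))
        }
        if (mech[3L]) {
          k <- sample(length(TE_PFAM_DOMAINS), 1L)
          pfam[[length(pfam) + 1L]] <-
            dom_hit(id, paste0("TEDom", k), TE_PFAM_DOMAINS[k],
                    runif_log10(1, -30, -10.2))
        }
        if (mech[4L]) {
          refmap[[length(refmap) + 1L]] <- data.frame(
            ref_gene_id = sprintf("TE%05d", i),
            ref_transcript_id = sprintf("TE%05d.1", i),
            class_code = sample(c("=", "c", "j"), 1L),
            query_ids = I(list(id)))
        }
      } else {
        ## sub-threshold decoys that must never trigger removal
        if (runif(1) < 0.15) {
          gypsy[[length(gypsy) + 1L]] <-
            dom_hit(id, "Gypsy", "GyDB_Ty3", runif_log10(1, -4.8, -1))
        }
        if (runif(1) < 0.15) {
          tpase[[length(tpase) + 1L]] <- data.frame(
            query_id = id, subject_id = "Tpase_0001",
            percent_identity = round(runif(1, 30, 60), 1),
            evalue = runif_log10(1, -9.8, -2))
        }
        if (runif(1) < 0.1) {
          k <- sample(length(TE_PFAM_DOMAINS), 1L)
          pfam[[length(pfam) + 1L]] <-
            dom_hit(id, paste0("TEDom", k), TE_PFAM_DOMAINS[k],
                    runif_log10(1, -9.8, -3))
        }
      }
    }
    bindrows <- function(x, proto) {
      if (length(x) == 0L) proto else
        do.call(rbind, c(x, list(make.row.names = FALSE)))
    }
    list(
      pfam_hits = bindrows(pfam, dom_hit(character(0), character(0),
                                         character(0), numeric(0))),
      gypsy_hits = bindrows(gypsy, dom_hit(character(0), character(0),
                                           character(0), numeric(0))),
      transposase_hits = bindrows(tpase, data.frame(
        query_id = character(0), subject_id = character(0),
        percent_identity = numeric(0), evalue = numeric(0))),
      te_refmap = bindrows(refmap, data.frame(
        ref_gene_id = character(0), ref_transcript_id = character(0),
        class_code = character(0), query_ids = I(list()))),
      te_pfam_domains = TE_PFAM_DOMAINS)
  })
}

#' Simulate TRAP-seq and mRNA-seq count tables
#'
#' Per gene and tissue, negative-binomial counts are drawn around means
#' proportional to a per-gene abundance (mRNA) and that abundance times a
#' per-gene, per-tissue enrichment (TRAP).  The table of true TEI values
#' (the exact TPM ratio implied by the generating means) is returned so
#' recovery can be measured.
#'
#' @param sim a `gc_simulation`.
#' @param n_tissues,mean_depth,dispersion override the config values.
#' @return list with matrices `trap` and `mrna` (genes x tissues),
#'   `lengths`, `true_tei` and `tissues`.
#' @export
simulate_counts <- function(sim, n_tissues = NULL, mean_depth = NULL,
                            dispersion = NULL) {
  stopifnot(inherits(sim, "gc_simulation"))
  cfg <- sim$cfg
  if (is.null(n_tissues)) n_tissues <- cfg$n_tissues
  if (is.null(mean_depth)) mean_depth <- cfg$mean_depth
  if (is.null(dispersion)) dispersion <- cfg$nb_dispersion
  tr <- sim$truth
  n <- nrow(tr)
  tissues <- paste0("tissue", seq_len(n_tissues))
  with_local_seed(cfg$seed + 3L, {
    abund <- rlnorm(n, 0, 1)
    trap <- matrix(0, n, n_tissues,
                   dimnames = list(tr$transcript_id, tissues))
    mrna <- trap
    true_tei <- trap
    for (t in seq_len(n_tissues)) {
      enrich <- rlnorm(n, 0, 0.5)
      mu_m <- abund * tr$length
      mu_m <- mu_m * (mean_depth / mean(mu_m))
      mu_t <- abund * enrich * tr$length
      mu_t <- mu_t * (mean_depth / mean(mu_t))
      mrna[, t] <- rnbinom(n, mu = mu_m, size = dispersion)
      trap[, t] <- rnbinom(n, mu = mu_t, size = dispersion)
      ## exact TPM ratio implied by the generating rates
      rate_m <- mu_m / tr$length
      rate_t <- mu_t / tr$length
      true_tei[, t] <- (rate_t / sum(rate_t)) / (rate_m / sum(rate_m))
    }
    list(trap = trap, mrna = mrna,
         lengths = stats::setNames(tr$length, tr$transcript_id),
         true_tei = true_tei, tissues = tissues)
  })
}

#' Write a simulation to disk as plain-text fixtures
#'
#' @param sim a `gc_simulation`.
#' @param dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "gc_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             models = file.path(dir, "models.gff3"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$genome, paths[["genome"]])
  write_gff3(sim$models, paths[["models"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
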