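#' Read a GFF3 annotation file (MAKER dialect)
#'
#' Parses gene models (`gene`/`mRNA`/`exon`/`CDS`) and evidence alignment
#' chains (`match`-type features with `*match_part` children) from a GFF3
#' file, optionally returning sequences embedded after a `##FASTA`
#' directive.  Feature parsing is delegated to [rtracklayer::readGFF()];
#' this function assembles the package's gene-model and evidence objects
#' on top of it and enforces the referential checks the downstream
#' pipeline relies on.
#'
#' Evidence `kind` is taken from the source column prefix:
#' sources starting with `protein2genome` become `"protein"`, anything
#' else `"transcript"`.
#'
#' @param path path to a GFF3 file.
#' @param with_fasta also parse sequences following a `##FASTA` directive.
#' @return list with elements `models` (list of [gene_model()]),
#'   `evidence` (list of [evidence_alignment()]) and `sequences`
#'   (a [Biostrings::DNAStringSet], or `NULL`).
#' @export
read_gff3 <- function(path, with_fasta = FALSE) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- grep("^##FASTA\\s*$", lines)[1L]
  feat_limit <- if (is.na(fasta_at)) length(lines) else fasta_at - 1L
  feat_lines <- which(!startsWith(lines, "#") & nzchar(lines) &
                        seq_along(lines) <= feat_limit)

  if (length(feat_lines) == 0L) {
    sequences <- NULL
    if (!is.na(fasta_at) && fasta_at < length(lines)) {
      tf <- tempfile(fileext = ".fa")
      on.exit(unlink(tf), add = TRUE)
      writeLines(lines[(fasta_at + 1L):length(lines)], tf)
      sequences <- read_fasta(tf)
    }
    return(list(models = list(), evidence = list(),
                sequences = if (with_fasta) sequences else NULL))
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (nrow(g) != length(feat_lines)) feat_lines <- rep(NA_integer_, nrow(g))
  g$.line <- feat_lines
  if (!"ID" %in% names(g)) g$ID <- NA_character_
  if (!"Parent" %in% names(g)) g$Parent <- vector("list", nrow(g))
  g$parent1 <- vapply(g$Parent, function(p)
    if (length(p) >= 1L) as.character(p[[1L]]) else NA_character_, "")
  g$strand <- ifelse(as.character(g$strand) %in% c("+", "-"),
                     as.character(g$strand), "*")
  if (any(g$start < 1L | g$end < g$start)) {
    bad <- which(g$start < 1L | g$end < g$start)[1L]
    stop("GFF3 line ", g$.line[bad], ": invalid coordinates")
  }

  type <- as.character(g$type)
  mrna <- g[type == "mRNA", , drop = FALSE]
  if (anyDuplicated(mrna$ID)) {
    stop("duplicate transcript ID in ", path, ": ",
         mrna$ID[duplicated(mrna$ID)][1L])
  }
  kids <- g[type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- !(kids$parent1 %in% mrna$ID)
  if (any(orphan)) {
    i <- which(orphan)[1L]
    stop("GFF3 line ", kids$.line[i], ": ", kids$type[i],
         " references unknown parent '", kids$parent1[i], "'")
  }

  aed_col <- intersect(c("X_AED", "_AED"), names(g))[1L]
  models <- lapply(seq_len(nrow(mrna)), function(i) {
    r <- mrna[i, ]
    ch <- kids[kids$parent1 == r$ID, , drop = FALSE]
    cds <- ch[ch$type == "CDS", , drop = FALSE]
    ex <- ch[ch$type == "exon", , drop = FALSE]
    if (nrow(cds) == 0L) {
      stop("GFF3: mRNA '", r$ID, "' has no CDS children")
    }
    aed <- NA_real_
    if (!is.na(aed_col)) aed <- suppressWarnings(as.numeric(r[[aed_col]]))
    gene_model(
      gene_id = if (!is.na(r$parent1)) r$parent1 else r$ID,
      transcript_id = r$ID,
      seqid = as.character(r$seqid), start = r$start, end = r$end,
      strand = r$strand,
      cds = intervals(cds$start, cds$end),
      exons = if (nrow(ex) > 0L) intervals(ex$start, ex$end) else NULL,
      source_label = as.character(r$source),
      aed = aed
    )
  })

  ## evidence: any feature whose type ends in "match_part", chained by
  ## Parent (the MAKER match feature)
  mp <- g[grepl("match_part$", type), , drop = FALSE]
  evidence <- list()
  if (nrow(mp) > 0L) {
    key <- ifelse(is.na(mp$parent1), as.character(mp$ID), mp$parent1)
    for (id in unique(key)) {
      b <- mp[key == id, , drop = FALSE]
      if (length(unique(as.character(b$seqid))) > 1L) {
        stop("GFF3: evidence chain '", id, "' spans multiple sequences")
      }
      blk <- IRanges::reduce(IRanges::IRanges(b$start, b$end),
                             min.gapwidth = 0L)
      src <- as.character(b$source[1L])
      evidence[[length(evidence) + 1L]] <- evidence_alignment(
        evidence_id = id, seqid = as.character(b$seqid[1L]),
        blocks = data.frame(start = IRanges::start(blk),
                            end = IRanges::end(blk)),
        kind = if (startsWith(src, "protein2genome")) "protein"
               else "transcript",
        strand = if (length(unique(b$strand)) == 1L) b$strand[1L] else "*"
      )
    }
  }

  sequences <- NULL
  if (!is.na(fasta_at) && fasta_at < length(lines)) {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf), add = TRUE)
    writeLines(lines[(fasta_at + 1L):length(lines)], tf)
    sequences <- read_fasta(tf)
  }
  if (!is.null(sequences)) {
    w <- stats::setNames(Biostrings::width(sequences), names(sequences))
    for (m in models) {
      if (m$seqid %in% names(w) && m$end > w[[m$seqid]]) {
        stop("GFF3: model '", m$transcript_id,
             "' extends past the end of sequence '", m$seqid, "'")
      }
    }
  }
  list(models = models,
       evidence = evidence,
       sequences = if (with_fasta) sequences else NULL)
}

format_num <- function(x) {
  ifelse(is.na(x), ".", vapply(x, function(v) as.character(v), ""))
}

cds_phases <- function(cds, strand) {
  widths <- cds$end - cds$start + 1L
  ord <- if (identical(strand, "-")) rev(seq_len(nrow(cds)))
         else seq_len(nrow(cds))
  ph <- integer(nrow(cds))
  done <- 0L
  for (i in ord) {
    ph[i] <- (3L - done %% 3L) %% 3L
    done <- done + widths[i]
  }
  ph
}

#' Write gene models as canonical GFF3
#'
#' Emits a deterministic, byte-stable GFF3 dialect: tab-separated
#' nine-column records, `gene` -> `mRNA` -> `exon` -> `CDS` nesting, `ID`
#' and `Parent` attributes (plus `_AED` on mRNA features when the model
#' carries an AED), gene blocks sorted by (seqid, start, gene id), and
#' UNIX newlines.  `read_gff3(write_gff3(models))` reproduces the models,
#' and a second write of the re-read models is byte-identical.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  for (m in models) validate_gene_model(m)
  if (anyDuplicated(model_ids(models))) {
    stop("duplicate transcript IDs in model list")
  }
  sp <- model_spans(models)
  out <- "##gff-version 3"
  if (length(models) > 0L) {
    gene_key <- paste(sp$seqid, sp$gene_id, sep = "\r")
    gene_start <- tapply(sp$start, gene_key, min)
    gene_ord <- order(vapply(strsplit(names(gene_start), "\r"),
                             `[[`, "", 1L),
                      as.integer(gene_start),
                      vapply(strsplit(names(gene_start), "\r"),
                             `[[`, "", 2L))
    for (gk in names(gene_start)[gene_ord]) {
      idx <- which(gene_key == gk)
      idx <- idx[order(sp$start[idx], sp$transcript_id[idx])]
      g1 <- models[[idx[1L]]]
      gstart <- min(sp$start[idx])
      gend <- max(sp$end[idx])
      strand <- unique(sp$strand[idx])
      gstrand <- if (length(strand) == 1L) strand else "*"
      out <- c(out, paste(g1$seqid, g1$source_label, "gene", gstart, gend,
                          ".", gff_strand(gstrand), ".",
                          paste0("ID=", g1$gene_id), sep = "\t"))
      for (i in idx) {
        m <- models[[i]]
        attrs <- paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)
        if (!is.na(m$aed)) attrs <- paste0(attrs, ";_AED=",
                                           as.character(m$aed))
        out <- c(out, paste(m$seqid, m$source_label, "mRNA", m$start,
                            m$end, ".", gff_strand(m$strand), ".", attrs,
                            sep = "\t"))
        if (!is.null(m$exons)) {
          for (j in seq_len(nrow(m$exons))) {
            out <- c(out, paste(m$seqid, m$source_label, "exon",
                                m$exons$start[j], m$exons$end[j], ".",
                                gff_strand(m$strand), ".",
                                paste0("ID=", m$transcript_id, ":exon:", j,
                                       ";Parent=", m$transcript_id),
                                sep = "\t"))
          }
        }
        ph <- cds_phases(m$cds, m$strand)
        for (j in seq_len(nrow(m$cds))) {
          out <- c(out, paste(m$seqid, m$source_label, "CDS",
                              m$cds$start[j], m$cds$end[j], ".",
                              gff_strand(m$strand), ph[j],
                              paste0("ID=", m$transcript_id, ":cds:", j,
                                     ";Parent=", m$transcript_id),
                              sep = "\t"))
        }
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

gff_strand <- function(s) if (s %in% c("+", "-")) s else "."

#' Write evidence alignments as GFF3 match/match_part features
#'
#' @param evidence list of [evidence_alignment()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence_gff3 <- function(evidence, path) {
  out <- "##gff-version 3"
  if (length(evidence) > 0L) {
    ord <- order(vapply(evidence, `[[`, "", "seqid"),
                 vapply(evidence, function(e) min(e$blocks$start), 0L),
                 vapply(evidence, `[[`, "", "evidence_id"))
    for (e in evidence[ord]) {
      src <- if (e$kind == "protein") "protein2genome" else "est2genome"
      type <- if (e$kind == "protein") "protein_match"
              else "expressed_sequence_match"
      out <- c(out, paste(e$seqid, src, type, min(e$blocks$start),
                          max(e$blocks$end), ".", gff_strand(e$strand), ".",
                          paste0("ID=", e$evidence_id), sep = "\t"))
      for (j in seq_len(nrow(e$blocks))) {
        out <- c(out, paste(e$seqid, src, "match_part", e$blocks$start[j],
                            e$blocks$end[j], ".", gff_strand(e$strand), ".",
                            paste0("ID=", e$evidence_id, ":", j,
                                   ";Parent=", e$evidence_id),
                            sep = "\t"))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
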